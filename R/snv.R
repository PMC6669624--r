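#' Write alignments as a minimal SAM file
#'
#' Emits a header (`@HD`, `@SQ`) plus one line per alignment with the core
#' fields (QNAME, FLAG, RNAME, POS, MAPQ, CIGAR, RNEXT, PNEXT, TLEN, SEQ,
#' QUAL). CIGARs are restricted to M/I/D/S.
#'
#' @param alignments data.frame with columns `qname`, `flag`, `pos`, `cigar`,
#'   `seq` and optionally `qual` (defaults to `*`).
#' @param path output file.
#' @param ref_id reference sequence name.
#' @param ref_len reference length in bp.
#' @export
write_sam <- function(alignments, path, ref_id, ref_len) {
  qual <- if (is.null(alignments$qual)) "*" else alignments$qual
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", ref_id, "\tLN:", ref_len)), con)
  writeLines(paste(alignments$qname, alignments$flag, ref_id,
                   alignments$pos, 255L, alignments$cigar, "*", 0L, 0L,
                   alignments$seq, qual, sep = "\t"), con)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Parses the subset emitted by [write_sam()]: header lines are skipped and
#' the core alignment fields returned.
#'
#' @param path SAM file.
#' @return list with `ref_id`, `ref_len` (from the first `@SQ` line, `NA` if
#'   absent) and `alignments` (data.frame `qname`, `flag`, `pos`, `cigar`,
#'   `seq`, `qual`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  ref_id <- NA_character_; ref_len <- NA_integer_
  sq <- lines[grepl("^@SQ", lines)]
  if (length(sq)) {
    ref_id <- sub(".*\tSN:([^\t]+).*", "\\1", sq[1])
    ref_len <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq[1]))
  }
  body <- strsplit(lines[!hdr], "\t", fixed = TRUE)
  if (length(body) && any(lengths(body) < 11))
    stop("truncated SAM record (need 11 fields)")
  get <- function(k) vapply(body, `[[`, character(1), k)
  alignments <- data.frame(
    qname = get(1), flag = as.integer(get(2)), pos = as.integer(get(4)),
    cigar = get(6), seq = get(10), qual = get(11), stringsAsFactors = FALSE)
  list(ref_id = ref_id, ref_len = ref_len, alignments = alignments)
}

#' Build a per-position pileup from read alignments
#'
#' Walks each alignment's CIGAR (M/I/D/S only) and tallies A/C/G/T, deletion
#' and insertion-start counts per reference position. Insertions are
#' attributed to the reference base preceding the inserted run. Reads
#' overhanging the reference end are clipped with a warning; an unknown CIGAR
#' operation is an error. Coverage at a position is the sum of base counts
#' and deletion count.
#'
#' @param alignments a SAM file path, the list returned by [read_sam()], or a
#'   data.frame with columns `pos`, `cigar`, `seq`.
#' @param reference the reference sequence (string), or `NULL` to take the
#'   length from the SAM header (base identities then unavailable).
#' @param ref_id reference name (defaults to the SAM header's).
#' @return object of class `isovar_pileup`: list with `ref_id`, `ref`
#'   (character vector of reference bases or `NA`), `counts` (L x 6 integer
#'   matrix, columns A, C, G, T, del, ins) and `coverage` (integer vector).
#' @export
build_pileup <- function(alignments, reference = NULL, ref_id = "ref") {
  if (is.character(alignments) && length(alignments) == 1)
    alignments <- read_sam(alignments)
  if (is.list(alignments) && !is.data.frame(alignments) &&
      !is.null(alignments$alignments)) {
    if (!is.na(alignments$ref_id)) ref_id <- alignments$ref_id
    ref_len_hdr <- alignments$ref_len
    alignments <- alignments$alignments
  } else ref_len_hdr <- NA_integer_
  if (!is.null(reference)) {
    reference <- toupper(reference)
    L <- nchar(reference)
    ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  } else if (!is.na(ref_len_hdr)) {
    L <- ref_len_hdr
    ref <- rep(NA_character_, L)
  } else stop("need a reference sequence or a SAM @SQ header")
  counts <- .pileup_accumulate(L, as.integer(alignments$pos),
                               as.character(alignments$cigar),
                               toupper(as.character(alignments$seq)))
  clipped <- attr(counts, "clipped")
  if (!is.null(clipped) && clipped > 0)
    warning(clipped, " read(s) overhanging the reference end were clipped")
  attr(counts, "clipped") <- NULL
  colnames(counts) <- c("A", "C", "G", "T", "del", "ins")
  structure(list(ref_id = ref_id, ref = ref, counts = counts,
                 coverage = as.integer(rowSums(counts[, 1:5, drop = FALSE]))),
            class = "isovar_pileup")
}

#' @export
print.isovar_pileup <- function(x, ...) {
  cov <- x$coverage
  cat("Pileup over", x$ref_id, "(", length(cov), "bp )\n")
  cat(sprintf("  coverage mean %.1f (sd %.1f), min %d, max %d\n",
              mean(cov), stats::sd(cov), min(cov), max(cov)))
  invisible(x)
}

#' Write a pileup as TSV
#'
#' Columns: `pos`, `ref`, `A`, `C`, `G`, `T`, `gap`, `insertion_count`.
#'
#' @param pileup an `isovar_pileup`.
#' @param path output file.
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.frame(pos = seq_along(pileup$coverage), ref = pileup$ref,
                   A = pileup$counts[, "A"], C = pileup$counts[, "C"],
                   G = pileup$counts[, "G"], T = pileup$counts[, "T"],
                   gap = pileup$counts[, "del"],
                   insertion_count = pileup$counts[, "ins"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup_tsv()]
#' @param path TSV file.
#' @param ref_id reference name.
#' @return an `isovar_pileup`.
#' @export
read_pileup_tsv <- function(path, ref_id = "ref") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", rep("integer", 6)))
  counts <- as.matrix(df[, c("A", "C", "G", "T", "gap", "insertion_count")])
  colnames(counts) <- c("A", "C", "G", "T", "del", "ins")
  structure(list(ref_id = ref_id, ref = df$ref, counts = counts,
                 coverage = as.integer(rowSums(counts[, 1:5, drop = FALSE]))),
            class = "isovar_pileup")
}

#' Call intra-isolate single-nucleotide variants from a pileup
#'
#' The caller is the minimum variant-frequency rule: every (position,
#' alternate base) pair with frequency at least `min_frequency` (inclusive at
#' the boundary) and coverage at least `min_coverage` is reported, so one
#' position may yield several records (multi-allelic sites). Frequency is the
#' alternate-base count divided by total coverage (bases + deletions).
#' Covered positions whose reference base is not one of A/C/G/T are skipped
#' with a warning.
#'
#' @param pileup an `isovar_pileup` built against the focal genome.
#' @param min_frequency minimum variant frequency (default 0.1, inclusive).
#' @param min_coverage minimum total coverage (default 10).
#' @return data.frame of class `snv_records`: `position`, `ref`, `alt`,
#'   `variant_coverage`, `total_coverage`, `frequency`, ordered by position
#'   then alternate base.
#' @export
call_snvs <- function(pileup, min_frequency = 0.1, min_coverage = 10) {
  stopifnot(inherits(pileup, "isovar_pileup"))
  if (all(is.na(pileup$ref)))
    stop("pileup carries no reference bases; rebuild with a reference sequence")
  cov <- pileup$coverage
  bad_ref <- which(!(pileup$ref %in% c("A", "C", "G", "T")) & cov > 0)
  if (length(bad_ref))
    warning(length(bad_ref), " covered position(s) with non-ACGT reference skipped")
  bases <- c("A", "C", "G", "T")
  recs <- vector("list", 4)
  for (b in seq_along(bases)) {
    cnt <- pileup$counts[, bases[b]]
    ok <- cov >= min_coverage & cnt > 0 & pileup$ref %in% bases &
      pileup$ref != bases[b] & cnt / cov >= min_frequency
    ok[bad_ref] <- FALSE
    idx <- which(ok)
    if (length(idx))
      recs[[b]] <- data.frame(position = idx, ref = pileup$ref[idx],
                              alt = bases[b], variant_coverage = cnt[idx],
                              total_coverage = cov[idx],
                              frequency = cnt[idx] / cov[idx],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(position = integer(), ref = character(),
                      alt = character(), variant_coverage = integer(),
                      total_coverage = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snv_records", "data.frame")
  out
}

#' Annotate SNV records with coding effects
#'
#' Adds ORF id, codon-level classification and the amino-acid change string
#' (focal-to-variant direction) to each SNV via [annotate_effect()].
#'
#' @param snvs an `snv_records` data.frame from [call_snvs()].
#' @param genome the focal genome sequence (string).
#' @param orfs an `orf_table` for that genome.
#' @return the input with `orf_id`, `effect` and `aa_change` columns added.
#' @export
annotate_snvs <- function(snvs, genome, orfs) {
  n <- nrow(snvs)
  snvs$orf_id <- NA_character_
  snvs$effect <- character(n)
  snvs$aa_change <- character(n)
  for (i in seq_len(n)) {
    eff <- annotate_effect(genome, orfs, snvs$position[i], snvs$alt[i])
    snvs$orf_id[i] <- eff$orf_id
    snvs$effect[i] <- eff$class
    snvs$aa_change[i] <- eff$substitution
  }
  snvs
}

#' Summarise a read set and its pileup
#'
#' Fractions of bases at or above Q20/Q30/Q40 are computed from Phred+33
#' quality strings over all reads; coverage statistics come from the pileup.
#' An empty read set is reported with zero fractions and `empty = TRUE`.
#'
#' @param quals character vector of Phred+33 quality strings (one per read).
#' @param pileup optional `isovar_pileup` for coverage statistics.
#' @return object of class `read_quality_summary`: list with `total_reads`,
#'   `q20`, `q30`, `q40` (fractions in `[0,1]`), `empty`, and `coverage`
#'   (list mean/sd/min/max, when a pileup is given).
#' @export
summarize_reads <- function(quals, pileup = NULL) {
  if (!length(quals)) {
    out <- list(total_reads = 0L, q20 = 0, q30 = 0, q40 = 0, empty = TRUE,
                coverage = NULL)
  } else {
    phred <- unlist(lapply(quals, function(q) utf8ToInt(q) - 33L))
    out <- list(total_reads = length(quals),
                q20 = mean(phred >= 20), q30 = mean(phred >= 30),
                q40 = mean(phred >= 40), empty = FALSE, coverage = NULL)
  }
  if (!is.null(pileup)) {
    cov <- pileup$coverage
    out$coverage <- list(mean = mean(cov), sd = stats::sd(cov),
                         min = min(cov), max = max(cov))
  }
  structure(out, class = "read_quality_summary")
}

#' @export
print.read_quality_summary <- function(x, ...) {
  cat("Reads:", x$total_reads, "\n")
  cat(sprintf("  >= Q20: %.1f%%  >= Q30: %.1f%%  >= Q40: %.1f%%\n",
              100 * x$q20, 100 * x$q30, 100 * x$q40))
  if (!is.null(x$coverage))
    cat(sprintf("  coverage mean %.1f (sd %.1f), min %d, max %d\n",
                x$coverage$mean, x$coverage$sd, x$coverage$min, x$coverage$max))
  invisible(x)
}

#' Write SNV records as a tab-separated table
#'
#' @param snvs an `snv_records` data.frame (annotated or not).
#' @param path output file.
#' @export
write_snv_table <- function(snvs, path) {
  utils::write.table(as.data.frame(snvs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
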