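#' Classify SNVs against inter-isolate SNP columns
#'
#' Each intra-isolate SNV (focal genome frame) is assigned exactly one class:
#' `no_overlap` if its position is not a SNP column; `snp_overlap` if it is;
#' `unique_snp_overlap` if additionally the column is attributed uniquely to
#' the focal isolate and the SNV's alternate base equals the base carried by
#' the non-focal isolates there. In `"strict"` mode (default) all non-focal
#' isolates must share that base; in `"majority"` mode the majority non-focal
#' base is used.
#'
#' @param snvs an `snv_records` data.frame (positions in the focal frame).
#' @param records a `snp_records` data.frame over an alignment containing the
#'   focal isolate.
#' @param focal id of the focal isolate.
#' @param aln optional [genome_alignment()]; when given, SNVs whose position
#'   falls in an alignment column where some other isolate is gapped are
#'   flagged (`gap_flag`) and classed `no_overlap`.
#' @param mode `"strict"` or `"majority"` (see above).
#' @return data.frame of class `overlap_classes`: `position`, `alt`, `class`,
#'   `matched_base` (the non-focal base for overlap classes), `gap_flag`.
#' @export
classify_overlaps <- function(snvs, records, focal, aln = NULL,
                              mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  ids <- attr(records, "isolates")
  if (!(focal %in% ids)) stop("focal isolate not in SNP records")
  others <- setdiff(ids, focal)
  fpos <- records[[paste0(focal, ".pos")]]
  bases <- snp_bases(records)
  attr_list <- strsplit(records$attribution, ",", fixed = TRUE)
  gap_flag <- rep(FALSE, nrow(snvs))
  if (!is.null(aln)) {
    cols_f <- which(aln$mat[focal, ] != "-")
    col_of <- cols_f[snvs$position]
    gap_flag <- colSums(aln$mat[, col_of, drop = FALSE] == "-") > 0
  }
  out <- data.frame(position = snvs$position, alt = snvs$alt,
                    class = "no_overlap", matched_base = NA_character_,
                    gap_flag = gap_flag, stringsAsFactors = FALSE)
  hit <- match(snvs$position, fpos)
  for (i in which(!is.na(hit) & !gap_flag)) {
    k <- hit[i]
    ob <- bases[k, others]
    out$class[i] <- "snp_overlap"
    consensus_other <- if (mode == "strict") {
      u <- unique(ob)
      if (length(u) == 1) u else NA_character_
    } else {
      tb <- sort(table(ob), decreasing = TRUE)
      if (length(tb) == 1 || tb[1] > tb[2]) names(tb)[1] else NA_character_
    }
    if (focal %in% attr_list[[k]] && !is.na(consensus_other) &&
        snvs$alt[i] == consensus_other) {
      out$class[i] <- "unique_snp_overlap"
      out$matched_base[i] <- consensus_other
    } else if (!is.na(consensus_other)) {
      out$matched_base[i] <- consensus_other
    }
  }
  class(out) <- c("overlap_classes", "data.frame")
  out
}

#' Read-level evidence at an indel site
#'
#' Counts, among reads spanning both flanks of the consensus bases
#' `[locus, locus + len - 1]`, those aligning through them (event present in
#' the read's genotype) versus those deleting all of them (event absent).
#' Reads too short to span the locus, or deleting it only partially, are
#' excluded from both counts. Raw counts only; no interval estimate.
#'
#' @param reads data.frame with `pos`, `cigar` (alignments against the focal
#'   consensus; M/I/D/S CIGARs), e.g. `read_set$reads` or [read_sam()]
#'   output.
#' @param locus first consensus position of the queried inserted/deleted run.
#' @param len run length in bp (default 1).
#' @return list with `spanning`, `present`, `absent`, `ambiguous` counts and
#'   `flag` (`TRUE` when no read spans the locus).
#' @export
indel_site_evidence <- function(reads, locus, len = 1L) {
  present <- absent <- ambiguous <- spanning <- 0L
  if (!is.null(reads$seq)) {
    # cheap prefilter: a read's reference span never exceeds its length plus
    # its deletions; use a generous bound before exact CIGAR walking
    bound <- reads$pos + nchar(reads$seq) + 1000L
    reads <- reads[reads$pos < locus & bound > locus + len, , drop = FALSE]
  }
  for (r in seq_len(nrow(reads))) {
    ops <- .parse_cigar(reads$cigar[r])
    refpos <- reads$pos[r]
    covered <- logical(len)   # target base consumed by M
    deleted <- logical(len)   # target base consumed by D
    left <- right <- FALSE
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; n <- ops$n[k]
      if (op %in% c("M", "D")) {
        span <- refpos:(refpos + n - 1L)
        inside <- span >= locus & span <= locus + len - 1L
        if (op == "M") {
          covered[span[inside] - locus + 1L] <- TRUE
          if (any(span < locus)) left <- TRUE
          if (any(span > locus + len - 1L)) right <- TRUE
        } else deleted[span[inside] - locus + 1L] <- TRUE
        refpos <- refpos + n
      }
      # I and S consume no reference
    }
    if (!(left && right)) next
    spanning <- spanning + 1L
    if (all(covered)) present <- present + 1L
    else if (all(deleted)) absent <- absent + 1L
    else ambiguous <- ambiguous + 1L
  }
  list(spanning = spanning, present = present, absent = absent,
       ambiguous = ambiguous, flag = spanning == 0L)
}

.parse_cigar <- function(cigar) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  if (length(n) != length(op)) stop("malformed CIGAR: ", cigar)
  data.frame(n = n, op = op, stringsAsFactors = FALSE)
}

#' Genotype-mixture report
#'
#' Tallies the SNV overlap classes and derives the range of SNPs genuinely
#' unique to the focal isolate: every `unique_snp_overlap` SNV marks a
#' focal-unique SNP that may instead reflect a genotype carrying the other
#' isolates' base, so the unique count ranges from
#' `unique - n(unique_snp_overlap)` to `unique`.
#'
#' @param overlaps an `overlap_classes` data.frame from
#'   [classify_overlaps()].
#' @param summary a `snp_summary` from [summarize_snps()].
#' @param focal focal isolate id.
#' @param indel_evidence optional list of [indel_site_evidence()] results to
#'   append.
#' @return object of class `mixture_report`: list with `class_counts`,
#'   `unique_snps`, `range` (`c(low, high)`), `sites` (the overlap table)
#'   and `indel_evidence`.
#' @export
mixture_report <- function(overlaps, summary, focal, indel_evidence = NULL) {
  counts <- c(no_overlap = sum(overlaps$class == "no_overlap"),
              snp_overlap = sum(overlaps$class == "snp_overlap"),
              unique_snp_overlap = sum(overlaps$class == "unique_snp_overlap"))
  uniq <- summary$unique_counts[[focal]]
  rng <- c(low = uniq - counts[["unique_snp_overlap"]], high = uniq)
  structure(list(class_counts = counts, unique_snps = uniq, range = rng,
                 focal = focal, sites = overlaps,
                 indel_evidence = indel_evidence),
            class = "mixture_report")
}

#' @export
print.mixture_report <- function(x, ...) {
  cat("Genotype-mixture evidence for", x$focal, "\n")
  cat(sprintf("  SNVs total: %d (no overlap %d, SNP overlap %d, unique-SNP overlap %d)\n",
              sum(x$class_counts), x$class_counts[["no_overlap"]],
              x$class_counts[["snp_overlap"]],
              x$class_counts[["unique_snp_overlap"]]))
  cat(sprintf("  SNPs unique to %s: %d; genuine unique count ranges %d-%d\n",
              x$focal, x$unique_snps, x$range[["low"]], x$range[["high"]]))
  if (!is.null(x$indel_evidence))
    for (ev in x$indel_evidence)
      cat(sprintf("  indel site: %d spanning reads, %d with event, %d without\n",
                  ev$spanning, ev$present, ev$absent))
  invisible(x)
}

#' Write a mixture report as TSV plus a text summary
#'
#' @param x a `mixture_report`.
#' @param tsv_path per-site overlap table destination.
#' @param txt_path human-readable summary destination.
#' @export
write_mixture_report <- function(x, tsv_path, txt_path) {
  utils::write.table(as.data.frame(x$sites), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(txt_path, "w")
  sink(con); print(x); sink()
  close(con)
  invisible(tsv_path)
}
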