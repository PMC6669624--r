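STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate one codon with the standard code; "*" for stop, NA for ambiguity
.codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a genome for open reading frames
#'
#' Finds all start-codon-to-stop frames on both strands under the standard
#' genetic code. An ORF runs from the first ATG after the previous in-frame
#' stop to the next in-frame stop (stop included in the span, excluded from
#' the amino-acid length). ORFs shorter than `min_aa` amino acids are treated
#' as absent; overlapping same-strand ORFs are resolved to the longest.
#'
#' @param genome a single sequence string over `{A,C,G,T}`.
#' @param min_aa minimum protein length in amino acids (default 50, the
#'   conventional floor below which a frame is regarded as absent).
#' @return a data.frame of class `orf_table`: `id`, `start`, `end` (1-based
#'   inclusive, stop codon included), `strand` (`"+"`/`"-"`) and `aa`
#'   (translation length, stop excluded), ordered by `start`.
#' @export
scan_orfs <- function(genome, min_aa = 50) {
  genome <- toupper(genome)
  if (grepl("[^ACGT]", genome)) stop("genome must be over {A,C,G,T}")
  L <- nchar(genome)
  one_strand <- function(s) {
    hits <- list()
    for (frame in 0:2) {
      starts <- seq.int(1 + frame, nchar(s) - 2, by = 3)
      codons <- substring(s, starts, starts + 2)
      stops <- which(codons %in% STOP_CODONS)
      seg_begin <- 1L
      for (sp in stops) {
        seg <- seg_begin:sp
        atg <- seg[codons[seg] == "ATG"][1]
        if (!is.na(atg) && sp > atg) {
          aa <- sp - atg  # codons strictly between ATG and stop, plus ATG, minus none: sp-atg = aa incl. start M
          if (aa >= 1)
            hits[[length(hits) + 1L]] <-
              c(start = starts[atg], end = starts[sp] + 2L, aa = aa)
        }
        seg_begin <- sp + 1L
      }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
  }
  fw <- one_strand(genome)
  rv <- one_strand(.revcomp(genome))
  orfs <- data.frame(start = integer(), end = integer(),
                     strand = character(), aa = integer())
  if (!is.null(fw))
    orfs <- rbind(orfs, data.frame(start = fw[, "start"], end = fw[, "end"],
                                   strand = "+", aa = fw[, "aa"]))
  if (!is.null(rv))
    orfs <- rbind(orfs, data.frame(start = L - rv[, "end"] + 1L,
                                   end = L - rv[, "start"] + 1L,
                                   strand = "-", aa = rv[, "aa"]))
  orfs <- orfs[orfs$aa >= min_aa, , drop = FALSE]
  # longest-wins resolution of same-strand overlaps
  orfs <- orfs[order(-orfs$aa, orfs$start), , drop = FALSE]
  keep <- logical(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    prior <- which(keep & orfs$strand == orfs$strand[i])
    ok <- !any(orfs$start[prior] <= orfs$end[i] & orfs$end[prior] >= orfs$start[i])
    keep[i] <- ok
  }
  orfs <- orfs[keep, , drop = FALSE]
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  orfs$id <- sprintf("orf%03d", seq_len(nrow(orfs)))
  rownames(orfs) <- NULL
  orfs <- orfs[, c("id", "start", "end", "strand", "aa")]
  class(orfs) <- c("orf_table", "data.frame")
  orfs
}

# amino acids of an ORF region, reading-direction aware
.orf_protein <- function(genome, start, end, strand) {
  s <- substring(genome, start, end)
  if (strand == "-") s <- .revcomp(s)
  n <- nchar(s) %/% 3
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  .codon_aa(codons)
}

# translate from an anchor until the first in-frame stop.
# strand "+": anchor is the leftmost base of the start codon, read rightwards;
# strand "-": anchor is the rightmost base, read leftwards on the complement.
# returns list(aa = length excl. stop, stop_found, end = genome coord of last stop base)
.translate_from <- function(genome, anchor, strand) {
  L <- nchar(genome)
  if (strand == "+") {
    n <- (L - anchor + 1L) %/% 3
    if (n < 1) return(list(aa = 0L, stop_found = FALSE, end = NA_integer_))
    starts <- anchor + 3L * (seq_len(n) - 1L)
    codons <- substring(genome, starts, starts + 2L)
  } else {
    n <- anchor %/% 3
    if (n < 1) return(list(aa = 0L, stop_found = FALSE, end = NA_integer_))
    ends <- anchor - 3L * (seq_len(n) - 1L)
    codons <- vapply(ends, function(e)
      .revcomp(substring(genome, e - 2L, e)), character(1))
  }
  st <- which(codons %in% STOP_CODONS)
  if (!length(st)) return(list(aa = n, stop_found = FALSE, end = NA_integer_))
  k <- st[1]
  end <- if (strand == "+") anchor + 3L * k - 1L else anchor - 3L * k + 1L
  list(aa = k - 1L, stop_found = TRUE, end = end)
}

#' Annotate the coding effect of a single-nucleotide variant
#'
#' Determines the codon holding `position` in the containing ORF (reverse-
#' strand codons are read on the reverse complement), substitutes `alt`, and
#' classifies the change. The substitution string is reported in the
#' focal-to-other direction, e.g. `"I -> T"` means the focal genome encodes I
#' where the compared sequence encodes T.
#'
#' @param genome the focal genome sequence (string); its base at `position`
#'   is the focal allele.
#' @param orfs an `orf_table` for that genome (see [scan_orfs()]).
#' @param position 1-based position of the variant in the genome.
#' @param alt the other allele (single base). IUPAC ambiguity codes yield an
#'   `"indeterminate"` call, never a substitution string.
#' @return one-row data.frame of class `coding_effect`: `position`, `ref`
#'   (focal base), `alt`, `orf_id`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `class` (synonymous / nonsynonymous / nonsense / stop_loss / noncoding /
#'   indeterminate) and `substitution` ("" unless amino acids differ).
#' @export
annotate_effect <- function(genome, orfs, position, alt) {
  genome <- toupper(genome); alt <- toupper(alt)
  if (position < 1 || position > nchar(genome)) stop("position out of range")
  if (alt == "-") stop("gap allele: route indels to annotate_indel_effect()")
  ref <- substring(genome, position, position)
  hit <- which(orfs$start <= position & orfs$end >= position)
  base <- data.frame(position = position, ref = ref, alt = alt,
                     orf_id = NA_character_, codon_index = NA_integer_,
                     ref_aa = NA_character_, alt_aa = NA_character_,
                     class = "noncoding", substitution = "",
                     stringsAsFactors = FALSE)
  if (!length(hit)) {
    class(base) <- c("coding_effect", "data.frame")
    return(base)
  }
  if (length(hit) > 1) hit <- hit[which.max(orfs$aa[hit])]
  o <- orfs[hit, ]
  if (o$strand == "+") {
    off <- position - o$start
    ci <- off %/% 3 + 1L
    cstart <- o$start + 3L * (ci - 1L)
    codon <- substring(genome, cstart, cstart + 2L)
    ipos <- off %% 3 + 1L
    alt_in <- alt
  } else {
    off <- o$end - position
    ci <- off %/% 3 + 1L
    cend <- o$end - 3L * (ci - 1L)
    codon <- .revcomp(substring(genome, cend - 2L, cend))
    ipos <- off %% 3 + 1L
    alt_in <- if (alt %in% c("A", "C", "G", "T"))
      chartr("ACGT", "TGCA", alt) else alt
  }
  base$orf_id <- o$id
  base$codon_index <- ci
  if (grepl("[^ACGT]", codon) || !(alt_in %in% c("A", "C", "G", "T"))) {
    base$class <- "indeterminate"
    class(base) <- c("coding_effect", "data.frame")
    return(base)
  }
  alt_codon <- codon
  substring(alt_codon, ipos, ipos) <- alt_in
  ra <- .codon_aa(codon); va <- .codon_aa(alt_codon)
  base$ref_aa <- ra; base$alt_aa <- va
  base$class <- if (ra == va) "synonymous"
    else if (va == "*") "nonsense"
    else if (ra == "*") "stop_loss"
    else "nonsynonymous"
  if (ra != va) base$substitution <- paste(ra, "->", va)
  class(base) <- c("coding_effect", "data.frame")
  base
}

#' Annotate the effect of an indel on one ORF
#'
#' Applies the event to the genome and retranslates the ORF from its
#' (unchanged) start codon to the next in-frame stop. In-frame events report
#' the amino-acid delta; events removing the stop codon report the extension
#' to the next in-frame stop; frameshifts report the new product length.
#' Indels overlapping the start codon, or lying outside the ORF, are flagged
#' `"complex"` with no length claim.
#'
#' @param genome genome sequence (string).
#' @param orf one row of an `orf_table`.
#' @param pos 1-based position: for a deletion, its first deleted base; for an
#'   insertion, the base after which `seq` is inserted.
#' @param kind `"insertion"` or `"deletion"`.
#' @param len event length in bp (for insertions, `nchar(seq)` wins).
#' @param seq inserted sequence (insertions only).
#' @return one-row data.frame of class `orf_indel_effect`: `orf_id`, `kind`,
#'   `len`, `class` (in_frame_insertion / in_frame_deletion / extension /
#'   frameshift / complex), `old_aa`, `new_aa`, `delta_aa`, `stop_found`.
#' @export
annotate_indel_effect <- function(genome, orf, pos, kind = c("deletion", "insertion"),
                                  len = 1L, seq = NULL) {
  kind <- match.arg(kind)
  genome <- toupper(genome)
  if (kind == "insertion") {
    if (is.null(seq)) stop("insertion needs `seq`")
    seq <- toupper(seq); len <- nchar(seq)
  }
  out <- data.frame(orf_id = orf$id, kind = kind, len = len,
                    class = "complex", old_aa = orf$aa,
                    new_aa = NA_integer_, delta_aa = NA_integer_,
                    stop_found = NA, stringsAsFactors = FALSE)
  start_codon <- if (orf$strand == "+") c(orf$start, orf$start + 2L)
                 else c(orf$end - 2L, orf$end)
  stop_codon <- if (orf$strand == "+") c(orf$end - 2L, orf$end)
                else c(orf$start, orf$start + 2L)
  span <- if (kind == "deletion") c(pos, pos + len - 1L) else c(pos, pos)
  inside <- span[1] >= orf$start && span[2] <= orf$end
  hits_start <- span[2] >= start_codon[1] && span[1] <= start_codon[2]
  if (!inside || hits_start) {
    class(out) <- c("orf_indel_effect", "data.frame")
    return(out)
  }
  mutated <- if (kind == "deletion")
    paste0(substring(genome, 1L, pos - 1L), substring(genome, pos + len, nchar(genome)))
  else
    paste0(substring(genome, 1L, pos), seq, substring(genome, pos + 1L, nchar(genome)))
  # anchor = start codon position in the mutated genome
  anchor <- if (orf$strand == "+") orf$start
            else orf$end + (if (kind == "deletion") -len else len)
  tr <- .translate_from(mutated, anchor, orf$strand)
  out$new_aa <- tr$aa
  out$delta_aa <- tr$aa - orf$aa
  out$stop_found <- tr$stop_found
  hits_stop <- span[2] >= stop_codon[1] && span[1] <= stop_codon[2]
  out$class <- if (len %% 3 != 0) "frameshift"
    else if (hits_stop) "extension"
    else if (kind == "deletion") "in_frame_deletion"
    else "in_frame_insertion"
  class(out) <- c("orf_indel_effect", "data.frame")
  out
}

# lift one extent between isolates, stepping inward past gaps
.lift_extent <- function(aln, from, to, start, end) {
  n <- end - start + 1L
  fwd <- lift_coordinate(aln, from, start:end, to)
  ok <- which(!is.na(fwd))
  if (!length(ok)) return(NULL)
  c(fwd[ok[1]], fwd[ok[length(ok)]])
}

#' Compare two ORF tables through a whole-genome alignment
#'
#' Each reference ORF's extent is lifted into the focal frame (orthology by
#' coordinate, not homology search) and classified against the focal ORFs
#' found there: `identical` (equal protein), `substituted` (equal length,
#' different protein), `truncated`/`extended` (with amino-acid delta and, for
#' truncations, percent of the coding region lost), `fused` (one focal ORF is
#' the best match of several reference ORFs), `split` (several focal ORFs
#' inside one reference extent), `absent` (no focal ORF of at least `min_aa`
#' amino acids there) or `unalignable` (extent lifts entirely into gaps).
#'
#' @param focal_orfs,ref_orfs `orf_table`s for the two genomes.
#' @param aln a [genome_alignment()] containing both genomes.
#' @param focal_id,ref_id isolate ids in `aln`.
#' @param focal_genome,ref_genome optional ungapped sequences; when given,
#'   equal-length pairs are split into `identical` vs `substituted` by protein
#'   comparison (otherwise reported `identical`).
#' @param min_aa absence threshold in amino acids (default 50).
#' @param stop_in_denominator logical; if `TRUE` the stop codon counts in the
#'   reference length when computing percent lost (default `FALSE`).
#' @return data.frame of class `orf_comparison`: `ref_orf`, `focal_orf`,
#'   `class`, `ref_aa`, `focal_aa`, `delta_aa`, `percent_lost`.
#' @export
compare_orf_tables <- function(focal_orfs, ref_orfs, aln, focal_id, ref_id,
                               focal_genome = NULL, ref_genome = NULL,
                               min_aa = 50, stop_in_denominator = FALSE) {
  stopifnot(inherits(aln, "genome_alignment"))
  nref <- nrow(ref_orfs)
  focal_orfs <- focal_orfs[focal_orfs$aa >= min_aa, , drop = FALSE]
  lifted <- vector("list", nref)
  for (i in seq_len(nref))
    lifted[i] <- list(.lift_extent(aln, ref_id, focal_id,
                                   ref_orfs$start[i], ref_orfs$end[i]))
  ov_len <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)
  # best focal ORF per reference ORF, by overlap with the lifted extent
  best <- rep(NA_integer_, nref)
  cand <- vector("list", nref)
  for (i in seq_len(nref)) {
    if (is.null(lifted[[i]])) next
    ex <- lifted[[i]]
    ov <- mapply(ov_len, focal_orfs$start, focal_orfs$end, ex[1], ex[2])
    hit <- which(ov > 0 &
                 ov >= 0.5 * pmin(focal_orfs$end - focal_orfs$start + 1L,
                                  ex[2] - ex[1] + 1L))
    cand[[i]] <- hit
    if (length(hit)) best[i] <- hit[which.max(ov[hit])]
  }
  res <- data.frame(ref_orf = ref_orfs$id, focal_orf = NA_character_,
                    class = NA_character_, ref_aa = ref_orfs$aa,
                    focal_aa = NA_integer_, delta_aa = NA_integer_,
                    percent_lost = NA_real_, stringsAsFactors = FALSE)
  fused_groups <- split(seq_len(nref)[!is.na(best)], best[!is.na(best)])
  for (i in seq_len(nref)) {
    if (is.null(lifted[[i]])) { res$class[i] <- "unalignable"; next }
    if (is.na(best[i])) { res$class[i] <- "absent"; next }
    b <- best[i]
    res$focal_orf[i] <- focal_orfs$id[b]
    res$focal_aa[i] <- focal_orfs$aa[b]
    grp <- fused_groups[[as.character(b)]]
    if (length(grp) > 1) { res$class[i] <- "fused"; next }
    if (length(cand[[i]]) > 1) {
      res$class[i] <- "split"
      res$focal_orf[i] <- paste(focal_orfs$id[cand[[i]]], collapse = ",")
      next
    }
    delta <- ref_orfs$aa[i] - focal_orfs$aa[b]
    res$delta_aa[i] <- delta
    if (delta > 0) {
      res$class[i] <- "truncated"
      denom <- ref_orfs$aa[i] + if (stop_in_denominator) 1L else 0L
      res$percent_lost[i] <- round(100 * delta / denom, 1)
    } else if (delta < 0) {
      res$class[i] <- "extended"
    } else if (!is.null(focal_genome) && !is.null(ref_genome)) {
      pf <- .orf_protein(focal_genome, focal_orfs$start[b], focal_orfs$end[b],
                         focal_orfs$strand[b])
      pr <- .orf_protein(ref_genome, ref_orfs$start[i], ref_orfs$end[i],
                         ref_orfs$strand[i])
      res$class[i] <- if (identical(pf, pr)) "identical" else "substituted"
    } else res$class[i] <- "identical"
  }
  class(res) <- c("orf_comparison", "data.frame")
  res
}

#' Write an ORF table as GFF3
#'
#' CDS features, 1-based inclusive coordinates.
#'
#' @param orfs an `orf_table`.
#' @param path output file.
#' @param seqid sequence name to use in column 1.
#' @export
write_orf_gff <- function(orfs, path, seqid = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(orfs$start, orfs$end),
    strand = orfs$strand,
    type = "CDS", ID = orfs$id, phase = 0L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file of CDS features as an ORF table
#'
#' @param path GFF3 file.
#' @return an `orf_table` (see [scan_orfs()]); `aa` is derived from the span.
#' @export
read_orf_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else sprintf("orf%03d", seq_along(gr))
  orfs <- data.frame(id = ids,
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     aa = (GenomicRanges::width(gr) %/% 3L) - 1L,
                     stringsAsFactors = FALSE)
  orfs <- orfs[order(orfs$start), ]
  rownames(orfs) <- NULL
  class(orfs) <- c("orf_table", "data.frame")
  orfs
}
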