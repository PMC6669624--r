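#' Construct a genome alignment object
#'
#' A `genome_alignment` holds two or more equal-length gapped genome sequences
#' keyed by isolate id. It is the coordinate frame for SNP scanning, coordinate
#' lifting, ORF comparison and tree building.
#'
#' Sequences may contain the four bases, IUPAC ambiguity symbols and `-` for
#' gaps. Symbols are uppercased on input; anything else is rejected with the
#' offending column named.
#'
#' @param x a named character vector of gapped sequences (one per isolate), or
#'   a named [Biostrings::DNAStringSet] of equal widths.
#' @return an object of class `genome_alignment`: a list with elements `ids`,
#'   `mat` (isolate-by-column character matrix), `length` (number of columns)
#'   and `ungapped` (named integer vector of ungapped genome lengths).
#' @examples
#' aln <- genome_alignment(c(a = "ACGT", b = "A-GT"))
#' aln$ungapped
#' @export
genome_alignment <- function(x) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || length(x) < 2)
    stop("need at least 2 sequences")
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x))))
    stop("sequences must carry unique non-empty isolate ids")
  x <- toupper(x)
  L <- unique(nchar(x))
  if (length(L) != 1)
    stop("ragged alignment: sequence lengths differ (",
         paste(nchar(x), collapse = ", "), ")")
  mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(mat) <- names(x)
  allowed <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
  bad <- !(mat %in% allowed)
  if (any(bad)) {
    idx <- which(bad)[1]
    stop("non-IUPAC symbol '", mat[idx], "' at alignment column ",
         ((idx - 1) %/% nrow(mat)) + 1)
  }
  structure(
    list(ids = names(x), mat = mat, length = L,
         ungapped = apply(mat != "-", 1, sum)),
    class = "genome_alignment"
  )
}

#' Read an aligned FASTA file as a genome alignment
#'
#' @param path path to a FASTA file in which all records have equal length.
#' @return a [genome_alignment()] object.
#' @export
read_genome_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_alignment(stats::setNames(as.character(seqs), names(seqs)))
}

#' @export
print.genome_alignment <- function(x, ...) {
  cat("Genome alignment:", length(x$ids), "isolates x", x$length, "columns\n")
  cat("  isolates:", paste(x$ids, collapse = ", "), "\n")
  cat("  ungapped lengths:", paste(x$ungapped, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the ungapped genome of one isolate from an alignment
#'
#' @param aln a [genome_alignment()].
#' @param id isolate id.
#' @return the ungapped sequence as a single string.
#' @export
ungapped_sequence <- function(aln, id) {
  stopifnot(inherits(aln, "genome_alignment"), id %in% aln$ids)
  paste(aln$mat[id, aln$mat[id, ] != "-"], collapse = "")
}

# per-isolate ungapped position of every alignment column (NA at gaps)
.position_matrix <- function(aln) {
  nong <- aln$mat != "-"
  pos <- matrix(0L, nrow(nong), ncol(nong), dimnames = dimnames(nong))
  for (i in seq_len(nrow(nong))) pos[i, ] <- cumsum(nong[i, ])
  pos[!nong] <- NA_integer_
  storage.mode(pos) <- "integer"
  pos
}

#' Attribute uniqueness within one alignment column
#'
#' An isolate is attributed iff its symbol occurs in no other isolate in the
#' column. Symbols are compared as opaque tokens, so an ambiguity code such as
#' `Y` never matches `C` or `T`: a column like `(T, C, C, Y, C, C)` attributes
#' both the `T` and the `Y` carrier. A monomorphic column attributes nobody.
#'
#' @param symbols named character vector of per-isolate non-gap symbols.
#' @return character vector of attributed isolate ids (possibly empty).
#' @examples
#' classify_uniqueness(c(sa = "A", e2 = "G", i07 = "G", m = "G"))
#' @export
classify_uniqueness <- function(symbols) {
  if (any(symbols == "-")) stop("gap symbol in column passed to classify_uniqueness")
  if (is.null(names(symbols))) names(symbols) <- seq_along(symbols)
  counts <- table(symbols)
  names(symbols)[counts[symbols] == 1L]
}

#' Scan a genome alignment for SNP columns
#'
#' A column is reported iff no isolate has a gap in it and at least two
#' distinct symbols occur. Optionally, columns within `indel_window` columns
#' of any gap-containing column are also excluded (default 0: the column
#' itself must be gap-free, flanking gaps do not disqualify it).
#'
#' @param aln a [genome_alignment()].
#' @param indel_window integer; exclusion radius (in columns) around
#'   gap-containing columns. Default 0.
#' @return a data.frame of class `snp_records` with one row per SNP column:
#'   `column` (1-based alignment column), per-isolate base columns
#'   (`<id>.base`), per-isolate 1-based ungapped positions (`<id>.pos`),
#'   `attribution` (comma-joined ids whose symbol is unique in the column,
#'   possibly empty), `n_attributed`, and `class` (`"unique"` or `"shared"`).
#' @export
scan_snp_columns <- function(aln, indel_window = 0) {
  stopifnot(inherits(aln, "genome_alignment"))
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)
  gapcol <- colSums(mat == "-") > 0
  excluded <- gapcol
  if (indel_window > 0 && any(gapcol)) {
    idx <- which(gapcol)
    lo <- pmax(1L, idx - indel_window)
    hi <- pmin(L, idx + indel_window)
    for (k in seq_along(idx)) excluded[lo[k]:hi[k]] <- TRUE
  }
  # polymorphic iff some row differs from the first row
  poly <- colSums(mat != rep(mat[1, ], each = n)) > 0
  keep <- which(!excluded & poly)

  pos <- .position_matrix(aln)
  bases <- t(mat[, keep, drop = FALSE])
  posk  <- t(pos[, keep, drop = FALSE])
  attribution <- character(length(keep))
  nattr <- integer(length(keep))
  for (k in seq_along(keep)) {
    u <- classify_uniqueness(stats::setNames(bases[k, ], aln$ids))
    attribution[k] <- paste(u, collapse = ",")
    nattr[k] <- length(u)
  }
  out <- data.frame(column = keep, check.names = FALSE)
  for (i in seq_len(n)) {
    out[[paste0(aln$ids[i], ".base")]] <- bases[, i]
    out[[paste0(aln$ids[i], ".pos")]] <- posk[, i]
  }
  out$attribution <- attribution
  out$n_attributed <- nattr
  out$class <- ifelse(nattr > 0, "unique", "shared")
  attr(out, "isolates") <- aln$ids
  class(out) <- c("snp_records", "data.frame")
  out
}

#' Per-isolate base matrix of a set of SNP records
#' @param records a `snp_records` data.frame from [scan_snp_columns()].
#' @return character matrix, one row per record, one column per isolate.
#' @export
snp_bases <- function(records) {
  ids <- attr(records, "isolates")
  m <- as.matrix(records[, paste0(ids, ".base"), drop = FALSE])
  colnames(m) <- ids
  m
}

#' Per-isolate ungapped positions of a set of SNP records
#' @inheritParams snp_bases
#' @return integer matrix, one row per record, one column per isolate.
#' @export
snp_positions <- function(records) {
  ids <- attr(records, "isolates")
  m <- as.matrix(records[, paste0(ids, ".pos"), drop = FALSE])
  colnames(m) <- ids
  m
}

#' Lift a coordinate between isolate frames through the alignment
#'
#' Finds the alignment column holding `position` in `isolate_from`'s ungapped
#' frame and returns the 1-based ungapped position of that column in
#' `isolate_to`, or `NA` where `isolate_to` has a gap there.
#'
#' @param aln a [genome_alignment()].
#' @param isolate_from,isolate_to isolate ids.
#' @param position integer vector of 1-based ungapped positions in
#'   `isolate_from`.
#' @return integer vector; `NA` marks a lift into a gap.
#' @export
lift_coordinate <- function(aln, isolate_from, position, isolate_to) {
  stopifnot(inherits(aln, "genome_alignment"),
            isolate_from %in% aln$ids, isolate_to %in% aln$ids)
  ng <- aln$ungapped[[isolate_from]]
  if (any(position < 1 | position > ng))
    stop("position out of range for isolate ", isolate_from,
         " (ungapped length ", ng, ")")
  cols_from <- which(aln$mat[isolate_from, ] != "-")
  col <- cols_from[position]
  pos_to <- cumsum(aln$mat[isolate_to, ] != "-")
  out <- ifelse(aln$mat[isolate_to, col] == "-", NA_integer_, pos_to[col])
  as.integer(out)
}

#' Summarise SNP records over an alignment
#'
#' Totals, per-isolate unique-SNP counts and pairwise differences/identities.
#' Pairwise identity between two isolates is computed over the columns where
#' both are ungapped: `100 * (1 - differing / shared)`, reported to 2 dp.
#'
#' @param records a `snp_records` data.frame from [scan_snp_columns()].
#' @param aln the same [genome_alignment()] the records came from.
#' @return an object of class `snp_summary`: list with `total`,
#'   `unique_counts` (named integer), `pairwise_snps` and
#'   `pairwise_identity` (matrices).
#' @export
summarize_snps <- function(records, aln) {
  stopifnot(inherits(aln, "genome_alignment"))
  ids <- aln$ids
  n <- length(ids)
  attr_list <- strsplit(records$attribution, ",", fixed = TRUE)
  unique_counts <- stats::setNames(integer(n), ids)
  for (a in attr_list)
    for (id in a) unique_counts[[id]] <- unique_counts[[id]] + 1L
  dif <- matrix(0L, n, n, dimnames = list(ids, ids))
  ident <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- aln$mat[i, ] != "-" & aln$mat[j, ] != "-"
    d <- sum(aln$mat[i, shared] != aln$mat[j, shared])
    dif[i, j] <- dif[j, i] <- d
    ident[i, j] <- ident[j, i] <- round(100 * (1 - d / sum(shared)), 2)
  }
  structure(list(total = nrow(records), unique_counts = unique_counts,
                 pairwise_snps = dif, pairwise_identity = ident),
            class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  cat("SNP summary:", x$total, "polymorphic gap-free columns\n")
  cat("unique SNPs per isolate:\n")
  print(x$unique_counts)
  cat("pairwise identity (%):\n")
  print(x$pairwise_identity)
  invisible(x)
}

#' Write SNP records as a tab-separated table
#'
#' One row per SNP column with per-isolate positions and bases, uniqueness
#' attribution and (if present) ORF id and substitution columns.
#'
#' @param records a `snp_records` data.frame.
#' @param path output file.
#' @export
write_snp_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
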