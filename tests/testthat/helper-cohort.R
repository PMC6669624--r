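# small cohort used across tests: 6 isolates, 5 kb, light mutation load
small_spec <- function(seed = 1, ...) {
  args <- list(genome_length = 5000, coverage_target = 120,
               subs_per_branch = 25, indels_per_branch = 2,
               revert_unique = 4, revert_shared = 4, private_subs = 6,
               orf_density = 0.6, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

# column-by-column SNP scan written independently of the package's
# vectorised implementation: explicit loops, per-isolate occurrence checks
brute_force_snps <- function(mat) {
  out <- list()
  for (k in seq_len(ncol(mat))) {
    col <- mat[, k]
    if (any(col == "-")) next
    if (length(unique(col)) < 2) next
    attributed <- character(0)
    for (i in seq_along(col))
      if (!any(col[-i] == col[i]))
        attributed <- c(attributed, rownames(mat)[i])
    out[[length(out) + 1L]] <- data.frame(
      column = k, attribution = paste(attributed, collapse = ","))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(column = integer(), attribution = character())
}

random_alignment <- function(n = 6, L = 50, gap_prob = 0.05,
                             ids = paste0("iso", seq_len(n))) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  mat[matrix(runif(n * L) < gap_prob, n, L)] <- "-"
  # avoid all-gap rows breaking the ungapped-length invariant trivially
  mat[, 1] <- "A"
  genome_alignment(stats::setNames(apply(mat, 1, paste, collapse = ""), ids))
}
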