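# random tree metric: topology + additive distances from random edge lengths
random_tree_metric <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# OLS residual of one 4-taxon topology, written from the closed path matrix
ls4_residual <- function(D, split) {
  taxa <- rownames(D)
  a <- split[[1]][1]; b <- split[[1]][2]; c <- split[[2]][1]; d <- split[[2]][2]
  # edges: pendant a,b,c,d + internal
  A <- rbind(c(1, 1, 0, 0, 0),   # ab
             c(1, 0, 1, 0, 1),   # ac
             c(1, 0, 0, 1, 1),   # ad
             c(0, 1, 1, 0, 1),   # bc
             c(0, 1, 0, 1, 1),   # bd
             c(0, 0, 1, 1, 0))   # cd
  y <- c(D[a, b], D[a, c], D[a, d], D[b, c], D[b, d], D[c, d])
  sum(stats::lm.fit(A, y)$residuals^2)
}

test_that("p-distances count differing symbols over shared columns", {
  aln <- genome_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(p_distance(aln)["a", "b"], 0)
  aln <- genome_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(p_distance(aln)["a", "b"], 0.25)
  # gapped columns drop out pairwise
  aln <- genome_alignment(c(a = "ACGT", b = "A-GA", c = "ACGT"))
  D <- p_distance(aln)
  expect_equal(D["a", "b"], 1 / 3)
  expect_equal(D["a", "c"], 0)
  # simulated cohort: distance near the ledger-predicted divergence
  s <- small_spec(seed = 19, indels_per_branch = 0)
  tr <- simulate_cohort(s)
  D <- p_distance(tr$alignment)
  led <- tr$ledger
  # iso1 and iso2 are sisters: at most 2 branches x 25 substitutions apart
  expect_lt(abs(D["iso1", "iso2"] - 50 / 5000), 0.002)
})

test_that("3-taxon NJ solves the three-point equations", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(len["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(len["c"]), (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "n >= 3")
})

test_that("NJ recovers generating topologies from additive matrices", {
  for (seed in 1:10) {
    for (n in c(5, 6, 8)) {
      tm <- random_tree_metric(n, seed * 100 + n)
      tr <- nj_tree(tm$D)
      expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(tm$tree))), 0)
    }
  }
})

test_that("4-taxon NJ+ME agrees with exhaustive least-squares enumeration", {
  for (seed in 1:20) {
    tm <- random_tree_metric(4, seed)
    taxa <- rownames(tm$D)
    splits <- list(list(taxa[c(1, 2)], taxa[c(3, 4)]),
                   list(taxa[c(1, 3)], taxa[c(2, 4)]),
                   list(taxa[c(1, 4)], taxa[c(2, 3)]))
    res <- vapply(splits, ls4_residual, numeric(1), D = tm$D)
    best <- splits[[which.min(res)]]
    tr <- me_refine(nj_tree(tm$D), tm$D)
    # the winning split must be a bipartition of the inferred tree
    got <- ape::prop.part(tr)
    want <- sort(match(best[[1]], tr$tip.label))
    parts <- lapply(got, sort)
    has <- any(vapply(parts, identical, logical(1), y = want)) ||
      any(vapply(parts, identical, logical(1),
                 y = sort(match(best[[2]], tr$tip.label))))
    expect_true(has)
  }
})

test_that("ME refinement repairs perturbed topologies and never lengthens", {
  for (seed in 1:10) {
    tm <- random_tree_metric(6, seed + 500)
    good <- me_refine(nj_tree(tm$D), tm$D)
    expect_equal(as.numeric(ape::dist.topo(good, ape::unroot(tm$tree))), 0)
    # perturb and refine back
    set.seed(seed)
    bad <- phangorn::rNNI(good, moves = 1)
    fixed <- me_refine(bad, tm$D)
    expect_equal(as.numeric(ape::dist.topo(fixed, ape::unroot(tm$tree))), 0)
  }
  # non-increase of the objective on arbitrary (non-additive) matrices
  for (seed in 1:100) {
    set.seed(seed)
    M <- matrix(runif(36, 0.1, 1), 6, 6)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:6), paste0("t", 1:6))
    start <- nj_tree(D)
    expect_lte(ols_tree_length(me_refine(start, D), D),
               ols_tree_length(start, D) + 1e-9)
  }
})

test_that("bootstrap supports are seeded, order-invariant and signal-driven", {
  # identical sequences: no supported bipartitions
  aln0 <- genome_alignment(stats::setNames(rep(strrep("ACGT", 25), 6),
                                           paste0("t", 1:6)))
  D0 <- p_distance(aln0)
  tr0 <- nj_tree(D0)
  sup0 <- bootstrap_support(aln0, tr0, n_replicates = 50, seed = 1)
  expect_true(all(sup0[!is.na(sup0)] == 0))

  # two deeply divergent clades, 500 informative columns
  clade <- c(rep("A", 3), rep("C", 3))
  mat <- matrix(rep(clade, 500), nrow = 6)
  set.seed(7)
  noise <- matrix(sample(c("A", "C", "G", "T"), 6 * 100, replace = TRUE), 6)
  aln <- genome_alignment(stats::setNames(
    apply(cbind(mat, noise), 1, paste, collapse = ""), paste0("t", 1:6)))
  D <- p_distance(aln)
  tr <- me_refine(nj_tree(D), D)
  sup <- bootstrap_support(aln, tr, n_replicates = 200, seed = 3)
  splits <- lapply(seq_len(nrow(tr$edge)), function(e) e)
  # the clade split is an internal edge with near-total support
  expect_gte(max(sup, na.rm = TRUE), 99)

  sup2 <- bootstrap_support(aln, tr, n_replicates = 200, seed = 3)
  expect_identical(sup, sup2)

  # isolate input order must not matter
  seqs <- apply(cbind(mat, noise), 1, paste, collapse = "")
  names(seqs) <- paste0("t", 1:6)
  perm <- genome_alignment(seqs[c(4, 2, 6, 1, 3, 5)])
  sup3 <- bootstrap_support(perm, tr, n_replicates = 200, seed = 3)
  expect_identical(sup, sup3)
})

test_that("SNP counts annotate leaves and clades from planted events", {
  # one substitution on a leaf branch
  tree <- default_cohort_tree(6, subs_per_branch = 0)
  tree$edge.length[tree$edge[, 2] == which(tree$tip.label == "iso5")] <- 1
  s <- small_spec(tree = tree, indels_per_branch = 0, revert_unique = 0,
                  revert_shared = 0, private_subs = 0, revert_indels = 0)
  tr <- simulate_cohort(s)
  rec <- scan_snp_columns(tr$alignment)
  ann <- annotate_snp_counts(s$tree, rec)
  expect_equal(unname(ann$leaf_counts[c("iso5")]), 1L)
  expect_equal(sum(ann$leaf_counts), 1L)
  expect_true(all(ann$node_counts == 0))

  # substitutions on one internal branch mark exactly its descendant clade
  tree2 <- default_cohort_tree(6, subs_per_branch = 0)
  ntip <- 6
  # the branch into the (iso3, iso4) clade
  tips34 <- match(c("iso3", "iso4"), tree2$tip.label)
  node34 <- ape::getMRCA(tree2, tips34)
  tree2$edge.length[tree2$edge[, 2] == node34] <- 5
  s2 <- small_spec(tree = tree2, indels_per_branch = 0, revert_unique = 0,
                   revert_shared = 0, private_subs = 0, revert_indels = 0)
  tr2 <- simulate_cohort(s2)
  rec2 <- scan_snp_columns(tr2$alignment)
  ann2 <- annotate_snp_counts(s2$tree, rec2)
  expect_true(all(ann2$leaf_counts == 0))
  expect_equal(unname(ann2$node_counts[as.character(node34)]), 5L)
  expect_equal(sum(ann2$node_counts), 5L)

  expect_error(annotate_snp_counts(default_cohort_tree(5), rec2), "differ")
})
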