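#' Pairwise p-distance matrix of an alignment
#'
#' For each pair of isolates: the proportion of differing symbols over the
#' columns where both are ungapped. Pairwise identity (in percent) is
#' `100 * (1 - d)`.
#'
#' @param aln a [genome_alignment()].
#' @return symmetric numeric matrix with zero diagonal, isolate ids as
#'   dimnames.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "genome_alignment"))
  ids <- aln$ids
  n <- length(ids)
  if (n < 2) stop("need at least 2 isolates")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- aln$mat[i, ] != "-" & aln$mat[j, ] != "-"
    ns <- sum(shared)
    if (ns == 0) stop("isolates ", ids[i], " and ", ids[j],
                      " share no gap-free columns")
    D[i, j] <- D[j, i] <- sum(aln$mat[i, shared] != aln$mat[j, shared]) / ns
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. Taxa are ordered lexicographically before
#' joining so ties break deterministically; negative branch-length estimates
#' are clamped to zero (with a message).
#'
#' @param D symmetric distance matrix with taxon ids as dimnames (n >= 3).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  ids <- rownames(D)
  if (is.null(ids) || nrow(D) < 3) stop("need a labelled matrix with n >= 3")
  ord <- order(ids)
  tr <- ape::nj(stats::as.dist(D[ord, ord]))
  if (any(tr$edge.length < 0)) {
    message(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

# tip membership (logical over tips, in tip.label order) for every edge's
# child side
.edge_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    below[p, ] <- below[p, ] | below[c, ]
  }
  splits <- below[tree$edge[, 2], , drop = FALSE]
  colnames(splits) <- tree$tip.label
  splits
}

# ordinary-least-squares branch lengths for an unrooted tree, given D
.ols_lengths <- function(tree, D) {
  ids <- tree$tip.label
  splits <- .edge_splits(tree)
  pairs <- utils::combn(length(ids), 2)
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  d <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k, ] <- xor(splits[, i], splits[, j])
    d[k] <- D[ids[i], ids[j]]
  }
  as.numeric(qr.coef(qr(A), d))
}

#' Total ordinary-least-squares tree length
#'
#' Sum of the OLS branch-length estimates of `tree` fitted to `D`; the
#' objective minimised by [me_refine()].
#'
#' @param tree an unrooted binary [ape::phylo].
#' @param D distance matrix over the tree's tips.
#' @return a single number.
#' @export
ols_tree_length <- function(tree, D) sum(.ols_lengths(tree, D))

#' Minimum-evolution refinement by nearest-neighbor interchanges
#'
#' Hill-climbs over the NNI neighborhood of the starting tree, moving to the
#' neighbor with the smallest total OLS branch length, until no neighbor
#' improves the objective or `max_rounds` is reached. The tree length never
#' increases. Returns the final topology with its OLS branch lengths
#' (negative estimates clamped to zero).
#'
#' @param tree starting unrooted binary tree (typically from [nj_tree()]).
#' @param D the distance matrix the objective is fitted to.
#' @param max_rounds maximum number of accepted interchanges (default 20).
#' @return an [ape::phylo] tree.
#' @export
me_refine <- function(tree, D, max_rounds = 20) {
  if (length(tree$tip.label) < 4) {
    tree$edge.length <- pmax(.ols_lengths(tree, D), 0)
    return(tree)
  }
  cur_len <- ols_tree_length(tree, D)
  for (round in seq_len(max_rounds)) {
    nb <- phangorn::nni(tree)
    lens <- vapply(nb, ols_tree_length, numeric(1), D = D)
    best <- which.min(lens)
    if (lens[best] >= cur_len - 1e-12) break
    tree <- nb[[best]]
    cur_len <- lens[best]
  }
  tree$edge.length <- pmax(.ols_lengths(tree, D), 0)
  tree
}

# canonical key of the bipartition induced by one edge: the sorted tip set on
# the side not containing the alphabetically first tip
.split_key <- function(members, all_tips) {
  first <- sort(all_tips)[1]
  side <- if (first %in% members) setdiff(all_tips, members) else members
  paste(sort(side), collapse = "|")
}

# keys of all internal (non-trivial) edges
.internal_split_keys <- function(tree) {
  splits <- .edge_splits(tree)
  ntip <- length(tree$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(splits))) {
    m <- sum(splits[e, ])
    if (m <= 1 || m >= ntip - 1) { keys <- c(keys, NA_character_); next }
    keys <- c(keys, .split_key(tree$tip.label[splits[e, ]], tree$tip.label))
  }
  keys
}

#' Bootstrap support for a tree's internal bipartitions
#'
#' Resamples alignment columns with replacement (via multinomial weights over
#' the distinct column patterns), rebuilds the tree per replicate with the
#' same NJ (+ optional minimum-evolution) procedure, and reports for each
#' internal edge of `tree` the percentage of replicates containing its
#' bipartition. Seeded and reproducible; invariant to isolate input order.
#'
#' @param aln the [genome_alignment()] the tree was built from.
#' @param tree the reference tree whose internal edges are scored.
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed PRNG seed.
#' @param refine logical: apply [me_refine()] per replicate (default TRUE).
#' @return numeric vector, one entry per edge of `tree` (in `tree$edge`
#'   order): support in percent for internal edges, `NA` for pendant edges.
#' @export
bootstrap_support <- function(aln, tree, n_replicates = 1000, seed = 1,
                              refine = TRUE) {
  stopifnot(inherits(aln, "genome_alignment"))
  set.seed(seed)
  ids <- sort(aln$ids)
  mat <- aln$mat[ids, , drop = FALSE]
  n <- length(ids); L <- ncol(mat)
  pat <- do.call(paste0, as.data.frame(t(mat)))
  upat <- unique(pat)
  pidx <- match(pat, upat)
  base_w <- tabulate(pidx, nbins = length(upat))
  cols <- do.call(rbind, strsplit(upat, "", fixed = TRUE))  # pattern x taxon
  pairs <- utils::combn(n, 2)
  npair <- ncol(pairs)
  diff_p <- matrix(0, length(upat), npair)
  shared_p <- matrix(0, length(upat), npair)
  for (k in seq_len(npair)) {
    a <- cols[, pairs[1, k]]; b <- cols[, pairs[2, k]]
    shared_p[, k] <- a != "-" & b != "-"
    diff_p[, k] <- shared_p[, k] & a != b
  }
  keys_ref <- .internal_split_keys(tree)
  hits <- numeric(length(keys_ref))
  valid <- 0L
  for (r in seq_len(n_replicates)) {
    w <- as.numeric(stats::rmultinom(1, L, base_w / L))
    den <- crossprod(shared_p, w)
    if (any(den == 0)) next  # replicate with an undefined pair distance
    valid <- valid + 1L
    dv <- crossprod(diff_p, w) / den
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (k in seq_len(npair))
      D[pairs[1, k], pairs[2, k]] <- D[pairs[2, k], pairs[1, k]] <- dv[k]
    tr <- nj_tree(D)
    if (refine) tr <- me_refine(tr, D)
    keys_rep <- .internal_split_keys(tr)
    # a zero-length internal edge carries no resolution signal: an alignment
    # of identical sequences must yield no supported bipartitions
    resolved <- !is.na(keys_rep) & tr$edge.length > 1e-12
    hits <- hits + (keys_ref %in% keys_rep[resolved])
  }
  support <- ifelse(is.na(keys_ref), NA_real_,
                    if (valid > 0) 100 * hits / valid else 0)
  support
}

#' Annotate a tree with per-branch SNP counts
#'
#' Leaves are annotated with the number of SNP columns attributed uniquely to
#' that isolate. Each internal node is annotated with the number of columns
#' in which all members of its clade share one symbol that occurs in no
#' isolate outside the clade (synapomorphic columns). A column counted at a
#' node is never counted again at an ancestor or descendant for the same
#' symbol.
#'
#' @param tree an [ape::phylo] whose tips are exactly the record isolates.
#' @param records a `snp_records` data.frame from [scan_snp_columns()].
#' @param support optional per-edge support vector from
#'   [bootstrap_support()].
#' @return object of class `annotated_tree`: list with `tree`, `leaf_counts`
#'   (named integer), `node_counts` (named by internal node number),
#'   `support`.
#' @export
annotate_snp_counts <- function(tree, records, support = NULL) {
  ids <- attr(records, "isolates")
  if (!setequal(tree$tip.label, ids))
    stop("tree tips and SNP record isolates differ")
  bases <- snp_bases(records)
  attr_list <- strsplit(records$attribution, ",", fixed = TRUE)
  leaf_counts <- stats::setNames(integer(length(ids)), tree$tip.label)
  for (a in attr_list) for (id in a)
    leaf_counts[[id]] <- leaf_counts[[id]] + 1L
  ntip <- length(tree$tip.label)
  splits <- .edge_splits(tree)
  internal <- which(tree$edge[, 2] > ntip)
  node_counts <- stats::setNames(integer(length(internal)),
                                 tree$edge[internal, 2])
  for (k in seq_along(internal)) {
    members <- tree$tip.label[splits[internal[k], ]]
    inb <- bases[, members, drop = FALSE]
    outb <- bases[, setdiff(colnames(bases), members), drop = FALSE]
    mono <- apply(inb, 1, function(r) length(unique(r)) == 1)
    shared_sym <- inb[, 1]
    absent_out <- !vapply(seq_len(nrow(bases)), function(r)
      shared_sym[r] %in% outb[r, ], logical(1))
    node_counts[k] <- sum(mono & absent_out)
  }
  structure(list(tree = tree, leaf_counts = leaf_counts,
                 node_counts = node_counts, support = support),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated tree over", length(x$tree$tip.label), "isolates\n")
  cat("unique SNPs per leaf:\n")
  print(x$leaf_counts)
  cat("synapomorphic SNPs per internal node:\n")
  print(x$node_counts)
  invisible(x)
}

#' Write an annotated tree as newick plus a node-annotation TSV
#'
#' Internal node labels in the newick carry `support/snps`; the sidecar TSV
#' lists one row per node with its SNP count and (for internal edges)
#' bootstrap support.
#'
#' @param x an `annotated_tree`.
#' @param newick_path,tsv_path output files.
#' @param outgroup optional tip id to root the written tree on.
#' @export
write_annotated_tree <- function(x, newick_path, tsv_path, outgroup = NULL) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  for (nd in names(x$node_counts)) {
    i <- as.integer(nd) - ntip
    sup <- if (!is.null(x$support)) {
      e <- which(tr$edge[, 2] == as.integer(nd))
      if (length(e) && !is.na(x$support[e])) round(x$support[e]) else NA
    } else NA
    lab[i] <- if (is.na(sup)) as.character(x$node_counts[[nd]])
              else paste0(sup, "/", x$node_counts[[nd]])
  }
  tr$node.label <- lab
  if (!is.null(outgroup)) tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  ape::write.tree(tr, newick_path)
  leaf <- data.frame(node = names(x$leaf_counts), type = "leaf",
                     snps = as.integer(x$leaf_counts), support = NA_real_)
  node_sup <- vapply(names(x$node_counts), function(nd) {
    e <- which(x$tree$edge[, 2] == as.integer(nd))
    if (length(e) && !is.null(x$support)) x$support[e] else NA_real_
  }, numeric(1))
  internal <- data.frame(node = names(x$node_counts), type = "internal",
                         snps = as.integer(x$node_counts),
                         support = round(node_sup, 1))
  utils::write.table(rbind(leaf, internal), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(newick_path)
}
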