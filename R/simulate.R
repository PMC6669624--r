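#' Specify a synthetic isolate cohort
#'
#' Collects every parameter of the cohort simulator: the isolate tree with
#' per-branch planted mutation counts, genome geometry, the within-isolate
#' genotype mixture of the focal isolate, and the read model. Defaults are
#' the study conditions the package is validated under: six ~120 kb dsDNA
#' genomes, 50 substitutions and 5 indels (1-30 bp) per branch, an 89% coding
#' genome, a 0.7/0.3 two-genotype mixture in the focal isolate, and paired
#' 250 bp reads at a per-base error rate of 0.24% and ~2000x coverage.
#'
#' @param n_isolates number of leaf genomes.
#' @param genome_length ancestor genome length in bp (must be at least
#'   `10 * read_length`).
#' @param tree an [ape::phylo] rooted binary tree whose tip labels are the
#'   isolate ids and whose edge lengths are planted substitution counts per
#'   branch; `NULL` builds a default tree over `iso1..isoN` with
#'   `subs_per_branch` on every branch.
#' @param subs_per_branch substitutions planted on each branch of the default
#'   tree.
#' @param indels_per_branch indels planted on each branch.
#' @param indel_length_range inclusive bp range of indel lengths.
#' @param orf_density fraction of the ancestor genome covered by planted ORFs.
#' @param mixture named numeric vector of genotype proportions within the
#'   focal isolate (must sum to 1); the first genotype is the focal consensus.
#' @param revert_unique,revert_shared number of focal-branch (respectively
#'   internal-branch) substitutions that genotype 2 reverts to the ancestral
#'   base, creating SNVs that coincide with focal-unique (respectively
#'   shared) SNP columns.
#' @param private_subs novel substitutions private to each non-consensus
#'   genotype (SNVs at positions with no SNP column).
#' @param revert_indels number of focal-branch insertions genotype 2 lacks.
#' @param read_length,fragment_mean,fragment_sd paired-read geometry in bp.
#' @param read_error_rate uniform per-base error probability.
#' @param coverage_target mean read depth per position.
#' @param focal focal isolate id (default: first tip).
#' @param seed integer PRNG seed; all simulator operations are byte-identical
#'   for a fixed spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_isolates = 6, genome_length = 120000, tree = NULL,
                        subs_per_branch = 50, indels_per_branch = 5,
                        indel_length_range = c(1, 30), orf_density = 0.89,
                        mixture = c(g1 = 0.7, g2 = 0.3),
                        revert_unique = 11, revert_shared = 20,
                        private_subs = 35, revert_indels = 1,
                        read_length = 250, fragment_mean = 500,
                        fragment_sd = 50, read_error_rate = 0.0024,
                        coverage_target = 2000, focal = NULL, seed = 1) {
  if (is.null(tree)) tree <- default_cohort_tree(n_isolates, subs_per_branch)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  if (any(mixture < 0)) stop("mixture proportions must be non-negative")
  if (is.null(names(mixture)))
    names(mixture) <- paste0("g", seq_along(mixture))
  if (genome_length < 10 * read_length)
    stop("genome_length must be at least 10 * read_length")
  if (read_error_rate < 0 || indels_per_branch < 0 || orf_density < 0)
    stop("all rates must be non-negative")
  if (indel_length_range[1] < 1 || indel_length_range[2] < indel_length_range[1])
    stop("bad indel_length_range")
  if (is.null(focal)) focal <- tree$tip.label[1]
  if (!(focal %in% tree$tip.label)) stop("focal id not a tree tip")
  structure(list(
    n_isolates = length(tree$tip.label), genome_length = genome_length,
    tree = tree, indels_per_branch = indels_per_branch,
    indel_length_range = indel_length_range, orf_density = orf_density,
    mixture = mixture, revert_unique = revert_unique,
    revert_shared = revert_shared, private_subs = private_subs,
    revert_indels = revert_indels, read_length = read_length,
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    read_error_rate = read_error_rate, coverage_target = coverage_target,
    focal = focal, seed = as.integer(seed)), class = "cohort_spec")
}

#' Default rooted binary cohort tree
#'
#' Balanced for six isolates, pectinate otherwise; every branch carries
#' `subs_per_branch` as its length (planted substitution count).
#'
#' @param n number of isolates (>= 2).
#' @param subs_per_branch branch length assigned to every edge.
#' @return an [ape::phylo] tree with tips `iso1..isoN`.
#' @export
default_cohort_tree <- function(n, subs_per_branch = 50) {
  s <- subs_per_branch
  if (n == 6) {
    nwk <- sprintf(
      "((iso1:%d,iso2:%d):%d,((iso3:%d,iso4:%d):%d,(iso5:%d,iso6:%d):%d):%d);",
      s, s, s, s, s, s, s, s, s, s)
  } else {
    inner <- sprintf("iso%d:%d", n, s)
    for (k in (n - 1):1)
      inner <- sprintf("(iso%d:%d,%s):%d", k, s, inner, s)
    # strip the root branch length
    nwk <- paste0(sub(":[0-9]+$", "", inner), ";")
  }
  ape::read.tree(text = nwk)
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) sample(.BASES, n, replace = TRUE)

# codons that are neither stops nor ATG (ATG excluded so planted ORFs have a
# single unambiguous start)
.SAFE_CODONS <- local({
  all3 <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                          .BASES, paste0))
  setdiff(all3, c(STOP_CODONS, "ATG"))
})

#' Simulate an ancestor genome with a planted ORF layout
#'
#' Lays non-overlapping ORFs (start codon, non-stop codons, stop codon; both
#' strands) along the genome with intergenic spacers sized so that the coding
#' fraction approximates `orf_density`. An in-frame stop is written
#' immediately upstream of each start codon so the planted coordinates are
#' exactly recoverable by [scan_orfs()].
#'
#' @param spec a [cohort_spec()].
#' @return list with `genome` (string) and `orfs` (an `orf_table` of planted
#'   ORFs). Deterministic for a fixed spec.
#' @export
simulate_ancestor <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$orf_density > 0.95)
    stop("orf_density ", spec$orf_density, " unsatisfiable: non-overlapping ",
         "ORFs with spacers cannot exceed ~0.95 coding fraction")
  set.seed(spec$seed)
  L <- spec$genome_length
  g <- .random_seq(L)
  orfs <- list()
  if (spec$orf_density > 0) {
    d <- spec$orf_density
    pos <- 1L
    repeat {
      aa <- sample(60:500, 1)
      orf_nt <- 3L * (aa + 1L)
      spacer <- max(6L, stats::rpois(1, orf_nt * (1 - d) / d))
      start <- pos + spacer
      end <- start + orf_nt - 1L
      if (end + 6L > L) break
      strand <- sample(c("+", "-"), 1)
      body <- sample(.SAFE_CODONS, aa - 1L, replace = TRUE)
      orf_seq <- paste0("ATG", paste(body, collapse = ""),
                        sample(STOP_CODONS, 1))
      if (strand == "-") orf_seq <- .revcomp(orf_seq)
      g[start:end] <- strsplit(orf_seq, "")[[1]]
      # in-frame guard stop just upstream of the start codon
      if (strand == "+") g[(start - 3L):(start - 1L)] <- c("T", "A", "A")
      else g[(end + 1L):(end + 3L)] <- c("T", "T", "A")
      orfs[[length(orfs) + 1L]] <-
        data.frame(start = start, end = end, strand = strand, aa = aa)
      pos <- end + 1L
    }
  }
  orfs <- if (length(orfs)) do.call(rbind, orfs)
          else data.frame(start = integer(), end = integer(),
                          strand = character(), aa = integer())
  orfs$id <- sprintf("orf%03d", seq_len(nrow(orfs)))
  orfs <- orfs[, c("id", "start", "end", "strand", "aa")]
  class(orfs) <- c("orf_table", "data.frame")
  list(genome = paste(g, collapse = ""), orfs = orfs)
}

# interval overlap helper
.overlaps_any <- function(iv, span) {
  if (!nrow(iv)) return(FALSE)
  any(iv[, 1] <= span[2] & iv[, 2] >= span[1])
}

#' Evolve a cohort of isolate genomes along the spec tree
#'
#' Plants the per-branch substitution count (the branch length, rounded) and
#' `indels_per_branch` indels on every branch, applying each branch's events
#' in its parent's coordinate frame. Every event is recorded in a replayable
#' ledger; alignment bookkeeping via persistent site identifiers yields the
#' true multiple alignment of the leaves without running an aligner. The
#' focal isolate additionally receives its within-isolate genotype structure
#' (see [cohort_spec()]) and the implied true SNV table.
#'
#' @param ancestor output of [simulate_ancestor()].
#' @param spec the same [cohort_spec()].
#' @return object of class `cohort_truth`: list with `genomes` (named
#'   character, per leaf), `alignment` (a [genome_alignment()] of the leaves),
#'   `ledger` (data.frame of every planted event), `expected_snps` (truth
#'   table of gap-free polymorphic columns with uniqueness attribution),
#'   `orfs` (ancestor ORF table), `leaf_orfs` (per-leaf coordinate-shifted
#'   ORF tables with a `disrupted` flag), `genotypes`, `expected_snvs`,
#'   `sites` (per-leaf site-id vectors) and `spec`.
#' @export
evolve_cohort <- function(ancestor, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  anc_chars <- strsplit(ancestor$genome, "")[[1]]
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(sites = as.numeric(seq_along(anc_chars)),
                         bases = anc_chars)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths (planted substitution counts)")
  ledger <- list()
  ev_counter <- 0L  # per-insertion offset keeping site ids globally unique
  ilo <- spec$indel_length_range[1]; ihi <- spec$indel_length_range[2]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    st <- states[[parent]]
    glen <- length(st$sites)
    branch <- if (child <= ntip) tree$tip.label[child]
              else paste0("node", child)
    n_sub <- round(tree$edge.length[e])
    n_ind <- spec$indels_per_branch
    iv <- matrix(numeric(0), ncol = 2)
    events <- list()
    for (j in seq_len(n_ind)) {
      repeat {
        kind <- sample(c("insertion", "deletion"), 1)
        len <- if (ilo == ihi) ilo else sample(ilo:ihi, 1)
        if (kind == "deletion") {
          p <- sample.int(glen - len - 1L, 1) + 1L
          span <- c(p, p + len - 1L)
        } else {
          p <- sample.int(glen - 1L, 1)
          span <- c(p, p + 1L)
        }
        if (!.overlaps_any(iv, span)) break
        message("resampled overlapping indel on branch ", branch)
      }
      iv <- rbind(iv, span)
      events[[length(events) + 1L]] <- list(kind = kind, pos = p, len = len)
    }
    blocked <- if (nrow(iv)) unlist(mapply(seq, iv[, 1], iv[, 2],
                                           SIMPLIFY = FALSE)) else integer()
    avail <- setdiff(seq_len(glen), blocked)
    sub_pos <- if (n_sub > 0) sample(avail, n_sub) else integer()
    for (p in sub_pos)
      events[[length(events) + 1L]] <- list(kind = "substitution", pos = p,
                                            len = 1L)
    ord <- order(-vapply(events, `[[`, numeric(1), "pos"))
    st2 <- st
    for (ev in events[ord]) {
      p <- ev$pos
      if (ev$kind == "substitution") {
        ref <- st2$bases[p]
        alt <- sample(setdiff(.BASES, ref), 1)
        st2$bases[p] <- alt
        ledger[[length(ledger) + 1L]] <- data.frame(
          branch = branch, kind = "substitution", position = p,
          site = st2$sites[p], site2 = NA_real_, ref_allele = ref,
          alt_allele = alt, length = 1L)
      } else if (ev$kind == "deletion") {
        idx <- p:(p + ev$len - 1L)
        ledger[[length(ledger) + 1L]] <- data.frame(
          branch = branch, kind = "deletion", position = p,
          site = st2$sites[p], site2 = NA_real_,
          ref_allele = paste(st2$bases[idx], collapse = ""),
          alt_allele = "", length = ev$len)
        st2$sites <- st2$sites[-idx]
        st2$bases <- st2$bases[-idx]
      } else {
        left <- st2$sites[p]
        right <- if (p < length(st2$sites)) st2$sites[p + 1L] else left + 1
        ev_counter <- ev_counter + 1L
        new_sites <- left + (right - left) *
          ((seq_len(ev$len) - 0.5) / ev$len * 0.9 + 0.04 + ev_counter * 1e-7)
        ins <- .random_seq(ev$len)
        ledger[[length(ledger) + 1L]] <- data.frame(
          branch = branch, kind = "insertion", position = p,
          site = left, site2 = new_sites[1], ref_allele = "",
          alt_allele = paste(ins, collapse = ""), length = ev$len)
        st2$sites <- append(st2$sites, new_sites, after = p)
        st2$bases <- append(st2$bases, ins, after = p)
      }
    }
    states[[child]] <- st2
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame(branch = character(), kind = character(),
                            position = integer(), site = numeric(),
                            site2 = numeric(), ref_allele = character(),
                            alt_allele = character(), length = integer())
  rownames(ledger) <- NULL

  leaf_ids <- tree$tip.label
  leaf_states <- states[seq_len(ntip)]
  names(leaf_states) <- leaf_ids
  genomes <- vapply(leaf_states, function(s) paste(s$bases, collapse = ""),
                    character(1))
  all_sites <- sort(unique(unlist(lapply(leaf_states, `[[`, "sites"))))
  amat <- matrix("-", nrow = ntip, ncol = length(all_sites),
                 dimnames = list(leaf_ids, NULL))
  for (id in leaf_ids) {
    s <- leaf_states[[id]]
    amat[id, match(s$sites, all_sites)] <- s$bases
  }
  aln <- genome_alignment(stats::setNames(
    apply(amat, 1, paste, collapse = ""), leaf_ids))

  expected_snps <- .truth_snp_table(amat, all_sites)
  leaf_orfs <- lapply(leaf_ids, function(id)
    .shift_orfs(ancestor$orfs, leaf_states[[id]], ledger, id, tree))
  names(leaf_orfs) <- leaf_ids

  truth <- list(genomes = genomes, alignment = aln, ledger = ledger,
                expected_snps = expected_snps, orfs = ancestor$orfs,
                leaf_orfs = leaf_orfs, sites = lapply(leaf_states, `[[`, "sites"),
                ancestor = ancestor$genome, spec = spec)
  truth <- c(truth, .build_genotypes(truth, spec, tree))
  class(truth) <- "cohort_truth"
  truth
}

# truth table of gap-free polymorphic columns, attribution by symbol counting
.truth_snp_table <- function(amat, all_sites) {
  n <- nrow(amat)
  gapfree <- colSums(amat == "-") == 0
  poly <- colSums(amat != rep(amat[1, ], each = n)) > 0
  keep <- which(gapfree & poly)
  rows <- lapply(keep, function(k) {
    col <- amat[, k]
    cnt <- table(col)
    uniq <- rownames(amat)[cnt[col] == 1]
    data.frame(column = k, site = all_sites[k],
               pattern = paste(col, collapse = ""),
               attribution = paste(uniq, collapse = ","),
               n_attributed = length(uniq))
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(column = integer(), site = numeric(),
                         pattern = character(), attribution = character(),
                         n_attributed = integer())
  rownames(out) <- NULL
  out
}

# shift ancestor ORF coordinates into one leaf's frame via its site map;
# flag ORFs whose interior lost or gained sites
.shift_orfs <- function(orfs, leaf_state, ledger, id, tree) {
  if (!nrow(orfs)) {
    out <- orfs; out$disrupted <- logical(0); return(out)
  }
  sites <- leaf_state$sites
  pos_of_site <- function(s) {
    i <- findInterval(s, sites)
    ifelse(i >= 1 & sites[pmax(i, 1)] == s, i, NA_integer_)
  }
  start <- pos_of_site(orfs$start)
  end <- pos_of_site(orfs$end)
  n_inside <- vapply(seq_len(nrow(orfs)), function(i)
    sum(sites >= orfs$start[i] & sites <= orfs$end[i]), numeric(1))
  out <- data.frame(id = orfs$id, start = start, end = end,
                    strand = orfs$strand, aa = orfs$aa,
                    disrupted = is.na(start) | is.na(end) |
                      n_inside != (orfs$end - orfs$start + 1))
  class(out) <- c("orf_table", "data.frame")
  out
}

# within-isolate genotype structure of the focal isolate + true SNV table
.build_genotypes <- function(truth, spec, tree) {
  focal <- spec$focal
  mix <- spec$mixture
  sites_f <- truth$sites[[focal]]
  bases_f <- strsplit(truth$genomes[[focal]], "")[[1]]
  es <- truth$expected_snps
  ids <- rownames(truth$alignment$mat)
  others <- setdiff(ids, focal)

  # ledger substitutions on the terminal branch to the focal isolate that
  # survive in the focal genome and sit in a focal-unique SNP column where
  # all other isolates share one base
  led <- truth$ledger
  term <- led[led$branch == focal & led$kind == "substitution", , drop = FALSE]
  col_of_site <- es$site
  uniq_cand <- integer()
  shared_base <- character()
  for (i in seq_len(nrow(term))) {
    k <- match(term$site[i], col_of_site)
    if (is.na(k) || es$attribution[k] != focal) next
    pat <- strsplit(es$pattern[k], "")[[1]]
    names(pat) <- ids
    ob <- unique(pat[others])
    if (length(ob) != 1) next
    uniq_cand <- c(uniq_cand, i)
    shared_base <- c(shared_base, ob)
  }
  # internal-branch substitutions on the root-to-focal path whose site is a
  # non-unique SNP column in the focal genome
  ntip <- length(tree$tip.label)
  node <- match(focal, tree$tip.label)
  path_nodes <- character()  # internal branches on the root-to-focal path
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (!length(parent) || parent == ntip + 1L) break
    path_nodes <- c(path_nodes, paste0("node", parent))
    node <- parent
  }
  internal <- led[led$branch %in% path_nodes & led$kind == "substitution", ,
                  drop = FALSE]
  shared_cand <- integer()
  for (i in seq_len(nrow(internal))) {
    k <- match(internal$site[i], col_of_site)
    if (is.na(k)) next
    attributed <- strsplit(es$attribution[k], ",", fixed = TRUE)[[1]]
    if (focal %in% attributed) next
    fp <- match(internal$site[i], sites_f)
    if (is.na(fp) || bases_f[fp] != internal$alt_allele[i]) next
    shared_cand <- c(shared_cand, i)
  }

  n_u <- min(spec$revert_unique, length(uniq_cand))
  n_s <- min(spec$revert_shared, length(shared_cand))
  pick_u <- if (n_u > 0) sort(sample(seq_along(uniq_cand), n_u)) else integer()
  pick_s <- if (n_s > 0) sort(sample(seq_along(shared_cand), n_s)) else integer()

  used_pos <- integer()
  snvs <- list()
  genotypes <- list()
  genotypes[[names(mix)[1]]] <- list(id = names(mix)[1],
                                     proportion = unname(mix[1]),
                                     subs = data.frame(pos = integer(),
                                                       ref = character(),
                                                       alt = character()),
                                     dels = data.frame(pos = integer(),
                                                       len = integer()))
  snp_cols_f <- stats::na.omit(match(es$site, sites_f))
  for (gk in seq_along(mix)[-1]) {
    gid <- names(mix)[gk]
    # genotype-2 lacks up to revert_indels of the focal branch's insertions
    dels <- data.frame(pos = integer(), len = integer())
    if (gk == 2 && spec$revert_indels > 0) {
      tins <- led[led$branch == focal & led$kind == "insertion", , drop = FALSE]
      k <- 0L
      for (i in seq_len(nrow(tins))) {
        if (k >= spec$revert_indels) break
        fp <- match(tins$site2[i], sites_f)
        if (is.na(fp) || fp + tins$length[i] - 1L > length(sites_f)) next
        dels <- rbind(dels, data.frame(pos = fp, len = tins$length[i]))
        k <- k + 1L
      }
    }
    del_span <- if (nrow(dels))
      unlist(mapply(function(p, l) p:(p + l - 1L), dels$pos, dels$len,
                    SIMPLIFY = FALSE)) else integer()
    subs <- list()
    if (gk == 2) {
      for (j in pick_u) {
        i <- uniq_cand[j]
        fp <- match(term$site[i], sites_f)
        subs[[length(subs) + 1L]] <- data.frame(
          pos = fp, ref = bases_f[fp], alt = shared_base[j],
          class = "unique_snp_overlap")
      }
      for (j in pick_s) {
        i <- shared_cand[j]
        fp <- match(internal$site[i], sites_f)
        subs[[length(subs) + 1L]] <- data.frame(
          pos = fp, ref = bases_f[fp], alt = internal$ref_allele[i],
          class = "snp_overlap")
      }
    }
    # private novel substitutions away from any SNP column or prior site
    avail <- setdiff(seq_along(sites_f),
                     c(snp_cols_f, used_pos, del_span,
                       vapply(subs, function(s) s$pos, numeric(1))))
    priv <- sample(avail, min(spec$private_subs, length(avail)))
    for (fp in priv)
      subs[[length(subs) + 1L]] <- data.frame(
        pos = fp, ref = bases_f[fp],
        alt = sample(setdiff(.BASES, bases_f[fp]), 1), class = "no_overlap")
    subs <- if (length(subs)) do.call(rbind, subs)
            else data.frame(pos = integer(), ref = character(),
                            alt = character(), class = character())
    subs <- subs[order(subs$pos), , drop = FALSE]
    used_pos <- c(used_pos, subs$pos, del_span)
    genotypes[[gid]] <- list(id = gid, proportion = unname(mix[gk]),
                             subs = subs, dels = dels)
    snvs[[gid]] <- subs
  }
  # true SNV table: frequency = sum of proportions of genotypes carrying alt
  snv_tab <- list()
  for (gid in names(snvs)) {
    s <- snvs[[gid]]
    if (!nrow(s)) next
    s$freq <- genotypes[[gid]]$proportion
    snv_tab[[gid]] <- s
  }
  snv_tab <- if (length(snv_tab)) do.call(rbind, snv_tab)
             else data.frame(pos = integer(), ref = character(),
                             alt = character(), class = character(),
                             freq = numeric())
  if (nrow(snv_tab)) {
    agg <- stats::aggregate(freq ~ pos + ref + alt + class, snv_tab, sum)
    snv_tab <- agg[order(agg$pos, agg$alt), ]
    rownames(snv_tab) <- NULL
  }
  list(genotypes = genotypes, expected_snvs = snv_tab)
}

#' Materialise one genotype's sequence from the focal consensus
#'
#' @param truth a `cohort_truth`.
#' @param genotype genotype id in `truth$genotypes`.
#' @return the genotype genome as a string.
#' @export
genotype_sequence <- function(truth, genotype) {
  g <- truth$genotypes[[genotype]]
  chars <- strsplit(truth$genomes[[truth$spec$focal]], "")[[1]]
  if (nrow(g$subs)) chars[g$subs$pos] <- g$subs$alt
  if (nrow(g$dels)) {
    drop <- unlist(mapply(function(p, l) p:(p + l - 1L), g$dels$pos,
                          g$dels$len, SIMPLIFY = FALSE))
    chars <- chars[-drop]
  }
  paste(chars, collapse = "")
}

#' Replay the mutation ledger from the ancestor
#'
#' Independently re-applies every ledger event on the root-to-leaf path of
#' each isolate, in recorded order, to reconstruct the leaf genomes. Used as
#' the oracle that the simulator's bookkeeping is exact.
#'
#' @param ancestor_genome the ancestor sequence (string).
#' @param ledger the `cohort_truth` ledger.
#' @param tree the spec tree.
#' @return named character vector of reconstructed leaf genomes.
#' @export
replay_ledger <- function(ancestor_genome, ledger, tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- strsplit(ancestor_genome, "")[[1]]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    branch <- if (child <= ntip) tree$tip.label[child]
              else paste0("node", child)
    chars <- states[[parent]]
    ev <- ledger[ledger$branch == branch, , drop = FALSE]
    ev <- ev[order(-ev$position), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      p <- ev$position[i]
      if (ev$kind[i] == "substitution") {
        stopifnot(chars[p] == ev$ref_allele[i])
        chars[p] <- ev$alt_allele[i]
      } else if (ev$kind[i] == "deletion") {
        chars <- chars[-(p:(p + ev$length[i] - 1L))]
      } else {
        chars <- append(chars, strsplit(ev$alt_allele[i], "")[[1]], after = p)
      }
    }
    states[[child]] <- chars
  }
  out <- vapply(states[seq_len(ntip)], paste, character(1), collapse = "")
  stats::setNames(out, tree$tip.label)
}

# map read start positions in a genotype's frame to the focal-consensus frame,
# emitting CIGARs with D runs where the genotype lacks consensus bases
.map_reads_to_ref <- function(starts, rl, dels) {
  n <- length(starts)
  cigar <- rep(paste0(rl, "M"), n)
  if (!nrow(dels))
    return(list(pos = starts, cigar = cigar))
  dels <- dels[order(dels$pos), , drop = FALSE]
  cumlen <- cumsum(dels$len)
  # genotype coordinate of the last base before each deleted run
  gb <- dels$pos - 1L - c(0L, cumlen[-length(cumlen)])
  shift <- c(0L, cumlen)[findInterval(starts - 1L, gb) + 1L]
  ends <- starts + rl - 1L
  pos <- starts + shift
  nspan <- findInterval(ends - 1L, gb) - findInterval(starts - 1L, gb)
  for (r in which(nspan > 0)) {
    s <- starts[r]; e <- ends[r]
    js <- which(gb >= s & gb <= e - 1L)
    bounds <- c(s - 1L, gb[js], e)
    segs <- diff(bounds)
    parts <- character(0)
    for (k in seq_along(js))
      parts <- c(parts, paste0(segs[k], "M"), paste0(dels$len[js[k]], "D"))
    cigar[r] <- paste0(paste(parts, collapse = ""),
                       segs[length(segs)], "M")
  }
  list(pos = pos, cigar = cigar)
}

#' Simulate paired reads from the focal isolate's genotype mixture
#'
#' Fragments are drawn genotype-by-genotype according to the mixture
#' proportions (the mixture is realised at the read level, not by pre-mixing
#' sequences); both fragment orientations are equiprobable; mates are the two
#' fragment ends. A uniform per-base error is injected independently of the
#' (constant Q37) quality symbols. Because every read's origin is known, true
#' alignments against the focal consensus are emitted directly -- no mapper
#' -- and aggregated into a pileup.
#'
#' @param truth a `cohort_truth` from [evolve_cohort()].
#' @param spec the same [cohort_spec()]; `coverage_target` must be positive.
#' @return object of class `read_set`: list with `reads` (data.frame `qname`,
#'   `mate`, `flag`, `pos`, `cigar`, `seq` -- `seq` reference-forward --,
#'   `genotype`), `qual` (the constant quality string), `pileup` (an
#'   `isovar_pileup` over the focal consensus), `ref` (the consensus),
#'   `ref_id` and `spec`.
#' @export
simulate_reads <- function(truth, spec) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(spec, "cohort_spec"))
  if (spec$coverage_target <= 0) stop("coverage_target must be positive")
  set.seed(spec$seed + 2L)
  focal <- spec$focal
  ref <- truth$genomes[[focal]]
  L <- nchar(ref)
  rl <- spec$read_length
  gids <- names(spec$mixture)
  gseq <- vapply(gids, function(g) genotype_sequence(truth, g), character(1))
  glen <- nchar(gseq)
  n_pairs <- round(spec$coverage_target * L / (2 * rl))
  gidx <- sample(gids, n_pairs, replace = TRUE, prob = spec$mixture)
  flen <- pmax(rl, pmin(round(stats::rnorm(n_pairs, spec$fragment_mean,
                                           spec$fragment_sd)),
                        min(glen)))
  gstart <- 1L + floor(stats::runif(n_pairs) * (glen[gidx] - flen + 1))
  minus <- stats::runif(n_pairs) < 0.5
  qname <- sprintf("frag%07d", seq_len(n_pairs))

  reads <- vector("list", length(gids))
  for (k in seq_along(gids)) {
    g <- gids[k]
    idx <- which(gidx == g)
    if (!length(idx)) next
    s1 <- gstart[idx]
    s2 <- gstart[idx] + flen[idx] - rl
    m1 <- .map_reads_to_ref(s1, rl, truth$genotypes[[g]]$dels)
    m2 <- .map_reads_to_ref(s2, rl, truth$genotypes[[g]]$dels)
    seq1 <- substring(gseq[g], s1, s1 + rl - 1L)
    seq2 <- substring(gseq[g], s2, s2 + rl - 1L)
    # fragment on the minus strand: mate 1 is the right end, reverse strand
    flag1 <- ifelse(minus[idx], 16L, 0L)
    flag2 <- ifelse(minus[idx], 0L, 16L)
    reads[[k]] <- data.frame(
      qname = rep(qname[idx], 2L),
      mate = rep(c(1L, 2L), each = length(idx)),
      flag = c(flag1, flag2),
      pos = c(ifelse(minus[idx], m2$pos, m1$pos),
              ifelse(minus[idx], m1$pos, m2$pos)),
      cigar = c(ifelse(minus[idx], m2$cigar, m1$cigar),
                ifelse(minus[idx], m1$cigar, m2$cigar)),
      seq = c(ifelse(minus[idx], seq2, seq1),
              ifelse(minus[idx], seq1, seq2)),
      genotype = g, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)
  reads <- reads[order(reads$qname, reads$mate), , drop = FALSE]
  rownames(reads) <- NULL
  if (spec$read_error_rate > 0)
    reads$seq <- as.character(.mutate_reads(reads$seq, spec$read_error_rate))
  counts <- .pileup_accumulate(L, reads$pos, reads$cigar, reads$seq)
  attr(counts, "clipped") <- NULL
  colnames(counts) <- c("A", "C", "G", "T", "del", "ins")
  pileup <- structure(
    list(ref_id = focal, ref = strsplit(ref, "")[[1]], counts = counts,
         coverage = as.integer(rowSums(counts[, 1:5, drop = FALSE]))),
    class = "isovar_pileup")
  structure(list(reads = reads, qual = strrep(rawToChar(as.raw(33L + 37L)), rl),
                 pileup = pileup, ref = ref, ref_id = focal, spec = spec),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", nrow(x$reads), "reads over", x$ref_id,
      "(", nchar(x$ref), "bp )\n")
  print(table(x$reads$genotype))
  invisible(x)
}

#' Write a cohort's genomes, alignment, annotations and ledger
#'
#' Emits `genomes.fasta` (ungapped leaf genomes), `alignment.fasta` (the true
#' multiple alignment), `orfs_ancestor.gff3` and `ledger.tsv` under `dir`.
#'
#' @param truth a `cohort_truth`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(truth$genomes),
                              file.path(dir, "genomes.fasta"))
  aln <- stats::setNames(apply(truth$alignment$mat, 1, paste, collapse = ""),
                         truth$alignment$ids)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln),
                              file.path(dir, "alignment.fasta"))
  write_orf_gff(truth$orfs, file.path(dir, "orfs_ancestor.gff3"), "ancestor")
  utils::write.table(truth$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a read set as paired FASTQ, minimal SAM and pileup TSV
#'
#' Emits `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>.sam` and
#' `<prefix>_pileup.tsv` under `dir`. FASTQ sequences are in sequencing
#' orientation (reverse-strand mates reverse-complemented); SAM records keep
#' the reference-forward sequence with FLAG 16.
#'
#' @param rs a `read_set` from [simulate_reads()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"reads"`).
#' @return the directory path, invisibly.
#' @export
write_reads <- function(rs, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in 1:2) {
    sel <- rs$reads[rs$reads$mate == m, , drop = FALSE]
    seqs <- Biostrings::DNAStringSet(sel$seq)
    rc <- sel$flag == 16L
    seqs[rc] <- Biostrings::reverseComplement(seqs[rc])
    names(seqs) <- paste0(sel$qname, "/", m)
    q <- Biostrings::PhredQuality(rep(rs$qual, length(seqs)))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(seqs, q),
      file.path(dir, paste0(prefix, "_R", m, ".fastq")))
  }
  write_sam(rs$reads, file.path(dir, paste0(prefix, ".sam")),
            rs$ref_id, nchar(rs$ref))
  write_pileup_tsv(rs$pileup, file.path(dir, paste0(prefix, "_pileup.tsv")))
  invisible(dir)
}

#' Simulate a full cohort (ancestor, isolate genomes, truth ledger)
#'
#' Convenience wrapper: [simulate_ancestor()] then [evolve_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_truth`.
#' @export
simulate_cohort <- function(spec) {
  evolve_cohort(simulate_ancestor(spec), spec)
}
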