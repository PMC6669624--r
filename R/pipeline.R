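#' Build a run configuration
#'
#' Exactly one of `simulate` (a list of [cohort_spec()] arguments) or
#' `inputs` (paths to real data: `alignment`, optionally `reads` (SAM) and
#' `orfs` (GFF3 per isolate)) must be supplied.
#'
#' @param simulate named list of [cohort_spec()] overrides, or `NULL`.
#' @param inputs named list with `alignment` (aligned FASTA) and optionally
#'   `reads`, `orfs`; or `NULL`.
#' @param focal focal isolate id (defaults to the simulation spec's focal, or
#'   the first alignment record).
#' @param reference reference isolate id for ORF comparison (defaults to the
#'   second isolate).
#' @param min_frequency,min_coverage SNV calling thresholds.
#' @param min_orf_aa ORF absence threshold in amino acids.
#' @param indel_window SNP-scan exclusion radius around gap columns.
#' @param bootstrap bootstrap replicate count for the tree (0 disables).
#' @param seed run seed.
#' @param outdir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, focal = NULL,
                       reference = NULL, min_frequency = 0.1,
                       min_coverage = 10, min_orf_aa = 50, indel_window = 0,
                       bootstrap = 100, seed = 1, outdir = tempfile("isovar_run")) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of `simulate` and `inputs` must be given")
  if (!is.null(inputs) && is.null(inputs$alignment))
    stop("real-input runs need inputs$alignment")
  stopifnot(min_frequency >= 0, min_frequency <= 1, min_coverage >= 0,
            min_orf_aa >= 0, indel_window >= 0, bootstrap >= 0)
  structure(list(simulate = simulate, inputs = inputs, focal = focal,
                 reference = reference, min_frequency = min_frequency,
                 min_coverage = min_coverage, min_orf_aa = min_orf_aa,
                 indel_window = indel_window, bootstrap = bootstrap,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> SNP scan -> ORF effects -> SNV calling
#' -> SNP/SNV cross-reference -> phylogeny, writing every table/figure
#' artifact plus a manifest to `config$outdir`. Identical config and seed
#' give identical outputs and manifest.
#'
#' @param config a [run_config()].
#' @return object of class `isovar_run`: list with the stage results
#'   (`truth`, `snps`, `summary`, `orf_comparison`, `snvs`, `mixture`,
#'   `tree`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  truth <- NULL; rs <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- config$seed
    spec <- do.call(cohort_spec, args)
    truth <- simulate_cohort(spec)
    rs <- simulate_reads(truth, spec)
    aln <- truth$alignment
    focal <- spec$focal
    genomes <- truth$genomes
    log_stage("simulate", "%d isolates, %d ledger events, %d reads",
              length(aln$ids), nrow(truth$ledger), nrow(rs$reads))
  } else {
    aln <- read_genome_alignment(config$inputs$alignment)
    focal <- if (!is.null(config$focal)) config$focal else aln$ids[1]
    genomes <- stats::setNames(
      vapply(aln$ids, function(id) ungapped_sequence(aln, id), character(1)),
      aln$ids)
    log_stage("load", "alignment of %d isolates, %d columns",
              length(aln$ids), aln$length)
  }
  reference <- if (!is.null(config$reference)) config$reference
               else setdiff(aln$ids, focal)[1]

  ## SNP scan
  snps <- scan_snp_columns(aln, indel_window = config$indel_window)
  summ <- summarize_snps(snps, aln)
  log_stage("snps", "%d SNP columns, %d unique to %s", nrow(snps),
            summ$unique_counts[[focal]], focal)

  ## ORFs + coding effects
  orfs <- lapply(genomes, scan_orfs, min_aa = config$min_orf_aa)
  focal_orfs <- orfs[[focal]]
  snps <- .annotate_snp_records(snps, genomes[[focal]], focal_orfs, focal,
                                setdiff(aln$ids, focal))
  orf_cmp <- compare_orf_tables(focal_orfs, orfs[[reference]], aln,
                                focal, reference,
                                focal_genome = genomes[[focal]],
                                ref_genome = genomes[[reference]],
                                min_aa = config$min_orf_aa)
  log_stage("orfs", "%d focal ORFs vs %d reference ORFs",
            nrow(focal_orfs), nrow(orfs[[reference]]))

  ## SNVs
  snvs <- NULL; mixture <- NULL
  pile <- if (!is.null(rs)) rs$pileup
          else if (!is.null(config$inputs$reads))
            build_pileup(config$inputs$reads, reference = genomes[[focal]])
  if (!is.null(pile)) {
    snvs <- call_snvs(pile, min_frequency = config$min_frequency,
                      min_coverage = config$min_coverage)
    snvs <- annotate_snvs(snvs, genomes[[focal]], focal_orfs)
    overlaps <- classify_overlaps(snvs, snps, focal, aln = aln)
    snvs$overlap_class <- overlaps$class
    mixture <- mixture_report(overlaps, summ, focal)
    log_stage("snvs", "%d SNVs; overlap classes %s", nrow(snvs),
              paste(names(mixture$class_counts), mixture$class_counts,
                    sep = "=", collapse = " "))
  }

  ## tree
  D <- p_distance(aln)
  tree <- me_refine(nj_tree(D), D)
  support <- if (config$bootstrap > 0)
    bootstrap_support(aln, tree, n_replicates = config$bootstrap,
                      seed = config$seed)
  ann <- annotate_snp_counts(tree, snps, support = support)
  log_stage("tree", "%d-taxon tree, %d internal nodes annotated",
            length(tree$tip.label), length(ann$node_counts))

  ## artifacts
  out <- config$outdir
  files <- c(snp_table = "snp_table.tsv", snp_summary = "snp_summary.tsv",
             orf_comparison = "orf_comparison.tsv",
             tree = "tree.nwk", node_annotations = "node_annotations.tsv")
  write_snp_table(snps, file.path(out, files["snp_table"]))
  .write_snp_summary(summ, file.path(out, files["snp_summary"]))
  utils::write.table(as.data.frame(orf_cmp),
                     file.path(out, files["orf_comparison"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotated_tree(ann, file.path(out, files["tree"]),
                       file.path(out, files["node_annotations"]))
  if (!is.null(snvs)) {
    files <- c(files, snv_table = "snv_table.tsv",
               mixture_report = "mixture_report.tsv",
               mixture_summary = "mixture_summary.txt")
    write_snv_table(snvs, file.path(out, "snv_table.tsv"))
    write_mixture_report(mixture, file.path(out, "mixture_report.tsv"),
                         file.path(out, "mixture_summary.txt"))
  }

  manifest <- list(
    package = "isovar",
    version = as.character(utils::packageVersion("isovar")),
    seed = config$seed,
    parameters = config[c("min_frequency", "min_coverage", "min_orf_aa",
                          "indel_window", "bootstrap")],
    focal = focal, reference = reference,
    mode = if (!is.null(config$simulate)) "simulate" else "real",
    counts = list(
      columns_scanned = aln$length, snps = nrow(snps),
      unique_to_focal = unname(summ$unique_counts[[focal]]),
      snvs = if (!is.null(snvs)) nrow(snvs) else 0L,
      unique_snp_overlaps = if (!is.null(mixture))
        unname(mixture$class_counts[["unique_snp_overlap"]]) else 0L),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), names(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(truth = truth, reads = rs, snps = snps, summary = summ,
                 orf_comparison = orf_cmp, snvs = snvs, mixture = mixture,
                 tree = ann, manifest = manifest, outdir = out),
            class = "isovar_run")
}

# per-record coding effect of the focal base vs the shared non-focal base
.annotate_snp_records <- function(snps, focal_genome, focal_orfs, focal,
                                  others) {
  n <- nrow(snps)
  snps$orf_id <- NA_character_
  snps$substitution <- character(n)
  bases <- snp_bases(snps)
  fpos <- snps[[paste0(focal, ".pos")]]
  for (i in seq_len(n)) {
    ob <- unique(bases[i, others])
    if (length(ob) != 1 || !(ob %in% c("A", "C", "G", "T"))) next
    if (bases[i, focal] == ob) next
    eff <- annotate_effect(focal_genome, focal_orfs, fpos[i], ob)
    snps$orf_id[i] <- eff$orf_id
    snps$substitution[i] <- eff$substitution
  }
  snps
}

.write_snp_summary <- function(summ, path) {
  ids <- names(summ$unique_counts)
  df <- data.frame(isolate = ids, unique_snps = as.integer(summ$unique_counts))
  for (id in ids) {
    df[[paste0("snps_vs_", id)]] <- summ$pairwise_snps[, id]
    df[[paste0("identity_vs_", id)]] <- summ$pairwise_identity[, id]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.isovar_run <- function(x, ...) {
  cat("isovar run (", x$manifest$mode, " mode), outputs in ", x$outdir,
      "\n", sep = "")
  cat("  SNP columns:", x$manifest$counts$snps,
      "| unique to focal:", x$manifest$counts$unique_to_focal, "\n")
  if (!is.null(x$snvs)) {
    cat("  SNVs:", nrow(x$snvs), "\n")
    print(x$mixture)
  }
  invisible(x)
}
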