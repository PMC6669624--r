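test_that("pileups tally reads position by position", {
  aln <- data.frame(pos = 1L, cigar = "4M", seq = "ACGT")
  p <- build_pileup(aln, reference = "ACGTAA")
  expect_equal(p$coverage, c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(p$counts[2, "C"]), 1L)

  two <- data.frame(pos = c(1L, 1L), cigar = c("4M", "4M"),
                    seq = c("ACGT", "AGGT"))
  p <- build_pileup(two, reference = "ACGT")
  expect_equal(unname(p$counts[2, "C"]), 1L)
  expect_equal(unname(p$counts[2, "G"]), 1L)
  expect_equal(p$coverage[2], 2L)

  # deletions count as coverage; insertions anchor on the preceding base
  d <- data.frame(pos = 1L, cigar = "2M2D2M", seq = "ACGT")
  p <- build_pileup(d, reference = "ACGTAA")
  expect_equal(unname(p$counts[3, "del"]), 1L)
  expect_equal(p$coverage[3], 1L)
  i <- data.frame(pos = 1L, cigar = "2M2I2M", seq = "ACTTGT")
  p <- build_pileup(i, reference = "ACGT")
  expect_equal(unname(p$counts[2, "ins"]), 1L)

  # overhang clipped with a warning; unknown ops rejected
  expect_warning(build_pileup(data.frame(pos = 3L, cigar = "4M", seq = "ACGT"),
                              reference = "ACGT"), "clipped")
  expect_error(build_pileup(data.frame(pos = 1L, cigar = "4X", seq = "ACGT"),
                            reference = "ACGT"), "CIGAR")
})

test_that("SAM and pileup TSV round trips preserve the pileup", {
  s <- small_spec(seed = 12, genome_length = 3000, coverage_target = 25)
  tr <- simulate_cohort(s)
  rs <- simulate_reads(tr, s)
  dir <- tempfile(); write_reads(rs, dir)
  p2 <- build_pileup(file.path(dir, "reads.sam"),
                     reference = tr$genomes[[s$focal]])
  expect_equal(p2$counts, rs$pileup$counts)
  p3 <- read_pileup_tsv(file.path(dir, "reads_pileup.tsv"))
  expect_equal(unname(p3$counts), unname(rs$pileup$counts))
  expect_equal(p3$ref, rs$pileup$ref)
})

test_that("pileup counts agree with the Rsamtools oracle", {
  s <- small_spec(seed = 2, genome_length = 4000, coverage_target = 30)
  tr <- simulate_cohort(s)
  rs <- simulate_reads(tr, s)
  dir <- tempfile(); write_reads(rs, dir)
  bam <- Rsamtools::asBam(file.path(dir, "reads.sam"), tempfile(),
                          overwrite = TRUE)
  oracle <- Rsamtools::pileup(bam, pileupParam = Rsamtools::PileupParam(
    max_depth = 10000, min_base_quality = 0, min_mapq = 0,
    distinguish_strands = FALSE, include_deletions = TRUE,
    include_insertions = FALSE))
  tab <- xtabs(count ~ pos + nucleotide, data = oracle)
  L <- nchar(tr$genomes[[s$focal]])
  for (b in c("A", "C", "G", "T", "-")) {
    v <- rep(0L, L)
    v[as.integer(rownames(tab))] <- tab[, b]
    col <- if (b == "-") "del" else b
    expect_equal(v, unname(rs$pileup$counts[, col]))
  }
})

test_that("the frequency-threshold caller is inclusive, multi-allelic and monotone", {
  mk <- function(ref, counts) {
    cm <- matrix(0L, nchar(ref), 6,
                 dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
    for (i in seq_along(counts)) cm[i, names(counts[[i]])] <- counts[[i]]
    structure(list(ref_id = "r", ref = strsplit(ref, "")[[1]], counts = cm,
                   coverage = as.integer(rowSums(cm[, 1:5, drop = FALSE]))),
              class = "isovar_pileup")
  }
  # pure pileup: no calls
  p <- mk("AAAA", list(c(A = 50L), c(A = 50L), c(A = 50L), c(A = 50L)))
  expect_equal(nrow(call_snvs(p)), 0L)

  # boundary inclusive: 10/100 at threshold 0.1 is reported
  p <- mk("A", list(c(A = 90L, G = 10L)))
  got <- call_snvs(p, min_frequency = 0.1, min_coverage = 10)
  expect_equal(nrow(got), 1L)
  expect_equal(got$frequency, 0.1)
  expect_equal(got$alt, "G")

  # multi-allelic site: one record per alternate
  p <- mk("T", list(c(T = 60L, A = 20L, C = 20L)))
  got <- call_snvs(p)
  expect_equal(got$alt, c("A", "C"))
  expect_equal(got$position, c(1L, 1L))

  # coverage floor
  p <- mk("A", list(c(A = 5L, G = 4L)))
  expect_equal(nrow(call_snvs(p, min_coverage = 10)), 0L)

  # non-ACGT reference site skipped with warning
  p <- mk("N", list(c(A = 50L, G = 50L)))
  expect_warning(got <- call_snvs(p), "non-ACGT")
  expect_equal(nrow(got), 0L)

  # monotone in the threshold, and alternate frequencies sum below 1
  set.seed(99)
  for (k in 1:10) {
    L <- 50
    cm <- matrix(rpois(L * 4, 20), L, 4)
    p <- mk(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""),
            lapply(seq_len(L), function(i)
              stats::setNames(as.integer(cm[i, ]), c("A", "C", "G", "T"))))
    lo <- call_snvs(p, min_frequency = 0.1)
    hi <- call_snvs(p, min_frequency = 0.25)
    expect_true(all(paste(hi$position, hi$alt) %in% paste(lo$position, lo$alt)))
    sums <- tapply(lo$frequency, lo$position, sum)
    expect_true(all(sums <= 1 + 1e-12))
  }
})

test_that("specificity and recall on simulated mixtures match the truth ledger", {
  # pure genotype, no errors: zero SNVs
  s <- small_spec(seed = 31, mixture = c(g1 = 1), read_error_rate = 0,
                  revert_unique = 0, revert_shared = 0, private_subs = 0,
                  revert_indels = 0, coverage_target = 60)
  tr <- simulate_cohort(s)
  rs <- simulate_reads(tr, s)
  expect_equal(nrow(call_snvs(rs$pileup)), 0L)

  # 0.7/0.3 mixture, no errors: called set equals ledger sites
  s <- small_spec(seed = 32, genome_length = 4000, coverage_target = 2000,
                  read_error_rate = 0)
  tr <- simulate_cohort(s)
  rs <- simulate_reads(tr, s)
  got <- call_snvs(rs$pileup)
  expect_setequal(paste(got$position, got$alt),
                  paste(tr$expected_snvs$pos, tr$expected_snvs$alt))
})

test_that("read quality summaries report Phred fractions and coverage", {
  q37 <- strrep(rawToChar(as.raw(33 + 37)), 50)
  s <- summarize_reads(rep(q37, 10))
  expect_equal(s$q20, 1); expect_equal(s$q30, 1); expect_equal(s$q40, 0)
  expect_false(s$empty)

  s0 <- summarize_reads(character(0))
  expect_true(s0$empty)
  expect_equal(s0$q20, 0)

  spec <- small_spec(seed = 14, genome_length = 3000, coverage_target = 100)
  tr <- simulate_cohort(spec)
  rs <- simulate_reads(tr, spec)
  s <- summarize_reads(rep(rs$qual, nrow(rs$reads)), rs$pileup)
  expect_lt(abs(s$coverage$mean / spec$coverage_target - 1), 0.1)
  expect_true(s$q20 >= s$q30 && s$q30 >= s$q40)
})
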