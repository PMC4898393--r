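cnv_fixture <- function(starts, stops, animals, types,
                        chrom = "chr1") {
  n <- length(starts)
  calls <- segment_calls(animal = animals, chrom = chrom, start = starts,
                         stop = stops, first_probe = seq_len(n),
                         last_probe = seq_len(n) + 2,
                         l2r = ifelse(types == "deletion", -0.5, 0.5),
                         datapoints = rep(3, n))
  calls$p <- 1
  as_cnv_calls(calls)
}

test_that("merging collapses calls within 1,500 bp, transitively", {
  # gap 1,400 -> one CNVR spanning both calls
  one <- merge_to_cnvrs(cnv_fixture(c(1000, 3400), c(2000, 4000),
                                    c("A", "B"), rep("deletion", 2)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1000)
  expect_equal(one$stop, 4000)
  expect_equal(one$n_animals, 2)

  # gap 1,600 -> two CNVRs
  two <- merge_to_cnvrs(cnv_fixture(c(1000, 3600), c(2000, 4200),
                                    c("A", "B"), rep("deletion", 2)))
  expect_equal(nrow(two), 2)

  # gap exactly 1,500 merges (boundary inclusive)
  bd <- merge_to_cnvrs(cnv_fixture(c(1000, 3500), c(2000, 4100),
                                   c("A", "B"), rep("deletion", 2)))
  expect_equal(nrow(bd), 1)

  # mixed types produce a compound CNVR
  both <- merge_to_cnvrs(cnv_fixture(c(1000, 1500), c(2500, 3000),
                                     c("A", "B"),
                                     c("deletion", "duplication")))
  expect_equal(both$type, "both")
})

test_that("merging is idempotent, order-invariant and partitions the calls", {
  set.seed(19)
  calls <- random_calls(80)
  calls$p <- 1
  calls <- as_cnv_calls(calls)
  a <- merge_to_cnvrs(calls)
  b <- merge_to_cnvrs(calls[sample(nrow(calls)), ])
  expect_equal(a[, c("chrom", "start", "stop", "type", "n_animals")],
               b[, c("chrom", "start", "stop", "type", "n_animals")])
  # every call lands in exactly one CNVR
  expect_equal(sum(a$n_calls), nrow(calls))
  # re-merging the CNVRs themselves changes nothing (they are > 1.5 kb apart)
  a2 <- a
  a2$animal <- "x"
  expect_equal(nrow(merge_to_cnvrs(a2)), nrow(a))
})

test_that("frequency spectrum and reference-effect flag summarize supports", {
  cn <- data.frame(n_animals = c(1, 1, 2))
  fs <- frequency_spectrum(cn)
  expect_equal(fs$fraction_singleton, 2 / 3)
  expect_equal(fs$fraction_multi, 1 / 3)
  expect_equal(sum(fs$spectrum$count), fs$n_total)

  fs0 <- frequency_spectrum(cn[0, , drop = FALSE])
  expect_equal(fs0$n_total, 0)

  flags <- flag_reference_effect(data.frame(n_animals = c(30, 29)), 30)
  expect_equal(flags, c(TRUE, FALSE))
  expect_warning(flag_reference_effect(data.frame(n_animals = 1), 1),
                 "one animal")
})

test_that("genome fraction equals a per-base oracle and handles unions", {
  layout <- genome_layout(c(chr1 = 1e8))
  one_mb <- data.frame(chrom = "chr1", start = 0, stop = 1e6)
  expect_equal(genome_fraction(one_mb, layout), 1.0)

  # overlapping calls count once
  twice <- data.frame(chrom = "chr1", start = c(0, 5e5), stop = c(1e6, 1.5e6))
  expect_equal(genome_fraction(twice, layout), 1.5)

  # per-base oracle on a 1e6-bp toy genome
  toy <- genome_layout(c(chr1 = 1e6))
  set.seed(23)
  st <- sample.int(9e5, 50)
  iv <- data.frame(chrom = "chr1", start = st,
                   stop = st + sample.int(5e4, 50))
  covered <- logical(1e6)
  for (i in seq_len(50)) covered[(iv$start[i] + 1):iv$stop[i]] <- TRUE
  expect_equal(genome_fraction(iv, toy), 100 * mean(covered))

  # per-animal variant
  iv$animal <- rep(c("A", "B"), 25)
  pa <- genome_fraction(iv, toy, per_animal = TRUE)
  expect_equal(sort(names(pa)), c("A", "B"))

  # interval beyond the chromosome end is a validation error
  expect_error(genome_fraction(data.frame(chrom = "chr1", start = 0,
                                          stop = 2e6), toy),
               "beyond")
})

test_that("uniform-null placement respects lengths, spacing and determinism", {
  layout <- toy_layout(2, 5e6)
  lens <- rep(1000, 10)
  set.seed(3); a <- simulate_uniform_null(lens, layout)
  set.seed(3); b <- simulate_uniform_null(lens, layout)
  expect_identical(a, b)
  expect_equal(a$stop - a$start, lens)
  gaps <- inter_cnvr_distances(a)
  expect_true(all(gaps > 1500))
  expect_error(simulate_uniform_null(rep(1e6, 20), toy_layout(1, 1e6)),
               "too small|could not place")

  # mean nearest-gap agrees with the uniform order-statistic expectation:
  # n points on [0, L) leave mean adjacent spacing ~ L / (n + 1)
  layout1 <- genome_layout(c(chr1 = 1e7))
  m <- replicate(100, {
    pl <- simulate_uniform_null(rep(1000, 20), layout1, min_spacing = 0)
    mean(inter_cnvr_distances(pl))
  })
  expected <- (1e7 - 20 * 1000) / 21
  expect_lt(abs(mean(m) - expected) / expected, 0.05)
})

test_that("KS uniformity test is calibrated and detects planted clustering", {
  layout <- genome_layout(c(chr1 = 2e7))
  # null calibration at reduced scale: observed is itself uniform
  set.seed(101)
  n_runs <- 60
  pvals <- replicate(n_runs, {
    obs <- simulate_uniform_null(rep(2000, 60), layout)
    obs$length <- obs$stop - obs$start
    ks_uniformity_test(obs, layout)$p_value
  })
  # spacing samples are sum-constrained (Dirichlet-like), so their ECDFs
  # fluctuate less than iid samples and ks.test's iid-null p-values are
  # conservative: never anti-conservative, and concentrated away from 0
  expect_lte(mean(pvals < 0.05), 0.12)
  expect_gte(mean(pvals > 0.5), 0.3)

  # planted clustering: pairs 2 kb apart are far tighter than uniform
  set.seed(102)
  centers <- simulate_uniform_null(rep(2000, 100), layout,
                                   min_spacing = 40000)
  clustered <- rbind(centers,
                     data.frame(chrom = centers$chrom,
                                start = centers$stop + 2000,
                                stop = centers$stop + 4000))
  clustered$length <- clustered$stop - clustered$start
  res <- ks_uniformity_test(clustered, layout)
  expect_lt(res$p_value, 0.01)
  expect_true(res$D >= 0 && res$D <= 1)

  # degenerate: identical samples give D = 0 (direct KS property check)
  d <- c(1, 2, 3, 4)
  kt <- suppressWarnings(stats::ks.test(d, d))
  expect_equal(unname(kt$statistic), 0)

  # too few CNVRs -> NULL with message
  expect_message(
    out <- ks_uniformity_test(data.frame(chrom = "chr1", start = 1,
                                         stop = 1000, length = 999),
                              layout),
    "too few")
  expect_null(out)
})
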