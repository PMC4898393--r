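flat_track <- function(depth = 10, L = 20000, mask = NULL, gc = 0.42) {
  depth_track(
    depth = list(chr1 = S4Vectors::Rle(depth, L)),
    mask = list(chr1 = if (is.null(mask)) IRanges::IRanges() else mask),
    gc = list(chr1 = S4Vectors::Rle(gc, L))
  )
}

default_params <- function(mu2 = 30, s2 = 30) {
  mixture_params(mu2, s2, 1.5, 0.01, 0.025, 0.001, 0.001)
}

test_that("binning averages unmasked positions and drops bad bins", {
  bins <- bin_depth(flat_track(10), max_depth_quantile = NULL)
  expect_true(all(bins$depth == 10))
  expect_true(all(bins$gc == 0.42))
  expect_equal(bins$stop - bins$start, rep(1000, nrow(bins)))
  expect_equal(diff(bins$start)[1], 200)

  # half-masked bin still averages only the unmasked half
  tr <- flat_track(10, mask = IRanges::IRanges(1, 500))
  b2 <- bin_depth(tr, max_depth_quantile = NULL)
  expect_true(all(b2$depth == 10))
  expect_equal(b2$n_unmasked[1], 500)

  # fully masked bins are dropped
  tr3 <- flat_track(10, L = 5000, mask = IRanges::IRanges(1, 1400))
  b3 <- bin_depth(tr3, step = 1000, max_depth_quantile = NULL)
  expect_false(0 %in% b3$start)

  # a single extreme position deletes every bin containing it
  v <- rep(10, 20000); v[10001] <- 1e5
  tr4 <- depth_track(depth = list(chr1 = S4Vectors::Rle(v)),
                     gc = list(chr1 = S4Vectors::Rle(0.42, 20000)))
  b4 <- bin_depth(tr4, max_depth_quantile = 0.999)
  spans <- b4$start < 10001 & b4$stop > 10000
  expect_false(any(spans))

  expect_error(bin_depth(flat_track(10), bin = 1000, step = 300),
               "multiple")
})

test_that("GC correction inverts a planted GC bias", {
  # GC-independent depth: correction is (nearly) the identity
  truth <- simulate_truth(toy_layout(1, 1e6), n_cnvr = 0, n_trios = 1,
                          mask_fraction = 0, seed = 61)
  tr <- simulate_depth(truth, "P01", seed = 61)
  bins <- gc_correct(bin_depth(tr, max_depth_quantile = NULL))
  expect_lt(stats::median(abs(bins$corrected - bins$depth) / bins$depth), 0.05)

  # a stratum whose median is double the global median is halved
  b <- data.frame(chrom = "chr1", start = 0, stop = 1000, n_unmasked = 1000,
                  gc = rep(c(0.40, 0.50), each = 40),
                  depth = rep(c(10, 20), each = 40))
  bc <- gc_correct(b)
  expect_equal(unique(bc$corrected[b$gc == 0.50]), 15)  # 20 * 15/20
  expect_equal(unique(bc$corrected[b$gc == 0.40]), 15)  # 10 * 15/10

  # synthetic multiplicative GC bias: corrected strata medians equalize
  truth2 <- simulate_truth(toy_layout(1, 4e6), n_cnvr = 0, n_trios = 1,
                           mask_fraction = 0, seed = 62)
  biased <- simulate_depth(truth2, "P01", mu2 = 30, sigma2_sq = 4,
                           gc_bias = function(gc) 2^(2 * (gc - 0.42)),
                           seed = 62)
  bb <- gc_correct(bin_depth(biased, max_depth_quantile = NULL))
  strata <- round(100 * bb$gc)
  big <- names(which(table(strata) >= 100))
  meds <- tapply(bb$corrected, strata, stats::median)[big]
  expect_lt(max(meds) / min(meds), 1.06)

  # zero global median is an error
  z <- data.frame(gc = 0.4, depth = 0)
  expect_error(gc_correct(z), "zero")
})

test_that("mixture fit recovers generating parameters", {
  p <- default_params()
  sim <- simulate_mixture_bins(50000, p, seed = 71)
  fit <- fit_mixture(sim$corrected)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$mu2 - 30) / 30, 0.02)
  expect_lt(abs(fit$params$pi0 - 0.01), 0.005)
  expect_lt(abs(fit$params$pi1 - 0.025), 0.005)
  expect_lt(abs(fit$params$pi3 - 0.001), 0.005)
  expect_lt(abs(fit$params$pi4 - 0.001), 0.005)
  # optimizer contract: achieved likelihood at least the start's
  start <- mixture_params(mean(sim$corrected), stats::var(sim$corrected),
                          1.5, 0.01, 0.025, 0.001, 0.001)
  expect_gte(fit$loglik, mixture_loglik(sim$corrected, start))

  # degenerate input reported, not silently accepted
  expect_false(fit_mixture(rep(30, 1000))$converged)
  expect_false(fit_mixture(rnorm(100, 30, 5))$converged)  # too few bins
})

test_that("fallback parameters average successful chromosomes", {
  p1 <- default_params(28); p2 <- default_params(32)
  fits <- list(
    chr1 = list(params = p1, loglik = -1, converged = TRUE, message = "ok"),
    chr2 = list(params = p2, loglik = -1, converged = TRUE, message = "ok"),
    chr3 = list(params = NULL, loglik = NA, converged = FALSE, message = "fail")
  )
  out <- fallback_params(fits)
  expect_equal(out$chr3$mu2, 30)
  expect_equal(out$chr1$mu2, 28)  # successes unchanged
  # averaged weights keep pi2 >= 0
  expect_gte(out$chr3$pi2, 0)
  expect_lt(abs(sum(out$chr3$pi0, out$chr3$pi1, out$chr3$pi2,
                    out$chr3$pi3, out$chr3$pi4) - 1), 1e-12)
  fits$chr1$converged <- fits$chr2$converged <- FALSE
  expect_error(fallback_params(fits), "no chromosome")
})

test_that("CN assignment equals the brute-force weighted-density argmax", {
  p <- default_params()
  # frozen worked examples
  ex <- data.frame(corrected = c(30, 0.1, 45))
  got <- assign_cn(ex, p)
  expect_equal(got$cn, c(2L, 0L, 2L))  # 45: prior pi3 outweighs likelihood
  expect_equal(rowSums(got[, paste0("post", 0:4)]), rep(1, 3))

  # oracle comparison on 10^4 random bins
  set.seed(81)
  d <- stats::runif(1e4, 0, 80)
  bins <- data.frame(corrected = d)
  got <- assign_cn(bins, p)
  w <- c(p$pi0, p$pi1, p$pi2, p$pi3, p$pi4)
  brute <- vapply(d, function(x) {
    dens <- c(if (x < 0) 0 else 2 * stats::dnorm(x, 0, sqrt(p$sigma0_sq)),
              stats::dnorm(x, p$mu2 / 2, sqrt(p$sigma2_sq / 2)),
              stats::dnorm(x, p$mu2, sqrt(p$sigma2_sq)),
              stats::dnorm(x, 1.5 * p$mu2, sqrt(1.5 * p$sigma2_sq)),
              stats::dnorm(x, 2 * p$mu2, sqrt(2 * p$sigma2_sq)))
    which.max(w * dens) - 1L
  }, 1L)
  expect_identical(got$cn, brute)
})

test_that("depth pipeline is scale-equivariant after refitting", {
  p <- default_params()
  sim <- simulate_mixture_bins(20000, p, seed = 91)
  bins <- data.frame(chrom = "chr1", corrected = sim$corrected)
  f1 <- fit_mixture(bins$corrected)
  a1 <- assign_cn(bins, f1$params)
  bins2 <- bins
  bins2$corrected <- bins$corrected * 3
  f2 <- fit_mixture(bins2$corrected)
  a2 <- assign_cn(bins2, f2$params)
  expect_gt(mean(a1$cn == a2$cn), 0.999)
})

test_that("depth verification distinguishes consistent, reference-effect and discordant", {
  cnvrs <- data.frame(chrom = "chr1",
                      start = c(0, 2000, 4000, 6000),
                      stop = c(1000, 3000, 5000, 7000),
                      type = c("deletion", "duplication", "deletion",
                               "duplication"))
  mkbins <- function(cns, starts) {
    data.frame(chrom = "chr1", start = starts, stop = starts + 1000,
               cn = cns)
  }
  test_bins <- mkbins(c(1L, 2L, 2L, 2L), c(0, 2000, 4000, 6000))
  ref_bins <- mkbins(c(2L, 1L, 2L, 3L), c(0, 2000, 4000, 6000))
  v <- verify_cnvrs_by_depth(cnvrs, test_bins, ref_bins)
  expect_equal(v$status,
               c("verified-consistent",      # deletion with CN=1 test bin
                 "verified-reference-effect",# dup in test = del in reference
                 "not-verified",             # no CNV bin anywhere
                 "verified-discordant-type"))# dup vs dup in reference

  # untestable: no bins at all in the region
  far <- data.frame(chrom = "chr1", start = 9e6, stop = 9.1e6,
                    type = "deletion")
  expect_equal(verify_cnvrs_by_depth(far, test_bins, ref_bins)$status,
               "untestable")
})

test_that("end-to-end depth calling finds planted CN regions", {
  # scaled-down version of the full-track accuracy property (runtime budget):
  # 2 Mb chromosome, ~10k sliding bins, large planted regions
  truth <- simulate_truth(toy_layout(1, 2e6), n_cnvr = 12, n_trios = 2,
                          length_meanlog = log(20000), length_sdlog = 0.3,
                          mask_fraction = 0.02, seed = 95)
  an <- "P01"
  truth$cn[, an] <- 2L
  truth$cn[1:12, an] <- rep(c(0L, 1L, 3L, 4L), 3)
  tr <- simulate_depth(truth, an, mu2 = 30, seed = 95)
  res <- call_depth_cn(tr, min_bins = 500)
  bins <- res$bins

  # per-bin accuracy inside planted non-diploid regions >= 5 kb
  ok <- 0; tot <- 0
  for (j in seq_len(nrow(truth$cnvrs))) {
    cv <- truth$cnvrs[j, ]
    cn <- truth$cn[j, an]
    if (cv$length < 5000) next
    sel <- bins$chrom == cv$chrom & bins$start >= cv$start &
      bins$stop <= cv$stop
    ok <- ok + sum(bins$cn[sel] == cn)
    tot <- tot + sum(sel)
  }
  expect_gt(tot, 50)
  expect_gt(ok / tot, 0.95)
})
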