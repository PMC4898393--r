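#' Bin a depth track into sliding windows
#'
#' Partitions each chromosome into 1-kb bins advanced by a 200-bp sliding
#' step. A bin's raw depth is the mean per-base depth over its unmasked
#' positions (masked positions are excluded from numerator and denominator);
#' fully masked bins are dropped. Bins in which any unmasked position
#' exceeds the chromosome's maximum-depth threshold (default: the 99.9th
#' percentile of unmasked per-base depth, aimed at unmasked residual
#' repeats) are deleted. The GC fraction over unmasked positions is recorded
#' when the track carries a per-base GC indicator.
#'
#' @param track a `depth_track`.
#' @param bin bin width in bp.
#' @param step sliding-window step in bp; must divide `bin`.
#' @param max_depth_quantile per-chromosome deletion threshold quantile, or
#'   `NULL` to disable the max-depth rule.
#' @return data.frame with `chrom`, `start`, `stop`, `n_unmasked`, `gc`,
#'   `depth` (raw mean), one row per surviving bin.
#' @export
bin_depth <- function(track, bin = 1000, step = 200,
                      max_depth_quantile = 0.999) {
  stopifnot(inherits(track, "depth_track"))
  if (bin %% step != 0) stop("bin size must be a multiple of the step")
  out <- list()
  for (ch in names(track$depth)) {
    d <- track$depth[[ch]]
    L <- length(d)
    if (L < bin) next
    mask <- track$mask[[ch]]
    masked <- as.logical(IRanges::coverage(mask, width = L) > 0)
    dvec <- as.numeric(d)
    dvec[masked] <- NA  # masked positions excluded everywhere below
    dm <- S4Vectors::Rle(dvec)
    thr <- if (!is.null(max_depth_quantile)) {
      stats::quantile(dvec, max_depth_quantile, na.rm = TRUE, names = FALSE)
    } else Inf
    starts <- seq(0, L - bin, by = step)
    v <- IRanges::Views(dm, start = starts + 1, width = bin)
    means <- IRanges::viewMeans(v, na.rm = TRUE)
    maxs <- suppressWarnings(IRanges::viewMaxs(v, na.rm = TRUE))
    na_rle <- S4Vectors::Rle(as.integer(masked))
    n_masked <- IRanges::viewSums(IRanges::Views(na_rle, start = starts + 1,
                                                 width = bin))
    n_unmasked <- bin - n_masked
    gc <- rep(NA_real_, length(starts))
    if (!is.null(track$gc) && !is.null(track$gc[[ch]])) {
      gvec <- as.numeric(track$gc[[ch]])
      gvec[masked] <- NA
      gc <- IRanges::viewMeans(IRanges::Views(S4Vectors::Rle(gvec),
                                              start = starts + 1,
                                              width = bin), na.rm = TRUE)
    }
    keep <- n_unmasked > 0 & maxs <= thr
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            stop = starts[keep] + bin,
                            n_unmasked = n_unmasked[keep],
                            gc = gc[keep], depth = means[keep])
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      n_unmasked = numeric(), gc = numeric(), depth = numeric())
  }
  res
}

#' GC-correct binned depth
#'
#' Median-ratio GC correction: bins are stratified by GC percentage (rounded
#' to the nearest integer percent) and each bin's depth is rescaled by the
#' ratio of the global median depth to its stratum's median depth. Strata
#' with fewer than `min_stratum` bins fall back to the global median (no
#' correction), avoiding unstable medians in sparse GC strata.
#'
#' @param bins data.frame from [bin_depth()] with finite `gc`.
#' @param min_stratum minimum bins per GC stratum for own-median correction.
#' @return `bins` with a `corrected` column added.
#' @export
gc_correct <- function(bins, min_stratum = 20) {
  if (anyNA(bins$gc)) stop("bins lack GC fractions; cannot GC-correct")
  global_med <- stats::median(bins$depth)
  if (global_med == 0) stop("global median depth is zero; track unusable")
  stratum <- round(100 * bins$gc)
  med <- tapply(bins$depth, stratum, stats::median)
  cnt <- tapply(bins$depth, stratum, length)
  med[cnt < min_stratum | med == 0] <- global_med
  bins$corrected <- bins$depth * global_med / as.numeric(med[as.character(stratum)])
  bins
}

#' Mixture parameters for the read-depth copy-number model
#'
#' The corrected bin depths on one chromosome are modelled as a five-class
#' mixture over copy number CN = 0..4: a half-normal at zero for CN = 0 and
#' normals for CN = 1..4 whose means and variances are tied to the diploid
#' class, mean (CN/2) mu2 and variance (CN/2) sigma2_sq. Seven parameters
#' are free: mu2, sigma2_sq, sigma0_sq, and the weights pi0, pi1, pi3, pi4
#' (pi2 is one minus their sum).
#'
#' @param mu2 diploid mean depth.
#' @param sigma2_sq diploid depth variance.
#' @param sigma0_sq half-normal scale squared for CN = 0.
#' @param pi0,pi1,pi3,pi4 mixture weights for CN 0, 1, 3, 4.
#' @return a `MixtureParams` list (with derived `pi2`).
#' @export
mixture_params <- function(mu2, sigma2_sq, sigma0_sq, pi0, pi1, pi3, pi4) {
  pi2 <- 1 - pi0 - pi1 - pi3 - pi4
  if (pi2 < 0) stop("weights exceed 1 (pi2 < 0)")
  if (any(c(pi0, pi1, pi3, pi4) < 0)) stop("negative mixture weight")
  if (sigma2_sq <= 0) stop("sigma2_sq must be > 0")
  if (sigma0_sq < 0.01) stop("sigma0_sq must be >= 0.01")
  structure(list(mu2 = mu2, sigma2_sq = sigma2_sq, sigma0_sq = sigma0_sq,
                 pi0 = pi0, pi1 = pi1, pi2 = pi2, pi3 = pi3, pi4 = pi4),
            class = "MixtureParams")
}

# Half-normal density at d >= 0 with scale sigma0.
.dhalfnorm <- function(d, sigma0_sq) {
  ifelse(d < 0, 0, 2 * stats::dnorm(d, mean = 0, sd = sqrt(sigma0_sq)))
}

# n x 5 matrix of weighted component densities pi_k f_k(d), CN = 0..4.
.weighted_densities <- function(d, params) {
  w <- c(params$pi0, params$pi1, params$pi2, params$pi3, params$pi4)
  dens <- cbind(
    .dhalfnorm(d, params$sigma0_sq),
    stats::dnorm(d, mean = params$mu2 / 2, sd = sqrt(params$sigma2_sq / 2)),
    stats::dnorm(d, mean = params$mu2, sd = sqrt(params$sigma2_sq)),
    stats::dnorm(d, mean = 1.5 * params$mu2, sd = sqrt(1.5 * params$sigma2_sq)),
    stats::dnorm(d, mean = 2 * params$mu2, sd = sqrt(2 * params$sigma2_sq))
  )
  sweep(dens, 2, w, `*`)
}

#' Mixture log-likelihood
#' @param d numeric vector of corrected bin depths.
#' @param params a `MixtureParams`.
#' @return the log-likelihood.
#' @export
mixture_loglik <- function(d, params) {
  sum(log(pmax(rowSums(.weighted_densities(d, params)), 1e-300)))
}

#' Fit the constrained read-depth mixture for one chromosome
#'
#' Maximizes the mixture log-likelihood directly over the seven free
#' parameters with the box-constrained quasi-Newton optimizer
#' [stats::nlminb()]. Starting values: mu2 at the sample mean, sigma2_sq at
#' the sample variance, sigma0_sq at 1.5, weights (0.01, 0.025, 0.001,
#' 0.001). Bounds: sigma2_sq > 0, sigma0_sq >= 0.01, pi0 <= 0.05,
#' pi1 <= 0.2, pi3 <= 0.2, pi4 <= 0.05, all weights >= 0 (and implicitly
#' pi2 >= 0 via a barrier). A fit that does not converge, or that is both
#' stuck at a weight bound and numerically singular, is reported as failed
#' rather than silently accepted.
#'
#' @param depths corrected bin depths for one chromosome.
#' @param min_bins minimum number of bins needed to attempt a fit.
#' @return list with `params` (a `MixtureParams` or `NULL`), `loglik`,
#'   `converged`, `message`.
#' @export
fit_mixture <- function(depths, min_bins = 500) {
  d <- depths[is.finite(depths)]
  if (length(d) < min_bins) {
    return(list(params = NULL, loglik = NA_real_, converged = FALSE,
                message = sprintf("too few bins (%d < %d)", length(d), min_bins)))
  }
  if (stats::var(d) == 0) {
    return(list(params = NULL, loglik = NA_real_, converged = FALSE,
                message = "degenerate input: zero depth variance"))
  }
  start <- c(mu2 = mean(d), sigma2_sq = stats::var(d), sigma0_sq = 1.5,
             pi0 = 0.01, pi1 = 0.025, pi3 = 0.001, pi4 = 0.001)
  lower <- c(-Inf, 1e-8, 0.01, 0, 0, 0, 0)
  upper <- c(Inf, Inf, Inf, 0.05, 0.2, 0.2, 0.05)
  negll <- function(theta) {
    pi2 <- 1 - sum(theta[4:7])
    if (pi2 < 0) return(1e12)  # barrier keeps the implicit weight feasible
    p <- mixture_params(theta[1], theta[2], theta[3],
                        theta[4], theta[5], theta[6], theta[7])
    -mixture_loglik(d, p)
  }
  # analytic gradient: numeric differentiation over 7 parameters is far too
  # slow at realistic bin counts
  negll_grad <- function(theta) {
    pi2 <- 1 - sum(theta[4:7])
    if (pi2 < 0) return(rep(0, 7))
    mu2 <- theta[1]; s2 <- theta[2]; s0 <- theta[3]
    w <- c(theta[4], theta[5], pi2, theta[6], theta[7])
    f <- matrix(0, length(d), 5)
    f[, 1] <- .dhalfnorm(d, s0)
    cks <- c(0.5, 1, 1.5, 2)
    for (k in 1:4) {
      f[, k + 1] <- stats::dnorm(d, cks[k] * mu2, sqrt(cks[k] * s2))
    }
    L <- pmax(drop(f %*% w), 1e-300)
    dmu2 <- ds2 <- numeric(length(d))
    for (k in 1:4) {
      ck <- cks[k]
      resid <- d - ck * mu2
      dmu2 <- dmu2 + w[k + 1] * f[, k + 1] * resid / (ck * s2) * ck
      ds2 <- ds2 + w[k + 1] * f[, k + 1] *
        (resid^2 / (2 * (ck * s2)^2) - 1 / (2 * ck * s2)) * ck
    }
    ds0 <- w[1] * f[, 1] * (d^2 / (2 * s0^2) - 1 / (2 * s0))
    g_mu2 <- -sum(dmu2 / L)
    g_s2 <- -sum(ds2 / L)
    g_s0 <- -sum(ds0 / L)
    g_pi <- vapply(c(1, 2, 4, 5), function(col) {
      -sum((f[, col] - f[, 3]) / L)
    }, 0)
    c(g_mu2, g_s2, g_s0, g_pi)
  }
  # PORT works on scale*par: bring depth-scale and weight-scale parameters
  # to comparable magnitude
  par_scale <- 1 / pmax(abs(start), 1e-2)
  opt <- stats::nlminb(start, negll, gradient = negll_grad,
                       scale = par_scale,
                       lower = lower, upper = upper,
                       control = list(rel.tol = 1e-8, iter.max = 3000,
                                      eval.max = 6000))
  theta <- opt$par
  params <- mixture_params(theta[1], theta[2], theta[3],
                           theta[4], theta[5], theta[6], theta[7])
  converged <- opt$convergence == 0
  msg <- opt$message
  if (converged) {
    # bound-stuck degenerate fit check: a weight pinned at its upper bound
    # with a singular curvature direction is not identified
    if (any(abs(theta[4:7] - upper[4:7]) < 1e-10)) {
      h <- tryCatch(stats::optimHess(theta, negll), error = function(e) NULL)
      if (is.null(h) || rcond(h) < 1e-14) {
        converged <- FALSE
        msg <- "bound-stuck degenerate fit (weight at bound, singular Hessian)"
      }
    }
  }
  list(params = if (converged) params else NULL,
       loglik = -opt$objective, converged = converged, message = msg)
}

#' Fallback parameters for chromosomes whose mixture fit failed
#'
#' Each failed chromosome receives the arithmetic mean of every parameter
#' over the successfully fitted chromosomes of the same animal. Averaged
#' weights are rescaled if their sum exceeds 1 (so the implicit diploid
#' weight stays non-negative).
#'
#' @param fits named list of [fit_mixture()] results, one per chromosome.
#' @return named list of `MixtureParams`, one per chromosome (fitted or
#'   fallback).
#' @export
fallback_params <- function(fits) {
  ok <- vapply(fits, function(f) f$converged, TRUE)
  if (!any(ok)) stop("no chromosome produced a usable mixture fit")
  good <- lapply(fits[ok], `[[`, "params")
  avg_of <- function(field) mean(vapply(good, `[[`, 0, field))
  mean_par <- c(mu2 = avg_of("mu2"), sigma2_sq = avg_of("sigma2_sq"),
                sigma0_sq = avg_of("sigma0_sq"), pi0 = avg_of("pi0"),
                pi1 = avg_of("pi1"), pi3 = avg_of("pi3"), pi4 = avg_of("pi4"))
  wsum <- sum(mean_par[c("pi0", "pi1", "pi3", "pi4")])
  if (wsum > 1) {
    mean_par[c("pi0", "pi1", "pi3", "pi4")] <-
      mean_par[c("pi0", "pi1", "pi3", "pi4")] / wsum
  }
  fb <- mixture_params(mean_par[["mu2"]], mean_par[["sigma2_sq"]],
                       mean_par[["sigma0_sq"]], mean_par[["pi0"]],
                       mean_par[["pi1"]], mean_par[["pi3"]], mean_par[["pi4"]])
  out <- lapply(seq_along(fits), function(i) {
    if (ok[i]) fits[[i]]$params else fb
  })
  names(out) <- names(fits)
  out
}

#' Assign a copy-number class to each bin
#'
#' Each bin is assigned the CN class maximizing the weighted density
#' pi_k f_k(corrected depth) — equivalently the posterior mode. The
#' normalized posterior over the five classes is returned alongside. Exact
#' ties break toward the diploid class CN = 2.
#'
#' @param bins data.frame with a `corrected` column (see [gc_correct()]).
#' @param params a `MixtureParams`.
#' @return `bins` with `cn` and posterior columns `post0`..`post4` added.
#' @export
assign_cn <- function(bins, params) {
  stopifnot(inherits(params, "MixtureParams"))
  wd <- .weighted_densities(bins$corrected, params)
  tot <- rowSums(wd)
  post <- wd / ifelse(tot > 0, tot, 1)
  best_val <- apply(wd, 1, max)
  cn <- max.col(wd, ties.method = "first") - 1L
  # tie toward CN = 2
  tie2 <- abs(wd[, 3] - best_val) <= 0
  cn[tie2] <- 2L
  bins$cn <- cn
  colnames(post) <- paste0("post", 0:4)
  cbind(bins, post)
}

#' Verify CNVRs against read-depth copy-number calls
#'
#' A CNVR is tested against the CN-assigned bins of a test animal and of the
#' reference animal. If at least one test-animal bin inside the region is a
#' CNV (CN != 2) of the same type as the CNVR, it is `verified-consistent`.
#' If the test animal shows no CNV bin but the reference animal shows a CNV
#' of the opposite type, the array call is explained by the reference effect
#' (`verified-reference-effect`): a deletion in the reference is seen as a
#' duplication in the test animal on the array, and vice versa. If both
#' animals show CNV bins but the types do not line up as above, the region
#' still contains copy-number signal (`verified-discordant-type`). A region
#' with CNV bins in neither animal is `not-verified`; a region with no
#' usable bins is `untestable` and excluded from verification rates.
#'
#' @param cnvrs CNVR data.frame with `chrom`, `start`, `stop`, `type`.
#' @param test_bins,ref_bins CN-assigned bin data.frames (see [assign_cn()])
#'   for the test and reference animal.
#' @return `cnvrs` with a `status` column added.
#' @export
verify_cnvrs_by_depth <- function(cnvrs, test_bins, ref_bins) {
  status <- character(nrow(cnvrs))
  bins_in <- function(bins, ch, st, sp) {
    bins[bins$chrom == ch & bins$start < sp & bins$stop > st, , drop = FALSE]
  }
  cn_type <- function(cn) {
    if (any(cn < 2) && any(cn > 2)) "both"
    else if (any(cn < 2)) "deletion"
    else if (any(cn > 2)) "duplication"
    else "none"
  }
  opposite <- c(deletion = "duplication", duplication = "deletion",
                both = "both")
  for (i in seq_len(nrow(cnvrs))) {
    tb <- bins_in(test_bins, cnvrs$chrom[i], cnvrs$start[i], cnvrs$stop[i])
    rb <- bins_in(ref_bins, cnvrs$chrom[i], cnvrs$start[i], cnvrs$stop[i])
    if (nrow(tb) == 0 && nrow(rb) == 0) {
      status[i] <- "untestable"
      next
    }
    tt <- if (nrow(tb)) cn_type(tb$cn) else "none"
    rt <- if (nrow(rb)) cn_type(rb$cn) else "none"
    qt <- cnvrs$type[i]
    status[i] <-
      if (tt != "none" && (tt == qt || tt == "both" || qt == "both")) {
        "verified-consistent"
      } else if (tt == "none" && rt != "none" &&
                 (rt == opposite[[qt]] || rt == "both")) {
        "verified-reference-effect"
      } else if (tt != "none" || rt != "none") {
        "verified-discordant-type"
      } else {
        "not-verified"
      }
  }
  cnvrs$status <- status
  cnvrs
}

#' Run the per-animal read-depth pipeline
#'
#' Convenience wrapper: bin, GC-correct, fit the mixture per chromosome
#' (with cross-chromosome fallback for failed fits) and assign CN classes.
#'
#' @param track a `depth_track` with GC.
#' @inheritParams bin_depth
#' @param min_bins per-chromosome minimum for [fit_mixture()].
#' @return list with `bins` (CN-assigned) and `params` (per chromosome).
#' @export
call_depth_cn <- function(track, bin = 1000, step = 200,
                          max_depth_quantile = 0.999, min_bins = 500) {
  bins <- bin_depth(track, bin = bin, step = step,
                    max_depth_quantile = max_depth_quantile)
  bins <- gc_correct(bins)
  fits <- lapply(split(bins$corrected, bins$chrom), fit_mixture,
                 min_bins = min_bins)
  params <- fallback_params(fits)
  out <- lapply(names(params), function(ch) {
    assign_cn(bins[bins$chrom == ch, , drop = FALSE], params[[ch]])
  })
  list(bins = do.call(rbind, c(out, list(make.row.names = FALSE))),
       params = params)
}
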