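#' Simulate a truth set of planted CNVRs, pedigree and genome annotation
#'
#' Generates a complete, truth-known world for the pipeline: planted CNVRs
#' (non-overlapping, at least 1,500 bp apart, lengths at least 1 kb from a
#' log-normal with a long right tail), a trio pedigree with a designated
#' reference animal, per-animal integer copy numbers at every CNVR, a gene
#' CDS interval set and a repeat mask.
#'
#' Copy numbers are Mendelian: each CNVR is a biallelic locus with a variant
#' allele frequency drawn from `freq_beta`; founders (trio parents and the
#' reference animal) are Hardy-Weinberg draws and progeny inherit one allele
#' from each parent. At a deletion locus CN = 2 - (variant alleles); at a
#' duplication locus CN = 2 + (variant alleles). Every CNVR is guaranteed at
#' least one carrier among the test animals (loci nobody carries are not
#' observable and are redrawn); the reference animal can itself carry CNVs,
#' which is what produces the reference effect downstream.
#'
#' @param layout a `GenomeLayout`.
#' @param n_cnvr number of CNVRs to plant.
#' @param length_meanlog,length_sdlog log-normal length parameters (defaults
#'   give a median near 9 kb with a long right tail).
#' @param del_frac fraction of CNVRs that are deletions.
#' @param freq_beta shape1/shape2 of the Beta variant-allele-frequency
#'   distribution (default favours rare variants).
#' @param n_trios number of sire-dam-progeny trios.
#' @param de_novo_rate probability a progeny gains a non-inherited variant
#'   allele at a CNVR (default 0).
#' @param n_genes,gene_length number and length of CDS intervals to scatter.
#' @param mask_fraction approximate fraction of the genome to repeat-mask.
#' @param seed optional RNG seed (set once at entry).
#' @return a `truth_set` list: `layout`, `cnvrs` (chrom/start/stop/length/
#'   type/freq), `cn` (CNVR x animal matrix), `pedigree`, `reference`,
#'   `genes`, `mask`.
#' @export
simulate_truth <- function(layout, n_cnvr = 100,
                           length_meanlog = log(9000), length_sdlog = 0.9,
                           del_frac = 0.6,
                           freq_beta = c(1, 4),
                           n_trios = 10,
                           de_novo_rate = 0,
                           n_genes = 200, gene_length = 1500,
                           mask_fraction = 0.05,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(layout, "GenomeLayout"))

  ped <- .make_trio_pedigree(n_trios)
  animals <- ped$animal
  test_animals <- animals[!ped$selfself]
  ref <- animals[ped$selfself][1]

  if (n_cnvr > 0) {
    lengths <- pmax(1000, round(stats::rlnorm(n_cnvr, length_meanlog,
                                              length_sdlog)))
    placed <- simulate_uniform_null(lengths, layout, min_spacing = 1500)
    type <- ifelse(stats::runif(n_cnvr) < del_frac, "deletion", "duplication")
    freq <- stats::rbeta(n_cnvr, freq_beta[1], freq_beta[2])
    cnvrs <- data.frame(cnvr = paste0("cnvr", seq_len(n_cnvr)),
                        chrom = placed$chrom, start = placed$start,
                        stop = placed$stop,
                        length = placed$stop - placed$start,
                        type = type, freq = freq)
    cn <- .mendelian_cn(cnvrs, ped, de_novo_rate, test_animals)
  } else {
    cnvrs <- data.frame(cnvr = character(), chrom = character(),
                        start = numeric(), stop = numeric(),
                        length = numeric(), type = character(),
                        freq = numeric())
    cn <- matrix(2L, nrow = 0, ncol = length(animals),
                 dimnames = list(NULL, animals))
  }

  genes <- .scatter_intervals(layout, n_genes, gene_length)
  mask <- .scatter_intervals(layout,
                             n = round(mask_fraction * autosome_length(layout) /
                                         2000),
                             len = 2000)

  structure(list(layout = layout, cnvrs = cnvrs, cn = cn, pedigree = ped,
                 reference = ref, genes = genes, mask = mask),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$cnvrs), "planted CNVRs,",
      nrow(x$pedigree), "animals (reference:", x$reference, ")\n")
  invisible(x)
}

# Trio pedigree: n_trios families (sire/dam/progeny) plus a reference
# founder hybridized against itself.
.make_trio_pedigree <- function(n_trios) {
  rows <- list()
  for (i in seq_len(n_trios)) {
    sire <- sprintf("S%02d", i); dam <- sprintf("D%02d", i)
    prog <- sprintf("P%02d", i)
    rows[[i]] <- data.frame(
      animal = c(sire, dam, prog),
      sire = c(NA, NA, sire), dam = c(NA, NA, dam),
      sex = c("M", "F", sample(c("M", "F"), 1)),
      selfself = FALSE)
  }
  ref <- data.frame(animal = "REF", sire = NA_character_, dam = NA_character_,
                    sex = "M", selfself = TRUE)
  out <- rbind(do.call(rbind, rows), ref)
  rownames(out) <- NULL
  out
}

# Per-animal copy numbers at each CNVR under Mendelian transmission.
.mendelian_cn <- function(cnvrs, ped, de_novo_rate, test_animals) {
  animals <- ped$animal
  founders <- ped$animal[is.na(ped$sire)]
  n <- nrow(cnvrs)
  alleles <- matrix(0L, nrow = n, ncol = length(animals),
                    dimnames = list(cnvrs$cnvr, animals))
  for (j in seq_len(n)) {
    repeat {
      q <- cnvrs$freq[j]
      a <- stats::setNames(integer(length(animals)), animals)
      a[founders] <- stats::rbinom(length(founders), 2, q)
      for (k in which(!is.na(ped$sire))) {
        from_sire <- stats::rbinom(1, 1, a[[ped$sire[k]]] / 2)
        from_dam <- stats::rbinom(1, 1, a[[ped$dam[k]]] / 2)
        a[[ped$animal[k]]] <- from_sire + from_dam
        if (de_novo_rate > 0 && stats::runif(1) < de_novo_rate) {
          a[[ped$animal[k]]] <- min(2L, a[[ped$animal[k]]] + 1L)
        }
      }
      if (any(a[test_animals] > 0)) break  # locus must be observable
    }
    alleles[j, ] <- a
  }
  sign <- ifelse(cnvrs$type == "deletion", -1L, 1L)
  cn <- sweep(alleles, 1, sign, `*`) + 2L
  cn
}

# Uniformly scattered fixed-length intervals on the autosomes (may overlap).
.scatter_intervals <- function(layout, n, len) {
  if (n <= 0) {
    return(data.frame(chrom = character(), start = numeric(), stop = numeric()))
  }
  chroms <- layout$autosomes
  lens <- layout$lengths[chroms]
  ch <- sample(chroms, n, replace = TRUE, prob = lens)
  start <- floor(stats::runif(n, 0, pmax(1, lens[ch] - len)))
  data.frame(chrom = ch, start = start, stop = start + len,
             row.names = NULL)
}

#' Simulate CGH segment calls from a truth set
#'
#' Emulates the array's segmentation output. For every test animal and every
#' CNVR where the log2 ratio of test to reference copy number is non-zero, a
#' segment call is emitted whose boundaries snap to the probe grid (one
#' probe per `probe_spacing` bp), so carrier parents and progeny report
#' identical probe boundaries — the property trio validation keys on. The
#' expected log2 ratio is `log2(CN_test / CN_ref)` with zero copies floored
#' at `cn_floor` (residual hybridization signal keeps array ratios finite),
#' plus Gaussian noise on the log2 scale. The self-self animal (reference
#' against itself) emits only false-positive calls; every animal receives
#' `Poisson(fp_rate)` false calls drawn from a short, low-ratio, few-probe
#' profile shaped like self-self calls.
#'
#' @param truth a `truth_set`.
#' @param l2r_noise_sd Gaussian noise sd on the log2 scale.
#' @param fp_rate expected false calls per genome per animal.
#' @param fp_datapoints range of probe counts for false calls.
#' @param fp_absl2r range of |log2 ratio| for false calls.
#' @param probe_spacing autosomal probe spacing in bp.
#' @param cn_floor effective copy number assigned to CN = 0 when forming
#'   ratios.
#' @param seed optional RNG seed.
#' @return list with `calls` (a `segment_calls` data.frame) and `labels`
#'   (one row per call: `animal`, `cnvr` (NA for false calls), `true_cnv`).
#' @export
simulate_cgh_calls <- function(truth, l2r_noise_sd = 0.15, fp_rate = 5,
                               fp_datapoints = c(3, 6),
                               fp_absl2r = c(0.1, 0.3),
                               probe_spacing = 1250, cn_floor = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "truth_set"))
  ped <- truth$pedigree
  ref <- truth$reference
  test_animals <- ped$animal[ped$animal != ref]
  eff <- function(cn) pmax(cn, cn_floor)

  rows <- list(); labels <- list()
  add <- function(row, label) {
    rows[[length(rows) + 1]] <<- row
    labels[[length(labels) + 1]] <<- label
  }

  # true calls, boundaries snapped to the probe grid per CNVR
  for (j in seq_len(nrow(truth$cnvrs))) {
    cv <- truth$cnvrs[j, ]
    first <- ceiling((cv$start - probe_spacing / 2) / probe_spacing)
    last <- floor((cv$stop - 1 - probe_spacing / 2) / probe_spacing)
    if (last < first) next  # CNVR too short to catch a probe
    st <- first * probe_spacing
    sp <- (last + 1) * probe_spacing
    cn_ref <- truth$cn[j, ref]
    for (an in test_animals) {
      exp_l2r <- log2(eff(truth$cn[j, an]) / eff(cn_ref))
      if (exp_l2r == 0) next
      add(data.frame(animal = an, chrom = cv$chrom, start = st, stop = sp,
                     first_probe = first, last_probe = last,
                     l2r = exp_l2r + stats::rnorm(1, 0, l2r_noise_sd),
                     datapoints = last - first + 1),
          data.frame(animal = an, cnvr = cv$cnvr, true_cnv = TRUE))
    }
  }

  # false calls for every animal (the self-self animal gets only these)
  chroms <- truth$layout$autosomes
  clens <- truth$layout$lengths[chroms]
  for (an in ped$animal) {
    n_fp <- stats::rpois(1, fp_rate)
    for (k in seq_len(n_fp)) {
      dp <- sample(seq(fp_datapoints[1], fp_datapoints[2]), 1)
      ch <- sample(chroms, 1, prob = clens)
      n_probes <- floor(clens[[ch]] / probe_spacing)
      first <- sample(seq_len(max(1, n_probes - dp)), 1) - 1
      last <- first + dp - 1
      l2r <- stats::runif(1, fp_absl2r[1], fp_absl2r[2]) *
        sample(c(-1, 1), 1)
      add(data.frame(animal = an, chrom = ch,
                     start = first * probe_spacing,
                     stop = (last + 1) * probe_spacing,
                     first_probe = first, last_probe = last,
                     l2r = l2r, datapoints = dp),
          data.frame(animal = an, cnvr = NA_character_, true_cnv = FALSE))
    }
  }

  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(), chrom = character(), start = numeric(),
               stop = numeric(), first_probe = numeric(),
               last_probe = numeric(), l2r = numeric(), datapoints = numeric())
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(animal = character(), cnvr = character(), true_cnv = logical())
  rownames(calls) <- rownames(labels) <- NULL
  calls <- validate_segment_calls(calls)
  list(calls = calls, labels = labels)
}

#' Simulate a per-base depth track for one animal
#'
#' Generates run-length encoded per-base read depth with the statistical
#' structure the read-depth caller assumes. Depth is piecewise constant over
#' `block`-bp blocks; a block at copy number CN draws its level from
#' N((CN/2) mu2 g, (CN/2) sigma2_sq) truncated at zero — so 1-kb bin means
#' inherit the mixture's component moments — except CN = 0 blocks, whose
#' residual depth is half-normal with scale sigma0. Each block carries a GC
#' fraction drawn around `gc_mean`, stored as a per-base GC value; the
#' multiplicative factor `g = gc_bias(gc)` distorts expected depth as a
#' function of GC (identity by default), which [gc_correct()] must undo.
#'
#' @param truth a `truth_set`.
#' @param animal animal id whose planted copy numbers shape the track.
#' @param mu2 mean diploid depth.
#' @param sigma2_sq diploid depth variance between 1-kb blocks (default 6,
#'   a coefficient of variation of ~8% at 10X coverage — typical of
#'   GC-corrected 1-kb bin means from real short-read data).
#' @param sigma0_sq half-normal scale squared for CN = 0 blocks.
#' @param gc_bias function of GC fraction returning a multiplicative depth
#'   factor.
#' @param gc_mean,gc_sd block GC fraction distribution.
#' @param block block size in bp.
#' @param chroms chromosomes to simulate (default: the autosomes).
#' @param seed optional RNG seed.
#' @return a `depth_track` with `gc` filled and the truth-set repeat mask
#'   attached.
#' @export
simulate_depth <- function(truth, animal, mu2 = 30, sigma2_sq = 6,
                           sigma0_sq = 1.5, gc_bias = function(gc) 1,
                           gc_mean = 0.42, gc_sd = 0.05, block = 1000,
                           chroms = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "truth_set"), mu2 > 0)
  layout <- truth$layout
  if (is.null(chroms)) chroms <- layout$autosomes
  depth <- list(); gc <- list(); mask <- list()
  for (ch in chroms) {
    L <- as.integer(layout$lengths[[ch]])
    n_blocks <- ceiling(L / block)
    block_cn <- rep(2L, n_blocks)
    cvs <- truth$cnvrs[truth$cnvrs$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(cvs))) {
      cn <- truth$cn[rownames(truth$cn) == cvs$cnvr[j], animal]
      if (cn == 2) next
      b0 <- floor(cvs$start[j] / block) + 1
      b1 <- ceiling(cvs$stop[j] / block)
      block_cn[b0:b1] <- cn
    }
    bgc <- pmin(0.8, pmax(0.2, stats::rnorm(n_blocks, gc_mean, gc_sd)))
    g <- vapply(bgc, gc_bias, 0)
    level <- numeric(n_blocks)
    zero <- block_cn == 0
    level[zero] <- abs(stats::rnorm(sum(zero), 0, sqrt(sigma0_sq)))
    nz <- !zero
    half_cn <- block_cn[nz] / 2
    level[nz] <- pmax(0, stats::rnorm(sum(nz), half_cn * mu2 * g[nz],
                                      sqrt(half_cn * sigma2_sq)))
    widths <- rep(block, n_blocks)
    widths[n_blocks] <- L - (n_blocks - 1) * block
    depth[[ch]] <- S4Vectors::Rle(level, widths)
    gc[[ch]] <- S4Vectors::Rle(bgc, widths)
    m <- truth$mask[truth$mask$chrom == ch, , drop = FALSE]
    mask[[ch]] <- if (nrow(m)) {
      IRanges::reduce(.as_iranges(m$start, pmin(m$stop, L)))
    } else IRanges::IRanges()
  }
  depth_track(depth = depth, mask = mask, gc = gc)
}

#' Draw bin depths directly from the read-depth mixture
#'
#' Small generator used for parameter-recovery checks: bin depths are drawn
#' i.i.d. from the five-class mixture itself (half-normal for CN = 0,
#' moment-tied normals for CN = 1..4, negative draws truncated to 0).
#'
#' @param n number of bins.
#' @param params a `MixtureParams`.
#' @param seed optional RNG seed.
#' @return data.frame with `corrected` (depth) and `cn` (true class).
#' @export
simulate_mixture_bins <- function(n, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- c(params$pi0, params$pi1, params$pi2, params$pi3, params$pi4)
  cn <- sample(0:4, n, replace = TRUE, prob = w)
  d <- numeric(n)
  z <- cn == 0
  d[z] <- abs(stats::rnorm(sum(z), 0, sqrt(params$sigma0_sq)))
  for (k in 1:4) {
    sel <- cn == k
    if (!any(sel)) next
    d[sel] <- pmax(0, stats::rnorm(sum(sel), (k / 2) * params$mu2,
                                   sqrt((k / 2) * params$sigma2_sq)))
  }
  data.frame(corrected = d, cn = cn)
}

#' Simulate a lower-sensitivity platform call set
#'
#' Emulates an independent, lower-resolution platform: each planted CNVR of
#' length at least `min_length` carried by an animal (CN != 2) is emitted
#' for that animal independently with probability `sensitivity`, with
#' boundary jitter uniform on +/- `jitter` bp.
#'
#' @param truth a `truth_set`.
#' @param sensitivity per-call detection probability in `[0, 1]`.
#' @param min_length platform resolution floor in bp.
#' @param jitter maximum boundary jitter in bp.
#' @param animals animals to emit for (default: all test animals).
#' @param seed optional RNG seed.
#' @return data.frame `animal`, `chrom`, `start`, `stop`, `type`, `cnvr`.
#' @export
simulate_platform_calls <- function(truth, sensitivity = 0.6, min_length = 0,
                                    jitter = 0, animals = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  if (is.null(animals)) {
    animals <- truth$pedigree$animal[truth$pedigree$animal != truth$reference]
  }
  out <- list()
  for (j in seq_len(nrow(truth$cnvrs))) {
    cv <- truth$cnvrs[j, ]
    if (cv$length < min_length) next
    for (an in animals) {
      if (truth$cn[j, an] == 2) next
      if (stats::runif(1) > sensitivity) next
      st <- cv$start + if (jitter > 0) round(stats::runif(1, -jitter, jitter)) else 0
      sp <- cv$stop + if (jitter > 0) round(stats::runif(1, -jitter, jitter)) else 0
      if (sp <= st) sp <- st + 1
      out[[length(out) + 1]] <- data.frame(
        animal = an, chrom = cv$chrom, start = max(0, st), stop = sp,
        type = if (truth$cn[j, an] < 2) "deletion" else "duplication",
        cnvr = cv$cnvr)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(animal = character(), chrom = character(), start = numeric(),
               stop = numeric(), type = character(), cnvr = character())
  rownames(res) <- NULL
  res
}
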