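#' Merge CNV calls into CNV regions
#'
#' CNV calls from all animals are combined: calls on the same chromosome that
#' overlap or lie within `gap` bp of one another (default 1,500) are
#' transitively collapsed into one CNV region (CNVR). A CNVR spans from the
#' smallest start to the largest stop of its member calls, is typed
#' `deletion`, `duplication`, or `both` according to the member call types,
#' and records the set of supporting animals. The result is independent of
#' input order.
#'
#' @param calls a `cnv_calls` data.frame (needs `chrom`, `start`, `stop`,
#'   `type`, `animal`).
#' @param gap maximum gap (bp) for merging; two calls merge iff
#'   `next.start - prev.stop <= gap`.
#' @return data.frame with one row per CNVR: `chrom`, `start`, `stop`,
#'   `length`, `type`, `n_animals`, `animals` (comma-joined), `n_calls`,
#'   and a `calls` list-column of member row indices into `calls`.
#' @export
merge_to_cnvrs <- function(calls, gap = 1500) {
  if (nrow(calls) == 0) {
    return(data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      length = numeric(), type = character(),
                      n_animals = integer(), animals = character(),
                      n_calls = integer()))
  }
  stopifnot(all(c("chrom", "start", "stop", "type", "animal") %in% names(calls)))
  out <- list()
  for (ch in sort(unique(calls$chrom))) {
    idx <- which(calls$chrom == ch)
    ir <- .as_iranges(calls$start[idx], calls$stop[idx])
    # reduce() merges ranges closer than min.gapwidth; gap <= 1500 merges
    red <- IRanges::reduce(ir, min.gapwidth = gap + 1)
    hit <- IRanges::findOverlaps(ir, red, maxgap = gap)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in seq_along(red)) {
      members <- idx[grp == g]
      types <- unique(calls$type[members])
      type <- if (length(types) > 1) "both" else types
      animals <- sort(unique(calls$animal[members]))
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = IRanges::start(red)[g] - 1,
        stop = IRanges::end(red)[g],
        type = type,
        n_animals = length(animals),
        animals = paste(animals, collapse = ","),
        n_calls = length(members)
      )
      out[[length(out)]]$calls <- I(list(members))
    }
  }
  res <- do.call(rbind, out)
  res$length <- res$stop - res$start
  rownames(res) <- NULL
  res[, c("chrom", "start", "stop", "length", "type", "n_animals",
          "animals", "n_calls", "calls")]
}

#' CNVR frequency spectrum
#'
#' Tabulates CNVRs by the number of supporting animals and summarizes the
#' singleton fraction and the fraction observed independently in at least
#' two animals.
#'
#' @param cnvrs CNVR data.frame from [merge_to_cnvrs()] (or any table with
#'   an `n_animals` column).
#' @return list with `spectrum` (data.frame n_animals/count), `n_total`,
#'   `fraction_singleton` and `fraction_multi` (>= 2 animals).
#' @export
frequency_spectrum <- function(cnvrs) {
  if (nrow(cnvrs) == 0) {
    return(list(spectrum = data.frame(n_animals = integer(), count = integer()),
                n_total = 0L, fraction_singleton = NaN, fraction_multi = NaN))
  }
  tab <- table(cnvrs$n_animals)
  spectrum <- data.frame(n_animals = as.integer(names(tab)),
                         count = as.integer(tab))
  list(spectrum = spectrum,
       n_total = nrow(cnvrs),
       fraction_singleton = mean(cnvrs$n_animals == 1),
       fraction_multi = mean(cnvrs$n_animals >= 2))
}

#' Flag putative reference-animal CNVRs
#'
#' A CNVR supported by every assayed animal most likely reflects a CNV in
#' the shared reference animal (every test/reference comparison shows the
#' same ratio shift) rather than a variant carried by all test animals —
#' the "reference effect".
#'
#' @param cnvrs CNVR data.frame.
#' @param n_animals number of assayed (test) animals.
#' @return logical vector flagging the all-animal CNVRs.
#' @export
flag_reference_effect <- function(cnvrs, n_animals) {
  if (n_animals == 1) {
    warning("only one animal assayed; every CNVR is flagged (uninformative)")
  }
  cnvrs$n_animals >= n_animals
}

#' Genome fraction covered by CNVRs or calls
#'
#' Union length of the intervals divided by the total autosome length, as a
#' percentage. The per-animal variant restricts to one animal's calls.
#'
#' @param intervals data.frame with `chrom`, `start`, `stop` (and `animal`
#'   for `per_animal = TRUE`).
#' @param layout a `GenomeLayout`.
#' @param per_animal compute one percentage per animal instead of overall.
#' @return numeric percentage (or named vector per animal).
#' @export
genome_fraction <- function(intervals, layout, per_animal = FALSE) {
  stopifnot(inherits(layout, "GenomeLayout"))
  check <- merge(intervals, data.frame(chrom = names(layout$lengths),
                                       .len = unname(layout$lengths)),
                 by = "chrom", all.x = TRUE)
  if (anyNA(check$.len) || any(check$stop > check$.len)) {
    stop("interval beyond chromosome end (or unknown chromosome)")
  }
  total <- autosome_length(layout)
  union_bp <- function(df) {
    sum(vapply(split(df, df$chrom), function(d) {
      sum(IRanges::width(IRanges::reduce(.as_iranges(d$start, d$stop))))
    }, 0))
  }
  if (!per_animal) return(100 * union_bp(intervals) / total)
  vapply(split(intervals, intervals$animal),
         function(d) 100 * union_bp(d) / total, 0)
}

#' Place CNVR lengths uniformly at random in the genome
#'
#' Simulates the uniform null used for the spatial-clustering test: the
#' observed CNVR lengths are kept but each region is re-placed uniformly at
#' random, with chromosome assignment proportional to chromosome length and
#' the constraint that no two simulated regions come within `min_spacing`
#' bp of each other. Placement is by bounded rejection sampling.
#'
#' @param lengths numeric vector of CNVR lengths (bp).
#' @param layout a `GenomeLayout` (autosomes are used).
#' @param min_spacing minimum allowed gap between placed regions (bp).
#' @param max_tries rejection-sampling attempts per region before a capacity
#'   error.
#' @return data.frame `chrom`, `start`, `stop` of the placed regions.
#' @export
simulate_uniform_null <- function(lengths, layout, min_spacing = 1500,
                                  max_tries = 1000) {
  chrom_names <- layout$autosomes
  chrom_len <- layout$lengths[chrom_names]
  if (sum(lengths) + (length(lengths) - 1) * min_spacing > sum(chrom_len)) {
    stop("genome too small to place ", length(lengths), " regions")
  }
  # plain numeric interval bookkeeping: this inner loop runs ~10^5 times in
  # the permutation tests, where IRanges call overhead would dominate
  pstart <- lapply(chrom_names, function(ch) numeric())
  pstop <- pstart
  names(pstart) <- names(pstop) <- chrom_names
  out_chrom <- character(length(lengths))
  out_start <- numeric(length(lengths))
  # place longest first: improves packing without biasing uniform placement
  ord <- order(lengths, decreasing = TRUE)
  n_chrom <- length(chrom_names)
  for (j in ord) {
    L <- lengths[j]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(n_chrom, 1, prob = chrom_len)
      ch <- chrom_names[ci]
      if (chrom_len[[ci]] < L) next
      st <- floor(stats::runif(1, 0, chrom_len[[ci]] - L + 1))
      # reject if candidate overlaps or comes within min_spacing of a
      # placed region (a gap of exactly min_spacing is allowed)
      clash <- any(st < pstop[[ch]] + min_spacing &
                     st + L + min_spacing > pstart[[ch]])
      if (!clash) {
        pstart[[ch]] <- c(pstart[[ch]], st)
        pstop[[ch]] <- c(pstop[[ch]], st + L)
        out_chrom[j] <- ch
        out_start[j] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place a region of length ", L, " after ",
                  max_tries, " tries (capacity error)")
  }
  data.frame(chrom = out_chrom, start = out_start,
             stop = out_start + lengths)
}

#' Inter-CNVR distances
#'
#' Gaps between consecutive CNVRs on the same chromosome (next start minus
#' previous stop); cross-chromosome pairs are excluded.
#'
#' @param cnvrs data.frame with `chrom`, `start`, `stop`.
#' @return numeric vector of distances (bp), possibly empty.
#' @export
inter_cnvr_distances <- function(cnvrs) {
  unlist(lapply(split(cnvrs, cnvrs$chrom), function(d) {
    if (nrow(d) < 2) return(numeric())
    d <- d[order(d$start), , drop = FALSE]
    d$start[-1] - d$stop[-nrow(d)]
  }), use.names = FALSE)
}

#' Test CNVR placement against a uniform null
#'
#' Compares the observed inter-CNVR distance distribution with the distances
#' from a size-matched simulated uniform placement (same lengths, same
#' genome, 1,500-bp minimum spacing) using a two-sample Kolmogorov-Smirnov
#' test. Clustered CNVRs show an excess of short distances relative to the
#' uniform null. With `replicates > 1` the simulated distances are pooled
#' over replicates for a more stable null sample.
#'
#' @param cnvrs observed CNVR data.frame.
#' @param layout a `GenomeLayout`.
#' @param min_spacing spacing constraint passed to the null simulator.
#' @param replicates number of simulated null replicates (default 1).
#' @return list with `D`, `p_value`, `observed` and `simulated` distance
#'   samples, or `NULL` (with a message) if fewer than two CNVRs share a
#'   chromosome.
#' @export
ks_uniformity_test <- function(cnvrs, layout, min_spacing = 1500,
                               replicates = 1) {
  obs <- inter_cnvr_distances(cnvrs)
  if (length(obs) < 2) {
    message("too few CNVRs for a spatial test; skipping")
    return(NULL)
  }
  sim <- unlist(lapply(seq_len(replicates), function(r) {
    null_set <- simulate_uniform_null(cnvrs$length, layout, min_spacing)
    inter_cnvr_distances(null_set)
  }))
  kt <- suppressWarnings(stats::ks.test(obs, sim))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       observed = obs, simulated = sim)
}
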