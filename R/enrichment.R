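#' Gene-overlap proportions by CNVR type
#'
#' A CNVR overlaps genes when its intersection with the union of gene coding
#' sequence (CDS) intervals is at least `min_overlap` bp; a CNVR spanning
#' several genes counts once. Proportions are computed per CNVR type
#' (deletion, duplication, both) and overall.
#'
#' @param cnvrs CNVR data.frame with `chrom`, `start`, `stop`, `type`.
#' @param cds data.frame of CDS intervals (`chrom`, `start`, `stop`).
#' @param min_overlap minimum intersection in bp.
#' @return list with `overlapping` (logical per CNVR), `proportions` (named:
#'   one per type plus `all`) and `counts` (per-type totals and overlaps).
#' @export
gene_overlap <- function(cnvrs, cds, min_overlap = 1) {
  overlapping <- logical(nrow(cnvrs))
  for (ch in unique(cnvrs$chrom)) {
    ci <- which(cnvrs$chrom == ch)
    g <- cds[cds$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    gr <- IRanges::reduce(.as_iranges(g$start, g$stop))
    hits <- IRanges::findOverlaps(.as_iranges(cnvrs$start[ci], cnvrs$stop[ci]),
                                  gr, minoverlap = min_overlap)
    overlapping[ci[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  types <- c("deletion", "duplication", "both")
  props <- vapply(types, function(t) {
    sel <- cnvrs$type == t
    if (!any(sel)) NaN else mean(overlapping[sel])
  }, 0)
  props <- c(props, all = mean(overlapping))
  counts <- data.frame(
    type = c(types, "all"),
    n = c(vapply(types, function(t) sum(cnvrs$type == t), 0L), nrow(cnvrs)),
    n_overlap = c(vapply(types, function(t) sum(overlapping[cnvrs$type == t]), 0L),
                  sum(overlapping))
  )
  list(overlapping = overlapping, proportions = props, counts = counts)
}

#' Chi-square test of duplication vs deletion gene overlap
#'
#' Standard 2x2 chi-square (without continuity correction by default) on
#' counts of duplication/deletion CNVRs overlapping vs not overlapping gene
#' coding sequence.
#'
#' @param n_dup_overlap,n_dup overlapping and total duplication CNVRs.
#' @param n_del_overlap,n_del overlapping and total deletion CNVRs.
#' @param correct apply Yates' continuity correction.
#' @return list with `statistic` and `p_value`.
#' @export
dup_del_test <- function(n_dup_overlap, n_dup, n_del_overlap, n_del,
                         correct = FALSE) {
  stopifnot(n_dup_overlap >= 0, n_del_overlap >= 0,
            n_dup >= n_dup_overlap, n_del >= n_del_overlap)
  m <- matrix(c(n_dup_overlap, n_dup - n_dup_overlap,
                n_del_overlap, n_del - n_del_overlap),
              nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("a zero margin makes the chi-square test undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Monte-Carlo gene-overlap enrichment test
#'
#' Re-places the CNVRs (lengths preserved) uniformly at random across the
#' autosomes `n_iter` times — the same placement engine and 1,500-bp spacing
#' constraint as the spatial-uniformity null — and recomputes the gene
#' overlap proportion per CNVR type each time. The observed proportion is
#' ranked among the simulated ones.
#'
#' Two empirical-p conventions are offered. `"add-one-two-tailed"` (default):
#' p = min(1, 2 * min(r_hi, r_lo) / (n_iter + 1)) with
#' r_hi = 1 + #(sim >= obs), r_lo = 1 + #(sim <= obs); the smallest
#' attainable p is 2 / (n_iter + 1). `"one-sided"`: p = r_hi / (n_iter + 1),
#' the enrichment direction only.
#'
#' @param cnvrs CNVR data.frame with `type`.
#' @param cds CDS interval data.frame.
#' @param layout a `GenomeLayout`.
#' @param n_iter number of randomizations (default 100; fewer than 20 gives
#'   a warning — the p resolution becomes too coarse).
#' @param p_convention empirical-p convention (see above).
#' @param min_spacing spacing constraint for placement.
#' @return list with `observed` proportions, `simulated` (n_iter x types
#'   matrix), `p_values` (per type), `n_iter` and `p_convention`.
#' @export
permute_enrichment <- function(cnvrs, cds, layout, n_iter = 100,
                               p_convention = c("add-one-two-tailed",
                                                "one-sided"),
                               min_spacing = 1500) {
  p_convention <- match.arg(p_convention)
  if (n_iter < 20) warning("n_iter < 20: empirical p resolution is coarse")
  obs <- gene_overlap(cnvrs, cds)$proportions
  types <- names(obs)
  sim <- matrix(NA_real_, nrow = n_iter, ncol = length(types),
                dimnames = list(NULL, types))
  for (it in seq_len(n_iter)) {
    placed <- simulate_uniform_null(cnvrs$stop - cnvrs$start, layout,
                                    min_spacing = min_spacing)
    placed$type <- cnvrs$type  # lengths/types travel with the regions
    sim[it, ] <- gene_overlap(placed, cds)$proportions
  }
  p_values <- vapply(types, function(t) {
    if (!is.finite(obs[[t]])) return(NaN)
    s <- sim[, t]
    s <- s[is.finite(s)]
    r_hi <- 1 + sum(s >= obs[[t]])
    r_lo <- 1 + sum(s <= obs[[t]])
    if (p_convention == "one-sided") {
      r_hi / (length(s) + 1)
    } else {
      min(1, 2 * min(r_hi, r_lo) / (length(s) + 1))
    }
  }, 0)
  list(observed = obs, simulated = sim, p_values = p_values,
       n_iter = n_iter, p_convention = p_convention)
}
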