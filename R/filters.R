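#' Filtering policy
#'
#' Collects every threshold used by the pre-model and post-model filters.
#' Defaults are the survey values: calls with absolute log2 ratio below 0.1
#' are dropped before modelling; model-accepted calls must reach probability
#' 0.95, be at least 1 kb long, span at least 3 probes and have absolute log2
#' ratio at least 0.25; calls on the virtual unknown chromosome need absolute
#' log2 ratio strictly above 0.32 (set from the self-self calls observed
#' there) and at least 2 probes.
#'
#' @param min_absl2r_prefilter pre-model |l2r| floor (inclusive).
#' @param p_threshold model acceptance probability (inclusive).
#' @param min_length minimum call length in bp (inclusive).
#' @param min_probes minimum probe count (inclusive).
#' @param min_absl2r post-model |l2r| floor (inclusive).
#' @param chrun_min_absl2r chrUn |l2r| floor (exclusive: `<=` is removed).
#' @param chrun_min_probes minimum probes for a chrUn call.
#' @param chrun_min_probes_outside minimum scaffold probes that must fall
#'   outside the call.
#' @param qc_k multiplier in the failed-array rule median + k * MAD.
#' @return a `FilterPolicy` list.
#' @export
filter_policy <- function(min_absl2r_prefilter = 0.1,
                          p_threshold = 0.95,
                          min_length = 1000,
                          min_probes = 3,
                          min_absl2r = 0.25,
                          chrun_min_absl2r = 0.32,
                          chrun_min_probes = 2,
                          chrun_min_probes_outside = 2,
                          qc_k = 3) {
  pol <- list(min_absl2r_prefilter = min_absl2r_prefilter,
              p_threshold = p_threshold,
              min_length = min_length,
              min_probes = min_probes,
              min_absl2r = min_absl2r,
              chrun_min_absl2r = chrun_min_absl2r,
              chrun_min_probes = chrun_min_probes,
              chrun_min_probes_outside = chrun_min_probes_outside,
              qc_k = qc_k)
  stopifnot(all(unlist(pol) > 0), p_threshold < 1)
  structure(pol, class = "FilterPolicy")
}

#' Flag failed arrays by probe-ratio variance
#'
#' Arrays whose genome-wide normalized log2-ratio variance is an outlier
#' relative to the other animals are treated as failed hybridizations and
#' their calls excluded. The rule is variance > median + k * MAD over
#' animals (k = 3 by default).
#'
#' @param variances named numeric vector, animal -> per-probe l2r variance.
#' @param k outlier multiplier.
#' @return character vector of flagged animal ids (possibly empty).
#' @export
qc_flag_failed_arrays <- function(variances, k = 3) {
  if (length(variances) < 3) {
    warning("fewer than 3 animals; array QC skipped")
    return(character())
  }
  cutoff <- stats::median(variances) + k * stats::mad(variances)
  names(variances)[variances > cutoff]
}

#' Pre-model ratio filter
#'
#' Removes segment calls with absolute log2 ratio below 0.1 before any
#' modelling (the floor is inclusive: 0.1 itself is kept).
#'
#' @param calls segment-call data.frame.
#' @param min_absl2r floor (inclusive).
#' @return the retained subset.
#' @export
prefilter_ratio <- function(calls, min_absl2r = 0.1) {
  calls[calls$absl2r >= min_absl2r, , drop = FALSE]
}

#' Post-model autosomal filter
#'
#' Keeps autosomal calls with model probability at or above the threshold
#' that are at least 1 kb long, span at least 3 probes and have absolute
#' log2 ratio at least 0.25. Kept calls are typed deletion/duplication by
#' the sign of the log2 ratio.
#'
#' @param calls_with_p segment-call data.frame with a `p` column.
#' @param policy a `FilterPolicy`.
#' @param layout a `GenomeLayout`; calls on non-autosomes raise an error
#'   (route them to [filter_chrX()] / [filter_chrun()]).
#' @return a `cnv_calls` data.frame.
#' @export
filter_autosomal <- function(calls_with_p, policy = filter_policy(),
                             layout = NULL) {
  if (!"p" %in% names(calls_with_p)) stop("calls need a 'p' column")
  if (!is.null(layout)) {
    bad <- !(calls_with_p$chrom %in% layout$autosomes)
    if (any(bad)) {
      stop(sum(bad), " non-autosomal call(s) in autosomal filter; use ",
           "filter_chrX()/filter_chrun() for X and chrUn calls")
    }
  }
  keep <- calls_with_p$p >= policy$p_threshold &
    calls_with_p$length >= policy$min_length &
    calls_with_p$datapoints >= policy$min_probes &
    calls_with_p$absl2r >= policy$min_absl2r
  as_cnv_calls(calls_with_p[keep, , drop = FALSE])
}

#' Chromosome X filter
#'
#' X calls pass the same model and size/ratio filters as autosomal calls,
#' then a sex rule: females keep deletions and duplications; males keep only
#' duplications (a male deletion against a female reference is inconclusive
#' because it may only reflect the X-dosage difference). Calls from animals
#' of unknown sex are dropped with a warning.
#'
#' @param calls_with_p X-chromosome calls with a `p` column.
#' @param sex named character vector animal -> "M"/"F".
#' @param policy a `FilterPolicy`.
#' @return a `cnv_calls` data.frame.
#' @export
filter_chrX <- function(calls_with_p, sex, policy = filter_policy()) {
  kept <- filter_autosomal(calls_with_p, policy)
  s <- sex[kept$animal]
  unknown <- is.na(s)
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " X call(s) from animals of unknown sex")
  }
  keep <- !unknown & (s == "F" | (s == "M" & kept$type == "duplication"))
  kept[keep, , drop = FALSE]
}

#' Virtual-unknown-chromosome filter
#'
#' Calls on the virtual chromosome built from unplaced scaffolds are handled
#' with their own rules: a call is kept only if it lies within a single
#' scaffold, does not contain every probe of that scaffold, leaves at least
#' two scaffold probes outside the call, spans at least two probes itself,
#' and has absolute log2 ratio strictly greater than 0.32.
#'
#' @param calls chrUn segment calls.
#' @param layout a `GenomeLayout` with chrUn scaffolds.
#' @param policy a `FilterPolicy`.
#' @param probe_spacing chrUn probe spacing in bp (design density, one probe
#'   per ~1,600 bp).
#' @return a `cnv_calls` data.frame (an all-zero `p` column is added when
#'   absent, since chrUn calls are not run through the autosomal model).
#' @export
filter_chrun <- function(calls, layout, policy = filter_policy(),
                         probe_spacing = 1600) {
  probes <- chrun_probe_positions(layout, spacing = probe_spacing)
  sc <- layout$chrun_scaffolds
  n <- nrow(calls)
  keep <- logical(n)
  for (i in seq_len(n)) {
    st <- calls$start[i]; sp <- calls$stop[i]
    in_sc <- which(sc$start <= st & sp <= sc$stop)
    if (length(in_sc) == 0) {
      hit <- which(st < sc$stop & sp > sc$start)
      if (length(hit) == 0) {
        stop("chrUn call at [", st, ",", sp, ") lies in an N spacer")
      }
      next  # spans more than one scaffold -> discarded
    }
    pp <- probes$pos[probes$scaffold == in_sc]
    inside <- pp >= st & pp < sp
    if (sum(inside) == length(pp)) next          # covers all scaffold probes
    if (length(pp) - sum(inside) < policy$chrun_min_probes_outside) next
    if (sum(inside) < policy$chrun_min_probes) next
    if (calls$absl2r[i] <= policy$chrun_min_absl2r) next
    keep[i] <- TRUE
  }
  out <- calls[keep, , drop = FALSE]
  if (!"p" %in% names(out)) out$p <- rep(0, nrow(out))
  as_cnv_calls(out)
}
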