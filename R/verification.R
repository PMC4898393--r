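#' Cross-platform overlap verification
#'
#' A query record (e.g. a CNVR call from the high-density array, mapped to
#' the evidence platform's coordinate system) is verified when at least one
#' evidence interval from the SAME animal overlaps it by at least
#' `min_overlap` bp. Comparisons are strictly per animal; a query animal
#' absent from the evidence set contributes not-verified records (logged).
#' Intervals are 0-based half-open, so abutting intervals do not overlap.
#'
#' @param query data.frame with `animal`, `chrom`, `start`, `stop`.
#' @param evidence data.frame with the same columns (pre-filtered as the
#'   evidence platform requires, e.g. absolute log2 ratio >= 0.25).
#' @param min_overlap minimum intersection length in bp.
#' @return list with `records` (query plus a logical `verified`), `verified`,
#'   `not_verified`, `total` and `percent_verified`.
#' @export
overlap_verify <- function(query, evidence, min_overlap = 1) {
  verified <- logical(nrow(query))
  missing_animals <- setdiff(unique(query$animal), unique(evidence$animal))
  if (length(missing_animals)) {
    message("no evidence intervals for animal(s): ",
            paste(missing_animals, collapse = ", "))
  }
  for (an in setdiff(unique(query$animal), missing_animals)) {
    qi <- which(query$animal == an)
    ev <- evidence[evidence$animal == an, , drop = FALSE]
    for (ch in unique(query$chrom[qi])) {
      qii <- qi[query$chrom[qi] == ch]
      evc <- ev[ev$chrom == ch, , drop = FALSE]
      if (nrow(evc) == 0) next
      qr <- .as_iranges(query$start[qii], query$stop[qii])
      er <- .as_iranges(evc$start, evc$stop)
      hits <- IRanges::findOverlaps(qr, er, minoverlap = min_overlap)
      verified[qii[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
  }
  records <- query
  records$verified <- verified
  verification_report(sum(verified), sum(!verified), records = records)
}

#' Assemble a verification report from counts
#'
#' The report arithmetic (totals and percentage verified) is exposed
#' separately so that published platform counts can be summarized with the
#' same code path that [overlap_verify()] uses.
#'
#' @param verified,not_verified call counts.
#' @param records optional per-call status table.
#' @return list with `verified`, `not_verified`, `total`,
#'   `percent_verified` and `records`.
#' @export
verification_report <- function(verified, not_verified, records = NULL) {
  total <- verified + not_verified
  list(verified = verified, not_verified = not_verified, total = total,
       percent_verified = if (total > 0) 100 * verified / total else NaN,
       records = records)
}

#' Compare CNVRs with literature study sets
#'
#' Annotates every literature CNVR with (a) the number of studies it appears
#' in — its own study plus any other study containing an interval that
#' overlaps it by at least `min_overlap` bp — and (b) whether any of our
#' CNVRs overlaps it by at least `min_overlap` bp. The detection table is
#' aggregated by study count (rows: observed-in-k-studies; columns: total
#' and detected). The reciprocal direction — the fraction of our CNVRs
#' overlapping any literature interval — is reported alongside.
#'
#' @param our_cnvrs data.frame `chrom`, `start`, `stop` (pre-mapped to the
#'   shared coordinate system).
#' @param studies named list of data.frames (`chrom`, `start`, `stop`), one
#'   per study; names must be unique.
#' @param min_overlap minimum intersection in bp.
#' @return list with `by_literature` (per-interval annotation), `table`
#'   (study-count rows), `summary` (see [study_comparison_summary()]) and
#'   `reciprocal` (fraction of our CNVRs overlapping any study).
#' @export
compare_to_studies <- function(our_cnvrs, studies, min_overlap = 1) {
  if (length(studies) == 0) stop("empty study list")
  if (is.null(names(studies)) || anyDuplicated(names(studies))) {
    stop("studies must be uniquely named")
  }
  lit <- do.call(rbind, lapply(names(studies), function(s) {
    df <- studies[[s]][, c("chrom", "start", "stop")]
    df$study <- s
    df
  }))
  n <- nrow(lit)
  overlaps_any <- function(a, b) {
    # logical: does each interval of a overlap >= min_overlap bp of b
    res <- logical(nrow(a))
    for (ch in unique(a$chrom)) {
      ai <- which(a$chrom == ch)
      bi <- b[b$chrom == ch, , drop = FALSE]
      if (nrow(bi) == 0) next
      hits <- IRanges::findOverlaps(.as_iranges(a$start[ai], a$stop[ai]),
                                    .as_iranges(bi$start, bi$stop),
                                    minoverlap = min_overlap)
      res[ai[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    res
  }
  study_count <- rep(1L, n)
  for (s in names(studies)) {
    mine <- lit$study == s
    others <- lit[!mine, , drop = FALSE]
    if (nrow(others) == 0) next
    for (o in unique(others$study)) {
      hit <- overlaps_any(lit[mine, , drop = FALSE],
                          others[others$study == o, , drop = FALSE])
      study_count[which(mine)[hit]] <- study_count[which(mine)[hit]] + 1L
    }
  }
  detected <- overlaps_any(lit, our_cnvrs)
  lit$study_count <- study_count
  lit$detected <- detected
  counts <- sort(unique(study_count))
  tab <- data.frame(
    study_count = counts,
    total = vapply(counts, function(k) sum(study_count == k), 0L),
    detected = vapply(counts, function(k) sum(detected[study_count == k]), 0L)
  )
  recip <- mean(overlaps_any(our_cnvrs, lit))
  list(by_literature = lit, table = tab,
       summary = study_comparison_summary(tab), reciprocal = recip)
}

#' Aggregate a study-count detection table
#'
#' Computes the grand totals of a detection table keyed by "number of
#' studies a CNVR was observed in": total literature CNVRs, how many we
#' detected (with percentage), and the same restricted to CNVRs observed in
#' more than one study.
#'
#' @param tab data.frame with `study_count`, `total`, `detected` (one row
#'   per study-count value), as produced by [compare_to_studies()] or
#'   entered from a published table.
#' @return list with `n_literature`, `n_detected`, `percent_detected`,
#'   `n_multi`, `n_multi_detected`, `percent_multi_detected`.
#' @export
study_comparison_summary <- function(tab) {
  stopifnot(all(c("study_count", "total", "detected") %in% names(tab)))
  multi <- tab$study_count > 1
  n_lit <- sum(tab$total)
  n_det <- sum(tab$detected)
  n_multi <- sum(tab$total[multi])
  n_multi_det <- sum(tab$detected[multi])
  list(n_literature = n_lit,
       n_detected = n_det,
       percent_detected = 100 * n_det / n_lit,
       n_multi = n_multi,
       n_multi_detected = n_multi_det,
       percent_multi_detected = 100 * n_multi_det / n_multi)
}
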