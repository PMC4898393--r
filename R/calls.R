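#' Segment-call tables
#'
#' The pipeline's central record is a segment call: one contiguous run of CGH
#' probes reported for one animal with a mean log2 test/reference intensity
#' ratio. Calls are kept in a plain data.frame with one row per call and the
#' columns:
#'
#' * `animal` — animal identifier
#' * `chrom` — chromosome name
#' * `start`, `stop` — 0-based half-open coordinates (bp)
#' * `first_probe`, `last_probe` — probe indices of the segment ends
#' * `l2r` — mean log2 ratio of the segment
#' * `datapoints` — number of probes in the segment
#' * `length` — `stop - start` (derived)
#' * `absl2r` — `abs(l2r)` (derived)
#'
#' `segment_calls()` builds and validates such a table; `validate_segment_calls()`
#' checks an existing one.
#'
#' @param animal,chrom,start,stop,first_probe,last_probe,l2r,datapoints
#'   per-call vectors, recycled to a common length.
#' @return a validated segment-call data.frame (class `segment_calls`).
#' @examples
#' sc <- segment_calls(animal = "A1", chrom = "chr1", start = 1000,
#'                     stop = 2000, first_probe = 10, last_probe = 14,
#'                     l2r = -0.62, datapoints = 5)
#' sc$length  # 1000
#' @export
segment_calls <- function(animal = character(), chrom = character(),
                          start = numeric(), stop = numeric(),
                          first_probe = numeric(), last_probe = numeric(),
                          l2r = numeric(), datapoints = numeric()) {
  df <- data.frame(animal = as.character(animal),
                   chrom = as.character(chrom),
                   start = as.numeric(start), stop = as.numeric(stop),
                   first_probe = as.numeric(first_probe),
                   last_probe = as.numeric(last_probe),
                   l2r = as.numeric(l2r),
                   datapoints = as.numeric(datapoints),
                   stringsAsFactors = FALSE)
  df$length <- df$stop - df$start
  df$absl2r <- abs(df$l2r)
  validate_segment_calls(df)
}

#' @rdname segment_calls
#' @param calls a candidate segment-call data.frame.
#' @export
validate_segment_calls <- function(calls) {
  req <- c("animal", "chrom", "start", "stop", "first_probe", "last_probe",
           "l2r", "datapoints")
  miss <- setdiff(req, names(calls))
  if (length(miss)) {
    stop("segment-call table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"length" %in% names(calls)) calls$length <- calls$stop - calls$start
  if (!"absl2r" %in% names(calls)) calls$absl2r <- abs(calls$l2r)
  bad <- which(calls$stop <= calls$start)
  if (length(bad)) {
    stop("invalid segment call(s): stop <= start at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(calls$datapoints < 1)
  if (length(bad)) {
    stop("invalid segment call(s): datapoints < 1 at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(calls$datapoints != calls$last_probe - calls$first_probe + 1)
  if (length(bad)) {
    stop("invalid segment call(s): datapoints != last_probe - first_probe + 1 ",
         "at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  class(calls) <- unique(c("segment_calls", class(calls)))
  calls
}

#' Type a call by the sign of its log2 ratio
#'
#' Negative mean log2 ratio is a deletion (fewer copies in the test animal
#' than the reference), positive a duplication.
#'
#' @param l2r numeric vector of mean log2 ratios.
#' @return character vector, "deletion" or "duplication".
#' @export
call_type <- function(l2r) ifelse(l2r < 0, "deletion", "duplication")

#' Promote filtered segment calls to CNV calls
#'
#' A CNV call is a segment call that passed the model and filters; it carries
#' a `type` (from the sign of `l2r`) and the model probability `p`.
#'
#' @param calls segment-call data.frame with a `p` column.
#' @return the same table with a `type` column, class `cnv_calls`.
#' @export
as_cnv_calls <- function(calls) {
  calls <- validate_segment_calls(calls)
  if (!"p" %in% names(calls)) stop("calls need a model probability column 'p'")
  calls$type <- call_type(calls$l2r)
  class(calls) <- unique(c("cnv_calls", class(calls)))
  calls
}

# Convert 0-based half-open starts/stops to an IRanges (1-based closed).
.as_iranges <- function(start, stop) {
  IRanges::IRanges(start = as.integer(start + 1), end = as.integer(stop))
}

# Back-convert an IRanges to 0-based half-open columns.
.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1, stop = IRanges::end(ir))
}
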