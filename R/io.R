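#' Read a segment-call table
#'
#' Reads a tab-separated segment-call export (one row per segmentation call:
#' animal, chromosome, start, stop, first/last probe index, mean log2 ratio,
#' probe count). Array exports use 1-based inclusive coordinates; these are
#' converted to the package's internal 0-based half-open convention at the
#' boundary (`dialect = "1-based"`, the default). Files already in 0-based
#' half-open coordinates can be read with `dialect = "0-based"`.
#'
#' @param path path to a TSV file with a header row naming at least
#'   `animal, chrom, start, stop, first_probe, last_probe, l2r, datapoints`.
#' @param dialect coordinate dialect of the file.
#' @return a validated segment-call data.frame (see [segment_calls()]).
#' @export
read_segment_calls <- function(path, dialect = c("1-based", "0-based")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  req <- c("animal", "chrom", "start", "stop", "first_probe", "last_probe",
           "l2r", "datapoints")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("segment-call file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(segment_calls())
  }
  if (dialect == "1-based") {
    # 1-based inclusive [start, stop] -> 0-based half-open [start-1, stop)
    df$start <- df$start - 1
  }
  bad <- which(df$stop <= df$start)
  if (length(bad)) {
    stop("stop <= start in ", path, " at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(df$datapoints != df$last_probe - df$first_probe + 1)
  if (length(bad)) {
    stop("probe count inconsistent with probe indices in ", path,
         " at data row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  segment_calls(animal = df$animal, chrom = df$chrom, start = df$start,
                stop = df$stop, first_probe = df$first_probe,
                last_probe = df$last_probe, l2r = df$l2r,
                datapoints = df$datapoints)
}

#' Write a segment-call table
#'
#' Inverse of [read_segment_calls()]; writes the chosen coordinate dialect.
#'
#' @param calls segment-call data.frame.
#' @param path output path.
#' @param dialect coordinate dialect to write.
#' @export
write_segment_calls <- function(calls, path, dialect = c("1-based", "0-based")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(calls)[, c("animal", "chrom", "start", "stop",
                                 "first_probe", "last_probe", "l2r",
                                 "datapoints")]
  if (dialect == "1-based") df$start <- df$start + 1
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write CNVRs as BED
#'
#' Standard BED (0-based half-open, no header); the name column encodes the
#' CNVR type and supporting-animal count as `type;n=<count>`.
#'
#' @param cnvrs CNVR data.frame (see [merge_to_cnvrs()]).
#' @param path output path.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  if (nrow(cnvrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- paste0(cnvrs$type, ";n=", cnvrs$n_animals)
  df <- data.frame(chrom = cnvrs$chrom, start = format(cnvrs$start, scientific = FALSE, trim = TRUE),
                   stop = format(cnvrs$stop, scientific = FALSE, trim = TRUE), name = name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads the first three (plus optional name) columns of a BED file into a
#' data.frame with 0-based half-open `start`/`stop`.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `stop` and, when present, `name`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), name = character()))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "stop")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Read a CNVR BED written by [write_cnvr_bed()]
#'
#' @param path BED path.
#' @return CNVR-style data.frame with `chrom`, `start`, `stop`, `type`,
#'   `n_animals`.
#' @export
read_cnvr_bed <- function(path) {
  df <- read_bed(path)
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      type = character(), n_animals = integer()))
  }
  parts <- strsplit(df$name, ";n=", fixed = TRUE)
  df$type <- vapply(parts, `[`, "", 1)
  df$n_animals <- as.integer(vapply(parts, `[`, "", 2))
  df$name <- NULL
  df
}

#' Read a per-base depth track
#'
#' Reads a bedGraph coverage file (0-based half-open intervals, fourth column
#' the depth over the interval) for one or more chromosomes, together with an
#' optional repeat-mask BED, into per-chromosome run-length encoded depth.
#' Intervals must tile each chromosome without overlap; uncovered positions
#' get depth 0.
#'
#' @param path bedGraph path.
#' @param mask_path optional repeat-mask BED path.
#' @param lengths named vector of chromosome lengths; inferred from the data
#'   (max stop per chromosome) when `NULL`.
#' @param gc optional named list of per-base GC indicator [S4Vectors::Rle]
#'   vectors (see [depth_track()]).
#' @return a `depth_track` object: a list with per-chromosome `depth` (Rle),
#'   `mask` (IRanges of masked intervals) and optional `gc` (Rle).
#' @export
read_depth_track <- function(path, mask_path = NULL, lengths = NULL, gc = NULL) {
  bg <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "stop", "depth"))
  if (any(bg$depth < 0)) stop("negative depth in ", path)
  chroms <- unique(bg$chrom)
  if (is.null(lengths)) {
    lengths <- vapply(split(bg$stop, bg$chrom), max, 0)[chroms]
  }
  mask_df <- if (!is.null(mask_path)) read_bed(mask_path) else NULL
  depth <- list(); mask <- list()
  for (ch in chroms) {
    b <- bg[bg$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$stop[-nrow(b)])) {
      stop("overlapping bedGraph intervals on ", ch, " in ", path)
    }
    L <- lengths[[ch]]
    # fill gaps (uncovered positions) with depth 0
    vals <- numeric(0); lens <- numeric(0)
    pos <- 0
    for (i in seq_len(nrow(b))) {
      if (b$start[i] > pos) {
        vals <- c(vals, 0); lens <- c(lens, b$start[i] - pos)
      }
      vals <- c(vals, b$depth[i]); lens <- c(lens, b$stop[i] - b$start[i])
      pos <- b$stop[i]
    }
    if (pos < L) { vals <- c(vals, 0); lens <- c(lens, L - pos) }
    depth[[ch]] <- S4Vectors::Rle(vals, lens)
    m <- if (!is.null(mask_df)) mask_df[mask_df$chrom == ch, , drop = FALSE]
         else NULL
    mask[[ch]] <- if (!is.null(m) && nrow(m) > 0) {
      IRanges::reduce(.as_iranges(m$start, pmin(m$stop, L)))
    } else IRanges::IRanges()
  }
  depth_track(depth = depth, mask = mask, gc = gc)
}

#' Depth-track container
#'
#' Bundles per-chromosome run-length encoded per-base read depth with a
#' repeat mask and (optionally) a per-base GC indicator.
#'
#' @param depth named list of per-chromosome depth [S4Vectors::Rle] vectors.
#' @param mask named list of per-chromosome masked-interval [IRanges::IRanges]
#'   (1-based closed, as IRanges convention; converted from 0-based input by
#'   the readers).
#' @param gc optional named list of per-base GC indicator Rle (1 = G/C base).
#' @return a `depth_track` object.
#' @export
depth_track <- function(depth, mask = NULL, gc = NULL) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  if (is.null(mask)) {
    mask <- lapply(depth, function(d) IRanges::IRanges())
  }
  for (ch in names(depth)) {
    if (any(S4Vectors::runValue(depth[[ch]]) < 0)) {
      stop("negative depths on ", ch)
    }
    if (length(mask[[ch]]) > 0 &&
        max(IRanges::end(mask[[ch]])) > length(depth[[ch]])) {
      stop("mask extends beyond chromosome ", ch)
    }
  }
  structure(list(depth = depth, mask = mask, gc = gc), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("depth_track:", length(x$depth), "chromosome(s)\n")
  for (ch in names(x$depth)) {
    cat("  ", ch, ": ", length(x$depth[[ch]]), " bp, ",
        sum(IRanges::width(x$mask[[ch]])), " bp masked\n", sep = "")
  }
  invisible(x)
}

#' Write a depth track as bedGraph
#'
#' @param track a `depth_track`.
#' @param path output bedGraph path.
#' @export
write_depth_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$depth)) {
    d <- track$depth[[ch]]
    starts <- cumsum(c(0, head(S4Vectors::runLength(d), -1)))
    stops <- starts + S4Vectors::runLength(d)
    utils::write.table(
      data.frame(ch, format(starts, scientific = FALSE, trim = TRUE),
                 format(stops, scientific = FALSE, trim = TRUE),
                 S4Vectors::runValue(d)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a pedigree file
#'
#' Plain-text whitespace/tab-separated pedigree with a header and columns
#' `animal`, `sire`, `dam`, `sex` (and optionally `selfself`, logical). `0`
#' or `NA` in sire/dam means unknown (founder). Rows flagged `selfself` mark
#' self-self hybridizations (the reference sample run against itself); their
#' calls are false positives by construction.
#'
#' @param path pedigree path.
#' @return data.frame with `animal`, `sire`, `dam`, `sex`, `selfself`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("animal", "sire", "dam", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"selfself" %in% names(df)) df$selfself <- FALSE
  df$selfself <- as.logical(df$selfself)
  for (col in c("sire", "dam")) {
    df[[col]][df[[col]] %in% c("0", "NA", ".")] <- NA_character_
  }
  df
}

#' Write a pedigree file
#' @param ped pedigree data.frame (see [read_pedigree()]).
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  for (col in c("sire", "dam")) out[[col]][is.na(out[[col]])] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
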