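#' Genome layout
#'
#' Describes the coordinate universe the pipeline works in: chromosome
#' lengths, which chromosomes are autosomes, which one is X, and (optionally)
#' a virtual "unknown" chromosome assembled from unplaced scaffolds that are
#' concatenated with 100-bp N spacers between consecutive scaffolds.
#'
#' All coordinates in this package are 0-based half-open; an interval
#' `[start, stop)` has length `stop - start`.
#'
#' @param lengths named numeric vector, chromosome name -> length in bp.
#' @param autosomes character vector of autosome names (subset of
#'   `names(lengths)`).
#' @param x_chrom name of the X chromosome, or `NA` if none.
#' @param chrun_scaffolds optional data.frame with columns `start`, `stop`
#'   giving scaffold intervals on the virtual unknown chromosome (0-based
#'   half-open, disjoint, ordered, separated by exactly 100 bp), or `NULL`.
#' @param chrun_name name of the virtual unknown chromosome (must be in
#'   `lengths` when scaffolds are supplied).
#'
#' @return an object of class `GenomeLayout`.
#' @examples
#' layout <- genome_layout(c(chr1 = 1e6, chr2 = 5e5, chrX = 3e5),
#'                         autosomes = c("chr1", "chr2"), x_chrom = "chrX")
#' @export
genome_layout <- function(lengths, autosomes = names(lengths),
                          x_chrom = NA_character_,
                          chrun_scaffolds = NULL, chrun_name = "chrUn") {
  if (is.null(names(lengths)) || anyNA(names(lengths)) ||
      any(names(lengths) == "")) {
    stop("'lengths' must be a fully named vector")
  }
  if (anyDuplicated(names(lengths))) stop("duplicated chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!all(autosomes %in% names(lengths))) {
    stop("autosomes must be a subset of names(lengths)")
  }
  if (!is.na(x_chrom) && !x_chrom %in% names(lengths)) {
    stop("x_chrom not present in lengths")
  }
  if (!is.null(chrun_scaffolds)) {
    sc <- chrun_scaffolds
    stopifnot(is.data.frame(sc), all(c("start", "stop") %in% names(sc)))
    if (nrow(sc) > 0) {
      if (!chrun_name %in% names(lengths)) {
        stop("chrun_name must appear in lengths when scaffolds are given")
      }
      o <- order(sc$start)
      sc <- sc[o, , drop = FALSE]
      if (any(sc$stop <= sc$start)) stop("scaffold intervals must be valid")
      if (nrow(sc) > 1) {
        gaps <- sc$start[-1] - sc$stop[-nrow(sc)]
        if (any(gaps != 100)) {
          stop("scaffolds on the virtual chromosome must be separated by ",
               "exactly 100 bp of N spacer")
        }
      }
      if (max(sc$stop) > lengths[[chrun_name]]) {
        stop("scaffolds exceed the stated virtual-chromosome length")
      }
      chrun_scaffolds <- sc
    }
  }
  structure(
    list(lengths = lengths,
         autosomes = autosomes,
         x_chrom = x_chrom,
         chrun_name = if (is.null(chrun_scaffolds)) NA_character_ else chrun_name,
         chrun_scaffolds = chrun_scaffolds),
    class = "GenomeLayout"
  )
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$lengths), "chromosomes,",
      length(x$autosomes), "autosomes",
      if (!is.na(x$x_chrom)) paste0("(X = ", x$x_chrom, ")") else "", "\n")
  cat("  total length:", format(sum(x$lengths), big.mark = ","), "bp\n")
  if (!is.null(x$chrun_scaffolds)) {
    cat("  virtual unknown chromosome:", x$chrun_name, "with",
        nrow(x$chrun_scaffolds), "scaffolds\n")
  }
  invisible(x)
}

#' Total autosome length of a layout
#' @param layout a `GenomeLayout`.
#' @return total autosomal length in bp.
#' @export
autosome_length <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(layout$lengths[layout$autosomes])
}

#' Build a virtual unknown chromosome from scaffold lengths
#'
#' Concatenates scaffolds in the given order with 100-bp N spacers, returning
#' the scaffold interval table and the total virtual-chromosome length.
#'
#' @param scaffold_lengths numeric vector of scaffold lengths (bp).
#' @return list with `scaffolds` (data.frame start/stop, 0-based half-open)
#'   and `length` (virtual chromosome length).
#' @export
chrun_from_scaffolds <- function(scaffold_lengths) {
  stopifnot(all(scaffold_lengths > 0))
  n <- length(scaffold_lengths)
  starts <- cumsum(c(0, head(scaffold_lengths, -1) + 100))
  stops <- starts + scaffold_lengths
  list(scaffolds = data.frame(start = starts, stop = stops),
       length = if (n > 0) stops[n] else 0)
}

#' Probe positions on the virtual unknown chromosome
#'
#' Probes are laid down per scaffold at a fixed average spacing (default one
#' probe per 1,600 bp, the chrUn design density); no probes fall in the N
#' spacers.
#'
#' @param layout a `GenomeLayout` with chrUn scaffolds.
#' @param spacing probe spacing in bp.
#' @return data.frame with columns `scaffold` (index) and `pos` (0-based).
#' @export
chrun_probe_positions <- function(layout, spacing = 1600) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sc <- layout$chrun_scaffolds
  if (is.null(sc)) stop("layout has no virtual unknown chromosome")
  out <- lapply(seq_len(nrow(sc)), function(i) {
    pos <- seq(sc$start[i] + spacing / 2, sc$stop[i] - 1, by = spacing)
    if (length(pos) == 0) return(NULL)
    data.frame(scaffold = i, pos = floor(pos))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
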