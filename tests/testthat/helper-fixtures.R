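# Shared fixture builders: everything is generated in code, no stored data.

toy_layout <- function(n_chrom = 2, chrom_len = 1e6) {
  lens <- stats::setNames(rep(chrom_len, n_chrom),
                          paste0("chr", seq_len(n_chrom)))
  genome_layout(lens)
}

# One-call builder with sensible defaults; probe indices derived from count.
make_call <- function(animal = "A1", chrom = "chr1", start = 10000,
                      length = 5000, l2r = -0.6, datapoints = 4,
                      first_probe = 10) {
  segment_calls(animal = animal, chrom = chrom, start = start,
                stop = start + length, first_probe = first_probe,
                last_probe = first_probe + datapoints - 1, l2r = l2r,
                datapoints = datapoints)
}

# Random valid calls for property-style tests; probe indices built
# consistently with the datapoint count (segment_calls() validates this).
random_calls <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dp <- sample(2:40, n, replace = TRUE)
  fp <- sample.int(1000, n, replace = TRUE)
  start <- sample.int(1e6, n, replace = TRUE)
  len <- sample(1000:200000, n, replace = TRUE)
  segment_calls(animal = sample(paste0("A", 1:5), n, replace = TRUE),
                chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                start = start, stop = start + len,
                first_probe = fp, last_probe = fp + dp - 1,
                l2r = round(stats::runif(n, -2, 2), 3),
                datapoints = dp)
}

# Small truth world reused by several suites.
small_truth <- function(seed = 42, n_cnvr = 30, n_trios = 5,
                        chrom_len = 3e6, n_chrom = 2) {
  simulate_truth(toy_layout(n_chrom, chrom_len), n_cnvr = n_cnvr,
                 n_trios = n_trios, seed = seed)
}
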