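# independent oracles and small shared fixtures

# O(n*m) half-open interval overlap: does any interval hit each window?
brute_force_overlap <- function(windows, intervals) {
  vapply(seq_len(nrow(windows)), function(i) {
    any(intervals$chrom == windows$chrom[i] &
          intervals$start < windows$end[i] &
          windows$start[i] < intervals$end)
  }, logical(1))
}

# upper-tail hypergeometric by direct summation
hyper_tail_oracle <- function(k, m, N, n) {
  kk <- k:min(m, n)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}

# textbook Benjamini-Hochberg, written independently of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# accuracy of both labels against generator truth
label_accuracy <- function(cells, truth, foci_threshold = 5) {
  m <- match_truth(cells, truth)
  mean((m$cap_positive == (m$true_phenotype == "cap_positive")) &
         (m$nucleoplasmic_fbl_positive == (m$true_n_foci >= foci_threshold)),
       na.rm = TRUE)
}

# small zero-noise field reused across imaging tests
small_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_field(10, mixture = c(0.4, 0.3, 0.3), noise = 0,
                               seed = 41)
    }
    cache
  }
})
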