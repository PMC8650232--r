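# Shared fixtures, built once per test run.

# default synthetic study (in memory, no files)
get_default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 1))
    cache
  }
})

# a tiny two-isoform gene for hand checks: exons in 0-based half-open coords
chain <- function(...) {
  m <- matrix(c(...), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# exhaustive hypergeometric upper tail by enumeration of all draws
enum_hyper_upper <- function(k, K, n, N) {
  universe <- seq_len(N)
  white <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% white, nrow = n))
  mean(hits >= k)
}
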