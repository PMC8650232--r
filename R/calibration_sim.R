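#' Simulate a plain NB count matrix for calibration studies
#'
#' Draws a genes x samples negative-binomial matrix with a common baseline
#' mean, an optional planted log2 fold change in the treatment group for the
#' first `n_de` genes (signs alternating), and equal library sizes. Used to
#' study type-I error and power of the differential-expression stage in
#' isolation.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group.
#' @param mean_count Baseline mean.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param log2fc Absolute planted log2 fold change.
#' @param n_de Number of genes carrying the planted fold change (default 0).
#' @param seed RNG seed.
#' @return List with `counts` (matrix), `groups`, `truth` (data frame:
#'   gene_id, is_de, true_log2fc).
#' @export
simulate_count_matrix <- function(n_genes, n_per_group = 3L,
                                  mean_count = 500, dispersion = 0.1,
                                  log2fc = 1.5, n_de = 0L, seed = 1L) {
  set.seed(seed)
  samples <- c(paste0("Ctrl_", seq_len(n_per_group)),
               paste0("Treat_", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("ctrl", "treat"), each = n_per_group),
                            samples)
  gids <- sprintf("g%05d", seq_len(n_genes))
  lfc <- rep(0, n_genes)
  if (n_de > 0L)
    lfc[seq_len(n_de)] <- rep(c(log2fc, -log2fc), length.out = n_de)
  mu <- matrix(mean_count, n_genes, 2 * n_per_group)
  mu[, groups == "treat"] <- mu[, groups == "treat"] * 2^lfc
  draw <- if (dispersion <= 0)
    stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  counts <- matrix(draw, n_genes, 2 * n_per_group,
                   dimnames = list(gids, samples))
  list(counts = counts, groups = groups,
       truth = data.frame(gene_id = gids, is_de = lfc != 0,
                          true_log2fc = lfc, stringsAsFactors = FALSE))
}

#' Simulate junction-ratio events for calibration studies
#'
#' Per event and sample, a Poisson read total is split between alternative
#' and model reads by a binomial draw at the group ratio; the first `n_ds`
#' events carry a planted ratio shift `delta` in the treatment group (signs
#' alternating). Used to study type-I error and power of the splicing-ratio
#' test in isolation.
#'
#' @param n_events Number of events.
#' @param n_per_group Replicates per group.
#' @param depth Expected reads per event per sample.
#' @param base_ratio Control-group ratio.
#' @param delta Absolute planted treatment shift.
#' @param n_ds Number of events carrying the shift (default 0).
#' @param seed RNG seed.
#' @return List with `alt`, `model` (event x sample count matrices),
#'   `groups`, `truth` (event_id, is_ds, true_delta).
#' @export
simulate_ratio_events <- function(n_events, n_per_group = 3L, depth = 100,
                                  base_ratio = 0.5, delta = 0.3,
                                  n_ds = 0L, seed = 1L) {
  set.seed(seed)
  samples <- c(paste0("Ctrl_", seq_len(n_per_group)),
               paste0("Treat_", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("ctrl", "treat"), each = n_per_group),
                            samples)
  eids <- sprintf("e%05d", seq_len(n_events))
  d <- rep(0, n_events)
  if (n_ds > 0L)
    d[seq_len(n_ds)] <- rep(c(delta, -delta), length.out = n_ds)
  if (any(base_ratio + d > 1 | base_ratio + d < 0))
    stop("delta pushes ratios outside [0, 1]")
  ns <- 2L * n_per_group
  alt <- model <- matrix(0L, n_events, ns, dimnames = list(eids, samples))
  for (i in seq_len(n_events)) {
    r <- ifelse(groups == "treat", base_ratio + d[i], base_ratio)
    tot <- stats::rpois(ns, depth)
    a <- stats::rbinom(ns, tot, r)
    alt[i, ] <- a
    model[i, ] <- tot - a
  }
  list(alt = alt, model = model, groups = groups,
       truth = data.frame(event_id = eids, is_ds = d != 0, true_delta = d,
                          stringsAsFactors = FALSE))
}
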