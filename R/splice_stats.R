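#' Per-sample alternative-splicing ratio
#'
#' The splicing ratio of an event in one sample is
#' `alt / (alt + model)` — alternative junction reads over the sum of
#' alternative and model junction reads. Ratios supported by fewer than
#' `min_total` reads are undefined (`NA`): at low coverage the ratio is
#' dominated by sampling noise.
#'
#' @param alt,model Non-negative read counts (vectorised).
#' @param min_total Minimum `alt + model` for a defined ratio (default 10).
#' @return Numeric ratio in `[0, 1]`, or `NA` below the coverage filter.
#' @export
compute_ratio <- function(alt, model, min_total = 10) {
  if (any(alt < 0, na.rm = TRUE) || any(model < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  total <- alt + model
  ifelse(total >= min_total, alt / total, NA_real_)
}

#' Ratio matrix for quantified events
#'
#' @param quant Output of [quantify_events()] (list of `alt`/`model` count
#'   matrices).
#' @inheritParams compute_ratio
#' @return Numeric matrix events x samples of ratios (`NA` where undefined).
#' @export
ratio_matrix <- function(quant, min_total = 10) {
  r <- compute_ratio(quant$alt, quant$model, min_total)
  dimnames(r) <- dimnames(quant$alt)
  r
}

#' Two-sample pooled-variance Student's t-test on splicing ratios
#'
#' @param x,y Numeric vectors of defined ratios for the two groups (`NA`s
#'   dropped). Both groups need at least two defined values.
#' @return List with `t`, `p` (two-sided, `n1 + n2 - 2` df), `df`, and a
#'   `reason` code (`"ok"`, `"insufficient"`, or `"zero_variance"` when both
#'   groups are constant at different means, where `p` is the smallest
#'   positive double).
#' @export
test_event <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                reason = "insufficient"))
  df <- n1 + n2 - 2L
  md <- mean(y) - mean(x)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = df, reason = "ok"))
    return(list(t = sign(md) * Inf, p = .Machine$double.xmin, df = df,
                reason = "zero_variance"))
  }
  t <- md / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, reason = "ok")
}

#' Test every event for a splicing-ratio difference between groups
#'
#' Applies [test_event()] per event (treatment minus control), with
#' Benjamini-Hochberg adjustment across all tested events.
#'
#' @param ratios Ratio matrix from [ratio_matrix()].
#' @param groups Named character vector (`"ctrl"`/`"treat"`) over samples.
#' @param events Optional event table to carry gene_id/type columns along.
#' @return Data frame per event: event_id, (gene_id, type,) mean_ctrl,
#'   mean_treat, delta, t, p, q, n_ctrl, n_treat, reason.
#' @export
test_splicing <- function(ratios, groups, events = NULL) {
  stopifnot(all(colnames(ratios) %in% names(groups)))
  g <- groups[colnames(ratios)]
  res <- lapply(seq_len(nrow(ratios)), function(i) {
    x <- ratios[i, g == "ctrl"]; y <- ratios[i, g == "treat"]
    tt <- test_event(x, y)
    data.frame(event_id = rownames(ratios)[i],
               mean_ctrl = mean(x, na.rm = TRUE),
               mean_treat = mean(y, na.rm = TRUE),
               delta = mean(y, na.rm = TRUE) - mean(x, na.rm = TRUE),
               t = tt$t, p = tt$p,
               n_ctrl = sum(!is.na(x)), n_treat = sum(!is.na(y)),
               reason = tt$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  if (!is.null(events)) {
    m <- match(out$event_id, events$event_id)
    out <- cbind(out[, "event_id", drop = FALSE],
                 events[m, c("gene_id", "type")],
                 out[, setdiff(names(out), "event_id")])
  }
  rownames(out) <- NULL
  out
}

#' Call regulated splicing events (RASEs) and genes (RASGs)
#'
#' Default selection uses raw `p < alpha`; `use_fdr = TRUE` selects on the
#' Benjamini-Hochberg `q` instead. Both conventions are in circulation for
#' junction-ratio tests, so both are exposed. The summary partitions selected
#' events into intron-retention and non-IR classes.
#'
#' @param res Result of [test_splicing()] (must carry gene_id/type).
#' @param alpha Significance cutoff (default 0.05).
#' @param use_fdr Select on BH `q` rather than raw `p` (default `FALSE`).
#' @return List with `rases` (the input with a `selected` flag), `rasg`
#'   (character vector of genes with >= 1 selected event) and `summary`
#'   (data frame of selected-event counts per type plus an IR/non-IR split).
#' @export
call_rases <- function(res, alpha = 0.05, use_fdr = FALSE) {
  if (nrow(res) == 0L)
    return(list(rases = res, rasg = character(0),
                summary = data.frame(type = character(0), n = integer(0))))
  crit <- if (use_fdr) res$q else res$p
  res$selected <- !is.na(crit) & crit < alpha
  sel <- res[res$selected, , drop = FALSE]
  tab <- table(factor(sel$type, levels = as_event_types()))
  summary <- data.frame(type = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  summary <- rbind(summary,
                   data.frame(type = c("IR_total", "non_IR_total"),
                              n = c(sum(sel$type == "IR"),
                                    sum(sel$type != "IR"))))
  list(rases = res, rasg = sort(unique(sel$gene_id)), summary = summary)
}
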