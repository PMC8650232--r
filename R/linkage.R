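#' Pearson correlation between a splicing-ratio and an expression vector
#'
#' Sample Pearson r with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Vectors
#' must be fully defined; a zero-variance vector yields `NA` (the edge is
#' skipped upstream with a reason).
#'
#' @param ratio,expr Equal-length numeric vectors, length >= 3, no `NA`.
#' @return List with `r`, `p`, `n`.
#' @export
correlate <- function(ratio, expr) {
  if (length(ratio) != length(expr)) stop("length mismatch")
  n <- length(ratio)
  if (n < 3L) stop("need at least 3 samples")
  if (anyNA(ratio) || anyNA(expr)) stop("undefined entries not allowed")
  if (stats::sd(ratio) == 0 || stats::sd(expr) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(ratio, expr)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Build the TF-splicing to target-expression correlation network
#'
#' Candidate pairs are (selected TF splicing event, differentially expressed
#' target) where the target's promoter carries at least one hit of any of
#' that TF's motifs. An edge is kept when the Pearson correlation between the
#' event's per-sample splicing ratios and the target's per-sample expression
#' passes `|r| >= r_cut` and `p <= p_cut` (set `absolute = FALSE` to require
#' `r >= r_cut` instead). Events with an undefined ratio in any sample are
#' skipped. Edge order is deterministic.
#'
#' @param rases RASE table (output `rases` of [call_rases()]; only rows with
#'   `selected` are used).
#' @param degs DEG table from [call_degs()]; targets are genes with direction
#'   `up` or `down`.
#' @param tf_map Data frame (tf_gene, motif_id) from [match_tfs()].
#' @param hits Promoter hit table from [scan_promoters()].
#' @param ratios Event x sample ratio matrix ([ratio_matrix()]).
#' @param expr Gene x sample expression matrix (e.g. FPKM).
#' @param r_cut,p_cut Edge thresholds (defaults 0.95, 0.005).
#' @param absolute Use `|r|` (default `TRUE`).
#' @return Data frame of edges: tf_gene, event_id, target_gene, direction,
#'   r, p, n_samples; attribute `n_candidates` counts candidate pairs.
#' @export
build_network <- function(rases, degs, tf_map, hits, ratios, expr,
                          r_cut = 0.95, p_cut = 0.005, absolute = TRUE) {
  sel <- rases[isTRUE_vec(rases$selected), , drop = FALSE]
  targets <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  empty <- data.frame(tf_gene = character(0), event_id = character(0),
                      target_gene = character(0), direction = character(0),
                      r = numeric(0), p = numeric(0), n_samples = integer(0))
  tf_events <- sel[sel$gene_id %in% tf_map$tf_gene, , drop = FALSE]
  if (nrow(tf_events) == 0L || nrow(targets) == 0L) {
    warning("no candidate TF-target pairs")
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  rows <- list()
  n_cand <- 0L
  for (ei in order(tf_events$event_id)) {
    ev <- tf_events[ei, ]
    motifs <- tf_map$motif_id[tf_map$tf_gene == ev$gene_id]
    with_hit <- unique(hits$gene_id[hits$motif_id %in% motifs])
    cand <- targets[targets$gene_id %in% with_hit &
                      targets$gene_id != ev$gene_id, , drop = FALSE]
    if (nrow(cand) == 0L) next
    rv <- ratios[ev$event_id, ]
    if (anyNA(rv)) next
    for (ti in order(cand$gene_id)) {
      tg <- cand[ti, ]
      n_cand <- n_cand + 1L
      xv <- expr[tg$gene_id, names(rv)]
      cc <- correlate(as.numeric(rv), as.numeric(xv))
      if (is.na(cc$r)) next
      keep <- if (absolute) abs(cc$r) >= r_cut else cc$r >= r_cut
      if (keep && cc$p <= p_cut)
        rows[[length(rows) + 1L]] <- data.frame(
          tf_gene = ev$gene_id, event_id = ev$event_id,
          target_gene = tg$gene_id, direction = tg$direction,
          r = cc$r, p = cc$p, n_samples = cc$n, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  out <- out[order(out$tf_gene, out$event_id, out$target_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- n_cand
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Export the network for Cytoscape
#'
#' Writes a SIF edge list and/or a GraphML file with node attributes
#' (`role` = TF/target, `direction`) and edge attributes (`r`, `p`).
#'
#' @param edges Edge table from [build_network()].
#' @param sif,graphml Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(edges, sif = NULL, graphml = NULL) {
  if (!is.null(sif)) {
    lines <- sprintf("%s\tsplicing_regulates\t%s",
                     edges$tf_gene, edges$target_gene)
    writeLines(unique(lines), sif)
  }
  if (!is.null(graphml)) {
    nodes <- data.frame(
      name = c(unique(edges$tf_gene), unique(edges$target_gene)),
      role = c(rep("TF", length(unique(edges$tf_gene))),
               rep("target", length(unique(edges$target_gene)))),
      stringsAsFactors = FALSE)
    nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
    dirs <- edges$direction[match(nodes$name, edges$target_gene)]
    nodes$direction <- ifelse(is.na(dirs), "", dirs)
    g <- igraph::graph_from_data_frame(
      edges[, c("tf_gene", "target_gene", "r", "p")],
      directed = TRUE, vertices = nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(c(sif = sif, graphml = graphml))
}
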