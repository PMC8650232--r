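#' Junction table I/O
#'
#' The junction table holds one row per splice junction (0-based half-open
#' intron coordinates) with columns chrom, start, end, strand and one count
#' column per sample, in the spirit of aligner `SJ.out.tab` output.
#'
#' @param junctions Junction data frame.
#' @param path TSV path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_junctions <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions
#' @export
read_junctions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# matrix <-> TSV with an explicit id column
write_tsv_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a gene count matrix / gene length table
#' @param path TSV path (`gene_id` first column).
#' @return Integer matrix (counts) or named vector (lengths).
#' @export
read_gene_counts <- function(path) read_tsv_matrix(path)

#' @rdname read_gene_counts
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$length, df$gene_id)
}

#' Pipeline configuration
#'
#' Collects the file paths, sample grouping and stage thresholds for
#' [run_pipeline()]. Every referenced path must exist at run start; exactly
#' two groups with at least two samples each are required.
#'
#' @param gtf,promoters,junctions,gene_counts,gene_lengths,pfms Input paths.
#' @param groups Named character vector sample -> `"ctrl"`/`"treat"`.
#' @param out_dir Output directory.
#' @param min_total Ratio coverage filter (default 10).
#' @param alpha RASE significance cutoff (default 0.05).
#' @param use_fdr Select RASEs on BH q instead of raw p (default `FALSE`).
#' @param fc_cut,fdr_cut DEG thresholds (defaults 2, 0.05).
#' @param enrich_p Motif enrichment cutoff (default 0.01).
#' @param windows TSS window half-widths in bp (default 1, 2, 3 kb).
#' @param threshold_frac PWM score-range threshold (default 0.8).
#' @param promoter_len Promoter length in bp (default 6000).
#' @param r_cut,p_cut Network edge thresholds (defaults 0.95, 0.005).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gtf, promoters, junctions, gene_counts,
                            gene_lengths, pfms, groups, out_dir,
                            min_total = 10, alpha = 0.05, use_fdr = FALSE,
                            fc_cut = 2, fdr_cut = 0.05, enrich_p = 0.01,
                            windows = c(1000, 2000, 3000),
                            threshold_frac = 0.8, promoter_len = 6000L,
                            r_cut = 0.95, p_cut = 0.005) {
  paths <- c(gtf = gtf, promoters = promoters, junctions = junctions,
             gene_counts = gene_counts, gene_lengths = gene_lengths,
             pfms = pfms)
  missing_p <- paths[!file.exists(paths)]
  if (length(missing_p) > 0L)
    stop("missing input file(s): ",
         paste(names(missing_p), "=", missing_p, collapse = ", "))
  tab <- table(groups)
  if (length(tab) != 2L || any(tab < 2L))
    stop("exactly two groups with >= 2 samples each are required")
  structure(list(paths = as.list(paths), groups = groups, out_dir = out_dir,
                 min_total = min_total, alpha = alpha, use_fdr = use_fdr,
                 fc_cut = fc_cut, fdr_cut = fdr_cut, enrich_p = enrich_p,
                 windows = windows, threshold_frac = threshold_frac,
                 promoter_len = as.integer(promoter_len),
                 r_cut = r_cut, p_cut = p_cut),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages on files: read gene models and counts, enumerate and
#' quantify splicing events, test splicing ratios and call RASEs/RASGs, run
#' the differential-expression stage, scan promoters and test motif
#' enrichment in down-regulated DEG promoters, match enriched motifs to
#' splicing-regulated TFs, compute the motif-overlap significance, and build
#' the TF-to-target correlation network. Writes every stage's table plus a
#' plain-text run report into `out_dir`. Deterministic: no randomness is
#' consumed.
#'
#' @param config A [pipeline_config()].
#' @return List with all stage results (`events`, `quant`, `ratios`,
#'   `splice_res`, `rases`, `de`, `hits`, `enrichment`, `tf_map`, `overlap`,
#'   `edges`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$paths
  models <- read_gtf(p$gtf)
  junctions <- read_junctions(p$junctions)
  counts <- read_gene_counts(p$gene_counts)
  lengths <- read_gene_lengths(p$gene_lengths)
  promoters <- Biostrings::readDNAStringSet(p$promoters)
  names(promoters) <- sub("\\s.*$", "", names(promoters))
  pfms <- read_jaspar(p$pfms)
  groups <- config$groups

  events <- enumerate_events(models)
  quant <- quantify_events(events, junctions)
  ratios <- ratio_matrix(quant, min_total = config$min_total)
  splice_res <- test_splicing(ratios, groups, events)
  rases <- call_rases(splice_res, alpha = config$alpha,
                      use_fdr = config$use_fdr)
  de <- de_table(counts, lengths, groups, fc_cut = config$fc_cut,
                 fdr_cut = config$fdr_cut)

  hits <- scan_promoters(promoters, pfms,
                         threshold_frac = config$threshold_frac)
  down <- de$degs$gene_id[de$degs$direction == "down"]
  enrichment <- if (length(down) > 0L)
    motif_enrich(hits, down, rownames(counts),
                 motif_ids = names(pfms),
                 promoter_len = config$promoter_len,
                 windows = config$windows, p_cut = config$enrich_p)
  else list(records = NULL, consistent = character(0))
  tf_map <- match_tfs(rases$rasg, pfms)
  overlap <- overlap_test(unique(tf_map$motif_id), enrichment$consistent,
                          universe_size = length(pfms))
  edges <- build_network(rases$rases, de$degs, tf_map, hits, ratios,
                         de$fpkm, r_cut = config$r_cut,
                         p_cut = config$p_cut)

  o <- function(f) file.path(config$out_dir, f)
  write_events(events, o("events.tsv"))
  utils::write.table(splice_res, o("splice_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rases$rases, o("rases.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rases$summary, o("rase_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de$degs, o("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_matrix(round(de$fpkm, 4), o("fpkm.tsv"))
  utils::write.table(hits, o("motif_hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(enrichment$records))
    utils::write.table(enrichment$records, o("motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tf_map, o("tf_motif_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges, o("network_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(edges) > 0L)
    write_network(edges, sif = o("network.sif"),
                  graphml = o("network.graphml"))

  report <- c(
    sprintf("splicelink run report"),
    sprintf("genes: %d, events: %d (complex excluded: %d)",
            nrow(counts), nrow(events), attr(events, "n_complex")),
    sprintf("RASEs selected: %d in %d RASGs (IR %d / non-IR %d)",
            sum(rases$rases$selected), length(rases$rasg),
            rases$summary$n[rases$summary$type == "IR_total"],
            rases$summary$n[rases$summary$type == "non_IR_total"]),
    sprintf("DEGs: %d up / %d down of %d genes",
            sum(de$degs$direction == "up"),
            sum(de$degs$direction == "down"), nrow(de$degs)),
    sprintf("motif hits: %d; consistently enriched motifs: %d",
            nrow(hits), length(enrichment$consistent)),
    sprintf("matched TFs: %d; motif overlap %d (p = %.3g)",
            length(unique(tf_map$tf_gene)), overlap$overlap, overlap$p),
    sprintf("network edges: %d (candidates %d)", nrow(edges),
            attr(edges, "n_candidates")))
  writeLines(report, o("report.txt"))

  list(events = events, quant = quant, ratios = ratios,
       splice_res = splice_res, rases = rases, de = de, hits = hits,
       enrichment = enrichment, tf_map = tf_map, overlap = overlap,
       edges = edges, report = report)
}
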