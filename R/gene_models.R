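#' Gene models: genes with strand, TSS and one or more isoforms
#'
#' A `gene_models` object is the substrate for alternative-splicing event
#' enumeration. It is a named list of genes; each gene holds its chromosome,
#' strand, transcription start site and a named list of isoforms, each isoform
#' an ordered two-column integer matrix of exon intervals. All internal
#' coordinates are 0-based half-open; conversion to/from the 1-based inclusive
#' GTF convention happens only in [read_gtf()] and [write_gtf()].
#'
#' @name gene_models
NULL

new_gene_model <- function(gene_id, chrom, strand, isoforms) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"), is.list(isoforms), length(isoforms) >= 1L)
  isoforms <- lapply(isoforms, validate_exon_chain, gene_id = gene_id)
  span <- c(min(vapply(isoforms, function(e) e[1L, 1L], numeric(1))),
            max(vapply(isoforms, function(e) e[nrow(e), 2L], numeric(1))))
  tss <- if (strand == "+") span[1L] else span[2L]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = tss, span = span, isoforms = isoforms),
            class = "gene_model")
}

# exon chain: ordered, strictly non-overlapping [start, end) intervals
validate_exon_chain <- function(exons, gene_id = "?") {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L)
    stop("empty exon chain in gene ", gene_id)
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon with end <= start in gene ", gene_id)
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
      stop("overlapping exons in an isoform of gene ", gene_id)
  }
  exons
}

gene_models <- function(genes) {
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  n_iso <- sum(vapply(x, function(g) length(g$isoforms), integer(1)))
  cat(sprintf("gene_models: %d genes, %d isoforms on %d sequence(s)\n",
              length(x), n_iso,
              length(unique(vapply(x, `[[`, character(1), "chrom")))))
  invisible(x)
}

# introns of an exon chain as a (start, end) matrix, 0-based half-open
chain_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(matrix(numeric(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

junction_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Read gene models from a GTF file
#'
#' Parses gene/transcript/exon features, groups exons into transcripts and
#' transcripts into genes, and converts the 1-based inclusive GTF coordinates
#' to the package's internal 0-based half-open convention.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon features and an explicit strand.
#' @return A `gene_models` object.
#' @export
read_gtf <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(gene_models(list()))
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) return(gene_models(list()))
  tid <- as.character(ex$transcript_id)
  gid <- as.character(ex$gene_id)
  if (anyNA(tid)) stop("exon feature without transcript_id in ", path)
  if (anyNA(gid)) stop("exon feature without gene_id in ", path)
  strand <- as.character(GenomicRanges::strand(ex))
  if (any(strand == "*")) stop("exon feature without strand in ", path)
  # GTF 1-based inclusive -> 0-based half-open
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex),
                   strand = strand, gene_id = gid, transcript_id = tid,
                   stringsAsFactors = FALSE)
  genes <- lapply(split(df, df$gene_id), function(d) {
    isoforms <- lapply(split(d, d$transcript_id), function(t)
      as.matrix(t[order(t$start), c("start", "end")]))
    new_gene_model(d$gene_id[1L], d$chrom[1L], d$strand[1L], isoforms)
  })
  gene_models(genes[order(names(genes))])
}

#' Write gene models to a GTF file
#'
#' Emits one `transcript` and per-exon `exon` features per isoform with
#' `gene_id`/`transcript_id` attributes, converting internal 0-based
#' half-open coordinates to GTF's 1-based inclusive convention.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- list()
  for (g in models) {
    for (tx in names(g$isoforms)) {
      e <- g$isoforms[[tx]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = c(min(e[, 1L]), e[, 1L]) + 1L,
        end = c(max(e[, 2L]), e[, 2L]),
        strand = g$strand,
        type = c("transcript", rep("exon", nrow(e))),
        gene_id = g$gene_id, transcript_id = tx, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "splicelink"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
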