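#' Read a JASPAR-style PFM text file
#'
#' Parses records of the form `>motif_id tf_name` followed by four count rows
#' in A, C, G, T order. Rows may be bare numbers or the JASPAR
#' `A [ 1 2 3 ]` layout.
#'
#' @param path Path to the PFM text file.
#' @return A `pfm_set`: named list of `pfm` objects (fields `motif_id`,
#'   `tf_name`, `counts` = 4 x L matrix with rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no PFM records in ", path)
  pfms <- lapply(seq_along(heads), function(i) {
    h <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1L]]
    motif_id <- h[1L]
    tf_name <- if (length(h) >= 2L) h[2L] else motif_id
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[(heads[i] + 1L):to]
    if (length(body) < 4L) stop("PFM ", motif_id, ": expected 4 count rows")
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^\\s*[ACGTacgt][:|]?", "", l)
      as.numeric(regmatches(l, gregexpr(
        "-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", l))[[1L]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L) stop("PFM ", motif_id, ": ragged count rows")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(colSums(m) == 0)) stop("PFM ", motif_id, ": all-zero column")
    structure(list(motif_id = motif_id, tf_name = tf_name, counts = m),
              class = "pfm")
  })
  names(pfms) <- vapply(pfms, `[[`, character(1), "motif_id")
  structure(pfms, class = "pfm_set")
}

#' Write a PFM collection in JASPAR text format
#'
#' @param pfms A `pfm_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$tf_name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Position weight matrix (log2 odds) from a PFM
#'
#' Column counts are converted to probabilities with a pseudocount
#' distributed by the background composition, then to log2 odds against that
#' background.
#'
#' @param pfm A `pfm` object.
#' @param pseudocount Total pseudocount per column (default 0.8).
#' @param background Base composition (A, C, G, T); default uniform.
#' @return 4 x L numeric log2-odds matrix.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  m <- pfm$counts
  names(background) <- c("A", "C", "G", "T")
  n <- colSums(m)
  pr <- sweep(m + pseudocount * background, 2L, n + pseudocount, "/")
  log2(pr / background)
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports windows scoring at least `min_score + threshold_frac * (max_score -
#' min_score)` (the conventional percentage-of-range PWM cutoff). Windows
#' containing non-ACGT characters are skipped. Minus-strand hits are scored on
#' the reverse complement and reported by their offset on the given strand.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @param pfm A `pfm` object.
#' @param threshold_frac Fraction of the score range (default 0.8), in (0, 1].
#' @inheritParams pfm_to_pwm
#' @return Data frame: offset (0-based), strand, score.
#' @export
scan_pwm <- function(sequence, pfm, threshold_frac = 0.8, pseudocount = 0.8,
                     background = rep(0.25, 4)) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  s <- toupper(as.character(sequence))
  pwm <- pfm_to_pwm(pfm, pseudocount, background)
  L <- ncol(pwm)
  n <- nchar(s)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  thr <- sum(apply(pwm, 2L, min)) +
    threshold_frac * (sum(apply(pwm, 2L, max)) - sum(apply(pwm, 2L, min)))
  code <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  npos <- n - L + 1L
  # score matrix lookup: rows = motif positions, columns = window offsets
  idx <- outer(seq_len(L) - 1L, seq_len(npos), "+")
  base <- matrix(code[idx], nrow = L)
  score_with <- function(w) {
    sc <- matrix(w[cbind(as.vector(base), rep(seq_len(L), npos))],
                 nrow = L)
    colSums(sc)
  }
  fw <- score_with(pwm)
  rc <- pwm[4:1, L:1, drop = FALSE]       # reverse complement of the PWM
  rv <- score_with(rc)
  bad <- colSums(is.na(base)) > 0L
  fw[bad] <- -Inf; rv[bad] <- -Inf
  hit_f <- which(fw >= thr); hit_r <- which(rv >= thr)
  out <- rbind(
    if (length(hit_f)) data.frame(offset = hit_f - 1L, strand = "+",
                                  score = fw[hit_f]) else empty,
    if (length(hit_r)) data.frame(offset = hit_r - 1L, strand = "-",
                                  score = rv[hit_r]) else empty)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a promoter set with a PFM collection
#'
#' @param promoters Named [Biostrings::DNAStringSet] (or character vector),
#'   one promoter per gene.
#' @param pfms A `pfm_set`.
#' @inheritParams scan_pwm
#' @return Data frame: motif_id, gene_id, offset, strand, score.
#' @export
scan_promoters <- function(promoters, pfms, threshold_frac = 0.8,
                           pseudocount = 0.8, background = rep(0.25, 4)) {
  seqs <- as.character(promoters)
  rows <- list()
  for (p in pfms) {
    for (g in names(seqs)) {
      h <- scan_pwm(seqs[[g]], p, threshold_frac, pseudocount, background)
      if (nrow(h) > 0L)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(motif_id = p$motif_id, gene_id = g,
                     stringsAsFactors = FALSE), h)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif_id = character(0), gene_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif over-representation in target promoters over multi-scale TSS windows
#'
#' For each motif and window half-width, a gene "has" the motif if it carries
#' at least one hit within that window around the TSS (promoters are taken as
#' TSS-centred, so a window of half-width `w` covers promoter positions
#' `centre - w` to `centre + w`). Over-representation in the target set versus
#' the background universe is scored by the upper-tail hypergeometric test.
#' The consistent set comprises motifs enriched in every window.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param target_genes,background_genes Character vectors,
#'   `target_genes` a subset of `background_genes` (the universe).
#' @param motif_ids Motifs to assess (default: all in `hits`).
#' @param promoter_len Promoter length in bp (TSS at `promoter_len/2`).
#' @param windows Window half-widths in bp (default 1, 2, 3 kb).
#' @param motif_len Motif length used to define hit spans (default from hit
#'   offsets; only needed for boundary bookkeeping).
#' @param p_cut Enrichment cutoff (default 0.01).
#' @return List with `records` (motif_id, window, n_target_hit,
#'   n_background_hit, p, enriched) and `consistent` (motifs enriched in all
#'   windows).
#' @export
motif_enrich <- function(hits, target_genes, background_genes, motif_ids,
                         promoter_len, windows = c(1000, 2000, 3000),
                         motif_len = 10L, p_cut = 0.01) {
  if (length(target_genes) == 0L) stop("target gene set is empty")
  if (!all(target_genes %in% background_genes))
    stop("targets must be a subset of the background universe")
  if (missing(motif_ids)) motif_ids <- sort(unique(hits$motif_id))
  centre <- promoter_len / 2
  N <- length(background_genes)
  n <- length(target_genes)
  rows <- list()
  for (m in motif_ids) {
    hm <- hits[hits$motif_id == m & hits$gene_id %in% background_genes, ,
               drop = FALSE]
    for (w in windows) {
      inw <- hm[hm$offset + motif_len > centre - w &
                  hm$offset < centre + w, , drop = FALSE]
      with_hit <- unique(inw$gene_id)
      K <- length(with_hit)
      k <- sum(target_genes %in% with_hit)
      p <- if (K == 0L) 1 else
        stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = m, window = w, n_target_hit = k, n_background_hit = K,
        p = p, enriched = p < p_cut, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  bym <- split(records$enriched, records$motif_id)
  consistent <- sort(names(bym)[vapply(bym, all, logical(1))])
  list(records = records, consistent = consistent)
}

#' Match splicing-regulated genes to transcription factors with known motifs
#'
#' Case-insensitive match of PFM TF names against a gene list; a TF with
#' several PFMs contributes all of them.
#'
#' @param rasg_genes Character vector of regulated-splicing gene symbols.
#' @param pfms A `pfm_set`.
#' @return Data frame (tf_gene, motif_id); zero rows when nothing matches.
#' @export
match_tfs <- function(rasg_genes, pfms) {
  rows <- list()
  for (p in pfms) {
    i <- match(tolower(p$tf_name), tolower(rasg_genes))
    if (!is.na(i))
      rows[[length(rows) + 1L]] <- data.frame(
        tf_gene = rasg_genes[i], motif_id = p$motif_id,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(tf_gene = character(0), motif_id = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$tf_gene, out$motif_id), , drop = FALSE]
}

#' Hypergeometric overlap significance of two motif sets
#'
#' Tests whether the overlap between the motifs of splicing-regulated TFs and
#' the promoter-enriched motifs exceeds chance, drawing from a universe of
#' `universe_size` motifs. The default is the standard inclusive upper tail
#' `P(X >= k)`; `inclusive = FALSE` gives the strictly-greater tail
#' `P(X > k)`, a convention some published analyses use.
#'
#' @param tf_motifs,enriched_motifs Character vectors (sets).
#' @param universe_size Size of the motif universe; both sets must fit in it.
#' @param inclusive Include the observed overlap in the tail (default `TRUE`).
#' @return List with `overlap` (count) and `p`.
#' @export
overlap_test <- function(tf_motifs, enriched_motifs, universe_size,
                         inclusive = TRUE) {
  tf_motifs <- unique(tf_motifs); enriched_motifs <- unique(enriched_motifs)
  K <- length(enriched_motifs); n <- length(tf_motifs)
  if (K > universe_size || n > universe_size)
    stop("set larger than the universe")
  k <- length(intersect(tf_motifs, enriched_motifs))
  q <- if (inclusive) k - 1L else k
  list(overlap = k,
       p = stats::phyper(q, K, universe_size - K, n, lower.tail = FALSE))
}
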