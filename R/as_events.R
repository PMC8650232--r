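#' The ten alternative-splicing event types
#'
#' Event labels used throughout the package. Skipping events are partitioned
#' by skipped-exon count: `ES` skips exactly one internal exon, `CassetteExon`
#' skips two or more consecutive internal exons with a single junction.
#' `A5SS`/`A3SS` are alternative donor/acceptor sites in transcript
#' orientation; `A5SS&ES`/`A3SS&ES` are single alternative junctions that
#' simultaneously shift a splice site and skip at least one exon. `MXE` is a
#' pair of internal mutually exclusive exons; `5pMXE`/`3pMXE` are mutually
#' exclusive first/last (terminal) exons. `IR` is intron retention, whose
#' alternative evidence is the pair of exon-intron boundary intervals.
#'
#' @return Character vector of the ten labels.
#' @export
as_event_types <- function() {
  c("ES", "A5SS", "A3SS", "IR", "MXE", "5pMXE", "3pMXE",
    "CassetteExon", "A3SS&ES", "A5SS&ES")
}

# Classify one isoform pair. Returns list(type, alt_side) where alt_side
# indicates which chain is structurally "alternative" (the skipping chain for
# (Cassette)ES and combined types, the retaining chain for IR) or NA for the
# symmetric types, where model/alternative is assigned by transcript order.
classify_chain_pair <- function(a, b, strand) {
  a <- validate_exon_chain(a); b <- validate_exon_chain(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == nb && all(a == b)) return(list(type = "no-event", alt_side = NA))
  row_eq <- function(x, i, y, j) all(x[i, ] == y[j, ])
  f <- 0L
  while (f < na && f < nb && row_eq(a, f + 1L, b, f + 1L)) f <- f + 1L
  r <- 0L
  while (r < na - f && r < nb - f && row_eq(a, na - r, b, nb - r)) r <- r + 1L
  ra <- if (na - r >= f + 1L) a[(f + 1L):(na - r), , drop = FALSE] else
    a[0L, , drop = FALSE]
  rb <- if (nb - r >= f + 1L) b[(f + 1L):(nb - r), , drop = FALSE] else
    b[0L, , drop = FALSE]
  lf <- f >= 1L; rf <- r >= 1L
  # orient so chain "x" has at least as many differing exons as chain "y"
  swapped <- nrow(ra) < nrow(rb)
  x <- if (swapped) rb else ra
  y <- if (swapped) ra else rb
  mx <- nrow(x); my <- nrow(y)
  side <- function(which_x) {
    # map "x"/"y" back to input chain 1/2
    if (which_x) (if (swapped) 2L else 1L) else (if (swapped) 1L else 2L)
  }
  donor_right <- if (strand == "+") "A5SS" else "A3SS"
  acceptor_left <- if (strand == "+") "A3SS" else "A5SS"
  cx <- function(type, alt_side = NA) list(type = type, alt_side = alt_side)

  if (my == 0L) {
    if (!lf || !rf) return(cx("complex"))
    type <- if (mx == 1L) "ES" else "CassetteExon"
    return(cx(type, side(FALSE)))           # the exon-less chain skips
  }
  if (mx == 1L && my == 1L) {
    overlap <- x[1L, 1L] < y[1L, 2L] && y[1L, 1L] < x[1L, 2L]
    if (overlap) {
      if (x[1L, 1L] == y[1L, 1L] && x[1L, 2L] != y[1L, 2L])
        return(if (rf) cx(donor_right) else cx("complex"))
      if (x[1L, 2L] == y[1L, 2L] && x[1L, 1L] != y[1L, 1L])
        return(if (lf) cx(acceptor_left) else cx("complex"))
      return(cx("complex"))
    }
    if (lf && rf) return(cx("MXE"))
    if (!lf && rf)
      return(cx(if (strand == "+") "5pMXE" else "3pMXE"))
    if (lf && !rf)
      return(cx(if (strand == "+") "3pMXE" else "5pMXE"))
    return(cx("complex"))
  }
  if (mx >= 2L && my == 1L) {
    if (y[1L, 1L] == x[1L, 1L] && y[1L, 2L] == x[mx, 2L]) {
      if (mx == 2L) return(cx("IR", side(FALSE)))  # retaining chain is alt
      return(cx("complex"))
    }
    if (y[1L, 1L] == x[1L, 1L] && y[1L, 2L] != x[1L, 2L] &&
        y[1L, 2L] < x[2L, 1L] && rf) {
      type <- if (strand == "+") "A5SS&ES" else "A3SS&ES"
      return(cx(type, side(FALSE)))
    }
    if (y[1L, 2L] == x[mx, 2L] && y[1L, 1L] != x[mx, 1L] &&
        y[1L, 1L] > x[mx - 1L, 2L] && lf) {
      type <- if (strand == "+") "A3SS&ES" else "A5SS&ES"
      return(cx(type, side(FALSE)))
    }
    return(cx("complex"))
  }
  cx("complex")
}

#' Classify the structural difference between two isoforms
#'
#' Compares two exon chains of one gene and returns the event-type label of
#' their structural difference: one of the ten types (see [as_event_types()]),
#' `"complex"` for differences not matching any rule, or `"no-event"` for
#' identical chains. The result is symmetric in argument order and
#' strand-aware (donor/acceptor assignment follows transcript orientation).
#'
#' @param iso_a,iso_b Two-column matrices of ordered exon `[start, end)`
#'   intervals (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return A single type label.
#' @export
classify_pair <- function(iso_a, iso_b, strand = "+") {
  classify_chain_pair(iso_a, iso_b, strand)$type
}

# Junction sets of a classified pair: unique introns of the alternative chain
# vs unique introns of the model chain; IR substitutes the boundary intervals
# of the retained intron as the alternative evidence.
event_junction_sets <- function(a, b, cls) {
  ja <- chain_introns(a); jb <- chain_introns(b)
  ka <- paste(ja[, 1L], ja[, 2L]); kb <- paste(jb[, 1L], jb[, 2L])
  ua <- ja[!(ka %in% kb), , drop = FALSE]
  ub <- jb[!(kb %in% ka), , drop = FALSE]
  alt_is_b <- if (!is.na(cls$alt_side)) cls$alt_side == 2L else TRUE
  alt <- if (alt_is_b) ub else ua
  model <- if (alt_is_b) ua else ub
  if (cls$type == "IR" && nrow(alt) == 0L && nrow(model) == 1L) {
    alt <- rbind(c(model[1L, 1L] - 1, model[1L, 1L] + 1),
                 c(model[1L, 2L] - 1, model[1L, 2L] + 1))
    colnames(alt) <- c("start", "end")
  }
  list(alt = alt, model = model)
}

#' Enumerate alternative-splicing events from gene models
#'
#' Compares every isoform pair of each gene, classifies the structural
#' difference (see [classify_pair()]) and emits one event per distinct
#' (gene, alternative junction set, model junction set) with a deterministic
#' sort order. Events classified `"complex"` are excluded and counted in the
#' `n_complex` attribute.
#'
#' @param models A `gene_models` object.
#' @return Data frame with columns event_id, gene_id, chrom, strand, type,
#'   alt_junctions, model_junctions (comma-joined `chrom:start-end:strand`
#'   keys), region_start, region_end. Attribute `n_complex` counts excluded
#'   pairs.
#' @export
enumerate_events <- function(models) {
  rows <- list()
  n_complex <- 0L
  for (g in models) {
    iso <- g$isoforms
    if (length(iso) < 2L) next
    pairs <- utils::combn(length(iso), 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      cls <- classify_chain_pair(iso[[i]], iso[[j]], g$strand)
      if (cls$type == "no-event") next
      if (cls$type == "complex") { n_complex <- n_complex + 1L; next }
      sets <- event_junction_sets(iso[[i]], iso[[j]], cls)
      alt_k <- junction_key(g$chrom, sets$alt[, 1L], sets$alt[, 2L], g$strand)
      mod_k <- junction_key(g$chrom, sets$model[, 1L], sets$model[, 2L],
                            g$strand)
      span <- range(c(sets$alt, sets$model))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        type = cls$type,
        alt_junctions = paste(sort(alt_k), collapse = ","),
        model_junctions = paste(sort(mod_k), collapse = ","),
        region_start = span[1L], region_end = span[2L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(event_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      type = character(0), alt_junctions = character(0),
                      model_junctions = character(0),
                      region_start = numeric(0), region_end = numeric(0))
    attr(out, "n_complex") <- n_complex
    return(out)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[!duplicated(ev[, c("gene_id", "alt_junctions",
                              "model_junctions")]), , drop = FALSE]
  ev <- ev[order(ev$chrom, ev$region_start, ev$region_end, ev$type), ,
           drop = FALSE]
  ev <- cbind(event_id = sprintf("%s|%s|%d-%d", ev$gene_id, ev$type,
                                 as.integer(ev$region_start),
                                 as.integer(ev$region_end)),
              ev, stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  attr(ev, "n_complex") <- n_complex
  ev
}

parse_junction_keys <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, ",", fixed = TRUE)[[1L]]
}

#' Quantify events against a junction count table
#'
#' Sums per-sample read counts over each event's alternative and model
#' junction sets. Junctions absent from the table count as zero.
#'
#' @param events Event table from [enumerate_events()].
#' @param junctions Junction count data frame (chrom, start, end, strand, one
#'   column per sample; 0-based half-open intron coordinates).
#' @return List of two integer matrices `alt` and `model`
#'   (events x samples, rownames = event_id).
#' @export
quantify_events <- function(events, junctions) {
  samples <- setdiff(colnames(junctions), c("chrom", "start", "end", "strand"))
  keys <- junction_key(junctions$chrom, junctions$start, junctions$end,
                       junctions$strand)
  cm <- as.matrix(junctions[, samples, drop = FALSE])
  rownames(cm) <- keys
  sum_keys <- function(ks) {
    hit <- ks[ks %in% keys]
    if (length(hit) == 0L) return(rep(0, length(samples)))
    colSums(cm[hit, , drop = FALSE])
  }
  alt <- t(vapply(events$alt_junctions,
                  function(s) sum_keys(parse_junction_keys(s)),
                  numeric(length(samples))))
  model <- t(vapply(events$model_junctions,
                    function(s) sum_keys(parse_junction_keys(s)),
                    numeric(length(samples))))
  dimnames(alt) <- dimnames(model) <- list(events$event_id, samples)
  list(alt = alt, model = model)
}

#' Quantify a single event
#'
#' @param event One-row event table (see [enumerate_events()]).
#' @param junctions Junction count data frame.
#' @return List with per-sample `alt_reads` and `model_reads` vectors.
#' @export
quantify_event <- function(event, junctions) {
  q <- quantify_events(event[1L, , drop = FALSE], junctions)
  list(event_id = event$event_id[1L], alt_reads = q$alt[1L, ],
       model_reads = q$model[1L, ])
}

#' Write / read the event table
#' @param events Event table.
#' @param path TSV path.
#' @return `path` invisibly (write); the event table (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(alt_junctions = "character",
                                   model_junctions = "character",
                                   region_start = "numeric",
                                   region_end = "numeric"))
}
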