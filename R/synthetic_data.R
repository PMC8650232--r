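#' Configuration for the synthetic two-condition splicing/expression study
#'
#' Builds the parameter set for the synthetic-data generator. The defaults
#' emulate a 2-condition x 3-replicate bulk RNA-seq junction/gene-count
#' experiment: ten alternative-splicing event types planted cyclically across
#' genes, negative-binomial gene counts with planted differential expression,
#' binomially split junction reads with planted splicing-ratio shifts,
#' promoters with planted transcription-factor motifs, and one designated TF
#' whose realised splicing ratio linearly drives the expression of a set of
#' repressed target genes (the planted regulatory network).
#'
#' @param n_genes Number of genes (default 80).
#' @param isoform_scheme Character vector, one entry per gene, each one of the
#'   ten event-type labels or `"constitutive"`. Default cycles through all ten
#'   types plus constitutive genes.
#' @param n_replicates Replicates per condition (default 3).
#' @param mean_depth Expected junction reads per event per sample
#'   (default 300, typical of well-covered junctions in bulk RNA-seq; at this
#'   depth the realised group ratios are tight enough that planted ratio
#'   shifts propagate faithfully into the driven-target fold changes).
#' @param nb_dispersion Negative-binomial dispersion of gene counts
#'   (default 0.1); 0 gives Poisson counts.
#' @param mean_count Mean expression level (expected counts) around which
#'   per-gene baselines are drawn (default 500).
#' @param de_fraction Fraction of genes with planted differential expression
#'   (default 0.25).
#' @param de_log2fc Absolute planted log2 fold change for non-network DE genes
#'   (default 1.5).
#' @param ds_fraction Fraction of event-bearing genes with a planted splicing
#'   ratio shift (default 0.3).
#' @param ds_delta Absolute planted shift of the alternative-splicing ratio in
#'   the treatment group (default 0.3); signs alternate across events.
#' @param base_ratio Baseline alternative/(alternative+model) ratio
#'   (default 0.5).
#' @param promoter_len Promoter length in bp, conceptually centred on the TSS
#'   so that symmetric windows up to `promoter_len/2` can be cut (default 6000).
#' @param motif_plant_rate Probability that a target-gene promoter receives a
#'   planted motif instance (default 0.8).
#' @param n_tf_motifs Number of splicing-regulated genes designated as TFs
#'   with their own PFM (default 5).
#' @param n_decoy_motifs Number of decoy PFMs whose TF names match no gene
#'   (default 10).
#' @param motif_len Length of generated PFMs (default 14).
#' @param motif_consensus_weight Probability mass on the consensus base per
#'   PFM column (default 0.97, a high-information-content motif; at the
#'   conventional 80%-of-range scan threshold this admits two mismatches over
#'   14 columns, giving ~99% recovery of sampled instances and a background
#'   hit rate of ~3e-6 per position and strand).
#' @param n_linked_targets Number of down-regulated targets whose expression is
#'   linearly driven by the designated TF's realised splicing ratio
#'   (default 10).
#' @param link_dispersion NB dispersion of the driven targets (default 1e-3,
#'   near-Poisson: tightly coupled regulation).
#' @param libsize_cv Log-normal coefficient of variation of per-sample library
#'   size factors (default 0.1).
#' @param seed Master seed; every stage derives its own stream from it by a
#'   fixed offset, so outputs are byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 80L,
                       isoform_scheme = NULL,
                       n_replicates = 3L,
                       mean_depth = 300,
                       nb_dispersion = 0.1,
                       mean_count = 500,
                       de_fraction = 0.25,
                       de_log2fc = 1.5,
                       ds_fraction = 0.3,
                       ds_delta = 0.3,
                       base_ratio = 0.5,
                       promoter_len = 6000L,
                       motif_plant_rate = 0.8,
                       n_tf_motifs = 5L,
                       n_decoy_motifs = 10L,
                       motif_len = 14L,
                       motif_consensus_weight = 0.97,
                       n_linked_targets = 10L,
                       link_dispersion = 1e-3,
                       libsize_cv = 0.1,
                       seed = 1L) {
  if (is.null(isoform_scheme)) {
    isoform_scheme <- rep(c(as_event_types(), "constitutive"),
                          length.out = n_genes)
  }
  unknown <- setdiff(isoform_scheme, c(as_event_types(), "constitutive"))
  if (length(unknown) > 0L)
    stop("isoform_scheme names unknown event type(s): ",
         paste(unknown, collapse = ", "))
  if (length(isoform_scheme) != n_genes)
    stop("isoform_scheme must have one entry per gene")
  fracs <- c(de_fraction = de_fraction, ds_fraction = ds_fraction,
             motif_plant_rate = motif_plant_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (base_ratio + abs(ds_delta) > 1 || base_ratio - abs(ds_delta) < 0)
    stop("ds_delta would push planted ratios outside [0, 1]")
  if (nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (n_replicates < 2L) stop("need >= 2 replicates per group")
  structure(
    list(n_genes = as.integer(n_genes), isoform_scheme = isoform_scheme,
         n_replicates = as.integer(n_replicates), mean_depth = mean_depth,
         nb_dispersion = nb_dispersion, mean_count = mean_count,
         de_fraction = de_fraction, de_log2fc = de_log2fc,
         ds_fraction = ds_fraction, ds_delta = ds_delta,
         base_ratio = base_ratio, promoter_len = as.integer(promoter_len),
         motif_plant_rate = motif_plant_rate,
         n_tf_motifs = as.integer(n_tf_motifs),
         n_decoy_motifs = as.integer(n_decoy_motifs),
         motif_len = as.integer(motif_len),
         motif_consensus_weight = motif_consensus_weight,
         n_linked_targets = as.integer(n_linked_targets),
         link_dispersion = link_dispersion, libsize_cv = libsize_cv,
         seed = as.integer(seed)),
    class = "sim_config")
}

sample_names <- function(config) {
  n <- config$n_replicates
  c(paste0("Ctrl_", seq_len(n)), paste0("Treat_", seq_len(n)))
}

sample_groups <- function(config) {
  n <- config$n_replicates
  stats::setNames(rep(c("ctrl", "treat"), each = n), sample_names(config))
}

# Per-stage RNG streams derived from the master seed by fixed offsets, so
# e.g. adding genes does not perturb motif planting.
stage_seed <- function(config, stage) {
  offs <- c(models = 101L, counts = 202L, pfms = 303L, motifs = 404L)
  set.seed((config$seed + offs[[stage]]) %% .Machine$integer.max)
}

# ---- gene model construction ------------------------------------------------

# Build the two isoform exon chains of one event type in gene-local,
# plus-orientation coordinates. t1 is the model isoform, t2 the alternative.
build_event_chains <- function(type) {
  # exon lengths 120-200, introns 150-300, splice-site shifts 30-60
  el <- function() round(stats::runif(1, 120, 200))
  il <- function() round(stats::runif(1, 150, 300))
  sh <- function() round(stats::runif(1, 30, 60))
  lay <- function(lens, gaps) {
    # alternate exon/gap lengths into [start,end) rows
    s <- cumsum(c(0, utils::head(as.vector(rbind(lens, c(gaps, 0))), -1)))
    starts <- s[seq(1, length(s), by = 2)]
    cbind(start = starts, end = starts + lens)
  }
  switch(type,
    constitutive = {
      e <- lay(c(el(), el(), el()), c(il(), il()))
      list(t1 = e)
    },
    ES = {
      e <- lay(c(el(), el(), el()), c(il(), il()))
      list(t1 = e, t2 = e[c(1L, 3L), , drop = FALSE])
    },
    CassetteExon = {
      e <- lay(c(el(), el(), el(), el()), c(il(), il(), il()))
      list(t1 = e, t2 = e[c(1L, 4L), , drop = FALSE])
    },
    IR = {
      e <- lay(c(el(), el()), il())
      list(t1 = e, t2 = cbind(start = e[1L, 1L], end = e[2L, 2L]))
    },
    A5SS = {
      e <- lay(c(el(), el()), il())
      a <- e; a[1L, 2L] <- a[1L, 2L] + sh()
      list(t1 = e, t2 = a)
    },
    A3SS = {
      e <- lay(c(el(), el()), il())
      a <- e; a[2L, 1L] <- a[2L, 1L] - sh()
      list(t1 = e, t2 = a)
    },
    MXE = {
      lens <- c(el(), el(), el(), el())
      gaps <- c(il(), il(), il())
      e <- lay(lens, gaps)
      list(t1 = e[c(1L, 2L, 4L), , drop = FALSE],
           t2 = e[c(1L, 3L, 4L), , drop = FALSE])
    },
    `5pMXE` = {
      e <- lay(c(el(), el(), el(), el()), c(il(), il(), il()))
      list(t1 = e[c(1L, 3L, 4L), , drop = FALSE],
           t2 = e[c(2L, 3L, 4L), , drop = FALSE])
    },
    `3pMXE` = {
      e <- lay(c(el(), el(), el(), el()), c(il(), il(), il()))
      list(t1 = e[c(1L, 2L, 3L), , drop = FALSE],
           t2 = e[c(1L, 2L, 4L), , drop = FALSE])
    },
    `A5SS&ES` = {
      e <- lay(c(el(), el(), el()), c(il(), il()))
      a <- e[c(1L, 3L), , drop = FALSE]
      a[1L, 2L] <- a[1L, 2L] - sh()   # shifted donor + skipped exon
      list(t1 = e, t2 = a)
    },
    `A3SS&ES` = {
      e <- lay(c(el(), el(), el()), c(il(), il()))
      a <- e[c(1L, 3L), , drop = FALSE]
      a[2L, 1L] <- a[2L, 1L] + sh()   # shifted acceptor + skipped exon
      list(t1 = e, t2 = a)
    },
    stop("unknown event type: ", type))
}

# Mirror local plus-orientation chains into minus-strand genomic layout.
mirror_chains <- function(chains, span_len) {
  lapply(chains, function(e) {
    m <- cbind(start = span_len - e[, 2L], end = span_len - e[, 1L])
    m[order(m[, 1L]), , drop = FALSE]
  })
}

#' Generate synthetic gene models and a genome sequence
#'
#' Lays out non-overlapping genes along one synthetic chromosome. Each gene
#' assigned an event type receives two isoforms whose exon structures differ by
#' exactly that event; constitutive genes receive one isoform. Strands
#' alternate; minus-strand genes are built by mirroring the plus-orientation
#' layout so every event type occurs on both strands.
#'
#' @param config A [sim_config()] object.
#' @return A list with `models` (a `gene_models` object), `genome` (a
#'   [Biostrings::DNAStringSet] of the synthetic chromosome) and `gene_info`
#'   (data frame of gene_id, planted type, strand).
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, "models")
  n <- config$n_genes
  genes <- vector("list", n)
  info <- vector("list", n)
  cursor <- 1000
  chrom <- "chrS"
  for (i in seq_len(n)) {
    type <- config$isoform_scheme[[i]]
    gid <- sprintf("G%03d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    chains <- build_event_chains(type)
    span_len <- max(vapply(chains, function(e) e[nrow(e), 2L], numeric(1)))
    if (strand == "-") chains <- mirror_chains(chains, span_len)
    chains <- lapply(chains, function(e) e + cursor)
    names(chains) <- paste0(gid, ".t", seq_along(chains))
    genes[[i]] <- new_gene_model(gid, chrom, strand, chains)
    info[[i]] <- data.frame(gene_id = gid, type = type, strand = strand,
                            stringsAsFactors = FALSE)
    cursor <- cursor + span_len + 500
  }
  genome_len <- cursor + 1000
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), genome_len, replace = TRUE), collapse = ""))
  names(genome) <- chrom
  list(models = gene_models(genes), genome = genome,
       gene_info = do.call(rbind, info))
}

# Planted alternative/model junction sets of a two-isoform gene, by the
# pipeline-wide convention: model = first isoform, alternative = second;
# intron retention contributes exon-intron boundary intervals (both
# boundaries) as its alternative evidence.
planted_junction_sets <- function(gene) {
  j1 <- chain_introns(gene$isoforms[[1L]])
  j2 <- chain_introns(gene$isoforms[[2L]])
  k1 <- junction_key(gene$chrom, j1[, 1L], j1[, 2L], gene$strand)
  k2 <- junction_key(gene$chrom, j2[, 1L], j2[, 2L], gene$strand)
  model <- j1[!(k1 %in% k2), , drop = FALSE]
  alt <- j2[!(k2 %in% k1), , drop = FALSE]
  shared <- j1[k1 %in% k2, , drop = FALSE]
  if (nrow(alt) == 0L && nrow(model) == 1L) {
    # retained intron: alternative evidence = the two boundary intervals
    alt <- rbind(c(model[1L, 1L] - 1, model[1L, 1L] + 1),
                 c(model[1L, 2L] - 1, model[1L, 2L] + 1))
    colnames(alt) <- c("start", "end")
  }
  list(alt = alt, model = model, shared = shared)
}

#' Simulate junction and gene count tables with planted truth
#'
#' Junction counts: per event and sample, a Poisson total split between the
#' alternative and model junction sets by a binomial draw at the planted group
#' ratio (reads are then distributed multinomially across the junctions of a
#' set); intron-retention events emit exon-intron boundary-read counts as
#' their alternative evidence. Gene counts: negative binomial with per-gene
#' log-normal baselines, per-sample library-size factors and planted log2 fold
#' changes; the designated TF's realised splicing ratio linearly drives the
#' planted network targets. Deterministic under a fixed seed.
#'
#' @param sim Output of [generate_gene_models()].
#' @param config The same [sim_config()].
#' @return A list with `junctions` (data frame: chrom, start, end, strand, one
#'   count column per sample; 0-based half-open intron coordinates),
#'   `gene_counts` (integer matrix genes x samples), `gene_lengths` (named bp
#'   vector, exonic length of the longest isoform), `groups` (named group
#'   labels) and `truth` (list of `genes`, `events` data frames).
#' @export
simulate_counts <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, "counts")
  models <- sim$models
  info <- sim$gene_info
  samples <- sample_names(config)
  groups <- sample_groups(config)
  ns <- length(samples)

  event_genes <- info$gene_id[info$type != "constitutive"]
  n_ds <- round(config$ds_fraction * length(event_genes))
  ds_genes <- if (n_ds > 0L) sort(event_genes)[seq_len(n_ds)] else character(0)
  tf_genes <- utils::head(ds_genes, config$n_tf_motifs)
  link_tf <- if (length(tf_genes) > 0L) tf_genes[[1L]] else NA_character_

  # --- junction counts -------------------------------------------------------
  jrows <- list()
  ev <- list()
  add_row <- function(start, end, gene, counts) {
    jrows[[length(jrows) + 1L]] <<- data.frame(
      chrom = gene$chrom, start = start, end = end, strand = gene$strand,
      t(counts), stringsAsFactors = FALSE)
  }
  ds_sign <- 1
  realised_ratio <- list()
  for (gid in info$gene_id) {
    gene <- models[[gid]]
    type <- info$type[info$gene_id == gid]
    if (type == "constitutive") {
      for (k in seq_len(nrow(chain_introns(gene$isoforms[[1L]])))) {
        j <- chain_introns(gene$isoforms[[1L]])[k, ]
        add_row(j[1L], j[2L], gene, stats::rpois(ns, config$mean_depth))
      }
      next
    }
    sets <- planted_junction_sets(gene)
    is_ds <- gid %in% ds_genes
    delta <- if (is_ds) { ds_sign <- -ds_sign; -ds_sign * config$ds_delta } else 0
    r_ctrl <- config$base_ratio
    r_treat <- config$base_ratio + delta
    ratio_s <- ifelse(groups == "treat", r_treat, r_ctrl)
    total <- stats::rpois(ns, config$mean_depth)
    alt_tot <- stats::rbinom(ns, total, ratio_s)
    model_tot <- total - alt_tot
    split_counts <- function(tot, m) {
      # multinomial split of a set total across its m junctions
      out <- matrix(0L, nrow = m, ncol = ns)
      for (s in seq_len(ns)) if (tot[s] > 0L)
        out[, s] <- stats::rmultinom(1L, tot[s], rep(1 / m, m))[, 1L]
      out
    }
    am <- split_counts(alt_tot, nrow(sets$alt))
    mm <- split_counts(model_tot, nrow(sets$model))
    for (k in seq_len(nrow(sets$alt)))
      add_row(sets$alt[k, 1L], sets$alt[k, 2L], gene, am[k, ])
    for (k in seq_len(nrow(sets$model)))
      add_row(sets$model[k, 1L], sets$model[k, 2L], gene, mm[k, ])
    if (nrow(sets$shared) > 0L)
      for (k in seq_len(nrow(sets$shared)))
        add_row(sets$shared[k, 1L], sets$shared[k, 2L], gene,
                stats::rpois(ns, config$mean_depth))
    obs_ratio <- ifelse(total > 0L, alt_tot / total, NA_real_)
    realised_ratio[[gid]] <- obs_ratio
    ev[[gid]] <- data.frame(gene_id = gid, type = type, is_ds = is_ds,
                            ratio_ctrl = r_ctrl, ratio_treat = r_treat,
                            stringsAsFactors = FALSE)
  }
  junctions <- do.call(rbind, jrows)
  names(junctions)[-(1:4)] <- samples
  rownames(junctions) <- NULL

  # --- gene counts -----------------------------------------------------------
  n <- config$n_genes
  gids <- info$gene_id
  # moderate baseline spread: with a small synthetic gene set, heavy-tailed
  # baselines would let single genes dominate library totals and destabilise
  # per-sample FPKM normalisation
  base <- stats::rlnorm(n, meanlog = log(config$mean_count), sdlog = 0.5)
  names(base) <- gids
  libfac <- stats::rlnorm(ns, meanlog = 0, sdlog = config$libsize_cv)

  non_tf <- setdiff(gids, tf_genes)
  n_de <- round(config$de_fraction * n)
  de_genes <- utils::head(sort(non_tf), n_de)
  linked <- utils::head(de_genes, min(config$n_linked_targets, length(de_genes)))
  rest <- setdiff(de_genes, linked)
  lfc <- stats::setNames(rep(0, n), gids)
  if (length(rest) > 0L)
    lfc[rest] <- rep(c(-config$de_log2fc, config$de_log2fc),
                     length.out = length(rest))

  tf_ratio <- if (!is.na(link_tf)) realised_ratio[[link_tf]] else NULL
  counts <- matrix(0L, nrow = n, ncol = ns, dimnames = list(gids, samples))
  rnb <- function(mu, disp) {
    if (disp <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
  }
  for (i in seq_len(n)) {
    gid <- gids[i]
    if (gid %in% linked && !is.null(tf_ratio)) {
      # expression linearly repressed by the TF's realised splicing ratio;
      # driven targets sit at a high baseline (strongly expressed signalling
      # genes) so regulatory coupling dominates counting noise, and the
      # affine drive keeps both group levels well away from zero so the
      # planted fold change is insensitive to ratio jitter
      drive <- function(r) pmax(2.8 - 3 * r, 0.1)
      mu <- 4 * config$mean_count * drive(tf_ratio) * libfac
      counts[i, ] <- rnb(mu, config$link_dispersion)
      lfc[gid] <- log2(drive(ev[[link_tf]]$ratio_treat) /
                       drive(ev[[link_tf]]$ratio_ctrl))
    } else {
      fc <- ifelse(groups == "treat", 2^lfc[gid], 1)
      mu <- base[i] * libfac * fc
      counts[i, ] <- rnb(mu, config$nb_dispersion)
    }
  }
  gene_lengths <- vapply(models, function(g)
    max(vapply(g$isoforms, function(e) sum(e[, 2L] - e[, 1L]), numeric(1))),
    numeric(1))

  truth_genes <- data.frame(
    gene_id = gids,
    is_de = gids %in% de_genes,
    true_log2fc = as.numeric(lfc[gids]),
    is_linked_target = gids %in% linked,
    is_tf = gids %in% tf_genes,
    base_mean = as.numeric(base[gids]),
    stringsAsFactors = FALSE)
  truth_events <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(gene_id = character(0), type = character(0),
               is_ds = logical(0), ratio_ctrl = numeric(0),
               ratio_treat = numeric(0))
  rownames(truth_events) <- NULL

  list(junctions = junctions, gene_counts = counts,
       gene_lengths = gene_lengths, groups = groups,
       truth = list(genes = truth_genes, events = truth_events,
                    link_tf = link_tf, tf_genes = tf_genes,
                    ds_genes = ds_genes,
                    lib_factors = stats::setNames(libfac, samples)))
}

#' Generate a synthetic JASPAR-style PFM collection
#'
#' Produces one high-information-content position frequency matrix per
#' designated TF gene (the first `n_tf_motifs` splicing-regulated genes) plus
#' decoy motifs whose TF names match no gene. Each column puts
#' `motif_consensus_weight` of its mass on a consensus base.
#'
#' @param tf_genes Character vector of gene ids to name motifs after.
#' @param config A [sim_config()].
#' @return A `pfm_set` (see [read_jaspar()]).
#' @export
generate_pfms <- function(tf_genes, config) {
  stage_seed(config, "pfms")
  total <- 100L
  w <- config$motif_consensus_weight
  cons_n <- round(total * w)
  off_n <- round(total * (1 - w) / 3)
  make <- function(motif_id, tf_name) {
    cons <- sample(1:4, config$motif_len, replace = TRUE)
    m <- matrix(off_n, nrow = 4, ncol = config$motif_len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(config$motif_len)) m[cons[j], j] <- cons_n
    structure(list(motif_id = motif_id, tf_name = tf_name, counts = m),
              class = "pfm")
  }
  ids <- sprintf("M%03d", seq_len(length(tf_genes) + config$n_decoy_motifs))
  tf_names <- c(tf_genes, sprintf("TFD%02d", seq_len(config$n_decoy_motifs)))
  pfms <- Map(make, ids, tf_names)
  names(pfms) <- ids
  structure(pfms, class = "pfm_set")
}

#' Plant motif instances into synthetic promoter sequences
#'
#' Generates one i.i.d.-uniform background promoter per gene and inserts, with
#' probability `motif_plant_rate`, a consensus-sampled instance of an assigned
#' PFM into each target promoter at a recorded offset and strand. Planted
#' offsets fall within the central +/- 1 kb so instances lie inside every
#' symmetric TSS window. Network-target promoters always receive their
#' driving TF's motif.
#'
#' @param gene_ids All gene ids (one promoter each).
#' @param pfms A `pfm_set`.
#' @param plan Data frame of candidate plantings with columns `gene_id`,
#'   `motif_id` and logical `forced`: each row plants one instance with
#'   probability `motif_plant_rate` (probability 1 when `forced`). Several
#'   rows per promoter are allowed; instances are placed at non-overlapping
#'   offsets.
#' @param config A [sim_config()].
#' @return List with `promoters` (a [Biostrings::DNAStringSet], one entry per
#'   gene, TSS at the centre) and `truth` (data frame gene_id, motif_id,
#'   offset, strand of planted instances; offsets 0-based from promoter start).
#' @export
plant_motifs <- function(gene_ids, pfms, plan, config) {
  stage_seed(config, "motifs")
  L <- config$promoter_len
  if (any(vapply(pfms, function(p) ncol(p$counts), integer(1)) > L))
    stop("motif longer than promoter")
  if (is.null(plan$forced)) plan$forced <- FALSE
  seqs <- character(length(gene_ids))
  truth <- list()
  centre <- L %/% 2L
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[[i]]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    used <- matrix(numeric(0), ncol = 2L)
    rows <- which(plan$gene_id == gid)
    for (ri in rows) {
      if (!plan$forced[ri] && stats::runif(1) >= config$motif_plant_rate)
        next
      pfm <- pfms[[plan$motif_id[ri]]]
      ml <- ncol(pfm$counts)
      if (plan$forced[ri]) {
        # forced plantings (network targets) carry the canonical consensus,
        # a guaranteed high-affinity site
        inst <- rownames(pfm$counts)[apply(pfm$counts, 2L, which.max)]
      } else {
        # sample an instance column-wise from the PFM base frequencies
        inst <- vapply(seq_len(ml), function(j)
          sample(rownames(pfm$counts), 1L, prob = pfm$counts[, j]),
          character(1))
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        inst <- rev(chartr("ACGT", "TGCA", inst))
      lo <- max(0L, centre - 900L)
      hi <- min(L - ml, centre + 900L - ml)
      off <- NA_integer_
      for (try in 1:25) {
        cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        if (nrow(used) == 0L ||
            all(cand + ml <= used[, 1L] | cand >= used[, 2L])) {
          off <- cand
          break
        }
      }
      if (is.na(off)) next   # no free slot; skip this instance
      used <- rbind(used, c(off, off + ml))
      s[(off + 1L):(off + ml)] <- inst
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, motif_id = pfm$motif_id, offset = off,
        strand = strand, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  promoters <- Biostrings::DNAStringSet(seqs)
  names(promoters) <- gene_ids
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0), motif_id = character(0),
               offset = integer(0), strand = character(0))
  list(promoters = promoters, truth = truth)
}

#' Simulate a complete synthetic study and write its files
#'
#' Runs all generator stages (gene models, junction and gene counts, PFMs,
#' promoters with planted motifs) and, if `dir` is given, writes every
#' standard-format file the pipeline consumes: GTF gene models, genome and
#' promoter FASTA, junction and gene-count TSVs, a JASPAR-style PFM file and
#' the truth tables.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing), or `NULL` to skip writing.
#' @return A list with all in-memory pieces (`models`, `genome`, `junctions`,
#'   `gene_counts`, `gene_lengths`, `groups`, `pfms`, `promoters`, `truth`)
#'   and, when written, `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  gm <- generate_gene_models(config)
  cnt <- simulate_counts(gm, config)
  pfms <- generate_pfms(cnt$truth$tf_genes, config)

  # motif planting: each down-regulated target promoter is a candidate for
  # every TF motif; network targets always carry their driving TF's motif
  tg <- cnt$truth$genes
  down <- tg$gene_id[tg$is_de & tg$true_log2fc < 0]
  tf_motifs <- names(pfms)[vapply(pfms, function(p)
    p$tf_name %in% cnt$truth$tf_genes, logical(1))]
  link_motif <- names(pfms)[vapply(pfms, function(p)
    identical(p$tf_name, cnt$truth$link_tf), logical(1))]
  linked <- tg$gene_id[tg$is_linked_target]
  plan <- expand.grid(gene_id = down, motif_id = tf_motifs,
                      stringsAsFactors = FALSE)
  plan$forced <- plan$gene_id %in% linked &
    plan$motif_id %in% link_motif[1L]
  plan <- plan[order(plan$gene_id, plan$motif_id), , drop = FALSE]
  pm <- plant_motifs(tg$gene_id, pfms, plan, config)

  out <- list(config = config, models = gm$models, genome = gm$genome,
              gene_info = gm$gene_info, junctions = cnt$junctions,
              gene_counts = cnt$gene_counts, gene_lengths = cnt$gene_lengths,
              groups = cnt$groups, pfms = pfms, promoters = pm$promoters,
              truth = c(cnt$truth, list(motifs = pm$truth)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      gtf = file.path(dir, "models.gtf"),
      genome = file.path(dir, "genome.fa"),
      promoters = file.path(dir, "promoters.fa"),
      junctions = file.path(dir, "junctions.tsv"),
      gene_counts = file.path(dir, "gene_counts.tsv"),
      gene_lengths = file.path(dir, "gene_lengths.tsv"),
      pfms = file.path(dir, "motifs.pfm"),
      truth_genes = file.path(dir, "truth_genes.tsv"),
      truth_events = file.path(dir, "truth_events.tsv"),
      truth_motifs = file.path(dir, "truth_motifs.tsv"))
    write_gtf(gm$models, p$gtf)
    Biostrings::writeXStringSet(gm$genome, p$genome)
    Biostrings::writeXStringSet(pm$promoters, p$promoters)
    write_junctions(cnt$junctions, p$junctions)
    write_tsv_matrix(cnt$gene_counts, p$gene_counts, id_col = "gene_id")
    utils::write.table(
      data.frame(gene_id = names(cnt$gene_lengths),
                 length = as.integer(cnt$gene_lengths)),
      p$gene_lengths, sep = "\t", quote = FALSE, row.names = FALSE)
    write_jaspar(pfms, p$pfms)
    utils::write.table(out$truth$genes, p$truth_genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth$events, p$truth_events, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth$motifs, p$truth_motifs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- p
  }
  out
}
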