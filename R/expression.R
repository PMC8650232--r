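#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count / (length/1000 * total/1e6)`. `total` defaults to the
#' per-sample column sums of the matrix (the counted fragments), so the
#' statistic is invariant to overall sequencing depth.
#'
#' @param counts Integer matrix genes x samples (or a vector for one sample).
#' @param gene_lengths Positive effective lengths in bp, one per gene.
#' @param totals Per-sample total mapped fragments; default `colSums(counts)`.
#' @return Numeric matrix (or vector) of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths, totals = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("total mapped fragments must be positive")
  if (length(gene_lengths) != nrow(counts))
    stop("one length per gene required")
  sweep(counts / (gene_lengths / 1e3), 2L, totals / 1e6, "/")
}

#' Trimmed mean of M-values normalisation factors
#'
#' Library-composition scaling factors computed against a reference sample
#' (the column whose library size is closest to the mean library size). Per
#' sample, gene-wise log2 ratios (M) and average log2 abundances (A) versus
#' the reference are doubly trimmed (30% of M, 5% of A, from each tail) and
#' the factor is `2^` the precision-weighted mean of the surviving M values
#' (weights: inverse asymptotic binomial variances). Factors are normalised to
#' geometric mean 1.
#'
#' @param counts Integer matrix genes x samples, no all-zero column.
#' @param trim_m,trim_a Tail trim fractions for M and A (defaults 0.3, 0.05).
#' @return Named per-sample scaling factor vector.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  ref <- which.min(abs(lib - mean(lib)))
  yr <- counts[, ref]; nr <- lib[ref]
  one <- function(s) {
    if (s == ref) return(1)
    y <- counts[, s]; n <- lib[s]
    keep <- y > 0 & yr > 0
    if (!any(keep)) return(1)
    y <- y[keep]; yk <- yr[keep]
    m <- log2((y / n) / (yk / nr))
    a <- 0.5 * log2((y / n) * (yk / nr))
    w <- 1 / ((n - y) / (n * y) + (nr - yk) / (nr * yk))
    fin <- is.finite(m) & is.finite(a)
    m <- m[fin]; a <- a[fin]; w <- w[fin]
    ng <- length(m)
    if (ng == 0L) return(1)
    lo_m <- floor(ng * trim_m) + 1; hi_m <- ng + 1 - floor(ng * trim_m)
    lo_a <- floor(ng * trim_a) + 1; hi_a <- ng + 1 - floor(ng * trim_a)
    rm_ <- rank(m); ra_ <- rank(a)
    keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep2)) return(1)
    f <- sum(w[keep2] * m[keep2]) / sum(w[keep2])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Moderated method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersions from the pooled within-group
#' variance of library-size-adjusted counts, `phi = (v - m) / m^2` floored at
#' zero, shrunk toward the common (all-gene) estimate with a prior weight
#' equivalent to `prior_n` pseudo-genes.
#'
#' @param counts Integer matrix genes x samples.
#' @param groups Named group labels over samples (exactly two groups).
#' @param norm_factors Optional per-sample scaling factors (e.g.
#'   [tmm_factors()]); default 1.
#' @param prior_n Prior weight in pseudo-genes (default 10).
#' @return Named per-gene dispersion vector (>= 0).
#' @export
estimate_dispersion <- function(counts, groups, norm_factors = NULL,
                                prior_n = 10) {
  counts <- as.matrix(counts)
  g <- groups[colnames(counts)]
  if (length(unique(g)) != 2L) stop("exactly two groups required")
  eff <- colSums(counts) * (if (is.null(norm_factors)) 1 else
    norm_factors[colnames(counts)])
  common_lib <- exp(mean(log(eff)))
  y <- sweep(counts, 2L, common_lib / eff, "*")
  per_gene <- function(i) {
    v <- 0; dfs <- 0
    for (grp in unique(g)) {
      x <- y[i, g == grp]
      v <- v + sum((x - mean(x))^2)
      dfs <- dfs + length(x) - 1L
    }
    v <- v / dfs
    m <- mean(y[i, ])
    if (m <= 0) return(NA_real_)
    max(0, (v - m) / m^2)
  }
  raw <- vapply(seq_len(nrow(counts)), per_gene, numeric(1))
  common <- mean(raw, na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  shrunk <- (raw + prior_n * common) / (1 + prior_n)
  shrunk[is.na(shrunk)] <- common
  stats::setNames(pmax(shrunk, 0), rownames(counts))
}

#' Negative-binomial conditional exact test for two groups
#'
#' Per gene, counts are scaled to a common effective library size (library
#' size times normalisation factor), and the two group sums are tested
#' conditionally on their total: the two-sided exact p-value sums the
#' probabilities of all group-sum splits as or less probable than the observed
#' one, under NB group sums with the gene's dispersion. As the dispersion
#' approaches zero this converges to the binomial exact test on the two sums.
#' log2 fold changes use normalised group means with a 0.5 pseudocount.
#'
#' @param counts Integer matrix genes x samples.
#' @param groups Named group labels (`"ctrl"` is the baseline; fold changes
#'   are treatment over control).
#' @param dispersions Per-gene dispersion vector (recycled if length 1).
#' @param norm_factors Optional per-sample factors from [tmm_factors()].
#' @return Data frame: gene_id, log2fc, p.
#' @export
nb_exact_test <- function(counts, groups, dispersions, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(dispersions < 0)) stop("dispersions must be non-negative")
  dispersions <- rep_len(dispersions, nrow(counts))
  g <- groups[colnames(counts)]
  lv <- unique(g)
  if (length(lv) != 2L) stop("exactly two groups required")
  base <- if ("ctrl" %in% lv) "ctrl" else lv[1L]
  other <- setdiff(lv, base)
  eff <- colSums(counts) * (if (is.null(norm_factors)) 1 else
    norm_factors[colnames(counts)])
  common_lib <- exp(mean(log(eff)))
  y <- sweep(counts, 2L, common_lib / eff, "*")
  iA <- which(g == base); iB <- which(g == other)
  nA <- length(iA); nB <- length(iB)
  one <- function(i) {
    sA <- round(sum(y[i, iA])); sB <- round(sum(y[i, iB]))
    tot <- sA + sB
    lfc <- log2((sum(y[i, iB]) / nB + 0.5) / (sum(y[i, iA]) / nA + 0.5))
    if (tot == 0) return(c(lfc, 1))
    phi <- dispersions[i]
    mu <- tot / (nA + nB)
    s <- 0:tot
    if (phi <= 1e-12) {
      lp <- stats::dbinom(s, tot, nA / (nA + nB), log = TRUE)
    } else {
      lp <- stats::dnbinom(s, size = nA / phi, mu = nA * mu, log = TRUE) +
        stats::dnbinom(tot - s, size = nB / phi, mu = nB * mu, log = TRUE)
      lp <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
    }
    obs <- lp[sA + 1L]
    p <- sum(exp(lp[lp <= obs + 1e-12]))
    c(lfc, min(1, p))
  }
  res <- t(vapply(seq_len(nrow(counts)), one, numeric(2)))
  data.frame(gene_id = rownames(counts), log2fc = res[, 1L], p = res[, 2L],
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Benjamini-Hochberg adjustment over all tested genes, then direction
#' assignment: `up` iff fold change >= `fc_cut` and `q < fdr_cut`, `down` iff
#' fold change <= `1/fc_cut` and `q < fdr_cut`, otherwise `ns`.
#'
#' @param res Result of [nb_exact_test()].
#' @param fc_cut Fold-change cutoff (default 2).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return The input with added `q` and `direction` columns.
#' @export
call_degs <- function(res, fc_cut = 2, fdr_cut = 0.05) {
  if (nrow(res) == 0L) {
    res$q <- numeric(0); res$direction <- character(0)
    return(res)
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  fc <- 2^res$log2fc
  res$direction <- ifelse(fc >= fc_cut & res$q < fdr_cut, "up",
                          ifelse(fc <= 1 / fc_cut & res$q < fdr_cut,
                                 "down", "ns"))
  res
}

#' Full differential-expression stage
#'
#' TMM normalisation, moderated dispersion estimation, NB conditional exact
#' test, DEG calling, and an FPKM matrix alongside.
#'
#' @inheritParams nb_exact_test
#' @param gene_lengths Effective gene lengths in bp for FPKM.
#' @param fc_cut,fdr_cut DEG thresholds (defaults 2, 0.05).
#' @return List with `degs` (per-gene table), `fpkm` (matrix),
#'   `norm_factors`, `dispersions`.
#' @export
de_table <- function(counts, gene_lengths, groups, fc_cut = 2,
                     fdr_cut = 0.05) {
  nf <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, groups, norm_factors = nf)
  res <- nb_exact_test(counts, groups, disp, norm_factors = nf)
  degs <- call_degs(res, fc_cut = fc_cut, fdr_cut = fdr_cut)
  list(degs = degs, fpkm = fpkm(counts, gene_lengths[rownames(counts)]),
       norm_factors = nf, dispersions = disp)
}
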