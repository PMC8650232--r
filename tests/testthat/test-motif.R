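make_pfm <- function(cols, motif_id = "MX", tf_name = "TFX") {
  m <- matrix(1, 4, length(cols), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cols)) m[cols[j], j] <- 97
  structure(list(motif_id = motif_id, tf_name = tf_name, counts = m),
            class = "pfm")
}

test_that("JASPAR text round-trips through the parser", {
  sim <- get_default_sim()
  path <- tempfile(fileext = ".pfm")
  write_jaspar(sim$pfms, path)
  back <- read_jaspar(path)
  expect_equal(names(back), names(sim$pfms))
  for (id in names(back)) {
    expect_equal(back[[id]]$tf_name, sim$pfms[[id]]$tf_name)
    expect_equal(unname(back[[id]]$counts), unname(sim$pfms[[id]]$counts))
  }
  expect_error(suppressWarnings(read_jaspar(tempfile())),
               "cannot open|no PFM")
})

test_that("a consensus-only promoter yields the top-scoring hit at offset 0", {
  # consensus must not be a reverse-complement palindrome
  pfm <- make_pfm(c("A", "A", "C", "G", "T", "A", "C", "C"))
  consensus <- "AACGTACC"
  h <- scan_pwm(consensus, pfm, threshold_frac = 0.8)
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 0)
  expect_equal(h$strand, "+")
  pwm <- pfm_to_pwm(pfm)
  expect_equal(h$score, sum(apply(pwm, 2, max)))
  # empty sequence -> empty hit list
  expect_equal(nrow(scan_pwm("", pfm)), 0)
})

test_that("reverse-complementing the sequence flips strand and mirrors offsets", {
  set.seed(71)
  pfm <- make_pfm(sample(c("A", "C", "G", "T"), 12, replace = TRUE))
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  # plant a consensus instance
  cons <- paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)],
                collapse = "")
  substr(s, 101, 112) <- cons
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_pwm(s, pfm, 0.8)
  h2 <- scan_pwm(rc, pfm, 0.8)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score))
  # a hit at offset o maps to offset (len - motif_len - o) with flipped strand
  expect_setequal(500 - 12 - h2$offset, h1$offset)
  flip <- stats::setNames(c("-", "+"), c("+", "-"))
  m1 <- h1[order(h1$offset), ]
  m2 <- h2[order(500 - 12 - h2$offset), ]
  expect_equal(unname(flip[m2$strand]), m1$strand)
  # windows with N never score
  sn <- s; substr(sn, 101, 101) <- "N"
  hn <- scan_pwm(sn, pfm, 0.8)
  expect_false(any(hn$offset %in% 90:101))
})

test_that("scanner agrees with Biostrings::matchPWM on a planted sequence", {
  set.seed(72)
  pfm <- make_pfm(sample(c("A", "C", "G", "T"), 10, replace = TRUE))
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  cons <- paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)],
                collapse = "")
  substr(s, 501, 510) <- cons
  pwm <- pfm_to_pwm(pfm)
  # forward-strand hits at the same percentage-of-range cutoff
  rng <- sum(apply(pwm, 2, max)) - sum(apply(pwm, 2, min))
  thr <- sum(apply(pwm, 2, min)) + 0.8 * rng
  bs <- Biostrings::matchPWM(pwm, Biostrings::DNAString(s),
                             min.score = thr)
  mine <- scan_pwm(s, pfm, 0.8)
  mine_fwd <- mine[mine$strand == "+", ]
  expect_setequal(mine_fwd$offset, Biostrings::start(bs) - 1L)
})

test_that("planted instances in the synthetic study are recovered at >= 95%", {
  sim <- get_default_sim()
  hits <- scan_promoters(sim$promoters, sim$pfms, threshold_frac = 0.8)
  tm <- sim$truth$motifs
  found <- mapply(function(g, m, o) {
    any(hits$gene_id == g & hits$motif_id == m & hits$offset == o)
  }, tm$gene_id, tm$motif_id, tm$offset)
  expect_gte(mean(found), 0.95)
  # false hits per kb stay near the background expectation
  planted_key <- paste(tm$gene_id, tm$motif_id, tm$offset)
  hit_key <- paste(hits$gene_id, hits$motif_id, hits$offset)
  n_false <- sum(!(hit_key %in% planted_key))
  kb_scanned <- length(sim$promoters) * sim$config$promoter_len *
    length(sim$pfms) / 1000
  # background rate for these PFMs: <= 2 mismatches over 14 positions,
  # two strands
  p_bg <- 2 * stats::pbinom(2, 14, 0.75)
  expect_lt(n_false / kb_scanned, 2 * p_bg * 1000)
})

test_that("hypergeometric enrichment matches exhaustive enumeration for N <= 12", {
  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(2, N %/% 3 + 1)) {
        for (k in 0:min(K, n)) {
          expect_equal(
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            enum_hyper_upper(k, K, n, N),
            tolerance = 1e-12,
            label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("enrichment over TSS windows: perfect separation and intersection rule", {
  # motif in all 5 targets, in no other of 20 background genes
  genes <- sprintf("g%02d", 1:20)
  targets <- genes[1:5]
  hits <- data.frame(motif_id = "M1", gene_id = targets, offset = 3000,
                     strand = "+", score = 10)
  enr <- motif_enrich(hits, targets, genes, motif_ids = "M1",
                      promoter_len = 6000)
  expect_equal(unique(enr$records$p), 1 / choose(20, 5))
  expect_equal(enr$consistent, "M1")
  # a motif enriched at 1k and 2k but with hits spread at 3k loses enrichment
  far <- data.frame(motif_id = "M2", gene_id = genes, offset = 5800,
                    strand = "+", score = 10)
  both <- rbind(hits, data.frame(motif_id = "M2", gene_id = targets,
                                 offset = 3000, strand = "+", score = 10),
                far)
  enr2 <- motif_enrich(both, targets, genes, motif_ids = c("M1", "M2"),
                       promoter_len = 6000)
  r2 <- enr2$records[enr2$records$motif_id == "M2", ]
  expect_true(all(r2$enriched[r2$window %in% c(1000, 2000)]))
  expect_false(r2$enriched[r2$window == 3000])
  expect_equal(enr2$consistent, "M1")
  # zero background hits -> p = 1; empty target set -> error
  none <- motif_enrich(hits[0, ], targets, genes, motif_ids = "M9",
                       promoter_len = 6000)
  expect_true(all(none$records$p == 1))
  expect_error(motif_enrich(hits, character(0), genes, "M1", 6000), "empty")
  expect_error(motif_enrich(hits, "not_there", genes, "M1", 6000), "subset")
})

test_that("enrichment p is monotone in the target hit count", {
  genes <- sprintf("g%02d", 1:30)
  targets <- genes[1:10]
  p_at <- vapply(3:10, function(k) {
    hits <- data.frame(motif_id = "M1",
                       gene_id = c(targets[1:k], genes[11:15]),
                       offset = 3000, strand = "+", score = 1)
    motif_enrich(hits, targets, genes, "M1", 6000)$records$p[1]
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("TF matching is case-insensitive and multimaps motifs", {
  pfms <- structure(list(
    a = structure(list(motif_id = "M1", tf_name = "USF2",
                       counts = make_pfm("A")$counts), class = "pfm"),
    b = structure(list(motif_id = "M2", tf_name = "usf2",
                       counts = make_pfm("C")$counts), class = "pfm"),
    c = structure(list(motif_id = "M3", tf_name = "NFIB",
                       counts = make_pfm("G")$counts), class = "pfm")),
    class = "pfm_set")
  tm <- match_tfs(c("USF2", "TEAD2"), pfms)
  expect_equal(tm$motif_id, c("M1", "M2"))  # one TF, two PFMs
  expect_equal(unique(tm$tf_gene), "USF2")
  expect_equal(nrow(match_tfs(c("XYZ"), pfms)), 0)
})

test_that("overlap significance matches enumeration and handles edge cases", {
  # exhaustive oracle at N = 10, K = 4, n = 5, k = 3: 66/252
  o <- overlap_test(paste0("t", 1:5), paste0("t", c(1:3, 9)), 10)
  expect_equal(o$overlap, 3)
  expect_equal(o$p, 66 / 252, tolerance = 1e-12)
  expect_equal(o$p, enum_hyper_upper(3, 4, 5, 10), tolerance = 1e-12)
  # zero overlap -> the whole upper tail, p = 1
  o0 <- overlap_test(paste0("a", 1:3), paste0("b", 1:3), 20)
  expect_equal(o0$p, 1)
  expect_error(overlap_test(paste0("t", 1:5), "t1", 3), "universe")
})
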