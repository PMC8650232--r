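test_that("FPKM follows its definition and is depth-invariant", {
  expect_equal(as.numeric(fpkm(1000, 2000, totals = 1e7)), 50)
  expect_equal(as.numeric(fpkm(0, 2000, totals = 1e7)), 0)
  m <- matrix(c(100, 300, 50, 150), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f1 <- fpkm(m, c(1000, 3000))
  f2 <- fpkm(2 * m, c(1000, 3000))
  expect_equal(f1, f2)
  expect_error(fpkm(m, c(0, 100)), "positive")
  expect_error(fpkm(m, c(1000, 3000), totals = c(0, 1)), "positive")
})

test_that("TMM factors: pure depth difference and identical samples give unit factors", {
  m <- matrix(rpois(400, 50) + 1, 100, 4)
  two <- cbind(m[, 1], 2 * m[, 1])
  f <- tmm_factors(two)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-10)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-10)
  z <- m; z[, 2] <- 0
  colnames(z) <- paste0("s", 1:4)
  expect_error(tmm_factors(z), "s2")
})

test_that("TMM recovers a constructed composition bias and agrees with edgeR", {
  set.seed(31)
  c1 <- rpois(1000, 1000)
  c2 <- c1; c2[1:50] <- c2[1:50] * 8   # 5% spiked high-count genes
  cc <- cbind(c1, c2)
  f <- tmm_factors(cc)
  bias <- sum(c2) / sum(c1)
  expect_lt(abs((f[1] / f[2]) / bias - 1), 0.05)
  skip_if_not_installed("edgeR")
  m <- matrix(rnbinom(4000, mu = 200, size = 5), 1000, 4)
  m[1:50, 2] <- m[1:50, 2] * 8
  lib <- colSums(m)
  ref <- which.min(abs(lib - mean(lib)))
  fe <- edgeR::calcNormFactors(m, refColumn = ref)
  expect_equal(unname(tmm_factors(m)), fe, tolerance = 0.005)
})

test_that("dispersion estimation: Poisson floor, NB recovery, degenerate shrinkage", {
  groups <- stats::setNames(rep(c("ctrl", "treat"), each = 3),
                            c(paste0("C", 1:3), paste0("T", 1:3)))
  sm0 <- simulate_count_matrix(2000, mean_count = 500, dispersion = 0,
                               seed = 1)
  d0 <- estimate_dispersion(sm0$counts, sm0$groups)
  expect_lt(stats::median(d0), 0.05)
  sm1 <- simulate_count_matrix(2000, mean_count = 500, dispersion = 0.4,
                               seed = 1)
  d1 <- estimate_dispersion(sm1$counts, sm1$groups)
  expect_gt(stats::median(d1), 0.2)
  expect_lt(stats::median(d1), 0.6)
  # single gene shrinks to its own estimate
  one <- sm1$counts[1, , drop = FALSE]
  dsingle <- estimate_dispersion(one, sm1$groups)
  y <- one[1, ]
  expect_equal(length(dsingle), 1L)
  expect_gte(dsingle[[1]], 0)
})

test_that("NB exact test: identical groups, label swap, binomial limit", {
  groups <- stats::setNames(rep(c("ctrl", "treat"), each = 3),
                            c(paste0("C", 1:3), paste0("T", 1:3)))
  sym <- matrix(rep(c(10, 20, 30), 2), 1, 6,
                dimnames = list("g1", names(groups)))
  r <- nb_exact_test(sym, groups, 0.1)
  expect_equal(r$p, 1)
  expect_equal(r$log2fc, 0)
  # swapping group labels flips the fold change, keeps p
  set.seed(41)
  cm <- matrix(rnbinom(60, mu = 100, size = 10), 10, 6,
               dimnames = list(paste0("g", 1:10), names(groups)))
  swapped <- stats::setNames(ifelse(groups == "ctrl", "treat", "ctrl"),
                             names(groups))
  r1 <- nb_exact_test(cm, groups, 0.1)
  r2 <- nb_exact_test(cm, swapped, 0.1)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
  expect_error(nb_exact_test(cm, groups, -0.5), "non-negative")
  # dispersion -> 0 converges to the conditional binomial exact test
  set.seed(42)
  cm2 <- matrix(rpois(60, 100), 10, 6,
                dimnames = list(paste0("g", 1:10), names(groups)))
  rb <- nb_exact_test(cm2, groups, 1e-8)
  eff <- colSums(cm2); L <- exp(mean(log(eff)))
  y <- sweep(cm2, 2, L / eff, "*")
  oracle <- vapply(1:10, function(i) {
    sA <- round(sum(y[i, 1:3])); sB <- round(sum(y[i, 4:6]))
    tot <- sA + sB
    pr <- stats::dbinom(0:tot, tot, 0.5)
    sum(pr[pr <= pr[sA + 1] * (1 + 1e-12)])
  }, numeric(1))
  expect_lt(max(abs(rb$p - oracle)), 1e-6)
})

test_that("DEG calling applies the fold-change and FDR rule", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = log2(c(2.5, 0.4, 3, 1.2)),
                    p = c(0.001, 0.004, 0.5, 0.8))
  out <- call_degs(res)
  # with BH over 4 genes, q = c(0.002, 0.008, 0.666, 0.8)
  expect_equal(out$direction, c("up", "down", "ns", "ns"))
  expect_true(all(out$q >= out$p))
  expect_equal(nrow(call_degs(res[0, ])), 0)
})

test_that("DE stage is calibrated on nulls and recovers planted fold changes", {
  sm0 <- simulate_count_matrix(2000, mean_count = 500, dispersion = 0.1,
                               seed = 51)
  d0 <- estimate_dispersion(sm0$counts, sm0$groups)
  r0 <- nb_exact_test(sm0$counts, sm0$groups, d0)
  frac <- mean(r0$p < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  sm1 <- simulate_count_matrix(600, mean_count = 500, dispersion = 0.1,
                               log2fc = 1.5, n_de = 200, seed = 52)
  d1 <- estimate_dispersion(sm1$counts, sm1$groups)
  degs <- call_degs(nb_exact_test(sm1$counts, sm1$groups, d1))
  de <- degs[sm1$truth$is_de, ]
  expect_gt(mean(de$direction != "ns"), 0.8)
  called <- de$direction != "ns"
  truth_dir <- ifelse(sm1$truth$true_log2fc[sm1$truth$is_de] > 0,
                      "up", "down")
  expect_gt(mean(de$direction[called] == truth_dir[called]), 0.95)
})

test_that("FPKM ranks track true expression on noise-free simulation", {
  set.seed(61)
  n <- 500
  base <- rlnorm(n, log(300), 1)
  lens <- sample(500:5000, n, replace = TRUE)
  mu <- base * lens / 1000          # counts proportional to level x length
  counts <- matrix(rpois(n * 2, rep(mu, 2)), n, 2)
  rownames(counts) <- paste0("g", 1:n)
  f <- fpkm(counts, lens)
  expect_gt(stats::cor(base, f[, 1], method = "spearman"), 0.95)
})
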