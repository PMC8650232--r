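# Hand-checkable isoform pairs for every classification rule. Coordinates are
# 0-based half-open; flanking exons shared unless the rule requires otherwise.
pair_cases <- list(
  list(a = chain(0, 100, 200, 300, 400, 500), b = chain(0, 100, 400, 500),
       strand = "+", type = "ES"),
  list(a = chain(0, 100, 200, 300, 350, 420, 500, 600),
       b = chain(0, 100, 500, 600), strand = "+", type = "CassetteExon"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 300),
       strand = "+", type = "IR"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 130, 200, 300),
       strand = "+", type = "A5SS"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 100, 170, 300),
       strand = "+", type = "A3SS"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 130, 200, 300),
       strand = "-", type = "A3SS"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 100, 170, 300),
       strand = "-", type = "A5SS"),
  list(a = chain(0, 100, 200, 300, 600, 700),
       b = chain(0, 100, 400, 500, 600, 700), strand = "+", type = "MXE"),
  list(a = chain(0, 100, 400, 500), b = chain(200, 300, 400, 500),
       strand = "+", type = "5pMXE"),
  list(a = chain(0, 100, 200, 300), b = chain(0, 100, 400, 500),
       strand = "+", type = "3pMXE"),
  list(a = chain(0, 100, 400, 500), b = chain(200, 300, 400, 500),
       strand = "-", type = "3pMXE"),
  list(a = chain(0, 100, 200, 300, 400, 500), b = chain(0, 80, 400, 500),
       strand = "+", type = "A5SS&ES"),
  list(a = chain(0, 100, 200, 300, 400, 500), b = chain(0, 100, 430, 500),
       strand = "+", type = "A3SS&ES"),
  list(a = chain(0, 100, 200, 300, 400, 500), b = chain(0, 80, 400, 500),
       strand = "-", type = "A3SS&ES"))

test_that("classification grammar labels each hand-built pair correctly", {
  for (cs in pair_cases) {
    expect_equal(classify_pair(cs$a, cs$b, cs$strand), cs$type,
                 label = sprintf("%s (%s strand)", cs$type, cs$strand))
  }
  expect_equal(classify_pair(chain(0, 100), chain(0, 100)), "no-event")
})

test_that("classification is symmetric in argument order", {
  for (cs in pair_cases) {
    expect_equal(classify_pair(cs$b, cs$a, cs$strand),
                 classify_pair(cs$a, cs$b, cs$strand))
  }
})

test_that("coordinate reflection swaps donor/acceptor and terminal-exon types", {
  swap <- c(ES = "ES", CassetteExon = "CassetteExon", IR = "IR", MXE = "MXE",
            A5SS = "A3SS", A3SS = "A5SS", `5pMXE` = "3pMXE",
            `3pMXE` = "5pMXE", `A5SS&ES` = "A3SS&ES", `A3SS&ES` = "A5SS&ES")
  mirror <- function(e, L) {
    m <- cbind(L - e[, 2], L - e[, 1])
    m[order(m[, 1]), , drop = FALSE]
  }
  for (cs in pair_cases) {
    L <- max(cs$a, cs$b)
    got <- classify_pair(mirror(cs$a, L), mirror(cs$b, L), cs$strand)
    expect_equal(got, unname(swap[cs$type]),
                 label = sprintf("mirrored %s", cs$type))
  }
})

test_that("malformed isoforms are rejected by name", {
  expect_error(splicelink:::new_gene_model(
    "gX", "chr1", "+", list(t1 = chain(0, 100, 50, 200))), "gX")
  expect_error(splicelink:::validate_exon_chain(chain(0, 100, 50, 200), "gX"),
               "overlapping")
  expect_error(splicelink:::validate_exon_chain(chain(100, 50), "gY"),
               "end <= start")
})

test_that("detected events on simulated models match planted types exactly", {
  sim <- get_default_sim()
  ev <- enumerate_events(sim$models)
  truth <- sim$truth$events
  expect_equal(nrow(ev), nrow(truth))
  m <- merge(ev[, c("gene_id", "type")], truth[, c("gene_id", "type")],
             by = "gene_id", suffixes = c("_det", "_true"))
  expect_equal(nrow(m), nrow(truth))
  expect_identical(m$type_det, m$type_true)
  expect_equal(attr(ev, "n_complex"), 0L)
  # deduplication and deterministic order
  expect_false(any(duplicated(ev$event_id)))
  expect_identical(ev, {
    ev2 <- enumerate_events(sim$models)
    attr(ev2, "n_complex") <- attr(ev, "n_complex"); ev2
  })
})

test_that("event quantification sums junction counts with absent rows as zero", {
  gene <- splicelink:::new_gene_model(
    "g1", "chr1", "+",
    list(t1 = chain(0, 100, 200, 300, 400, 500), t2 = chain(0, 100, 400, 500)))
  ev <- enumerate_events(splicelink:::gene_models(list(gene)))
  expect_equal(ev$type, "ES")
  jt <- data.frame(chrom = "chr1", start = c(100, 100, 300),
                   end = c(400, 200, 400), strand = "+",
                   s1 = c(10, 5, 5), s2 = c(0, 7, 3))
  q <- quantify_event(ev, jt)
  expect_equal(unname(q$alt_reads), c(10, 0))
  expect_equal(unname(q$model_reads), c(10, 10))
  # nothing observed -> zeros
  q0 <- quantify_event(ev, jt[0, ])
  expect_equal(unname(q0$alt_reads), c(0, 0))
  expect_equal(unname(q0$model_reads), c(0, 0))
})

test_that("intron retention uses boundary reads as alternative evidence", {
  gene <- splicelink:::new_gene_model(
    "g1", "chr1", "+",
    list(t1 = chain(0, 100, 200, 300), t2 = chain(0, 300)))
  ev <- enumerate_events(splicelink:::gene_models(list(gene)))
  expect_equal(ev$type, "IR")
  # boundary intervals straddle the retained intron's ends
  expect_match(ev$alt_junctions, "chr1:99-101:\\+")
  expect_match(ev$alt_junctions, "chr1:199-201:\\+")
  expect_equal(ev$model_junctions, "chr1:100-200:+")
  jt <- data.frame(chrom = "chr1", start = c(100, 99, 199),
                   end = c(200, 101, 201), strand = "+",
                   s1 = c(30, 12, 8))
  q <- quantify_event(ev, jt)
  expect_equal(unname(q$alt_reads), 20)   # both boundaries summed
  expect_equal(unname(q$model_reads), 30) # the spliced junction
  # round-trip through the simulator's own IR convention
  sim <- get_default_sim()
  ir_ev <- enumerate_events(sim$models)
  ir_ev <- ir_ev[ir_ev$type == "IR", ]
  qq <- quantify_events(ir_ev, sim$junctions)
  expect_true(all(qq$alt + qq$model > 0))
})

test_that("event tables survive a write/read round trip", {
  sim <- get_default_sim()
  ev <- enumerate_events(sim$models)
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  attr(ev, "n_complex") <- NULL
  expect_equal(back, ev)
})
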