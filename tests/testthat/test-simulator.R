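test_that("usage tables are valid distributions with controlled divergence", {
  t1 <- sample_usage_tables(1L, divergence = 0.5, seed = 1L)
  expect_length(t1, 1L)
  sums <- vapply(t1[[1L]]$probs, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(unlist(lapply(t1[[1L]]$probs, function(p) p >= 0))))

  # zero divergence -> identical tables
  t0 <- sample_usage_tables(2L, divergence = 0, seed = 2L)
  expect_equal(t0[[1L]]$probs, t0[[2L]]$probs)
})

test_that("full divergence yields near-disjoint codon preferences", {
  tvs <- vapply(1:50, function(s) {
    tabs <- sample_usage_tables(2L, divergence = 1, seed = s)
    degenerate <- names(tabs[[1L]]$probs)[lengths(tabs[[1L]]$probs) > 1L]
    mean(vapply(degenerate, function(aa) {
      sum(abs(tabs[[1L]]$probs[[aa]] - tabs[[2L]]$probs[[aa]])) / 2
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(tvs), 0.9)
})

test_that("synthetic genomes are deterministic and correctly annotated", {
  tabs <- sample_usage_tables(2L, divergence = 1, seed = 4L)
  spec <- synthetic_genome_spec(6L, c(50L, 90L), 0.15, tabs, "transmissible",
                                seed = 10L, genome_id = "gA")
  g1 <- synth_genome(spec)
  g2 <- synth_genome(spec)
  expect_identical(g1$sequence, g2$sequence)   # byte-identical under a seed
  expect_identical(g1$cds, g2$cds)

  # CDS coordinates re-slice to genes: ATG start, stop codon end, in frame
  for (i in seq_len(nrow(g1$cds))) {
    cds <- substring(g1$sequence, g1$cds$start[i], g1$cds$end[i])
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substr(cds, 1L, 3L), "ATG")
    expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  # intergenic fraction approximately honoured
  coding <- sum(g1$cds$end - g1$cds$start + 1L)
  expect_equal(1 - coding / g1$length, 0.15, tolerance = 0.02)

  expect_error(synthetic_genome_spec(0L, c(50L, 90L), 0.1, tabs,
                                     "transmissible", seed = 1L),
               "n_genes")
  expect_error(synthetic_genome_spec(5L, c(50L, 90L), 0.1, tabs[1L],
                                     "transmissible", seed = 1L),
               ">= 2 mixture components")
  expect_error(synthetic_genome_spec(5L, c(50L, 90L), 0.1, tabs,
                                     "non-transmissible", seed = 1L),
               "exactly 1")
})

test_that("single-host full-divergence genomes have near-zero IEA", {
  tabs <- sample_usage_tables(1L, divergence = 1, seed = 8L)
  g <- synth_genome(synthetic_genome_spec(10L, c(80L, 120L), 0.1, tabs,
                                          "non-transmissible", seed = 9L,
                                          genome_id = "pure"))
  prof <- iea_profile(g)
  expect_lt(mean(prof$iea, na.rm = TRUE), 0.2)
})

test_that("mean IEA is non-decreasing as the mixture approaches 50/50", {
  tabs <- sample_usage_tables(2L, divergence = 1, seed = 12L)
  mean_at_weight <- function(w, seeds) {
    vapply(seeds, function(s) {
      mixture <- list(list(table = tabs[[1L]], weight = w),
                      list(table = tabs[[2L]], weight = 1 - w))
      lab <- "transmissible"
      g <- synth_genome(synthetic_genome_spec(8L, c(60L, 100L), 0.1, mixture,
                                              lab, seed = s, genome_id = "w"))
      mean(iea_profile(g)$iea, na.rm = TRUE)
    }, numeric(1))
  }
  seeds <- 1:20
  m_90 <- mean(mean_at_weight(0.9, seeds))
  m_70 <- mean(mean_at_weight(0.7, seeds + 40L))
  m_50 <- mean(mean_at_weight(0.5, seeds + 80L))
  expect_lt(m_90, m_70)
  expect_lt(m_70, m_50)
})

test_that("fragment extraction honours its contract and is deterministic", {
  tabs <- sample_usage_tables(1L, divergence = 0.5, seed = 14L)
  g <- synth_genome(synthetic_genome_spec(30L, c(80L, 140L), 0.1, tabs,
                                          "non-transmissible", seed = 15L,
                                          genome_id = "big"))
  fr <- extract_fragments(g, c(100L, 400L), 500L, seed = 16L, group = "A")
  expect_equal(nrow(fr), 500L)
  expect_true(all(fr$length >= 100L & fr$length <= 400L))
  expect_true(all(fr$end <= g$length))
  expect_equal(fr$length, fr$end - fr$start)  # 0-based half-open coordinates
  # re-slicing the genome reproduces every fragment (strand-aware)
  resliced <- substring(g$sequence, fr$start + 1L, fr$end)
  flip <- fr$strand == "-"
  resliced[flip] <- vapply(resliced[flip], reverse_complement, character(1),
                           USE.NAMES = FALSE)
  expect_equal(fr$sequence, resliced)

  fr2 <- extract_fragments(g, c(100L, 400L), 500L, seed = 16L, group = "A")
  expect_identical(fr, fr2)
  expect_error(extract_fragments(g, c(g$length + 1L, g$length + 10L), 5L),
               "shorter")
})

test_that("fragment lengths are uniform over the requested range", {
  tabs <- sample_usage_tables(1L, divergence = 0.5, seed = 18L)
  g <- synth_genome(synthetic_genome_spec(40L, c(100L, 160L), 0.1, tabs,
                                          "non-transmissible", seed = 19L,
                                          genome_id = "uni"))
  fr <- extract_fragments(g, c(100L, 400L), 10000L, seed = 20L)
  bins <- cut(fr$length, breaks = seq(99.5, 400.5, length.out = 31L))
  # 301 lengths over 30 near-equal bins: compare to the exact bin masses
  expected <- as.numeric(table(cut(100:400,
                                   seq(99.5, 400.5, length.out = 31L)))) / 301
  p <- suppressWarnings(stats::chisq.test(table(bins), p = expected)$p.value)
  expect_gt(p, 0.01)
})

test_that("benchmark building balances classes and prevents genome leakage", {
  tabs <- sample_usage_tables(2L, divergence = 1, seed = 22L)
  make_genome <- function(label, split, i, seed) {
    mixture <- if (label == "transmissible") tabs else tabs[1L]
    g <- synth_genome(synthetic_genome_spec(10L, c(60L, 100L), 0.1, mixture,
                                            label, seed = seed,
                                            genome_id = sprintf("%s_%s_%d",
                                                                label, split,
                                                                i)))
    g$split <- split
    g
  }
  genomes <- list(make_genome("transmissible", "train", 1L, 31L),
                  make_genome("non-transmissible", "train", 1L, 32L),
                  make_genome("transmissible", "test", 1L, 33L),
                  make_genome("non-transmissible", "test", 1L, 34L))
  cfg <- benchmark_config(n_train_per_class = 100L,
                          n_test_per_class = c(A = 30L), seed = 5L)
  cfg$group_ranges <- cfg$group_ranges["A"]
  bench <- build_benchmark(genomes, cfg)
  expect_equal(nrow(bench$train), 200L)
  expect_equal(as.vector(table(bench$train$label)), c(100L, 100L))
  expect_equal(nrow(bench$test$A), 60L)
  # leakage guard: no genome contributes to both sides
  expect_length(intersect(unique(bench$train$genome_id),
                          unique(bench$test$A$genome_id)), 0L)
  expect_equal(nrow(bench$manifest), 260L)
  expect_null(bench$manifest$sequence)

  # a class missing from a split is an error
  expect_error(build_benchmark(genomes[-3L], cfg), "absent from the test")
})

test_that("default benchmark configuration carries the full-scale counts", {
  cfg <- benchmark_config()
  expect_equal(cfg$n_train_per_class, 300000L)
  expect_equal(cfg$n_test_per_class,
               c(A = 30000L, B = 30000L, C = 30000L, D = 10000L))
  expect_equal(cfg$group_ranges$A, c(100L, 400L))
  expect_equal(cfg$group_ranges$D, c(5000L, 10000L))
})
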