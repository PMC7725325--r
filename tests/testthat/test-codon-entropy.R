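code <- build_genetic_code()

test_that("bacterial genetic code yields the 19 IEA categories", {
  expect_s3_class(code, "genetic_code")
  expect_length(code$codon_to_aa, 64L)
  expect_length(code$categories, 19L)
  # stop codons collapse into one category
  expect_setequal(code$codons_by_category[["*"]], c("TAA", "TAG", "TGA"))
  # degeneracy of the standard code
  expect_length(code$codons_by_category[["L"]], 6L)
  expect_length(code$codons_by_category[["S"]], 6L)
  expect_length(code$codons_by_category[["K"]], 2L)
  # single-codon amino acids are not categories
  expect_false(any(c("M", "W") %in% code$categories))
  expect_true(all(lengths(code$codons_by_category) >= 2L))
  expect_error(build_genetic_code(9999), "unsupported")
})

test_that("synonymous codon counting tallies in-frame codons", {
  cc <- count_synonymous_codons("ATGAAAAAGTAA", code)
  expect_equal(cc$counts[["K"]][["AAA"]], 1L)
  expect_equal(cc$counts[["K"]][["AAG"]], 1L)
  expect_equal(cc$counts[["*"]][["TAA"]], 1L)
  expect_equal(cc$total_codons, 4L)

  # ambiguous codons are skipped, not miscounted
  cc2 <- count_synonymous_codons("ATGNNNTAA", code)
  expect_true(all(cc2$counts[["K"]] == 0L))
  expect_equal(cc2$counts[["*"]][["TAA"]], 1L)

  # replication scales counts linearly
  cc3 <- count_synonymous_codons(rep("ATGAAATAA", 100L), code)
  expect_equal(cc3$counts[["K"]][["AAA"]], 100L)
  expect_equal(cc3$counts[["K"]][["AAG"]], 0L)

  expect_error(count_synonymous_codons(character(0), code), "empty")
  expect_error(count_synonymous_codons(c(ok = "ATGAAATAA", bad = "ATGXXXTAA"),
                                       code),
               "bad")
  expect_warning(count_synonymous_codons("ATGAAATAAG", code), "partial")
})

test_that("IEA hits its analytic limits and the derived binary-entropy value", {
  # uniform synonymous usage -> maximum value 1, for any degeneracy
  for (n in c(2L, 3L, 4L, 6L)) {
    expect_equal(iea(rep(1L, n)), 1, tolerance = 1e-9)
    expect_equal(iea(rep(17L, n)), 1, tolerance = 1e-9)
  }
  # single-codon usage -> 0
  expect_equal(iea(c(5L, 0L)), 0)
  # frozen from the independent closed form -(0.75*log2(0.75)+0.25*log2(0.25))
  expect_equal(iea(c(3L, 1L)), 0.811278124459133, tolerance = 1e-12)
  # unobserved category is missing, never zero
  expect_true(is.na(iea(c(0L, 0L))))
  expect_error(iea(5L, n_i = 1L), "n_i")
  expect_error(iea(c(-1L, 2L)), "non-negative")
})

test_that("IEA matches a high-precision entropy oracle on random count vectors", {
  withr::with_seed(99L, {
    for (rep in 1:25) {
      n <- sample(2:6, 1L)
      counts <- stats::rpois(n, lambda = sample(1:50, 1L))
      if (sum(counts) == 0) counts[1L] <- 1L
      p <- counts[counts > 0] / sum(counts)
      oracle <- -sum(p * log2(p)) / log2(n)
      expect_equal(iea(counts, n_i = n), oracle, tolerance = 1e-12)
    }
  })
})

test_that("IEA is invariant to permutation and scaling, and bounded in [0,1]", {
  withr::with_seed(123L, {
    for (rep in 1:20) {
      n <- sample(2:6, 1L)
      counts <- sample(0:30, n, replace = TRUE)
      if (sum(counts) == 0) counts[1L] <- 1L
      v <- iea(counts, n_i = n)
      expect_gte(v, 0)
      expect_lte(v, 1)
      expect_equal(iea(sample(counts), n_i = n), v)
      expect_equal(iea(counts * 7L, n_i = n), v)
      # 1 iff all observed frequencies equal; 0 iff a single codon observed
      obs <- counts[counts > 0]
      expect_equal(v == 1, length(unique(obs)) == 1L && length(obs) == n)
      expect_equal(v == 0, length(obs) == 1L)
    }
  })
})

test_that("IEA profiles hit the uniform and deterministic limits", {
  # every synonymous codon of every category used exactly once -> all 1
  uniform_cds <- unlist(lapply(code$codons_by_category, function(cs) {
    paste0("ATG", paste(cs, collapse = ""))
  }))
  cc <- count_synonymous_codons(uniform_cds, code)
  vals <- vapply(code$categories, function(cat)
    iea(cc$counts[[cat]]), numeric(1))
  expect_true(all(abs(vals - 1) < 1e-12))

  # exactly one codon per amino acid -> all 0
  single_cds <- vapply(code$codons_by_category, function(cs)
    paste0("ATG", strrep(cs[1L], 5L)), character(1))
  cc0 <- count_synonymous_codons(single_cds, code)
  vals0 <- vapply(code$categories, function(cat)
    iea(cc0$counts[[cat]]), numeric(1))
  expect_true(all(vals0 == 0))
})

test_that("iea_profile uses CDS annotation and errors without coding sequence", {
  tabs <- sample_usage_tables(1L, divergence = 0, seed = 5L)
  g <- synth_genome(synthetic_genome_spec(5L, c(60L, 100L), 0.1, tabs,
                                          "non-transmissible", seed = 6L,
                                          genome_id = "g1"))
  prof <- iea_profile(g)
  expect_s3_class(prof, "iea_profile")
  expect_named(prof$iea, code$categories)
  expect_true(all(prof$iea >= 0 & prof$iea <= 1, na.rm = TRUE))
  expect_equal(prof$n_cds, 5L)
  # a genome of pure intergenic sequence has no usable ORFs
  expect_error(iea_profile(list(genome_id = "empty", sequence = strrep("A", 500),
                                cds = NULL, label = NA)),
               "no usable coding")
})

test_that("mixture genomes have systematically higher IEA than single-host genomes", {
  tabs <- sample_usage_tables(2L, divergence = 1, seed = 31L)
  mean_iea <- function(mixture, seed) {
    lab <- if (length(mixture) > 1L) "transmissible" else "non-transmissible"
    g <- synth_genome(synthetic_genome_spec(8L, c(60L, 100L), 0.1, mixture,
                                            lab, seed = seed,
                                            genome_id = "m"))
    mean(iea_profile(g)$iea, na.rm = TRUE)
  }
  seeds <- 1:20
  mix <- vapply(seeds, function(s) mean_iea(tabs, 100L + s), numeric(1))
  pure1 <- vapply(seeds, function(s) mean_iea(tabs[1L], 200L + s), numeric(1))
  pure2 <- vapply(seeds, function(s) mean_iea(tabs[2L], 300L + s), numeric(1))
  # mixing two distinct codon-usage distributions cannot decrease entropy
  expect_true(all(mix > pure1))
  expect_true(all(mix > pure2))
})

test_that("find_orfs reports stop-closed in-frame ORFs only", {
  expect_equal(find_orfs("ATGAAATAA", min_codons = 2L), "ATGAAATAA")
  # an open-ended run with no stop codon is not an ORF under this convention
  expect_equal(find_orfs(strrep("A", 300L), min_codons = 30L), character(0))

  s <- random_dna(10000L, seed = 17L)
  orfs <- find_orfs(s, min_codons = 20L)
  expect_gt(length(orfs), 0L)
  stops <- c("TAA", "TAG", "TGA")
  rc <- reverse_complement(s)
  for (o in orfs) {
    expect_equal(nchar(o) %% 3L, 0L)
    expect_gte(nchar(o) / 3L, 20L)
    expect_true(substr(o, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(o, nchar(o) - 2L, nchar(o)) %in% stops)
    # no internal stop codon in frame
    internal <- substring(o, seq(1L, nchar(o) - 3L, by = 3L),
                          seq(3L, nchar(o) - 3L, by = 3L))
    expect_false(any(internal %in% stops))
    expect_true(grepl(o, s, fixed = TRUE) || grepl(o, rc, fixed = TRUE))
  }
})

test_that("find_orfs agrees with an independent brute-force frame scan", {
  s <- random_dna(3000L, seed = 23L)
  # oracle: enumerate codons of all six frames directly
  oracle <- character(0)
  stops <- c("TAA", "TAG", "TGA")
  for (strand in c(s, reverse_complement(s))) {
    for (off in 0:2) {
      n <- (nchar(strand) - off) %/% 3L
      cod <- substring(strand, off + 3L * seq_len(n) - 2L,
                       off + 3L * seq_len(n))
      last_stop <- 0L
      for (k in seq_len(n)) {
        if (cod[k] %in% stops) {
          seg <- (last_stop + 1L):k
          st <- seg[cod[seg] %in% c("ATG", "GTG", "TTG")]
          if (length(st) && k - st[1L] + 1L >= 10L) {
            oracle <- c(oracle, paste(cod[st[1L]:k], collapse = ""))
          }
          last_stop <- k
        }
      }
    }
  }
  expect_setequal(find_orfs(s, min_codons = 10L), oracle)
})

make_profile <- function(values, label, id = "p") {
  v <- rep(NA_real_, 19L)
  names(v) <- code$categories
  v["K"] <- values
  structure(list(genome_id = id, iea = v, label = label,
                 n_cds = 1L, total_codons = 100L),
            class = "iea_profile")
}

test_that("compare_groups: exchangeable and separated groups behave analytically", {
  pa <- lapply(c(0.2, 0.5, 0.8), make_profile, label = "a")
  cmp_same <- compare_groups(pa, pa)
  k <- cmp_same[cmp_same$category == "K", ]
  expect_equal(k$auc, 0.5)
  expect_gt(k$p_value, 0.9)
  # unobserved categories are flagged, not dropped
  expect_equal(nrow(cmp_same), 19L)
  expect_true(all(cmp_same$note[cmp_same$category != "K"] != ""))

  pb <- lapply(c(0.1, 0.12, 0.15), make_profile, label = "b")
  cmp_sep <- compare_groups(pa, pb)
  expect_equal(cmp_sep[cmp_sep$category == "K", "auc"], 1)
})

test_that("compare_groups p-value equals the exact permutation distribution", {
  a_vals <- c(0.91, 0.88, 0.95, 0.82, 0.90)
  b_vals <- c(0.80, 0.85, 0.78, 0.89, 0.83)
  pa <- lapply(seq_along(a_vals),
               function(i) make_profile(a_vals[i], "a", paste0("a", i)))
  pb <- lapply(seq_along(b_vals),
               function(i) make_profile(b_vals[i], "b", paste0("b", i)))
  p_pkg <- compare_groups(pa, pb)[1, ]  # first row with data
  p_pkg <- compare_groups(pa, pb)
  p_pkg <- p_pkg[p_pkg$category == "K", "p_value"]

  # oracle: full enumeration of all choose(10, 5) = 252 group assignments
  pooled <- c(a_vals, b_vals)
  w_obs <- sum(rank(pooled)[1:5])
  combs <- utils::combn(10L, 5L)
  w_null <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- mean(w_null)
  p_exact <- mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)
})

test_that("compare_groups AUC equals the normalized Mann-Whitney pair count", {
  withr::with_seed(7L, {
    for (rep in 1:5) {
      a_vals <- round(stats::runif(6L), 2)
      b_vals <- round(stats::runif(8L), 2)
      pa <- lapply(seq_along(a_vals),
                   function(i) make_profile(a_vals[i], "a", paste0("a", i)))
      pb <- lapply(seq_along(b_vals),
                   function(i) make_profile(b_vals[i], "b", paste0("b", i)))
      got <- compare_groups(pa, pb)
      got <- got[got$category == "K", "auc"]
      expect_equal(got, pair_count_auc(c(a_vals, b_vals),
                                       rep(c(TRUE, FALSE), c(6L, 8L))))
    }
  })
})
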