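# shared fixtures: tiny deterministic generators used across test files

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a small model configuration that trains in seconds
tiny_model_config <- function(...) {
  model_config(kernels_triplet = 16L, kernels_base = 16L, hidden = 16L,
               batch_size = 32L, max_epochs = 2L, patience = 2L, seed = 42L,
               ...)
}

# labeled fragments from a pair of synthetic genomes (mixture vs single host)
tiny_benchmark_fragments <- function(n_per_class = 150L, seed = 7L,
                                     range = c(100L, 400L), group = "train") {
  tabs <- sample_usage_tables(2L, divergence = 1, seed = seed)
  gt <- synth_genome(synthetic_genome_spec(
    10L, c(60L, 120L), 0.1, tabs, "transmissible",
    seed = seed + 1L, genome_id = paste0("t", seed)))
  gn <- synth_genome(synthetic_genome_spec(
    10L, c(60L, 120L), 0.1, tabs[1L], "non-transmissible",
    seed = seed + 2L, genome_id = paste0("n", seed)))
  rbind(extract_fragments(gt, range, n_per_class, seed = seed + 3L,
                          group = group),
        extract_fragments(gn, range, n_per_class, seed = seed + 4L,
                          group = group))
}

# brute-force AUC by exhaustive pair counting (independent oracle)
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
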