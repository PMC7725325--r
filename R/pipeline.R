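#' Desk-scale pipeline configuration
#'
#' A fully synthetic, minutes-scale configuration of the
#' simulate-train-predict-evaluate pipeline: two host usage tables at full
#' divergence, a few labeled surrogate genomes per class and split, modest
#' fragment counts, and a reduced network (32+32 kernels, hidden width 32).
#' All values can be overridden; the full-scale counts live in
#' [benchmark_config()].
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer master seed.
#' @return A nested list configuration for [run_pipeline()].
#' @export
desk_config <- function(out_dir = tempfile("plastrans_run"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(
      n_hosts = 2L, divergence = 1, gc_bias = 0.5,
      n_genomes_per_class_split = 2L,
      n_genes = 28L, gene_len_codons = c(120L, 200L),
      intergenic_frac = 0.1,
      n_train_per_class = 400L,
      n_test_per_class = c(A = 30L, B = 30L, C = 30L, D = 30L)
    ),
    model = list(kernels_triplet = 32L, kernels_base = 32L, hidden = 32L,
                 batch_size = 64L, max_epochs = 6L, patience = 2L,
                 lr = 1e-3),
    evaluate = list(t_values = c(0, 0.1, 0.2))
  )
}

# simulate stage: labeled synthetic genomes -> benchmark fragments on disk
.stage_simulate <- function(cfg, out_dir) {
  sc <- cfg$simulate
  tables <- sample_usage_tables(sc$n_hosts, sc$divergence, seed = cfg$seed,
                                gc_bias = sc$gc_bias)
  genomes <- list()
  idx <- 0L
  for (split in c("train", "test")) {
    for (cl in c("transmissible", "non-transmissible")) {
      for (i in seq_len(sc$n_genomes_per_class_split)) {
        idx <- idx + 1L
        mixture <- if (cl == "transmissible") tables else tables[1L]
        spec <- synthetic_genome_spec(
          n_genes = sc$n_genes, gene_len_codons = sc$gene_len_codons,
          intergenic_frac = sc$intergenic_frac, usage_mixture = mixture,
          label = cl, seed = (cfg$seed + 1000L * idx) %% .Machine$integer.max,
          genome_id = sprintf("%s_%s_%02d", substr(cl, 1L, 5L), split, i)
        )
        g <- synth_genome(spec)
        g$split <- split
        genomes[[idx]] <- g
      }
    }
  }
  bcfg <- benchmark_config(n_train_per_class = sc$n_train_per_class,
                           n_test_per_class = unlist(sc$n_test_per_class),
                           seed = cfg$seed)
  bcfg$group_ranges <- bcfg$group_ranges[names(bcfg$n_test_per_class)]
  bench <- build_benchmark(genomes, bcfg)
  paths <- write_benchmark(bench, out_dir)
  list(bench = bench, paths = paths)
}

.write_manifest <- function(out_dir, stage, cfg, outputs) {
  manifest <- list(
    stage = stage,
    tool_version = as.character(utils::packageVersion("plastrans")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg[[stage]] %||% list(),
    outputs = as.list(outputs),
    digests = as.list(tools::md5sum(unlist(outputs)))
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the simulate-train-predict-evaluate pipeline
#'
#' Executes the configured stages in order under one master seed, writing
#' every artifact plus a per-stage JSON run manifest (config snapshot, seed,
#' output paths and md5 digests) into the configured output directory.
#' Inputs are never mutated. A `stages` subset runs a prefix of the
#' pipeline (e.g. simulation only).
#'
#' @param config A configuration list as from [desk_config()], or the path
#'   to a YAML file holding one.
#' @param stages Character vector of stages to run, a prefix of
#'   `c("simulate", "train", "predict", "evaluate")`.
#' @param quiet Suppress progress messages.
#' @return List with the output directory, per-stage artifact paths and the
#'   evaluation report (when the evaluate stage ran).
#' @export
run_pipeline <- function(config = desk_config(),
                         stages = c("simulate", "train", "predict",
                                    "evaluate"),
                         quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir) || is.null(cfg$seed)) {
    stop("pipeline config must provide 'out_dir' and 'seed'")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  order_all <- c("simulate", "train", "predict", "evaluate")
  stages <- order_all[order_all %in% stages]
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- list(out_dir = out_dir, manifests = character(0))
  say <- function(...) if (!quiet) message(...)

  bench <- NULL
  model <- NULL
  for (stage in stages) {
    say("stage: ", stage)
    if (stage == "simulate") {
      sim <- .stage_simulate(cfg, out_dir)
      bench <- sim$bench
      result$simulate <- sim$paths
      result$manifests["simulate"] <-
        .write_manifest(out_dir, "simulate", cfg, sim$paths)
      say("  fragments: ", nrow(bench$manifest))
    } else if (stage == "train") {
      if (is.null(bench)) stop("train stage needs the simulate stage")
      mc <- cfg$model %||% list()
      mcfg <- do.call(model_config, c(mc, list(seed = cfg$seed)))
      model <- train_model(build_model(mcfg), bench$train, quiet = quiet)
      model_path <- file.path(out_dir, "model.rds")
      save_model(model, model_path)
      result$train <- c(model = model_path)
      result$manifests["train"] <-
        .write_manifest(out_dir, "train", cfg, result$train)
      say("  final val loss: ",
          signif(utils::tail(model$history$val_loss, 1L), 4L))
    } else if (stage == "predict") {
      if (is.null(model) || is.null(bench)) {
        stop("predict stage needs the simulate and train stages")
      }
      test_all <- do.call(rbind, bench$test)
      seqs <- stats::setNames(test_all$sequence, test_all$fragment_id)
      preds <- predict_sequences(model, seqs)
      pred_path <- file.path(out_dir, "predictions.tsv")
      utils::write.table(preds, pred_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      result$predict <- c(predictions = pred_path)
      result$predictions <- preds
      result$manifests["predict"] <-
        .write_manifest(out_dir, "predict", cfg, result$predict)
      say("  predictions: ", nrow(preds))
    } else if (stage == "evaluate") {
      if (is.null(result$predictions) || is.null(bench)) {
        stop("evaluate stage needs the predict stage")
      }
      report <- evaluate_groups(result$predictions, bench$manifest,
                                t_values = cfg$evaluate$t_values %||%
                                  c(0, 0.1, 0.2))
      report_path <- file.path(out_dir, "report.tsv")
      utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      result$evaluate <- c(report = report_path)
      result$report <- report
      result$manifests["evaluate"] <-
        .write_manifest(out_dir, "evaluate", cfg, result$evaluate)
    }
  }
  result
}
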