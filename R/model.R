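MODEL_FORMAT_VERSION <- 1L

#' Configuration of the two-branch convolutional classifier
#'
#' The default architecture follows the published design: each branch
#' applies a one-dimensional convolution with 512 kernels of length 6 and
#' rectified-linear activation to its one-hot input (connected six-frame
#' triplet codes, `T x 64`; connected dual-strand bases, `2L x 4`), global
#' average pooling reduces each branch to a 512-dimensional feature vector,
#' and the two vectors are concatenated to 1024 dimensions. The head then
#' applies batch normalization, a full connection (rectified-linear) and a
#' second batch normalization before the single sigmoid output unit.
#' Optimization is adaptive-moment (Adam) on binary cross-entropy.
#'
#' Training hyperparameters (batch size, epochs, learning rate, validation
#' split, early-stopping patience) are configuration defaults, not part of
#' the published design.
#'
#' @param kernels_triplet,kernels_base Kernels per convolution branch.
#' @param kernel_len Convolution kernel length (triplets / bases).
#' @param hidden Width of the full-connection layer in the head.
#' @param max_len Scan-window / maximum training fragment length in bp.
#' @param min_len Minimum fragment length in bp.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param val_frac Fraction of the training fragments held out for
#'   validation.
#' @param seed Integer seed governing weight initialization, shuffling and
#'   the validation split.
#' @return A list of class `model_config`.
#' @export
model_config <- function(kernels_triplet = 512L, kernels_base = 512L,
                         kernel_len = 6L, hidden = 1024L,
                         max_len = 400L, min_len = 100L,
                         lr = 1e-3, batch_size = 256L, max_epochs = 50L,
                         patience = 5L, val_frac = 0.1, seed = 1L) {
  cfg <- list(kernels_triplet = as.integer(kernels_triplet),
              kernels_base = as.integer(kernels_base),
              kernel_len = as.integer(kernel_len),
              hidden = as.integer(hidden),
              max_len = as.integer(max_len), min_len = as.integer(min_len),
              lr = lr, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), val_frac = val_frac,
              seed = as.integer(seed))
  if (cfg$kernels_triplet < 1L || cfg$kernels_base < 1L ||
      cfg$kernel_len < 1L || cfg$hidden < 1L) {
    stop("kernel counts, kernel length and hidden width must be positive")
  }
  if (cfg$min_len < cfg$kernel_len * 3L) {
    stop("min_len too small for the kernel length")
  }
  if (cfg$max_len < cfg$min_len) stop("max_len must be >= min_len")
  class(cfg) <- "model_config"
  cfg
}

#' Build an untrained classifier
#'
#' Instantiates the two-branch network of [model_config()] with
#' He-initialized weights (deterministic under the config seed). The merged
#' feature dimension equals the sum of the two branches' kernel counts
#' (1024 under the defaults).
#'
#' @param config A `model_config`.
#' @return An object of class `plastrans_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  params <- withr::with_seed(config$seed, .nn_init_params(config))
  structure(
    list(config = config,
         params = params,
         bn_state = .nn_init_bn_state(config),
         trained = FALSE,
         history = NULL,
         format_version = MODEL_FORMAT_VERSION),
    class = "plastrans_model"
  )
}

#' @export
print.plastrans_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<plastrans_model> %s: %d+%d kernels (len %d), ",
                     "merged dim %d, hidden %d, window %d bp\n"),
              if (x$trained) "trained" else "untrained",
              cfg$kernels_triplet, cfg$kernels_base, cfg$kernel_len,
              cfg$kernels_triplet + cfg$kernels_base, cfg$hidden,
              cfg$max_len))
  invisible(x)
}

#' Merged feature dimension of a model
#' @param model A `plastrans_model`.
#' @return Integer: triplet-branch kernels + base-branch kernels.
#' @export
merged_dim <- function(model) {
  model$config$kernels_triplet + model$config$kernels_base
}

# encode fragments and compute pooling weights for a batch of sequences
.model_batch <- function(sequences, cfg) {
  enc <- .encode_batch_codes(sequences, max_len = cfg$max_len)
  wts <- .batch_window_weights(enc$len, cfg$max_len, cfg$kernel_len)
  list(tcodes = enc$tcodes, bcodes = enc$bcodes,
       wt = wts$wt, wb = wts$wb, len = enc$len)
}

.LABELS <- c("transmissible", "non-transmissible")

#' Train the classifier on labeled fragments
#'
#' Minimizes binary cross-entropy with the adaptive-moment optimizer on
#' minibatches of encoded fragments, holding out a stratified validation
#' split for early stopping; the parameters of the best validation epoch
#' are kept. Deterministic under the config seed at same-machine
#' reproducibility.
#'
#' @param model An untrained (or trained) `plastrans_model`.
#' @param fragments A fragment `data.frame` (columns `sequence`, `label`)
#'   as produced by [extract_fragments()]/[build_benchmark()]. Lengths must
#'   lie within `[min_len, max_len]`.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained model with a `history` data.frame (per-epoch train
#'   and validation loss).
#' @export
train_model <- function(model, fragments, quiet = TRUE) {
  stopifnot(inherits(model, "plastrans_model"))
  cfg <- model$config
  if (!all(fragments$label %in% .LABELS)) {
    stop("fragment labels must be one of: ", paste(.LABELS, collapse = ", "))
  }
  if (length(unique(fragments$label)) < 2L) {
    stop("training data must contain both classes")
  }
  lens <- nchar(fragments$sequence)
  bad <- which(lens < cfg$min_len | lens > cfg$max_len)
  if (length(bad)) {
    stop("fragments out of the ", cfg$min_len, "-", cfg$max_len,
         " bp training range: ",
         paste(utils::head(fragments$fragment_id %||% bad, 5L),
               collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  }
  y_all <- as.numeric(fragments$label == "transmissible")
  batch_all <- .model_batch(fragments$sequence, cfg)

  withr::with_seed(cfg$seed, {
    n <- length(y_all)
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), y_all), function(idx) {
      sample(idx, max(1L, round(cfg$val_frac * length(idx))))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)

    take <- function(idx) list(tcodes = batch_all$tcodes[idx, , drop = FALSE],
                               bcodes = batch_all$bcodes[idx, , drop = FALSE],
                               wt = batch_all$wt[idx, , drop = FALSE],
                               wb = batch_all$wb[idx, , drop = FALSE])
    val_batch <- take(val_idx)
    y_val <- y_all[val_idx]

    params <- model$params
    bn_state <- model$bn_state
    adam <- .nn_adam_init(params)
    Kt <- cfg$kernels_triplet
    best <- list(loss = Inf, params = params, bn_state = bn_state)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    stale <- 0L

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        if (length(idx) < 2L) next  # batch norm needs > 1 example
        mb <- take(idx)
        fw <- .nn_forward(params, bn_state, mb, training = TRUE)
        bn_state <- fw$bn_state
        losses <- c(losses, .nn_bce(fw$score, y_all[idx]))
        grads <- .nn_backward(params, fw$cache, fw$score, y_all[idx], Kt)
        step <- .nn_adam_step(params, grads, adam, lr = cfg$lr)
        params <- step$params
        adam <- step$state
      }
      val_score <- .nn_forward(params, bn_state, val_batch)$score
      val_loss <- .nn_bce(val_score, y_val)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_loss = val_loss))
      if (!quiet) {
        message(sprintf("epoch %d: train loss %.4f, val loss %.4f",
                        epoch, mean(losses), val_loss))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, bn_state = bn_state)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    model$params <- best$params
    model$bn_state <- best$bn_state
    model$trained <- TRUE
    model$history <- history
    model
  })
}

#' Score one scan window
#'
#' Encodes a fragment of at most one scan window and returns the sigmoid
#' output of the network, a likelihood in `(0, 1)` that the fragment derives
#' from a transmissible plasmid.
#'
#' @param model A `plastrans_model`, or a function `sequence -> score` (a
#'   stub scorer, useful for testing the windowing arithmetic in isolation).
#' @param sequence DNA string with length in `[min_len, max_len]`.
#' @return A single score in `(0, 1)`.
#' @export
score_window <- function(model, sequence) {
  if (is.function(model)) return(model(sequence))
  stopifnot(inherits(model, "plastrans_model"))
  cfg <- model$config
  L <- nchar(sequence)
  if (L < cfg$min_len || L > cfg$max_len) {
    stop("window length ", L, " outside [", cfg$min_len, ", ", cfg$max_len, "]")
  }
  .score_batch(model, sequence)
}

# scores for a character vector of window sequences (eval mode)
.score_batch <- function(model, sequences) {
  batch <- .model_batch(sequences, model$config)
  .nn_forward(model$params, model$bn_state, batch)$score
}

# non-overlapping scan windows: full windows of `window` bp left to right;
# a trailing remainder >= min_len is kept as its own short window
.split_windows <- function(L, window, min_len) {
  if (L < min_len) stop("sequence shorter than the minimum window (",
                        min_len, " bp)")
  n_full <- L %/% window
  starts <- window * seq_len(n_full) - window + 1L
  ends <- window * seq_len(n_full)
  rem <- L - n_full * window
  if (rem >= min_len) {
    starts <- c(starts, n_full * window + 1L)
    ends <- c(ends, L)
  }
  data.frame(start = starts, end = ends)
}

#' Score a sequence of arbitrary length by scan-window averaging
#'
#' Moves a non-overlapping scan window of `max_len` bp (400 by default)
#' across the sequence, scores each window independently, and reports the
#' unweighted mean of the window scores; a trailing remainder of at least
#' `min_len` bp is scored as its own short window, shorter remainders are
#' dropped.
#'
#' @param model A `plastrans_model` (or stub scorer function; then windowing
#'   uses 400/100 bp defaults).
#' @param sequence DNA string, length >= `min_len`.
#' @param t Uncertainty threshold in `[0, 0.5)` for the class label.
#' @param sequence_id Identifier.
#' @return An object of class `prediction_record`: list with `sequence_id`,
#'   `score`, `window_scores`, `label`, `threshold_t`, `length`.
#' @export
score_sequence <- function(model, sequence, t = 0, sequence_id = "sequence") {
  cfg <- if (is.function(model)) list(max_len = 400L, min_len = 100L) else {
    stopifnot(inherits(model, "plastrans_model"))
    model$config
  }
  s <- .as_upper_chr(sequence)[1L]
  wins <- .split_windows(nchar(s), cfg$max_len, cfg$min_len)
  pieces <- substring(s, wins$start, wins$end)
  window_scores <- if (is.function(model)) {
    vapply(pieces, model, numeric(1), USE.NAMES = FALSE)
  } else {
    as.numeric(.score_batch(model, pieces))
  }
  score <- mean(window_scores)
  structure(
    list(sequence_id = sequence_id, score = score,
         window_scores = window_scores,
         label = classify_score(score, t), threshold_t = t,
         length = nchar(s)),
    class = "prediction_record"
  )
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> %s (%d bp, %d windows): score %.4f -> %s\n",
              x$sequence_id, x$length, length(x$window_scores), x$score,
              x$label))
  invisible(x)
}

#' Score a set of sequences into a prediction table
#'
#' @param model A `plastrans_model`.
#' @param sequences Named character vector or `DNAStringSet`.
#' @param t Uncertainty threshold in `[0, 0.5)`.
#' @return A `data.frame` with columns `sequence_id`, `length`, `n_windows`,
#'   `score`, `label`.
#' @export
predict_sequences <- function(model, sequences, t = 0) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  seqs <- .as_upper_chr(sequences)
  recs <- lapply(seq_along(seqs), function(i) {
    score_sequence(model, seqs[i], t = t, sequence_id = ids[i])
  })
  data.frame(
    sequence_id = ids,
    length = vapply(recs, `[[`, numeric(1), "length"),
    n_windows = vapply(recs, function(r) length(r$window_scores), numeric(1)),
    score = vapply(recs, `[[`, numeric(1), "score"),
    label = vapply(recs, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
}

#' Turn scores into class labels with an uncertainty band
#'
#' A score is `"uncertain"` when `|score - 0.5| < t`; otherwise
#' `"transmissible"` when strictly above 0.5 and `"non-transmissible"`
#' otherwise (a score of exactly 0.5 at `t = 0` is non-transmissible, since
#' only scores strictly higher than 0.5 are positive).
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param t Uncertainty threshold in `[0, 0.5)`.
#' @return Character vector of labels.
#' @examples
#' classify_score(c(0.9, 0.4664, 0.5), t = 0.05)
#' @export
classify_score <- function(score, t = 0) {
  if (length(t) != 1L || is.na(t) || t < 0 || t >= 0.5) {
    stop("'t' must lie in [0, 0.5)")
  }
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  ifelse(abs(score - 0.5) < t, "uncertain",
         ifelse(score > 0.5, "transmissible", "non-transmissible"))
}

#' Persist a trained model
#'
#' @param model A `plastrans_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plastrans_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a persisted model
#'
#' @param path File written by [save_model()].
#' @return The `plastrans_model`; loading a saved model reproduces its
#'   scores exactly.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': corrupted or not a model",
                                           call. = FALSE))
  if (!inherits(obj, "plastrans_model") ||
      !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("file '", path, "' is not a compatible model artifact ",
         "(format version mismatch)")
  }
  obj
}
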