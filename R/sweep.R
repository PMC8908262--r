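sweep_params <- c("phi", "alpha", "beta", "mu", "output_V_th",
                  "connectivity_rate", "n_train", "n_regions")

# Internal: string keys for overlap detection between train and test images.
dataset_keys <- function(data) {
  vapply(data$images, function(m) paste(as.integer(m), collapse = ","),
         character(1))
}

#' Run a seeded parameter sweep
#'
#' For every grid value and replicate, builds the per-class ensemble with
#' the parameter applied, trains it on the training set, evaluates it on
#' the test set, and records one result row. Sweepable parameters:
#' `phi` (inhibition, turned on when swept), `alpha`, `beta`, `mu`,
#' `output_V_th`, `connectivity_rate`, `n_train` (training samples drawn
#' per class), and `n_regions` (the first k of the eight partition
#' regions, shrinking the first layer to `28 k` neurons).
#'
#' Fully seeded: identical inputs and seed reproduce the result table bit
#' for bit, and each row can be replayed from its recorded seed. Input
#' datasets are never modified.
#'
#' @param param Parameter name, one of the above.
#' @param grid Non-empty vector of parameter values.
#' @param train,test `labeled_dataset`s; they must not share images.
#' @param replicates Replicates per grid value (>= 1).
#' @param net_cfg,plast_cfg,enc_cfg Base configurations.
#' @param epochs Training epochs.
#' @param seed Integer root seed.
#' @param replicates_eval Encoding replicates per test image.
#' @return A `sweep_result` data frame with one row per grid value x
#'   replicate: `param`, `value`, `replicate`, `seed`, `accuracy` (macro),
#'   `micro_accuracy`, `tie_rate`, and one `acc_<class>` column per class.
#'   Provenance (configs, root seed) is attached as an attribute.
#' @export
run_sweep <- function(param, grid, train, test, replicates = 1L,
                      net_cfg = network_config(),
                      plast_cfg = plasticity_config(),
                      enc_cfg = encoding_config(), epochs = 1L, seed = 1L,
                      replicates_eval = 1L) {
  param <- match.arg(param, sweep_params)
  if (!length(grid)) stop("`grid` must be non-empty")
  stopifnot(replicates >= 1)
  if (any(dataset_keys(train) %in% dataset_keys(test)))
    stop("train and test sets share images", call. = FALSE)
  classes <- sort(unique(train$labels))
  pool <- min(table(train$labels))
  if (param == "n_train" && (any(grid < 1) || any(grid > pool)))
    stop(sprintf("`n_train` values must lie in [1, %d] (available per class)", pool))
  if (param == "n_regions" && (any(grid < 1) || any(grid > 8)))
    stop("`n_regions` values must lie in 1..8")

  rows <- vector("list", length(grid) * replicates)
  i <- 0L
  for (vi in seq_along(grid)) {
    v <- grid[vi]
    for (r in seq_len(replicates)) {
      i <- i + 1L
      sd_run <- split_seed(seed, vi * 10000L + r)
      nc <- net_cfg; pc <- plast_cfg; ec <- enc_cfg
      train_use <- train
      switch(param,
        phi = { nc$phi <- v; nc$inhibition <- TRUE },
        alpha = { pc$alpha <- v },
        beta = { pc$beta <- v },
        mu = { pc$mu <- v },
        output_V_th = { nc$output_V_th <- v },
        connectivity_rate = { nc$connectivity_rate <- v },
        n_train = {
          keep <- unlist(lapply(seq_along(classes), function(k) {
            idx <- which(train$labels == classes[k])
            with_seed(split_seed(sd_run, 3L + k), sample(idx, v))
          }))
          train_use <- list(images = train$images[keep],
                            labels = train$labels[keep])
        },
        n_regions = {
          ec <- encoding_config(side = enc_cfg$side, theta = enc_cfg$theta,
                                p_max = enc_cfg$p_max, n_bins = enc_cfg$n_bins,
                                dt_ms = enc_cfg$dt_ms,
                                partition = subset_partition(enc_cfg$partition,
                                                             seq_len(v)))
          nc$n1 <- ec$n1
        })
      ens <- train_ensemble(train_use, net_cfg = nc, plast_cfg = pc,
                            enc_cfg = ec, epochs = epochs,
                            seed = split_seed(sd_run, 1))
      ev <- evaluate_ensemble(test, ens, seed = split_seed(sd_run, 2),
                              replicates = replicates_eval)
      row <- data.frame(param = param, value = v, replicate = r,
                        seed = sd_run, accuracy = ev$accuracy,
                        micro_accuracy = ev$micro_accuracy,
                        tie_rate = ev$ties / ev$n)
      for (k in seq_along(classes))
        row[[paste0("acc_", classes[k])]] <- ev$per_class_accuracy[k]
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(param = param, grid = grid,
                                  replicates = replicates, seed = seed,
                                  net_config = net_cfg,
                                  plast_config = plast_cfg, epochs = epochs)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Accuracy as a function of training-set size
#'
#' Convenience wrapper around [run_sweep()] for the `n_train` parameter:
#' trains the ensemble with the given numbers of samples per class and
#' reports the replicated accuracies.
#'
#' @param sizes Vector of per-class training-set sizes, each >= 1 and at
#'   most the smallest class pool in `train`.
#' @inheritParams run_sweep
#' @return A `sweep_result` data frame (see [run_sweep()]).
#' @export
training_size_curve <- function(sizes, train, test, replicates = 1L,
                                net_cfg = network_config(),
                                plast_cfg = plasticity_config(),
                                enc_cfg = encoding_config(), epochs = 1L,
                                seed = 1L) {
  run_sweep("n_train", sizes, train, test, replicates = replicates,
            net_cfg = net_cfg, plast_cfg = plast_cfg, enc_cfg = enc_cfg,
            epochs = epochs, seed = seed)
}

#' Aggregate a sweep result per grid value
#'
#' @param res A `sweep_result` from [run_sweep()].
#' @return Data frame with one row per grid value: mean accuracy, standard
#'   error, replicate count.
#' @export
summarize_sweep <- function(res) {
  stopifnot(inherits(res, "sweep_result"))
  vals <- unique(res$value)
  out <- do.call(rbind, lapply(vals, function(v) {
    a <- res$accuracy[res$value == v]
    data.frame(value = v, mean_accuracy = mean(a),
               se = if (length(a) > 1) sd(a) / sqrt(length(a)) else NA_real_,
               replicates = length(a))
  }))
  rownames(out) <- NULL
  out
}
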