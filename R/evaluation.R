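# Cross-validation protocol and accuracy summarisation.
#
# The protocol is k-fold cross-validation repeated `reps` times with fresh
# seeded shuffles (10 x 10 by default, giving 100 test sets); per split, a
# CNN is trained from a fresh seeded initialisation on the training-fold
# images and scored on the held-out fold. Image normalisation is per-image
# min-max (trial-local), so no statistic of the training fold leaks into
# test images.

#' Repeated k-fold split indices
#'
#' For each repetition, a fresh seeded shuffle is partitioned into `k`
#' disjoint folds (sizes differing by at most one); each trial appears in
#' exactly one test fold per repetition. When `labels` are supplied the
#' partition is stratified: each class is shuffled and dealt into the folds
#' separately, keeping every training fold's class ratio close to the
#' overall ratio. Stratification matters for the permutation-null check:
#' with unstratified folds a classifier that collapses to the training
#' majority class scores systematically *below* chance on the
#' complementarily imbalanced test fold.
#'
#' @param n Number of trials.
#' @param k Folds per repetition (`n >= k >= 2`).
#' @param reps Repetitions.
#' @param seed Integer seed; identical seeds give identical split lists.
#' @param labels Optional length-`n` class labels for stratified folds.
#' @return List of `k * reps` elements, each `list(train, test, rep, fold)`
#'   of integer index vectors.
#' @export
repeated_kfold <- function(n, k = 10L, reps = 10L, seed = 1L, labels = NULL) {
  if (!is_count(n) || !is_count(k) || n < k || k < 2L)
    stop_input("need n >= k >= 2, got n = %s, k = %s", format(n), format(k))
  if (!is.null(labels) && length(labels) != n)
    stop_input("labels must have length n")
  with_seed(seed, {
    splits <- list()
    for (r in seq_len(reps)) {
      fold_of <- integer(n)
      if (is.null(labels)) {
        fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
      } else {
        offset <- 0L
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          ## rotate the starting fold per class so remainders spread evenly
          fold_of[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
          offset <- offset + length(idx)
        }
      }
      for (f in seq_len(k)) {
        splits[[length(splits) + 1L]] <-
          list(train = which(fold_of != f), test = which(fold_of == f),
               rep = r, fold = f)
      }
    }
    splits
  })
}

#' Alternative protocol: repeated random 90/10 splits
#'
#' Reads "repeated 10 times, 100 test sets" as 100 independent random
#' splits with `1/k` of the trials held out, instead of repeated k-fold
#' partitions. Provided for comparison; repeated k-fold is the default
#' protocol in [evaluate_cv()].
#'
#' @inheritParams repeated_kfold
#' @param n_splits Number of random splits.
#' @return As [repeated_kfold()].
#' @export
random_splits <- function(n, k = 10L, n_splits = 100L, seed = 1L) {
  if (n < k || k < 2L) stop_input("need n >= k >= 2")
  n_test <- max(1L, round(n / k))
  with_seed(seed, lapply(seq_len(n_splits), function(i) {
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test, rep = i, fold = 1L)
  }))
}

#' Cross-validated classification accuracy of the full pipeline
#'
#' Builds the CNN input image for every trial (per-image normalisation),
#' then for every split trains a freshly initialised CNN on the training
#' fold and scores the held-out fold. Folds are stratified by class (see
#' [repeated_kfold()]), which keeps every training fold balanced and the
#' label-permutation null centred on chance. If a training fold still
#' misses a class, that repetition is re-shuffled with a shifted seed.
#'
#' @param epochs An `epoch_set`, or a precomputed list of labelled
#'   `mi_image` objects.
#' @param wavelet A [mother_wavelet()].
#' @param variant Image variant, `"dual"` or `"mu"`.
#' @param cnn A [cnn_config()]; its seed is offset per split so each split
#'   trains from a fresh initialisation.
#' @param k,reps Folds and repetitions.
#' @param seed Seed for the fold shuffles.
#' @param protocol `"kfold"` (repeated k-fold, default) or `"random"`
#'   (independent 90/10-style splits).
#' @param win_s,task_window_s Image construction parameters, see
#'   [build_images()].
#' @return Object of class `cv_result`: `accuracies` (%, one per split),
#'   `mean`, `sd` (population), `n_splits`, `seed`, `config`.
#' @export
evaluate_cv <- function(epochs, wavelet = mother_wavelet("morlet"),
                        variant = c("dual", "mu"), cnn = cnn_config(),
                        k = 10L, reps = 10L, seed = 1L,
                        protocol = c("kfold", "random"),
                        win_s = 0.5, task_window_s = c(0.5, 2.5)) {
  variant <- match.arg(variant)
  protocol <- match.arg(protocol)
  images <- if (inherits(epochs, "epoch_set")) {
    build_images(epochs, wavelet, variant, task_window_s, win_s)
  } else epochs
  labels <- vapply(images, function(im) im$label, "")
  n <- length(images)
  splits <- if (protocol == "kfold") repeated_kfold(n, k, reps, seed, labels)
            else random_splits(n, k, k * reps, seed)
  acc <- numeric(length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tries <- 0L
    while (length(unique(labels[sp$train])) < 2L && tries < 10L) {
      tries <- tries + 1L
      sp <- repeated_kfold(n, k, 1L, seed + 1000L * sp$rep + tries,
                           labels)[[sp$fold]]
    }
    cfg <- cnn
    cfg$seed <- cnn$seed + i
    model <- cnn_train(images[sp$train], labels[sp$train], cfg)
    pred <- predict(model, images[sp$test])
    acc[i] <- 100 * mean(pred$labels == labels[sp$test])
  }
  structure(
    list(accuracies = acc, mean = mean(acc), sd = sd_pop(acc),
         n_splits = length(splits), seed = seed,
         config = list(wavelet = wavelet, variant = variant, cnn = cnn,
                       k = k, reps = reps, protocol = protocol,
                       win_s = win_s, task_window_s = task_window_s)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s/%s, %d splits, accuracy %.1f +/- %.1f %%>\n",
              x$config$wavelet$kind, x$config$variant, x$n_splits,
              x$mean, x$sd))
  invisible(x)
}

#' Summarise cross-validation results across configurations
#'
#' @param results List of `cv_result` objects.
#' @param path Optional path: when given, the table is also written as
#'   tab-separated text.
#' @return `data.frame` with one row per result (wavelet, variant,
#'   mean_accuracy, sd_accuracy, n_splits), ordered by wavelet then
#'   variant.
#' @export
summarize_cv <- function(results, path = NULL) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (length(results) < 1L) stop_input("need at least one cv_result")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(wavelet = r$config$wavelet$kind,
               variant = r$config$variant,
               mean_accuracy = r$mean, sd_accuracy = r$sd,
               n_splits = r$n_splits)))
  df <- df[order(df$wavelet, df$variant), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
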