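# On-disk artifact container and epoch ingestion.
#
# A single JSON container format (schema "micwt/1") holds every artifact
# type: epoch sets, scalograms, images, CNN models and CV results. Numeric
# data are written at full precision (jsonlite digits = NA), so a
# write -> read round trip reproduces arrays bit-exactly, and serialisation
# is deterministic: identical objects give identical bytes.

SCHEMA <- "micwt/1"

enc_mat <- function(m) list(dim = dim(m), data = as.vector(m))
dec_mat <- function(e) {
  d <- as.integer(unlist(e$dim))
  matrix(as.numeric(unlist(e$data)), d[1], d[2])
}
enc_cmat <- function(m) list(dim = dim(m), re = as.vector(Re(m)),
                             im = as.vector(Im(m)))
dec_cmat <- function(e) {
  d <- as.integer(unlist(e$dim))
  matrix(complex(real = as.numeric(unlist(e$re)),
                 imaginary = as.numeric(unlist(e$im))),
         d[1], d[2])
}

container_type <- function(x) {
  if (inherits(x, "epoch_set")) return("epoch_set")
  if (inherits(x, "scalogram")) return("scalograms")
  if (inherits(x, "mi_image")) return("images")
  if (inherits(x, "cnn_model")) return("model")
  if (inherits(x, "cv_result")) return("cv_result")
  if (is.list(x) && length(x) && inherits(x[[1L]], "scalogram")) return("scalograms")
  if (is.list(x) && length(x) && inherits(x[[1L]], "mi_image")) return("images")
  stop_input("no container encoding for class %s", paste(class(x), collapse = "/"))
}

enc_wavelet <- function(w) w[c("kind", "sigma", "mu", "center_freq")]
dec_wavelet <- function(e)
  mother_wavelet(e$kind, sigma = e$sigma,
                 mu = if (is.null(e$mu) || is.na(e$mu)) 5 else e$mu)

encode_payload <- function(x, type) {
  switch(type,
    epoch_set = list(
      seed = x$seed, params = unclass(x$params),
      epochs = lapply(x$epochs, function(ep)
        list(label = ep$label, fs = ep$fs, cue_onset_s = ep$cue_onset_s,
             channels = ep$channels, data = enc_mat(ep$data)))),
    scalograms = {
      if (inherits(x, "scalogram")) x <- list(x)
      list(items = lapply(x, function(sc)
        list(channel = sc$channel, freqs = sc$freqs, times = sc$times,
             fs = sc$fs, grid_spacing = sc$grid_spacing,
             wavelet = enc_wavelet(sc$wavelet),
             coefficients = enc_cmat(sc$coefficients))))
    },
    images = {
      if (inherits(x, "mi_image")) x <- list(x)
      list(items = lapply(x, function(im)
        list(values = enc_mat(im$values), row_map = as.list(im$row_map),
             window = im$window, label = im$label,
             normalized = im$normalized)))
    },
    model = list(
      conv_w = enc_mat(x$conv_w), conv_b = x$conv_b,
      fc_w = enc_mat(x$fc_w), fc_b = x$fc_b,
      config = unclass(x$config), input_dim = x$input_dim,
      conv_len = x$conv_len, pooled_len = x$pooled_len,
      classes = x$classes, loss_history = x$loss_history),
    cv_result = list(
      accuracies = x$accuracies, mean = x$mean, sd = x$sd,
      n_splits = x$n_splits, seed = x$seed,
      config = list(wavelet = enc_wavelet(x$config$wavelet),
                    variant = x$config$variant,
                    cnn = unclass(x$config$cnn),
                    k = x$config$k, reps = x$config$reps,
                    protocol = x$config$protocol,
                    win_s = x$config$win_s,
                    task_window_s = x$config$task_window_s)),
    stop_input("unknown container type %s", type))
}

decode_payload <- function(p, type) {
  switch(type,
    epoch_set = {
      pr <- p$params
      params <- erd_params(fs = pr$fs, duration_s = pr$duration_s,
                           cue_onset_s = pr$cue_onset_s,
                           task_window_s = as.numeric(pr$task_window_s),
                           mu_freq = pr$mu_freq, beta_freq = pr$beta_freq,
                           mu_amp = pr$mu_amp, beta_amp = pr$beta_amp,
                           erd_attenuation = pr$erd_attenuation,
                           ers_rebound = pr$ers_rebound,
                           noise_sigma = pr$noise_sigma, cz_mix = pr$cz_mix)
      epochs <- lapply(p$epochs, function(ep) {
        d <- dec_mat(ep$data)
        colnames(d) <- as.character(ep$channels)
        structure(list(channels = as.character(ep$channels), data = d,
                       fs = ep$fs, label = ep$label,
                       cue_onset_s = ep$cue_onset_s),
                  class = "eeg_epoch")
      })
      structure(list(epochs = epochs, seed = p$seed, params = params),
                class = "epoch_set")
    },
    scalograms = lapply(p$items, function(sc) {
      coef <- dec_cmat(sc$coefficients)
      structure(list(channel = sc$channel, freqs = as.numeric(sc$freqs),
                     times = as.numeric(sc$times), values = abs(coef),
                     coefficients = coef, wavelet = dec_wavelet(sc$wavelet),
                     fs = sc$fs, grid_spacing = sc$grid_spacing),
                class = "scalogram")
    }),
    images = lapply(p$items, function(im) {
      rm_df <- data.frame(electrode = as.character(unlist(im$row_map$electrode)),
                          band = as.character(unlist(im$row_map$band)),
                          frequency = as.numeric(unlist(im$row_map$frequency)))
      img <- new_mi_image(dec_mat(im$values), rm_df,
                          window = as.numeric(unlist(im$window)),
                          label = im$label)
      img$normalized <- isTRUE(im$normalized)
      img
    }),
    model = {
      cfg <- do.call(cnn_config, p$config)
      structure(list(conv_w = dec_mat(p$conv_w),
                     conv_b = as.numeric(p$conv_b),
                     fc_w = dec_mat(p$fc_w), fc_b = as.numeric(p$fc_b),
                     config = cfg, input_dim = as.integer(p$input_dim),
                     conv_len = as.integer(p$conv_len),
                     pooled_len = as.integer(p$pooled_len),
                     classes = as.character(p$classes),
                     loss_history = as.numeric(p$loss_history)),
                class = "cnn_model")
    },
    cv_result = {
      cfgj <- p$config
      structure(list(accuracies = as.numeric(p$accuracies), mean = p$mean,
                     sd = p$sd, n_splits = p$n_splits, seed = p$seed,
                     config = list(wavelet = dec_wavelet(cfgj$wavelet),
                                   variant = cfgj$variant,
                                   cnn = do.call(cnn_config, cfgj$cnn),
                                   k = cfgj$k, reps = cfgj$reps,
                                   protocol = cfgj$protocol,
                                   win_s = cfgj$win_s,
                                   task_window_s = as.numeric(cfgj$task_window_s))),
                class = "cv_result")
    },
    stop_input("unknown container type %s", type))
}

#' Write any artifact to the JSON container format
#'
#' @param x An `epoch_set`, `scalogram` (or list of), `mi_image` (or list
#'   of), `cnn_model` or `cv_result`.
#' @param path Output file path.
#' @param metadata Optional named list embedded alongside the payload
#'   (e.g. the resolved run configuration).
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path, metadata = NULL) {
  type <- container_type(x)
  obj <- list(schema = SCHEMA, type = type,
              metadata = metadata, payload = encode_payload(x, type))
  ## 17 significant digits: lossless (bit-exact) for IEEE doubles
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  tryCatch(writeLines(json, path),
           error = function(e) stop_input("cannot write %s: %s",
                                          path, conditionMessage(e)))
  invisible(path)
}

#' Read an artifact from the JSON container format
#'
#' @param path Container file written by [write_container()].
#' @return The reconstructed object (lists for scalogram/image
#'   collections); the embedded metadata is attached as attribute
#'   `"metadata"`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_input("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  if (!identical(obj$schema, SCHEMA))
    stop_input("%s: unsupported schema %s", path, format(obj$schema))
  out <- decode_payload(obj$payload, obj$type)
  attr(out, "metadata") <- obj$metadata
  out
}

#' @rdname write_container
#' @export
write_epochs <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  write_container(x, path, metadata)
}

#' @rdname write_container
#' @export
write_scalograms <- function(x, path, metadata = NULL) write_container(x, path, metadata)

#' @rdname write_container
#' @export
write_images <- function(x, path, metadata = NULL) write_container(x, path, metadata)

#' @rdname write_container
#' @export
write_model <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "cnn_model"))
  write_container(x, path, metadata)
}

#' Read an epoch set
#'
#' `format = "container"` reads the package's JSON container.
#' `format = "matrix"` reads plain delimited text in long layout with
#' columns `trial, label, channel, sample, value` plus constant columns
#' `fs` and `cue_onset_s`; channels are reordered to C3, Cz, C4 and a
#' missing channel is an explicit error.
#'
#' @param path Input file.
#' @param format `"container"` or `"matrix"`.
#' @return An `epoch_set`. Matrix-format sets get `seed = NA` and default
#'   generator parameters as placeholders (the data are external).
#' @export
read_epochs <- function(path, format = c("container", "matrix")) {
  format <- match.arg(format)
  if (format == "container") {
    out <- read_container(path)
    if (!inherits(out, "epoch_set")) stop_input("%s is not an epoch container", path)
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "label", "channel", "sample", "value", "fs", "cue_onset_s")
  if (!all(need %in% names(df)))
    stop_input("matrix format needs columns: %s", paste(need, collapse = ", "))
  missing_ch <- setdiff(CHANNELS, unique(df$channel))
  if (length(missing_ch))
    stop_input("missing channel(s): %s", paste(missing_ch, collapse = ", "))
  fs <- df$fs[1L]
  epochs <- lapply(split(df, df$trial), function(tr) {
    n <- max(tr$sample)
    m <- matrix(NA_real_, n, 3L, dimnames = list(NULL, CHANNELS))
    for (ch in CHANNELS) {
      sub <- tr[tr$channel == ch, ]
      m[sub$sample, ch] <- sub$value
    }
    if (anyNA(m)) stop_input("trial %s has missing samples", tr$trial[1L])
    structure(list(channels = CHANNELS, data = m, fs = fs,
                   label = tr$label[1L], cue_onset_s = tr$cue_onset_s[1L]),
              class = "eeg_epoch")
  })
  dur <- nrow(epochs[[1L]]$data) / fs
  cue <- epochs[[1L]]$cue_onset_s
  params <- erd_params(fs = fs, duration_s = dur, cue_onset_s = cue,
                       task_window_s = c(0, max(dur - cue, 1 / fs)))
  structure(list(epochs = unname(epochs), seed = NA_integer_, params = params),
            class = "epoch_set")
}

#' Export an epoch set as plain delimited text (long layout)
#'
#' @param x An `epoch_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs_matrix <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  rows <- lapply(seq_along(x$epochs), function(i) {
    ep <- x$epochs[[i]]
    n <- nrow(ep$data)
    data.frame(trial = i, label = ep$label,
               channel = rep(ep$channels, each = n),
               sample = rep(seq_len(n), 3L),
               value = as.vector(ep$data),
               fs = ep$fs, cue_onset_s = ep$cue_onset_s)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export ERD curves as delimited text
#'
#' @param curves Named list of `erd_curve` from [erd_timecourse()].
#' @param path Output TSV path (columns: time, channel, percent).
#' @return `path`, invisibly.
#' @export
write_erd_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(time = cu$times, channel = cu$channel, percent = cu$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
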