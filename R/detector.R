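# CNN "insect" vs "non-insect" classifier over 1-s spectrograms.
# Architecture: conv(16,3x3)+ReLU+BN -> dropout -> conv(32,3x3)+ReLU+BN ->
# maxpool(2x2) -> flatten -> dense(256)+BN+ReLU -> dropout -> dense(1)+sigmoid.
# Loss is binary cross-entropy with the positive class weighted by the
# negative/positive ratio of the training set (no rebalancing of the data).

#' Detector configuration
#'
#' @param conv_filters filters in the two convolutional layers.
#' @param dense_units units in the fully connected layer.
#' @param kernel_size convolution kernel side (square).
#' @param pool_size max-pooling side (square, stride = size).
#' @param dropout_rate dropout rate, applied between the conv blocks and
#'   after the dense block.
#' @param epochs,batch_size,learning_rate Adam training parameters.
#' @param patience early-stopping patience on validation loss.
#' @param augment_prob probability of augmenting a training segment per
#'   epoch.
#' @param class_weighting weight the positive class by the
#'   negative/positive count ratio.
#' @param threshold decision threshold; probability >= threshold is
#'   labeled insect.
#' @return a `detector_config` list.
#' @export
detector_config <- function(conv_filters = c(16L, 32L), dense_units = 256L,
                            kernel_size = 3L, pool_size = 2L,
                            dropout_rate = 0.5, epochs = 10L,
                            batch_size = 32L, learning_rate = 1e-3,
                            patience = 5L, augment_prob = 0.5,
                            class_weighting = TRUE, threshold = 0.5) {
  stopifnot(length(conv_filters) == 2, dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 augment_prob = augment_prob,
                 class_weighting = class_weighting, threshold = threshold),
            class = "detector_config")
}

#' Build an untrained detector
#'
#' Weights are He-initialized from the current RNG stream, so a fixed seed
#' yields a bit-identical model.
#'
#' @param cfg a [detector_config].
#' @param input_shape spectrogram shape (bins, frames); default the
#'   canonical 129 x 32.
#' @return an `insect_detector` (untrained).
#' @export
build_model <- function(cfg = detector_config(), input_shape = c(129L, 32L)) {
  k <- cfg$kernel_size
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  h1 <- input_shape[1] - k + 1L; w1 <- input_shape[2] - k + 1L
  h2 <- h1 - k + 1L; w2 <- w1 - k + 1L
  hp <- h2 %/% cfg$pool_size; wp <- w2 %/% cfg$pool_size
  flat <- hp * wp * f2
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  params <- list(
    W1 = he(k * k, f1, k * k), b1 = rep(0, f1),
    g1 = rep(1, f1), be1 = rep(0, f1),
    W2 = he(k * k * f1, f2, k * k * f1), b2 = rep(0, f2),
    g2 = rep(1, f2), be2 = rep(0, f2),
    W3 = he(flat, cfg$dense_units, flat), b3 = rep(0, cfg$dense_units),
    g3 = rep(1, cfg$dense_units), be3 = rep(0, cfg$dense_units),
    W4 = he(cfg$dense_units, 1L, cfg$dense_units), b4 = 0
  )
  bn <- list(bn1 = bn_init(f1), bn2 = bn_init(f2), bn3 = bn_init(cfg$dense_units))
  structure(list(cfg = cfg, input_shape = as.integer(input_shape),
                 dims = list(h1 = h1, w1 = w1, h2 = h2, w2 = w2,
                             hp = hp, wp = wp, flat = flat),
                 params = params, bn = bn, trained = FALSE, history = NULL),
            class = "insect_detector")
}

#' Number of trainable parameters of a detector
#' @param model an `insect_detector`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.insect_detector <- function(x, ...) {
  cat(sprintf(
    "<insect_detector> %dx%d input, conv(%d)+conv(%d) -> dense(%d), %s, %d parameters\n",
    x$input_shape[1], x$input_shape[2], x$cfg$conv_filters[1],
    x$cfg$conv_filters[2], x$cfg$dense_units,
    if (x$trained) "trained" else "untrained", n_parameters(x)))
  invisible(x)
}

#' Log-compress and max-normalize a magnitude spectrogram for the CNN
#'
#' @param spec magnitude spectrogram matrix.
#' @return matrix of the same shape, `log1p` scaled and divided by its
#'   maximum (all-zero input stays all-zero).
#' @export
preprocess_spectrogram <- function(spec) {
  feat <- log1p(unclass(spec))
  m <- max(feat)
  if (m > 0) feat <- feat / m
  feat
}

# stack a list of preprocessed spectrogram matrices into (H, W, N, 1)
stack_specs <- function(specs, input_shape) {
  N <- length(specs)
  A <- array(0, c(input_shape[1], input_shape[2], N, 1L))
  for (i in seq_len(N)) A[, , i, 1L] <- specs[[i]]
  A
}

detector_forward <- function(model, A, training = FALSE) {
  p <- model$params; d <- model$dims; cfg <- model$cfg
  k <- cfg$kernel_size
  N <- dim(A)[3]                       # layout (H, W, N, C)
  M1 <- im2col(A, k)
  Z1 <- col_add(M1 %*% p$W1, p$b1)
  R1 <- relu(Z1)
  bf1 <- bn_forward(R1, c(model$bn$bn1[c("run_mean", "run_var")],
                          list(gamma = p$g1, beta = p$be1)), training)
  dp1 <- dropout_forward(bf1$Y, cfg$dropout_rate, training)
  A1 <- mat_to_arr(dp1$Y, d$h1, d$w1, N)
  M2 <- im2col(A1, k)
  Z2 <- col_add(M2 %*% p$W2, p$b2)
  R2 <- relu(Z2)
  bf2 <- bn_forward(R2, c(model$bn$bn2[c("run_mean", "run_var")],
                          list(gamma = p$g2, beta = p$be2)), training)
  A2 <- mat_to_arr(bf2$Y, d$h2, d$w2, N)
  pl <- maxpool_forward(A2)
  Xf <- aperm(pl$Y, c(1L, 2L, 4L, 3L))   # (hp, wp, C, N): sample-major flatten
  dim(Xf) <- c(d$flat, N)
  X3 <- t(Xf)
  H <- col_add(X3 %*% p$W3, p$b3)
  bf3 <- bn_forward(H, c(model$bn$bn3[c("run_mean", "run_var")],
                         list(gamma = p$g3, beta = p$be3)), training)
  R3 <- relu(bf3$Y)
  dp2 <- dropout_forward(R3, cfg$dropout_rate, training)
  z <- drop(dp2$Y %*% p$W4) + p$b4
  prob <- sigmoid_(z)
  list(prob = prob,
       cache = list(A = A, M1 = M1, Z1 = Z1, bf1 = bf1, dp1 = dp1, A1 = A1,
                    M2 = M2, Z2 = Z2, bf2 = bf2, pl = pl, X3 = X3, bf3 = bf3,
                    R3 = R3, dp2 = dp2, z = z, N = N),
       bn_updates = list(bn1 = bf1$p[c("run_mean", "run_var")],
                         bn2 = bf2$p[c("run_mean", "run_var")],
                         bn3 = bf3$p[c("run_mean", "run_var")]))
}

detector_backward <- function(model, cache, y, sample_w) {
  p <- model$params; d <- model$dims; cfg <- model$cfg
  k <- cfg$kernel_size
  N <- cache$N
  prob <- sigmoid_(cache$z)
  dz <- sample_w * (prob - y) / N                       # weighted BCE
  dW4 <- crossprod(cache$dp2$Y, dz)
  db4 <- sum(dz)
  dR3 <- matrix(dz, ncol = 1) %*% t(p$W4)
  if (!is.null(cache$dp2$mask)) dR3 <- dR3 * cache$dp2$mask
  dbn3_in <- dR3 * (cache$bf3$Y > 0)
  bb3 <- bn_backward(dbn3_in, list(gamma = p$g3), cache$bf3$cache)
  dH <- bb3$dX
  dW3 <- crossprod(cache$X3, dH)
  db3 <- colSums(dH)
  dX3 <- tcrossprod(dH, p$W3)        # N x flat
  dXf <- t(dX3)
  dim(dXf) <- c(d$hp, d$wp, cfg$conv_filters[2], N)
  dXf <- aperm(dXf, c(1L, 2L, 4L, 3L))   # back to (hp, wp, N, C)
  dA2 <- maxpool_backward(cache$pl, dXf)
  dBN2 <- arr_to_mat(dA2)
  bb2 <- bn_backward(dBN2, list(gamma = p$g2), cache$bf2$cache)
  dZ2 <- bb2$dX * (cache$Z2 > 0)
  dW2 <- crossprod(cache$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- tcrossprod(dZ2, p$W2)
  dA1 <- col2im(dM2, dim(cache$A1), k)
  dDP1 <- arr_to_mat(dA1)
  if (!is.null(cache$dp1$mask)) dDP1 <- dDP1 * cache$dp1$mask
  bb1 <- bn_backward(dDP1, list(gamma = p$g1), cache$bf1$cache)
  dZ1 <- bb1$dX * (cache$Z1 > 0)
  dW1 <- crossprod(cache$M1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       W2 = dW2, b2 = db2, g2 = bb2$dgamma, be2 = bb2$dbeta,
       W3 = dW3, b3 = db3, g3 = bb3$dgamma, be3 = bb3$dbeta,
       W4 = dW4, b4 = db4)
}

weighted_bce <- function(prob, y, sample_w) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  mean(sample_w * -(y * log(prob) + (1 - y) * log(1 - prob)))
}

#' Labeled segment dataset
#'
#' @param segments list of normalized 1-s waveforms (length 4000 each).
#' @param labels integer/logical vector, 1 = insect.
#' @param sensor_ids character vector of source sensors (used to enforce
#'   leakage-free splits).
#' @return a `labeled_segments` object.
#' @export
labeled_segments <- function(segments, labels, sensor_ids) {
  stopifnot(length(segments) == length(labels),
            length(labels) == length(sensor_ids),
            all(nzchar(sensor_ids)))
  structure(list(segments = segments, labels = as.integer(labels),
                 sensor_ids = as.character(sensor_ids)),
            class = "labeled_segments")
}

#' @export
length.labeled_segments <- function(x) length(x$labels)

segments_to_specs <- function(waves) {
  lapply(waves, function(w) preprocess_spectrogram(spectrogram(w)))
}

#' Train the detector
#'
#' Weighted binary cross-entropy (positive weight = #negative/#positive in
#' the training set), Adam, per-epoch stochastic augmentation, early
#' stopping and best-model selection on validation loss. Training and
#' validation sets must come from disjoint sensors.
#'
#' @param model an `insect_detector` from [build_model()].
#' @param train,val [labeled_segments] with disjoint sensor sets.
#' @param noise_bank list of noise waveforms for the real-noise
#'   augmentation (may be empty).
#' @param verbose print per-epoch losses.
#' @return the trained model, with a `history` data frame
#'   (epoch, train_loss, val_loss) and `pos_weight` attached.
#' @export
train_detector <- function(model, train, val, noise_bank = list(),
                           verbose = FALSE) {
  stopifnot(inherits(model, "insect_detector"),
            inherits(train, "labeled_segments"),
            inherits(val, "labeled_segments"))
  overlap <- intersect(unique(train$sensor_ids), unique(val$sensor_ids))
  if (length(overlap) > 0) {
    stop("split leakage: sensor(s) ", paste(overlap, collapse = ", "),
         " appear in both train and validation sets", call. = FALSE)
  }
  cfg <- model$cfg
  n_pos <- sum(train$labels == 1L); n_neg <- sum(train$labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("training set must contain both classes", call. = FALSE)
  }
  pos_weight <- if (cfg$class_weighting) n_neg / n_pos else 1
  if (length(noise_bank) == 0) {
    warning("empty noise bank: real-noise mix augmentation will be skipped",
            call. = FALSE)
  }
  base_specs <- segments_to_specs(train$segments)
  val_specs <- segments_to_specs(val$segments)
  y_val <- val$labels
  w_val <- ifelse(y_val == 1L, pos_weight, 1)
  state <- adam_init(model$params)
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, bn = model$bn)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  n <- length(train)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; epoch_n <- 0L
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
      specs <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        aug <- suppressWarnings(
          augment_segment(train$segments[[i]], noise_bank,
                          p_augment = cfg$augment_prob))
        if (identical(aug, train$segments[[i]])) {
          specs[[j]] <- base_specs[[i]]
        } else {
          specs[[j]] <- preprocess_spectrogram(spectrogram(aug))
        }
      }
      A <- stack_specs(specs, model$input_shape)
      y <- train$labels[idx]
      sw <- ifelse(y == 1L, pos_weight, 1)
      fw <- detector_forward(model, A, training = TRUE)
      for (nm in names(fw$bn_updates)) {
        model$bn[[nm]]$run_mean <- fw$bn_updates[[nm]]$run_mean
        model$bn[[nm]]$run_var <- fw$bn_updates[[nm]]$run_var
      }
      loss <- weighted_bce(fw$prob, y, sw)
      grads <- detector_backward(model, fw$cache, y, sw)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, state, cfg$learning_rate, t_step)
      model$params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + loss * length(idx)
      epoch_n <- epoch_n + length(idx)
    }
    vp <- forward_in_batches(model, val_specs)
    val_loss <- weighted_bce(vp, y_val, w_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / epoch_n,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      epoch_loss / epoch_n, val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = model$params, bn = model$bn)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$trained <- TRUE
  model$history <- history
  model$pos_weight <- pos_weight
  model
}

#' Classify a spectrogram
#'
#' @param model a trained `insect_detector`.
#' @param spec a 129 x 32 magnitude spectrogram (raw, as produced by
#'   [spectrogram()]); preprocessing is applied internally.
#' @param threshold decision threshold; probability >= threshold is
#'   labeled insect (ties at the threshold count as insect).
#' @return list with `probability` and `is_insect`.
#' @export
classify <- function(model, spec, threshold = model$cfg$threshold) {
  stopifnot(inherits(model, "insect_detector"))
  if (!all(dim(spec) == model$input_shape)) {
    stop("spectrogram shape ", paste(dim(spec), collapse = "x"),
         " does not match the model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  }
  prob <- predict_prob(model, list(unclass(spec)))
  list(probability = prob, is_insect = prob >= threshold)
}

# eval-mode probabilities for a list of *preprocessed* spectrograms,
# batched so the im2col temporaries stay small
forward_in_batches <- function(model, specs, batch = 64L) {
  probs <- numeric(length(specs))
  for (bstart in seq(1L, length(specs), by = batch)) {
    idx <- bstart:min(bstart + batch - 1L, length(specs))
    A <- stack_specs(specs[idx], model$input_shape)
    probs[idx] <- detector_forward(model, A, training = FALSE)$prob
  }
  probs
}

#' Batch insect probabilities for a list of spectrograms
#' @param model a trained `insect_detector`.
#' @param specs list of raw magnitude spectrograms.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, specs) {
  forward_in_batches(model, lapply(specs, preprocess_spectrogram))
}

#' Rank-based AUC (Mann-Whitney)
#' @keywords internal
auc_score <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: test set contains a single class", call. = FALSE)
  }
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a detector on a labeled test set
#'
#' @param model a trained `insect_detector`.
#' @param test a [labeled_segments] test set (sensor-disjoint from
#'   training by construction of the split).
#' @param threshold decision threshold for the F1-point metrics.
#' @return list with `auc`, `f1`, `precision`, `recall` and the confusion
#'   counts.
#' @export
evaluate_detector <- function(model, test, threshold = model$cfg$threshold) {
  specs <- lapply(test$segments, function(w) unclass(spectrogram(w)))
  prob <- predict_prob(model, specs)
  metrics_from_scores(prob, test$labels, threshold)
}

#' Classification metrics from scores and labels
#' @param prob numeric scores in \[0, 1\].
#' @param y binary labels.
#' @param threshold decision threshold (>= is positive).
#' @export
metrics_from_scores <- function(prob, y, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(auc = auc_score(prob, y), f1 = f1, precision = precision,
       recall = recall, tp = tp, fp = fp, fn = fn, tn = tn)
}

# ---- checkpoints --------------------------------------------------------

#' Save a detector checkpoint as JSON
#'
#' The package's native checkpoint format: configuration, dimensions,
#' weights and batch-norm running statistics in one JSON document (text,
#' full double precision).
#'
#' @param model an `insect_detector`.
#' @param path output path (`.json`).
#' @export
save_detector <- function(model, path) {
  obj <- list(
    format = "entofield-detector-1",
    cfg = unclass(model$cfg),
    input_shape = model$input_shape,
    trained = model$trained,
    pos_weight = model$pos_weight,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    bn = model$bn
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a detector checkpoint
#' @param path JSON checkpoint written by [save_detector()].
#' @return an `insect_detector`.
#' @export
load_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "entofield-detector-1")) {
    stop("not an entofield detector checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(detector_config, obj$cfg[names(obj$cfg) %in%
                                            names(formals(detector_config))])
  model <- build_model(cfg, input_shape = obj$input_shape)
  model$params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else if (length(p$data) == 1) p$data else as.numeric(p$data)
  })
  model$bn <- lapply(obj$bn, function(b) lapply(b, as.numeric))
  model$trained <- isTRUE(obj$trained)
  model$pos_weight <- obj$pos_weight
  model
}
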