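# Small depthwise convolutional classifier separating sperm whale clicks
# from other transients, and the recall-versus-SNR characterisation that
# feeds the effective-area model. No deep-learning framework ships with the
# analysis environment, so forward, backprop and Adam are implemented here
# with plain matrix algebra; the network is small enough (~11.5k
# parameters) that this trains in seconds.

default_feature_config <- function(fs = 50000) {
  list(clip_ms = 250, n_mels = 64, n_fft = 1024, hop = 512,
       f_lo = 100, f_hi = fs / 2, log_floor = 1e-6)
}

#' Log mel-spectrum features for one clip
#'
#' The clip's overall median is removed after the log, making the
#' features invariant to the absolute recording gain (a global amplitude
#' factor shifts every log-mel cell by the same constant); what remains
#' is the spectro-temporal contrast the classifier needs.
#'
#' @param clip numeric waveform; its length must equal the configured
#'   window (`clip_ms` at `fs`).
#' @param fs sample rate (Hz).
#' @param config feature configuration, see
#'   `stereopam:::default_feature_config()`.
#' @param center subtract the per-clip median (default TRUE).
#' @return `n_mels` x frames matrix of `log10(mel power + floor)`.
#' @export
featurize <- function(clip, fs, config = NULL, center = TRUE) {
  cfg <- if (is.null(config)) default_feature_config(fs) else config
  want <- round(cfg$clip_ms * fs / 1000)
  if (length(clip) != want) {
    stop("clip length ", length(clip), " != configured window ", want)
  }
  sp <- stft_power(clip, fs, cfg$n_fft, cfg$hop)
  fb <- mel_filterbank(cfg$n_mels, cfg$n_fft, fs, cfg$f_lo, cfg$f_hi)
  f <- log10(fb %*% sp$power + cfg$log_floor)
  if (center) f - stats::median(f) else f
}

# ---- network ----------------------------------------------------------------
# input projection (n_mels -> C channels), 3 depthwise temporal conv layers
# of C kernels of size 7 with ReLU, global average pooling, dense sigmoid.

cnn_init <- function(n_mels = 64, channels = 128, kernel = 7, n_layers = 3,
                     seed = 1) {
  set.seed(seed)
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)),
                                     nr, nc)
  list(W0 = he(channels, n_mels, n_mels), b0 = numeric(channels),
       K = lapply(seq_len(n_layers), function(i) he(channels, kernel, kernel)),
       bk = lapply(seq_len(n_layers), function(i) numeric(channels)),
       w = stats::rnorm(channels, 0, sqrt(1 / channels)), b = 0,
       kernel = kernel, n_layers = n_layers, channels = channels,
       n_mels = n_mels)
}

cnn_n_params <- function(par) {
  length(par$W0) + length(par$b0) +
    sum(vapply(par$K, length, numeric(1))) +
    sum(vapply(par$bk, length, numeric(1))) + length(par$w) + 1
}

# block-wise column shift: each clip occupies T consecutive columns;
# shifting never leaks across clip boundaries (zero padding)
shift_blocks <- function(M, s, T) {
  if (s == 0) return(M)
  out <- matrix(0, nrow(M), ncol(M))
  t <- ((seq_len(ncol(M)) - 1) %% T) + 1
  ok <- t + s >= 1 & t + s <= T
  out[, ok] <- M[, which(ok) + s]
  out
}

dw_conv <- function(H, K, T) {
  off <- (ncol(K) + 1) %/% 2
  Z <- matrix(0, nrow(H), ncol(H))
  for (j in seq_len(ncol(K))) {
    Z <- Z + K[, j] * shift_blocks(H, j - off, T)
  }
  Z
}

cnn_forward <- function(par, Xb, T, keep_cache = FALSE) {
  B <- ncol(Xb) / T
  Z0 <- par$W0 %*% Xb + par$b0
  H <- pmax(Z0, 0)
  Zs <- list(); Hs <- list(H)
  for (l in seq_len(par$n_layers)) {
    Z <- dw_conv(H, par$K[[l]], T) + par$bk[[l]]
    H <- pmax(Z, 0)
    Zs[[l]] <- Z; Hs[[l + 1]] <- H
  }
  pooled <- t(rowsum(t(H), group = rep(seq_len(B), each = T))) / T
  u <- as.numeric(crossprod(pooled, par$w)) + par$b
  p <- 1 / (1 + exp(-u))
  if (!keep_cache) return(p)
  list(p = p, u = u, pooled = pooled, Z0 = Z0, Zs = Zs, Hs = Hs, Xb = Xb,
       T = T, B = B)
}

cnn_backward <- function(par, cache, y, wt) {
  T <- cache$T; B <- cache$B
  du <- wt * (cache$p - y) / B
  g <- list(w = as.numeric(cache$pooled %*% du), b = sum(du),
            K = vector("list", par$n_layers),
            bk = vector("list", par$n_layers))
  dH <- (par$w %o% du)[, rep(seq_len(B), each = T)] / T
  off <- (par$kernel + 1) %/% 2
  for (l in rev(seq_len(par$n_layers))) {
    dZ <- dH * (cache$Zs[[l]] > 0)
    g$bk[[l]] <- rowSums(dZ)
    Hprev <- cache$Hs[[l]]
    dK <- matrix(0, par$channels, par$kernel)
    for (j in seq_len(par$kernel)) {
      dK[, j] <- rowSums(dZ * shift_blocks(Hprev, j - off, T))
    }
    g$K[[l]] <- dK
    dHn <- matrix(0, nrow(dZ), ncol(dZ))
    for (j in seq_len(par$kernel)) {
      dHn <- dHn + par$K[[l]][, j] * shift_blocks(dZ, -(j - off), T)
    }
    dH <- dHn
  }
  dZ0 <- dH * (cache$Z0 > 0)
  g$W0 <- dZ0 %*% t(cache$Xb)
  g$b0 <- rowSums(dZ0)
  g
}

adam_new <- function(par) {
  flat <- c("W0", "b0", "w", "b")
  st <- list(t = 0, m = list(), v = list())
  for (nm in flat) { st$m[[nm]] <- par[[nm]] * 0; st$v[[nm]] <- par[[nm]] * 0 }
  st$m$K <- lapply(par$K, function(x) x * 0)
  st$v$K <- lapply(par$K, function(x) x * 0)
  st$m$bk <- lapply(par$bk, function(x) x * 0)
  st$v$bk <- lapply(par$bk, function(x) x * 0)
  st
}

adam_step <- function(par, g, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  upd <- function(p, gr, m, v) {
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    mh <- m / (1 - b1^st$t); vh <- v / (1 - b2^st$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in c("W0", "b0", "w", "b")) {
    r <- upd(par[[nm]], g[[nm]], st$m[[nm]], st$v[[nm]])
    par[[nm]] <- r$p; st$m[[nm]] <- r$m; st$v[[nm]] <- r$v
  }
  for (l in seq_along(par$K)) {
    r <- upd(par$K[[l]], g$K[[l]], st$m$K[[l]], st$v$K[[l]])
    par$K[[l]] <- r$p; st$m$K[[l]] <- r$m; st$v$K[[l]] <- r$v
    r <- upd(par$bk[[l]], g$bk[[l]], st$m$bk[[l]], st$v$bk[[l]])
    par$bk[[l]] <- r$p; st$m$bk[[l]] <- r$m; st$v$bk[[l]] <- r$v
  }
  list(par = par, st = st)
}

#' Train the click classifier
#'
#' Binary classification (sperm whale vs anything else) with a weighted
#' binary cross-entropy loss: sperm whale samples weighted 3, other
#' cetacean transients 10, plain noise 1, compensating class imbalance.
#' Training is deterministic given `seed`.
#'
#' @param clips list of waveform clips (each the configured window
#'   length).
#' @param labels character vector per clip: `"sperm"`, `"cetacean"`, or
#'   `"noise"` (only `"sperm"` is the positive class).
#' @param fs sample rate (Hz).
#' @param seed RNG seed (weights init and batch shuffling).
#' @param epochs,batch_size,lr optimiser settings (Adam).
#' @param channels,kernel,n_layers network size; the default
#'   3 x 128-kernel depthwise design has 11,521 parameters.
#' @param class_weights named loss weights.
#' @param feature_config see [featurize()].
#' @param verbose print per-epoch loss.
#' @return object of class `click_classifier` with elements `par`
#'   (weights), `norm` (feature standardisation), `history` (per-epoch
#'   training loss), `n_params`.
#' @export
train_classifier <- function(clips, labels, fs, seed = 1, epochs = 15,
                             batch_size = 32, lr = 2e-3, channels = 128,
                             kernel = 7, n_layers = 3,
                             class_weights = c(sperm = 3, cetacean = 10,
                                               noise = 1),
                             feature_config = NULL, verbose = FALSE) {
  stopifnot(length(clips) == length(labels))
  y <- as.numeric(labels == "sperm")
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  wt <- unname(class_weights[labels])
  wt[is.na(wt)] <- 1
  cfg <- if (is.null(feature_config)) default_feature_config(fs) else
    feature_config
  feats <- lapply(clips, featurize, fs = fs, config = cfg)
  T <- ncol(feats[[1]])
  Xall <- do.call(cbind, feats)
  mu <- rowMeans(Xall)
  sdv <- pmax(apply(Xall, 1, stats::sd), 1e-6)
  Xall <- (Xall - mu) / sdv
  n <- length(clips)
  par <- cnn_init(cfg$n_mels, channels, kernel, n_layers, seed)
  st <- adam_new(par)
  set.seed(seed + 1)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (bs in seq(1, n, by = batch_size)) {
      ix <- ord[bs:min(n, bs + batch_size - 1)]
      cols <- as.vector(outer(seq_len(T), (ix - 1) * T, "+"))
      Xb <- Xall[, cols, drop = FALSE]
      cache <- cnn_forward(par, Xb, T, keep_cache = TRUE)
      p <- pmin(pmax(cache$p, 1e-12), 1 - 1e-12)
      losses <- c(losses, mean(wt[ix] *
        -(y[ix] * log(p) + (1 - y[ix]) * log(1 - p))))
      g <- cnn_backward(par, cache, y[ix], wt[ix])
      r <- adam_step(par, g, st, lr)
      par <- r$par; st <- r$st
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, history[ep]))
  }
  structure(list(par = par, norm = list(mu = mu, sd = sdv),
                 feature_config = cfg, fs = fs, history = history,
                 n_params = cnn_n_params(par)),
            class = "click_classifier")
}

#' Classifier confidences for clips
#'
#' @param model a trained [train_classifier()] model.
#' @param clips list of waveform clips.
#' @param fs sample rate (must match training).
#' @return numeric vector of confidences in `[0, 1]`.
#' @export
predict_classifier <- function(model, clips, fs = model$fs) {
  cfg <- model$feature_config
  feats <- lapply(clips, featurize, fs = fs, config = cfg)
  T <- ncol(feats[[1]])
  Xb <- (do.call(cbind, feats) - model$norm$mu) / model$norm$sd
  cnn_forward(model$par, Xb, T)
}

#' Save / load classifier weights
#'
#' Portable plain-JSON serialisation of the trained weights.
#' @param model a `click_classifier`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_classifier <- function(model, path) {
  obj <- list(par = model$par, norm = model$norm,
              feature_config = model$feature_config, fs = model$fs,
              history = model$history, n_params = model$n_params)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- obj$par
  par$W0 <- as.matrix(par$W0)
  par$K <- lapply(seq_len(dim(par$K)[1]), function(i) par$K[i, , ])
  par$bk <- lapply(seq_len(dim(par$bk)[1]), function(i) par$bk[i, ])
  par$w <- as.numeric(par$w); par$b <- as.numeric(par$b)
  structure(list(par = par, norm = obj$norm,
                 feature_config = as.list(obj$feature_config), fs = obj$fs,
                 history = obj$history, n_params = obj$n_params),
            class = "click_classifier")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#' @param scores numeric confidences.
#' @param labels 0/1 or logical.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Flag days needing manual validation
#'
#' A day is flagged when it has strictly more than `count_thresh`
#' confidences strictly above `conf_thresh` (the 0.95 / 40 rule).
#'
#' @param confidences data.frame with columns `day` and `confidence`.
#' @param conf_thresh confidence threshold.
#' @param count_thresh count threshold.
#' @return character vector of flagged day identifiers.
#' @export
flag_days <- function(confidences, conf_thresh = 0.95, count_thresh = 40) {
  counts <- tapply(confidences$confidence > conf_thresh,
                   as.character(confidences$day), sum)
  names(counts)[counts > count_thresh]
}

#' Classifier recall as a function of SNR
#'
#' Clean clicks are mixed with ambient-noise clips scaled to target SNRs
#' (2 ms / 6-15 kHz RMS conventions for both click and noise level); the
#' unfiltered mixture is scored by the model, and recall at each SNR is
#' the fraction of confidences above `threshold`.
#'
#' @param model trained classifier.
#' @param clicks list of clean click clips (window length, click near the
#'   centre).
#' @param noises list of noise clips (window length).
#' @param fs sample rate.
#' @param snr_grid_db target SNRs (dB).
#' @param threshold decision threshold (default 0.5; the 0.95 level is
#'   only used for day flagging).
#' @return data.frame `snr_db`, `recall`, `n`.
#' @export
recall_vs_snr <- function(model, clicks, noises, fs,
                          snr_grid_db = seq(-10, 30, by = 2.5),
                          threshold = 0.5) {
  band <- c(6000, 15000)
  click_spl <- vapply(clicks, function(ck) {
    yb <- bandpass(ck, band[1], band[2], fs)
    i <- which.max(abs(yb))
    half <- round(0.001 * fs)
    db(rms(yb[max(1, i - half):min(length(yb), i + half)]))
  }, numeric(1))
  noise_spl <- vapply(noises, function(nz) {
    db(rms(bandpass(nz, band[1], band[2], fs)))
  }, numeric(1))
  rows <- lapply(snr_grid_db, function(snr) {
    mixed <- lapply(seq_along(clicks), function(i) {
      j <- (i - 1) %% length(noises) + 1
      gain_db <- click_spl[i] - noise_spl[j] - snr
      clicks[[i]] + noises[[j]] * 10^(gain_db / 20)
    })
    conf <- predict_classifier(model, mixed, fs)
    data.frame(snr_db = snr, recall = mean(conf > threshold),
               n = length(conf))
  })
  do.call(rbind, rows)
}

#' Fit a sigmoid recall model to (SNR, recall) points
#'
#' Least squares fit of `L / (1 + exp(-k (snr - x0)))`. Flat data (no
#' transition) cannot identify `x0`/`k` and is returned flagged.
#'
#' @param points data.frame with `snr_db` and `recall`.
#' @return a [recall_model()] with attributes `residual_rms` and `flat`.
#' @export
fit_sigmoid <- function(points) {
  stopifnot(all(c("snr_db", "recall") %in% names(points)))
  x <- points$snr_db; r <- points$recall
  if (length(x) < 4) stop("need at least 4 points spanning the transition")
  if (diff(range(r)) < 1e-9) {
    m <- recall_model(L = min(max(mean(r), 1e-6), 1), x0 = min(x), k = 1)
    attr(m, "flat") <- TRUE
    attr(m, "residual_rms") <- 0
    warning("flat recall data: L fixed at the mean, x0/k not identifiable")
    return(m)
  }
  obj <- function(th) {
    L <- th[1]; x0 <- th[2]; k <- th[3]
    if (L <= 0 || L > 1 || k <= 0) return(1e6)
    sum((r - L / (1 + exp(-k * (x - x0))))^2)
  }
  L0 <- min(max(r), 1)
  x00 <- x[which.min(abs(r - L0 / 2))]
  best <- stats::optim(c(L0, x00, 0.5), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  th <- best$par
  m <- recall_model(L = min(th[1], 1), x0 = th[2], k = th[3])
  attr(m, "flat") <- FALSE
  attr(m, "residual_rms") <- sqrt(best$value / length(x))
  m
}

#' Isotonic smoothing of a recall curve
#'
#' Pool-adjacent-violators regression making recall monotone
#' nondecreasing in SNR.
#'
#' @param points data.frame `snr_db`, `recall` (sorted by `snr_db`).
#' @return the points with a `recall_iso` column.
#' @export
isotonic_recall <- function(points) {
  o <- order(points$snr_db)
  fit <- stats::isoreg(points$snr_db[o], points$recall[o])
  points$recall_iso[o] <- fit$yf
  points
}
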