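# Vector-quantised autoencoder over non-overlapping 3D patches.
#
# The encoder/decoder are small MLPs applied per patch (patch size =
# downsample_factor^3), so a volume of H x W x D voxels maps to an
# (H/f) x (W/f) x (D/f) grid of discrete codebook indices. Latents are
# snapped to their nearest codebook vector (straight-through gradient);
# the codebook is updated by EMA (default) or by gradient. A spatial
# dropout layer sits mid-decoder so that repeated decodings of one latent
# grid differ, which supplies the model uncertainty the KDE anomaly maps
# consume. An optional patch discriminator adds an adversarial term.

#' VQ codec configuration
#'
#' @param downsample_factor spatial downsampling per axis (power of 2);
#'   input dims must be divisible by it.
#' @param K codebook vocabulary size (>= 2).
#' @param n_z latent vector length.
#' @param channels hidden width of the per-patch encoder/decoder MLPs.
#' @param dropout_p decoder spatial dropout probability in `[0, 1)`; drives
#'   the decode-time stochasticity used for reconstruction ensembles.
#' @param adversarial add a small patch discriminator during training?
#' @param codebook_update `"ema"` or `"grad"`.
#' @param beta commitment loss weight.
#' @param lr Adam learning rate.
#' @param epochs full-batch training iterations.
#' @param ema_decay EMA decay for codebook updates.
#' @param adv_weight weight of the adversarial generator term.
#' @param seed training seed.
#' @export
codec_config <- function(downsample_factor = 8L, K = 32L, n_z = 8L,
                         channels = 64L, dropout_p = 0.1,
                         adversarial = FALSE,
                         codebook_update = c("ema", "grad"),
                         beta = 0.25, lr = 2e-3, epochs = 150L,
                         ema_decay = 0.99, adv_weight = 0.05, seed = 1L) {
  codebook_update <- match.arg(codebook_update)
  f <- as.integer(downsample_factor)
  if (f < 2L || bitwAnd(f, f - 1L) != 0L)
    stop_("'downsample_factor' must be a power of 2, >= 2")
  if (K < 2L) stop_("'K' must be >= 2")
  if (dropout_p < 0 || dropout_p >= 1) stop_("'dropout_p' must be in [0, 1)")
  structure(list(downsample_factor = f, K = as.integer(K),
                 n_z = as.integer(n_z), channels = as.integer(channels),
                 dropout_p = dropout_p, adversarial = isTRUE(adversarial),
                 codebook_update = codebook_update, beta = beta, lr = lr,
                 epochs = as.integer(epochs), ema_decay = ema_decay,
                 adv_weight = adv_weight, seed = as.integer(seed)),
            class = "codec_config")
}

# volume array -> (n_patches x f^3) matrix, patch order column-major over
# the latent grid (axis 1 fastest), matching array(idx, dim = latent_shape)
extract_patches <- function(arr, f) {
  d <- dim(arr)
  if (any(d %% f != 0L))
    stop_("input dims ", paste(d, collapse = "x"),
          " not divisible by downsample factor ", f, "; pad to ",
          paste(ceiling(d / f) * f, collapse = "x"))
  h <- d %/% f
  dim(arr) <- c(f, h[1], f, h[2], f, h[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  t(matrix(arr, nrow = f^3))
}

assemble_patches <- function(Xp, f, h) {
  arr <- array(t(Xp), dim = c(f, f, f, h))
  arr <- aperm(arr, c(1, 4, 2, 5, 3, 6))
  dim(arr) <- h * f
  arr
}

#' Quantise latent vectors against a codebook
#'
#' Each latent vector is mapped to the index of its nearest codebook vector
#' in Euclidean distance; exact ties go to the lowest index. Indices are
#' 0-based, matching the token ids used by the sequence model.
#'
#' @param latents numeric matrix (rows = latent vectors) or a single vector.
#' @param codebook numeric `K x n_z` matrix of codebook vectors.
#' @return integer vector of 0-based codebook indices.
#' @export
quantize <- function(latents, codebook) {
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1)
  if (!all(is.finite(latents))) stop_("non-finite latent vectors")
  if (ncol(latents) != ncol(codebook))
    stop_("latent length ", ncol(latents), " != codebook n_z ", ncol(codebook))
  K <- nrow(codebook)
  d2 <- matrix(0, nrow(latents), K)
  for (k in seq_len(K))
    d2[, k] <- rowSums(sweep(latents, 2, codebook[k, ])^2)
  max.col(-d2, ties.method = "first") - 1L
}

relu <- function(x) { x[x < 0] <- 0; x }

codec_encode_latents <- function(codec, X) {
  p <- codec$params
  H1 <- relu(sweep(X %*% p$W1, 2, p$b1, `+`))
  sweep(H1 %*% p$W2, 2, p$b2, `+`)
}

codec_decode_patches <- function(codec, Zq, dropout_mask = NULL) {
  p <- codec$params
  G <- relu(sweep(Zq %*% p$W3, 2, p$b3, `+`))
  if (!is.null(dropout_mask)) G <- sweep(G, 2, dropout_mask, `*`)
  sweep(G %*% p$W4, 2, p$b4, `+`)
}

#' Train a VQ codec on a set of volumes
#'
#' Full-batch Adam on reconstruction MSE + commitment loss, with
#' straight-through gradients past the quantiser and EMA (or gradient)
#' codebook updates. Aborts with a diagnostic if the loss goes non-finite.
#'
#' @param volumes list of [volume()]s (>= 2), all the same shape and
#'   modality.
#' @param config a [codec_config()].
#' @return A `vq_codec` with `params`, `codebook` (`K x n_z`), `config`,
#'   `history` (per-epoch mse/mae/commitment/codebook usage), and the
#'   training volumes' `spacing`/`modality`.
#' @export
train_codec <- function(volumes, config) {
  stopifnot(inherits(config, "codec_config"))
  if (length(volumes) < 2L) stop_("need at least 2 training volumes")
  f <- config$downsample_factor
  X <- do.call(rbind, lapply(volumes, function(v) extract_patches(as_volume_data(v), f)))
  P <- f^3; C <- config$channels; nz <- config$n_z; K <- config$K
  N <- nrow(X)
  with_seed(config$seed, {
    params <- list(
      W1 = matrix(rnorm(P * C, 0, sqrt(2 / P)), P, C), b1 = numeric(C),
      W2 = matrix(rnorm(C * nz, 0, sqrt(2 / C)), C, nz), b2 = numeric(nz),
      W3 = matrix(rnorm(nz * C, 0, sqrt(2 / nz)), nz, C), b3 = numeric(C),
      W4 = matrix(rnorm(C * P, 0, sqrt(2 / C)), C, P), b4 = numeric(P))
    codec <- list(params = params)
    Z0 <- codec_encode_latents(codec, X)
    E <- Z0[sample(N, K, replace = N < K), , drop = FALSE] +
      matrix(rnorm(K * nz, 0, 1e-3), K, nz)
    ema_n <- rep(1, K); ema_m <- E
    if (config$adversarial) {
      disc <- list(Wd1 = matrix(rnorm(P * C, 0, sqrt(2 / P)), P, C),
                   bd1 = numeric(C), wd2 = rnorm(C, 0, 0.05), bd2 = 0)
      dst <- adam_state(disc)
    }
    st <- adam_state(params)
    hist <- data.frame(epoch = integer(), mse = numeric(), mae = numeric(),
                       commit = numeric(), usage = numeric())
    for (ep in seq_len(config$epochs)) {
      H1 <- relu(sweep(X %*% params$W1, 2, params$b1, `+`))
      Z <- sweep(H1 %*% params$W2, 2, params$b2, `+`)
      idx <- quantize(Z, E)
      Eq <- E[idx + 1L, , drop = FALSE]
      Zq <- Eq                                  # straight-through input
      drop_mask <- if (config$dropout_p > 0) {
        keep <- rbinom(C, 1, 1 - config$dropout_p)
        keep / (1 - config$dropout_p)
      } else NULL
      G <- relu(sweep(Zq %*% params$W3, 2, params$b3, `+`))
      Gd <- if (is.null(drop_mask)) G else sweep(G, 2, drop_mask, `*`)
      Xr <- sweep(Gd %*% params$W4, 2, params$b4, `+`)
      R <- Xr - X
      mse <- mean(R^2)
      commit <- config$beta * mean((Z - Eq)^2)
      if (!is.finite(mse + commit))
        stop_("non-finite codec loss at epoch ", ep,
              " (mse=", mse, ", commit=", commit, "); lower lr")
      # ---- backward ----
      dXr <- 2 * R / length(R)
      if (config$adversarial) {
        hD_f <- relu(sweep(Xr %*% disc$Wd1, 2, disc$bd1, `+`))
        lg_f <- drop(hD_f %*% disc$wd2) + disc$bd2
        p_f <- 1 / (1 + exp(-lg_f))
        dlg <- config$adv_weight * (p_f - 1) / N
        dhD <- outer(dlg, disc$wd2); dhD[hD_f <= 0] <- 0
        dXr <- dXr + dhD %*% t(disc$Wd1)
      }
      g <- list()
      g$W4 <- t(Gd) %*% dXr; g$b4 <- colSums(dXr)
      dGd <- dXr %*% t(params$W4)
      dG <- if (is.null(drop_mask)) dGd else sweep(dGd, 2, drop_mask, `*`)
      dG[G <= 0] <- 0
      g$W3 <- t(Zq) %*% dG; g$b3 <- colSums(dG)
      dZq <- dG %*% t(params$W3)
      dZ <- dZq + config$beta * 2 * (Z - Eq) / length(Z)
      g$W2 <- t(H1) %*% dZ; g$b2 <- colSums(dZ)
      dH1 <- dZ %*% t(params$W2); dH1[H1 <= 0] <- 0
      g$W1 <- t(X) %*% dH1; g$b1 <- colSums(dH1)
      upd <- adam_step(params, g, st, config$lr)
      params <- upd$P; st <- upd$st
      # ---- codebook update ----
      cnt <- tabulate(idx + 1L, nbins = K)
      sums <- matrix(0, K, nz)
      agg <- rowsum(Z, group = idx)
      sums[as.integer(rownames(agg)) + 1L, ] <- agg
      if (config$codebook_update == "ema") {
        ema_n <- config$ema_decay * ema_n + (1 - config$ema_decay) * cnt
        ema_m <- config$ema_decay * ema_m + (1 - config$ema_decay) * sums
        upd_rows <- ema_n > 1e-6
        E[upd_rows, ] <- ema_m[upd_rows, , drop = FALSE] / ema_n[upd_rows]
      } else {
        dE <- 2 * (E * cnt - sums) / length(Z)
        E <- E - 10 * config$lr * dE
      }
      if (config$adversarial) {
        # discriminator step on real vs (detached) fake patches
        dg <- list(Wd1 = 0 * disc$Wd1, bd1 = 0 * disc$bd1,
                   wd2 = 0 * disc$wd2, bd2 = 0)
        for (pass in 1:2) {
          Xin <- if (pass == 1) X else Xr
          lab <- if (pass == 1) 1 else 0
          hD <- relu(sweep(Xin %*% disc$Wd1, 2, disc$bd1, `+`))
          lg <- drop(hD %*% disc$wd2) + disc$bd2
          pr <- 1 / (1 + exp(-lg))
          dlg <- (pr - lab) / (2 * N)
          dg$wd2 <- dg$wd2 + drop(t(hD) %*% dlg); dg$bd2 <- dg$bd2 + sum(dlg)
          dhD <- outer(dlg, disc$wd2); dhD[hD <= 0] <- 0
          dg$Wd1 <- dg$Wd1 + t(Xin) %*% dhD; dg$bd1 <- dg$bd1 + colSums(dhD)
        }
        dupd <- adam_step(disc, dg, dst, config$lr)
        disc <- dupd$P; dst <- dupd$st
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, mse = mse, mae = mean(abs(R)), commit = commit,
        usage = length(unique(idx)) / K))
    }
    structure(list(params = params, codebook = E, config = config,
                   history = hist,
                   spacing = if (inherits(volumes[[1]], "vq_volume"))
                     volumes[[1]]$spacing else c(1, 1, 1),
                   modality = if (inherits(volumes[[1]], "vq_volume"))
                     volumes[[1]]$modality else "functional"),
              class = "vq_codec")
  })
}

#' @export
print.vq_codec <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<vq_codec> %s, f=%d, K=%d, n_z=%d; final mae %.4f, ",
                     "codebook usage %.0f%%\n"),
              x$modality, x$config$downsample_factor, x$config$K,
              x$config$n_z, h$mae, 100 * h$usage))
  invisible(x)
}

#' Encode a volume to a latent index grid
#'
#' @param v a [volume()] (or bare 3D array) with dims divisible by the
#'   codec's downsample factor.
#' @param codec a trained [train_codec()] model.
#' @return A `latent_grid`: integer 3D array of 0-based codebook indices
#'   with attribute `K`.
#' @export
encode <- function(v, codec) {
  stopifnot(inherits(codec, "vq_codec"))
  arr <- as_volume_data(v)
  f <- codec$config$downsample_factor
  X <- extract_patches(arr, f)
  idx <- quantize(codec_encode_latents(codec, X), codec$codebook)
  structure(array(idx, dim = dim(arr) %/% f),
            K = codec$config$K, class = "latent_grid")
}

#' Decode a latent index grid to a volume
#'
#' With `dropout_on = TRUE` a fresh spatial dropout mask (seeded) is applied
#' mid-decoder, so different seeds give different reconstructions of the
#' same latent grid; with `dropout_on = FALSE` decoding is deterministic.
#'
#' @param g a `latent_grid` (from [encode()] or [derasterize()]).
#' @param codec the matching trained codec.
#' @param dropout_on apply decoder dropout?
#' @param seed dropout seed (required for reproducible stochastic decodes).
#' @return A [volume()]; functional outputs are clamped at 0.
#' @export
decode <- function(g, codec, dropout_on = FALSE, seed = NULL) {
  stopifnot(inherits(codec, "vq_codec"))
  idx <- as.vector(g)
  K <- codec$config$K
  if (any(idx < 0L | idx >= K))
    stop_("latent index out of range [0, ", K, ")")
  h <- dim(g)
  Zq <- codec$codebook[idx + 1L, , drop = FALSE]
  drop_mask <- NULL
  if (dropout_on && codec$config$dropout_p > 0) {
    drop_mask <- with_seed(seed, {
      keep <- rbinom(codec$config$channels, 1, 1 - codec$config$dropout_p)
      keep / (1 - codec$config$dropout_p)
    })
  }
  Xp <- codec_decode_patches(codec, Zq, drop_mask)
  arr <- assemble_patches(Xp, codec$config$downsample_factor, h)
  if (codec$modality == "functional") arr[arr < 0] <- 0
  volume(arr, spacing = codec$spacing, modality = codec$modality)
}

#' Save / load a codec checkpoint
#'
#' The checkpoint is a single archive holding weights, codebook and config;
#' reloading reproduces [encode()]/[decode()] outputs bit-exactly.
#'
#' @param codec a `vq_codec`.
#' @param path checkpoint file path.
#' @return `load_codec` returns the `vq_codec`.
#' @export
save_codec <- function(codec, path) {
  stopifnot(inherits(codec, "vq_codec"))
  saveRDS(codec, path)
  invisible(path)
}

#' @rdname save_codec
#' @export
load_codec <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "vq_codec")) stop_("'", path, "' is not a codec checkpoint")
  x
}

# flat-list Adam used by both the codec and the sequence model
adam_state <- function(P) {
  list(m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0),
       t = 0L)
}

adam_step <- function(P, G, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(P)) {
    g <- G[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(P = P, st = st)
}
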