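# Autoregressive transformer over latent token sequences.
#
# A pre-norm transformer (RMSNorm) with causal self-attention, an optional
# cross-attention block after each self-attention layer that reads the full
# anatomical token sequence (no causal mask on the conditioning stream),
# and a position-wise feed-forward block. A begin-of-sequence token with id
# K primes generation. Forward and backward passes are written directly in
# matrix algebra and verified against numerical gradients in the test
# suite; exact softmax attention is the reference implementation.

#' Sequence model configuration
#'
#' @param K functional codebook vocabulary size; token ids are `0..K-1` and
#'   the begin-of-sequence token has id `K`.
#' @param layers number of transformer layers.
#' @param heads attention heads; must divide `width`.
#' @param width model width (embedding dimension).
#' @param ffn_mult feed-forward hidden width as a multiple of `width`.
#' @param conditional include cross-attention over an anatomical token
#'   sequence after each self-attention layer, giving
#'   `p(s_i | s_<i, c)` instead of `p(s_i | s_<i)`?
#' @param cond_K anatomical codebook vocabulary size (conditional models).
#' @param max_len,cond_len maximum functional / conditioning sequence
#'   lengths (positional-embedding tables).
#' @param attention `"exact"` softmax attention (the reference); linear
#'   attention approximations are not implemented.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   (not embeddings, gains or biases) after each Adam step, as a multiple
#'   of `lr`; regularises against overfitting small training sets.
#' @param seed training seed.
#' @export
lm_config <- function(K, layers = 2L, heads = 2L, width = 32L, ffn_mult = 2L,
                      conditional = FALSE, cond_K = NULL, max_len = 160L,
                      cond_len = max_len, attention = c("exact", "favor_plus"),
                      lr = 3e-3, epochs = 30L, weight_decay = 0, seed = 1L) {
  attention <- match.arg(attention)
  if (attention != "exact")
    stop_("only exact softmax attention is implemented; ",
          "linear-attention approximation is not available")
  if (width %% heads != 0L) stop_("'width' must be divisible by 'heads'")
  if (conditional && is.null(cond_K))
    stop_("conditional models need 'cond_K'")
  structure(list(K = as.integer(K), layers = as.integer(layers),
                 heads = as.integer(heads), width = as.integer(width),
                 ffn_mult = as.integer(ffn_mult),
                 conditional = isTRUE(conditional),
                 cond_K = if (is.null(cond_K)) NULL else as.integer(cond_K),
                 max_len = as.integer(max_len + 1L),
                 cond_len = as.integer(cond_len),
                 attention = attention, lr = lr,
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "lm_config")
}

rms_fwd <- function(x, g) {
  r <- sqrt(rowMeans(x^2) + 1e-6)
  list(y = (x / r) * rep(g, each = nrow(x)), r = r)
}

rms_bwd <- function(dy, x, g, r) {
  d <- ncol(x)
  gx_dy <- dy * rep(g, each = nrow(x))
  list(dg = colSums(dy * x / r),
       dx = gx_dy / r - x * (rowSums(gx_dy * x) / (d * r^3)))
}

attn_fwd <- function(qin, kvin, Wq, Wk, Wv, Wo, heads, causal) {
  d <- ncol(qin); dh <- d %/% heads; isd <- 1 / sqrt(dh)
  Q <- qin %*% Wq; Km <- kvin %*% Wk; Vm <- kvin %*% Wv
  L <- nrow(qin)
  O <- matrix(0, L, d); A <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(Km[, cols, drop = FALSE])) * isd
    if (causal) S[upper.tri(S)] <- -Inf
    Ah <- row_softmax(S)
    A[[h]] <- Ah
    O[, cols] <- Ah %*% Vm[, cols, drop = FALSE]
  }
  list(out = O %*% Wo, Q = Q, K = Km, V = Vm, A = A, O = O)
}

attn_bwd <- function(dout, cc, qin, kvin, Wq, Wk, Wv, Wo, heads) {
  d <- ncol(qin); dh <- d %/% heads; isd <- 1 / sqrt(dh)
  dWo <- t(cc$O) %*% dout
  dO <- dout %*% t(Wo)
  L <- nrow(qin); Lk <- nrow(kvin)
  dQ <- matrix(0, L, d); dK <- matrix(0, Lk, d); dV <- matrix(0, Lk, d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cc$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dAh <- dOh %*% t(cc$V[, cols, drop = FALSE])
    dV[, cols] <- t(Ah) %*% dOh
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) * isd
    dK[, cols] <- (t(dS) %*% cc$Q[, cols, drop = FALSE]) * isd
  }
  list(dWq = t(qin) %*% dQ, dWk = t(kvin) %*% dK, dWv = t(kvin) %*% dV,
       dWo = dWo,
       dq_in = dQ %*% t(Wq),
       dkv = dK %*% t(Wk) + dV %*% t(Wv))
}

init_lm_params <- function(cfg) {
  d <- cfg$width
  mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  P <- list(tok = mat(cfg$K + 1L, d, 0.02),
            pos = mat(cfg$max_len, d, 0.02),
            gf = rep(1, d),
            Wout = matrix(0, d, cfg$K), bout = numeric(cfg$K))
  if (cfg$conditional) {
    P$cemb <- mat(cfg$cond_K, d, 0.02)
    P$cpos <- mat(cfg$cond_len, d, 0.02)
  }
  sa <- 1 / sqrt(d)
  for (l in seq_len(cfg$layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    P[[nm("g1")]] <- rep(1, d)
    P[[nm("Wq")]] <- mat(d, d, sa); P[[nm("Wk")]] <- mat(d, d, sa)
    P[[nm("Wv")]] <- mat(d, d, sa)
    P[[nm("Wo")]] <- mat(d, d, sa / sqrt(2 * cfg$layers))
    if (cfg$conditional) {
      P[[nm("gx")]] <- rep(1, d)
      P[[nm("Wq2")]] <- mat(d, d, sa); P[[nm("Wk2")]] <- mat(d, d, sa)
      P[[nm("Wv2")]] <- mat(d, d, sa)
      P[[nm("Wo2")]] <- mat(d, d, sa / sqrt(2 * cfg$layers))
    }
    P[[nm("g2")]] <- rep(1, d)
    dff <- cfg$ffn_mult * d
    P[[nm("W1")]] <- mat(d, dff, sqrt(2 / d)); P[[nm("b1")]] <- numeric(dff)
    P[[nm("W2")]] <- mat(dff, d, sqrt(1 / dff) / sqrt(2 * cfg$layers))
    P[[nm("b2")]] <- numeric(d)
  }
  P
}

.lm_fwd <- function(P, cfg, ids0, cond0 = NULL, keep = FALSE) {
  L <- length(ids0)
  if (L > cfg$max_len)
    stop_("sequence length ", L, " exceeds context window ", cfg$max_len)
  if (cfg$conditional && is.null(cond0))
    stop_("conditional model requires a conditioning sequence")
  if (!cfg$conditional && !is.null(cond0))
    stop_("unconditional model given a conditioning sequence")
  ids1 <- as.integer(ids0) + 1L
  x <- P$tok[ids1, , drop = FALSE] + P$pos[seq_len(L), , drop = FALSE]
  C <- NULL; cond1 <- NULL
  if (cfg$conditional) {
    Lc <- length(cond0)
    if (Lc > cfg$cond_len)
      stop_("conditioning length ", Lc, " exceeds ", cfg$cond_len)
    cond1 <- as.integer(cond0) + 1L
    C <- P$cemb[cond1, , drop = FALSE] + P$cpos[seq_len(Lc), , drop = FALSE]
  }
  cache <- if (keep) list(ids1 = ids1, cond1 = cond1, L = L, C = C,
                          layers = vector("list", cfg$layers)) else NULL
  for (l in seq_len(cfg$layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    a0 <- x
    n1 <- rms_fwd(a0, P[[nm("g1")]])
    sa <- attn_fwd(n1$y, n1$y, P[[nm("Wq")]], P[[nm("Wk")]], P[[nm("Wv")]],
                   P[[nm("Wo")]], cfg$heads, causal = TRUE)
    a1 <- a0 + sa$out
    if (cfg$conditional) {
      nx <- rms_fwd(a1, P[[nm("gx")]])
      ca <- attn_fwd(nx$y, C, P[[nm("Wq2")]], P[[nm("Wk2")]], P[[nm("Wv2")]],
                     P[[nm("Wo2")]], cfg$heads, causal = FALSE)
      a2 <- a1 + ca$out
    } else {
      nx <- NULL; ca <- NULL; a2 <- a1
    }
    n2 <- rms_fwd(a2, P[[nm("g2")]])
    Hpre <- sweep(n2$y %*% P[[nm("W1")]], 2, P[[nm("b1")]], `+`)
    Hf <- relu(Hpre)
    ff <- sweep(Hf %*% P[[nm("W2")]], 2, P[[nm("b2")]], `+`)
    x <- a2 + ff
    if (keep)
      cache$layers[[l]] <- list(a0 = a0, n1 = n1, sa = sa, a1 = a1, nx = nx,
                                ca = ca, a2 = a2, n2 = n2, Hf = Hf)
  }
  nf <- rms_fwd(x, P$gf)
  logits <- sweep(nf$y %*% P$Wout, 2, P$bout, `+`)
  if (keep) { cache$xfinal <- x; cache$nf <- nf }
  list(logits = logits, cache = cache)
}

.lm_bwd <- function(P, cfg, cache, dlogits) {
  G <- list()
  G$Wout <- t(cache$nf$y) %*% dlogits
  G$bout <- colSums(dlogits)
  rb <- rms_bwd(dlogits %*% t(P$Wout), cache$xfinal, P$gf, cache$nf$r)
  G$gf <- rb$dg
  dx <- rb$dx
  dC <- if (cfg$conditional) 0 * cache$C else NULL
  for (l in rev(seq_len(cfg$layers))) {
    nm <- function(s) paste0("L", l, ".", s)
    cl <- cache$layers[[l]]
    dff <- dx
    G[[nm("W2")]] <- t(cl$Hf) %*% dff; G[[nm("b2")]] <- colSums(dff)
    dHf <- dff %*% t(P[[nm("W2")]]); dHf[cl$Hf <= 0] <- 0
    G[[nm("W1")]] <- t(cl$n2$y) %*% dHf; G[[nm("b1")]] <- colSums(dHf)
    rb2 <- rms_bwd(dHf %*% t(P[[nm("W1")]]), cl$a2, P[[nm("g2")]], cl$n2$r)
    G[[nm("g2")]] <- rb2$dg
    da2 <- dx + rb2$dx
    if (cfg$conditional) {
      ab <- attn_bwd(da2, cl$ca, cl$nx$y, cache$C, P[[nm("Wq2")]],
                     P[[nm("Wk2")]], P[[nm("Wv2")]], P[[nm("Wo2")]],
                     cfg$heads)
      G[[nm("Wq2")]] <- ab$dWq; G[[nm("Wk2")]] <- ab$dWk
      G[[nm("Wv2")]] <- ab$dWv; G[[nm("Wo2")]] <- ab$dWo
      dC <- dC + ab$dkv
      rbx <- rms_bwd(ab$dq_in, cl$a1, P[[nm("gx")]], cl$nx$r)
      G[[nm("gx")]] <- rbx$dg
      da1 <- da2 + rbx$dx
    } else {
      da1 <- da2
    }
    sb <- attn_bwd(da1, cl$sa, cl$n1$y, cl$n1$y, P[[nm("Wq")]],
                   P[[nm("Wk")]], P[[nm("Wv")]], P[[nm("Wo")]], cfg$heads)
    G[[nm("Wq")]] <- sb$dWq; G[[nm("Wk")]] <- sb$dWk
    G[[nm("Wv")]] <- sb$dWv; G[[nm("Wo")]] <- sb$dWo
    rb1 <- rms_bwd(sb$dq_in + sb$dkv, cl$a0, P[[nm("g1")]], cl$n1$r)
    G[[nm("g1")]] <- rb1$dg
    dx <- da1 + rb1$dx
  }
  G$tok <- matrix(0, nrow(P$tok), ncol(P$tok))
  agg <- rowsum(dx, group = cache$ids1)
  G$tok[as.integer(rownames(agg)), ] <- agg
  G$pos <- matrix(0, nrow(P$pos), ncol(P$pos))
  G$pos[seq_len(cache$L), ] <- dx
  if (cfg$conditional) {
    G$cemb <- matrix(0, nrow(P$cemb), ncol(P$cemb))
    agg <- rowsum(dC, group = cache$cond1)
    G$cemb[as.integer(rownames(agg)), ] <- agg
    G$cpos <- matrix(0, nrow(P$cpos), ncol(P$cpos))
    G$cpos[seq_len(nrow(dC)), ] <- dC
  }
  G
}

# one teacher-forced step: loss and (optionally) gradients for sequence s0
lm_step <- function(P, cfg, s0, cond0 = NULL, grad = TRUE) {
  L0 <- length(s0)
  if (any(s0 < 0L | s0 >= cfg$K)) stop_("token id out of range [0, K)")
  ids0 <- c(cfg$K, if (L0 > 1L) s0[seq_len(L0 - 1L)] else integer(0))
  fw <- .lm_fwd(P, cfg, ids0, cond0, keep = grad)
  logp <- fw$logits - row_logsumexp(fw$logits)
  tgt <- cbind(seq_len(L0), s0 + 1L)
  loss <- -mean(logp[tgt])
  if (!grad) return(list(loss = loss, logp = logp))
  Pr <- exp(logp)
  dlog <- Pr / L0
  dlog[tgt] <- dlog[tgt] - 1 / L0
  list(loss = loss, logp = logp, G = .lm_bwd(P, cfg, fw$cache, dlog))
}

#' Train the latent sequence model
#'
#' Maximises the autoregressive log-likelihood of the training token
#' sequences (teacher forcing, per-sequence Adam steps). Conditional models
#' receive the spatially aligned anatomical token sequence of each sample.
#'
#' @param seqs list of equal-length integer token sequences (0-based ids in
#'   `[0, K)`, no begin-of-sequence token).
#' @param conds `NULL`, or a list of anatomical token sequences parallel to
#'   `seqs` (required iff `config$conditional`).
#' @param config an [lm_config()].
#' @param val_seqs,val_conds optional held-out sequences; when supplied,
#'   validation NLL is tracked per epoch and the returned model carries the
#'   parameters of the best validation epoch (early stopping), which guards
#'   the larger conditional models against overfitting small training sets.
#' @return A `latent_lm` with `params`, `config`, `history` (per-epoch mean
#'   training NLL per token) and, with validation data, `val_history` and
#'   `best_epoch`.
#' @export
train_lm <- function(seqs, conds = NULL, config, val_seqs = NULL,
                     val_conds = NULL) {
  stopifnot(inherits(config, "lm_config"))
  if (length(unique(lengths(seqs))) != 1L)
    stop_("all training sequences must have equal length")
  if (config$conditional && (is.null(conds) || length(conds) != length(seqs)))
    stop_("conditional training needs one conditioning sequence per sample")
  if (!config$conditional) { conds <- NULL; val_conds <- NULL }
  eval_nll <- function(P, ss, cc) {
    tot <- 0
    for (i in seq_along(ss))
      tot <- tot + lm_step(P, config, ss[[i]],
                           if (is.null(cc)) NULL else cc[[i]],
                           grad = FALSE)$loss
    tot / length(ss)
  }
  wd <- config$weight_decay %||% 0
  with_seed(config$seed, {
    P <- init_lm_params(config)
    decay_nms <- names(P)[vapply(names(P), function(nm)
      is.matrix(P[[nm]]) && grepl("W", nm, fixed = TRUE), NA)]
    shrink <- 1 - config$lr * wd
    st <- adam_state(P)
    nll <- numeric(config$epochs)
    vnll <- if (is.null(val_seqs)) NULL else numeric(config$epochs)
    best <- list(nll = Inf, P = P, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(seqs))
      tot <- 0
      for (i in ord) {
        r <- lm_step(P, config, seqs[[i]],
                     if (is.null(conds)) NULL else conds[[i]])
        if (!is.finite(r$loss))
          stop_("non-finite NLL at epoch ", ep, " (sequence ", i,
                "); lower lr")
        tot <- tot + r$loss
        upd <- adam_step(P, r$G, st, config$lr)
        P <- upd$P; st <- upd$st
        if (wd > 0)
          for (nm in decay_nms) P[[nm]] <- P[[nm]] * shrink
      }
      nll[ep] <- tot / length(seqs)
      if (!is.null(val_seqs)) {
        vnll[ep] <- eval_nll(P, val_seqs, val_conds)
        if (vnll[ep] < best$nll)
          best <- list(nll = vnll[ep], P = P, epoch = ep)
      }
    }
    if (!is.null(val_seqs)) P <- best$P
    structure(list(params = P, config = config, history = nll,
                   val_history = vnll,
                   best_epoch = if (is.null(val_seqs)) length(nll)
                                else best$epoch),
              class = "latent_lm")
  })
}

#' @export
print.latent_lm <- function(x, ...) {
  cat(sprintf("<latent_lm> %s, %d layers x %d heads, width %d, K=%d; NLL %.3f -> %.3f\n",
              if (x$config$conditional) "conditional" else "unconditional",
              x$config$layers, x$config$heads, x$config$width, x$config$K,
              x$history[1], x$history[length(x$history)]))
  invisible(x)
}

#' Distribution of the next token given a prefix
#'
#' @param prefix integer vector of observed tokens (0-based, possibly
#'   empty); the begin-of-sequence token is supplied internally.
#' @param cond anatomical token sequence (conditional models only).
#' @param lm a trained [train_lm()] model.
#' @return Probability vector over the `K` codebook tokens (sums to 1).
#' @export
next_token_distribution <- function(prefix, cond = NULL, lm) {
  cfg <- lm$config
  if (length(prefix) && any(prefix < 0L | prefix >= cfg$K))
    stop_("token id out of range [0, K)")
  ids0 <- c(cfg$K, as.integer(prefix))
  fw <- .lm_fwd(lm$params, cfg, ids0, cond, keep = FALSE)
  lg <- fw$logits[nrow(fw$logits), ]
  p <- exp(lg - max(lg))
  p / sum(p)
}

#' Per-position likelihood of an observed token sequence
#'
#' Teacher-forced evaluation of `p(s_i | s_<i)` (or `p(s_i | s_<i, c)` for
#' conditional models) in a single forward pass; exactly equal to scoring
#' each position with [next_token_distribution()] on its prefix.
#'
#' @param s integer token sequence (0-based, no begin-of-sequence token).
#' @param cond anatomical token sequence (conditional models only).
#' @param lm a trained model.
#' @return Numeric vector of per-position probabilities in `(0, 1]`.
#' @export
sequence_likelihoods <- function(s, cond = NULL, lm) {
  cfg <- lm$config
  r <- lm_step(lm$params, cfg, as.integer(s), cond, grad = FALSE)
  p <- exp(r$logp[cbind(seq_along(s), as.integer(s) + 1L)])
  pmax(p, 1e-300)
}

#' Mean held-out negative log-likelihood per token
#'
#' @param lm a trained model.
#' @param seqs list of token sequences.
#' @param conds optional parallel list of conditioning sequences.
#' @return Mean NLL per token across the dataset.
#' @export
lm_nll <- function(lm, seqs, conds = NULL) {
  tot <- 0
  for (i in seq_along(seqs))
    tot <- tot + lm_step(lm$params, lm$config, seqs[[i]],
                         if (is.null(conds)) NULL else conds[[i]],
                         grad = FALSE)$loss
  tot / length(seqs)
}

#' Save / load a sequence-model checkpoint
#'
#' @param lm a `latent_lm`.
#' @param path checkpoint file path.
#' @return `load_lm` returns the `latent_lm`; reloading reproduces
#'   likelihoods bit-exactly.
#' @export
save_lm <- function(lm, path) {
  stopifnot(inherits(lm, "latent_lm"))
  saveRDS(lm, path)
  invisible(path)
}

#' @rdname save_lm
#' @export
load_lm <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "latent_lm")) stop_("'", path, "' is not an lm checkpoint")
  x
}
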