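# Likelihood-based token healing.
#
# A latent grid is flattened by a fixed 3D raster scan, scored by the
# sequence model, and every position whose likelihood falls below the
# threshold t is flagged in a resampling mask. Flagged tokens are then
# replaced left-to-right by draws from the model's multinomial at that
# position (the edited prefix feeds later predictions); the mask itself is
# frozen from the initial scoring pass. Repeating the resampling and
# decoding with dropout yields a reconstruction ensemble.

#' Flatten a latent grid to a token sequence (3D raster scan)
#'
#' The raster order is fixed: axis 1 slowest, axis 3 fastest, i.e. the
#' grid `g[i, j, k]` is read with `k` varying fastest. [derasterize()]
#' inverts it exactly.
#'
#' @param g a `latent_grid` (integer 3D array).
#' @return Integer token vector of length `prod(dim(g))` with attribute
#'   `shape` recording the grid dimensions.
#' @export
rasterize <- function(g) {
  stopifnot(length(dim(g)) == 3L)
  s <- as.vector(aperm(unclass(g), c(3, 2, 1)))
  structure(as.integer(s), shape = dim(g))
}

#' @rdname rasterize
#' @param s integer token sequence.
#' @param shape integer length-3 latent grid dimensions.
#' @export
derasterize <- function(s, shape = attr(s, "shape")) {
  if (is.null(shape)) stop_("'shape' must be given")
  if (length(s) != prod(shape))
    stop_("sequence length ", length(s), " != prod(shape) = ", prod(shape))
  g <- aperm(array(as.integer(s), dim = rev(shape)), c(3, 2, 1))
  structure(g, class = "latent_grid")
}

#' Binary resampling mask from a likelihood profile
#'
#' Position `i` is flagged for healing iff `p[i] < t` (strict inequality),
#' so `t = 0` flags nothing and masks are nested in `t`.
#'
#' @param lp numeric likelihood profile from [sequence_likelihoods()].
#' @param t likelihood threshold in `[0, 1]`; the pipeline default is 0.01.
#' @return Logical vector with attribute `threshold_used`.
#' @export
resampling_mask <- function(lp, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    stop_("'t' must be a single probability in [0, 1]")
  structure(as.vector(lp) < t, threshold_used = t)
}

#' Heal a token sequence by multinomial resampling
#'
#' Flagged positions are replaced left-to-right by draws from the model's
#' full-vocabulary multinomial at that position (temperature 1); positions
#' after a replacement therefore condition on the edited prefix. Unflagged
#' positions pass through bit-identically.
#'
#' @param s integer token sequence (0-based).
#' @param mask logical resampling mask, same length as `s`.
#' @param cond anatomical token sequence (conditional models only).
#' @param lm a trained [train_lm()] model.
#' @param seed RNG seed; fixed seed gives an identical healed sequence.
#' @return Healed integer token sequence (attributes of `s` preserved).
#' @export
heal_sequence <- function(s, mask, cond = NULL, lm, seed = NULL) {
  if (length(mask) != length(s))
    stop_("mask length ", length(mask), " != sequence length ", length(s))
  out <- as.integer(s)
  flagged <- which(mask)
  if (!length(flagged)) return(structure(out, shape = attr(s, "shape")))
  with_seed(seed, {
    for (i in flagged) {
      p <- next_token_distribution(out[seq_len(i - 1L)], cond, lm)
      out[i] <- sample.int(length(p), 1L, prob = p) - 1L
    }
  })
  structure(out, shape = attr(s, "shape"))
}

#' Generate a healed reconstruction ensemble
#'
#' Encodes the functional volume once, scores it once (so the resampling
#' mask is shared by all members), then draws `n` healed sequences and
#' decodes each with a fresh decoder-dropout mask. The members are the KDE
#' sample set for [kde_anomaly_map()].
#'
#' @param x functional [volume()].
#' @param ct anatomical [volume()] (required iff `lm` is conditional).
#' @param codec functional-volume codec.
#' @param ct_codec anatomical-volume codec (conditional models only).
#' @param lm trained sequence model.
#' @param t likelihood threshold for the resampling mask (default 0.01).
#' @param n ensemble size (>= 2; default 16).
#' @param seed base seed; member k heals with seed `seed + 2k` and decodes
#'   with dropout seed `seed + 2k + 1`.
#' @return A `recon_ensemble`: `members` (list of n volumes),
#'   `healed_sequences`, `mask`, `likelihoods`, `seeds`, and the single
#'   deterministic `base_reconstruction` (no healing, no dropout).
#' @export
generate_ensemble <- function(x, ct = NULL, codec, ct_codec = NULL, lm,
                              t = 0.01, n = 16L, seed = 1L) {
  if (n < 2L) stop_("'n' must be >= 2 for ensemble use")
  if (lm$config$conditional && (is.null(ct) || is.null(ct_codec)))
    stop_("conditional model requires 'ct' and 'ct_codec'")
  g <- encode(x, codec)
  s <- rasterize(g)
  cond <- if (lm$config$conditional) rasterize(encode(ct, ct_codec)) else NULL
  lp <- sequence_likelihoods(s, cond, lm)
  mask <- resampling_mask(lp, t)
  seeds <- as.integer(seed) + 2L * seq_len(n)
  healed <- vector("list", n)
  members <- vector("list", n)
  for (k in seq_len(n)) {
    healed[[k]] <- heal_sequence(s, mask, cond, lm, seed = seeds[k])
    members[[k]] <- decode(derasterize(healed[[k]], dim(g)), codec,
                           dropout_on = TRUE, seed = seeds[k] + 1L)
  }
  structure(list(members = members, healed_sequences = healed,
                 mask = mask, likelihoods = lp, seeds = seeds,
                 tokens = s, cond = cond,
                 base_reconstruction = decode(g, codec)),
            class = "recon_ensemble")
}

#' @export
print.recon_ensemble <- function(x, ...) {
  cat(sprintf("<recon_ensemble> n=%d members, %d/%d tokens flagged (t=%g)\n",
              length(x$members), sum(x$mask), length(x$mask),
              attr(x$mask, "threshold_used")))
  invisible(x)
}

#' Single healed reconstruction
#'
#' The residual-map route: encode, score, heal once, decode without
#' dropout.
#'
#' @inheritParams generate_ensemble
#' @return A list with `reconstruction` ([volume()]), `healed`, `mask`,
#'   `likelihoods`, `tokens`.
#' @export
healed_reconstruction <- function(x, ct = NULL, codec, ct_codec = NULL, lm,
                                  t = 0.01, seed = 1L) {
  if (lm$config$conditional && (is.null(ct) || is.null(ct_codec)))
    stop_("conditional model requires 'ct' and 'ct_codec'")
  g <- encode(x, codec)
  s <- rasterize(g)
  cond <- if (lm$config$conditional) rasterize(encode(ct, ct_codec)) else NULL
  lp <- sequence_likelihoods(s, cond, lm)
  mask <- resampling_mask(lp, t)
  healed <- heal_sequence(s, mask, cond, lm, seed = seed)
  list(reconstruction = decode(derasterize(healed, dim(g)), codec),
       healed = healed, mask = mask, likelihoods = lp, tokens = s,
       cond = cond)
}
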