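# Segmentation and evaluation.
#
# Anomaly maps become binary segmentations by thresholding (scores >= tau);
# the clinical 40%-of-maximum rule then grows every connected component to
# include all voxels reachable through intensities >= 0.4 x that
# component's maximum uptake. Evaluation reports Dice, the best achievable
# Dice over a threshold grid (an upper bound on segmentation performance),
# AUPRC (robust under the extreme class imbalance of lesion voxels), and
# paired t-tests between methods.

neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  man <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = man == 1L, "18" = man <= 2L, "26" = rep(TRUE, 26L),
                 stop_("'connectivity' must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# vectorised BFS frontier expansion from linear seed indices through the
# logical array `allowed`; returns linear indices of the reached region
flood_from <- function(seed_idx, allowed, off) {
  dims <- dim(allowed)
  reached <- array(FALSE, dims)
  reached[seed_idx] <- TRUE
  frontier <- arrayInd(seed_idx, dims)
  m <- nrow(off)
  while (nrow(frontier) > 0L) {
    n <- nrow(frontier)
    cand <- frontier[rep(seq_len(n), times = m), , drop = FALSE] +
      off[rep(seq_len(m), each = n), , drop = FALSE]
    ok <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
      cand[, 2] >= 1L & cand[, 2] <= dims[2] &
      cand[, 3] >= 1L & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) break
    lin <- cand[, 1] + dims[1] * ((cand[, 2] - 1L) + dims[2] * (cand[, 3] - 1L))
    lin <- unique(lin)
    lin <- lin[allowed[lin] & !reached[lin]]
    if (!length(lin)) break
    reached[lin] <- TRUE
    frontier <- arrayInd(lin, dims)
  }
  which(reached)
}

#' Label connected components of a binary 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (full neighbourhood,
#'   the default used throughout the pipeline).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as_mask(mask)
  off <- neighbor_offsets(connectivity)
  lab <- array(0L, dim(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    comp <- flood_from(start, mask & (lab == 0L), off)
    lab[comp] <- cur
  }
  lab
}

as_mask <- function(x) {
  if (inherits(x, "seg_mask")) return(x$mask)
  if (is.logical(x)) return(x)
  array(as.logical(x), dim(x))
}

new_seg_mask <- function(mask, connectivity = 26L) {
  structure(list(mask = mask, connectivity = as.integer(connectivity)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d positive, connectivity %d\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              x$connectivity))
  invisible(x)
}

#' Threshold an anomaly map into a segmentation
#'
#' Voxels with `scores >= tau` are segmented (ties at the threshold are
#' included).
#'
#' @param m an `anomaly_map` (or bare array).
#' @param tau threshold.
#' @param connectivity component connectivity recorded on the mask.
#' @return A `seg_mask`.
#' @export
threshold_map <- function(m, tau, connectivity = 26L) {
  sc <- map_scores(m)
  if (!all(is.finite(sc))) stop_("anomaly map contains non-finite scores")
  new_seg_mask(sc >= tau, connectivity)
}

#' Grow segmentations to the clinical 40%-of-maximum contour
#'
#' For each connected component of the segmentation, all voxels reachable
#' from it through functional intensities `>= frac * max(pet within the
#' component)` are absorbed; each component uses its own maximum. The rule
#' is applied to a fixed point, so the result is idempotent and always a
#' superset of the input.
#'
#' @param seg a `seg_mask` (or logical array).
#' @param pet the functional [volume()] the intensities come from.
#' @param frac fraction of the component maximum (clinical standard 0.4).
#' @param connectivity neighbourhood used for components and growing;
#'   defaults to the mask's own connectivity (26 for arrays).
#' @param strict use `>` instead of the default boundary-including `>=`.
#' @return A `seg_mask` containing the input.
#' @export
grow_to_clinical <- function(seg, pet, frac = 0.4, connectivity = NULL,
                             strict = FALSE) {
  conn <- connectivity %||%
    (if (inherits(seg, "seg_mask")) seg$connectivity else 26L)
  cur <- as_mask(seg)
  petd <- as_volume_data(pet)
  if (!identical(dim(cur), dim(petd))) stop_("segmentation/PET shape mismatch")
  if (!any(cur)) return(new_seg_mask(cur, conn))
  off <- neighbor_offsets(conn)
  repeat {
    lab <- label_components(cur, conn)
    nc <- max(lab)
    new <- cur
    for (k in seq_len(nc)) {
      comp <- which(lab == k)
      thr <- frac * max(petd[comp])
      allowed <- if (strict) petd > thr else petd >= thr
      allowed[comp] <- TRUE              # output always contains the input
      new[flood_from(comp, allowed, off)] <- TRUE
    }
    if (identical(new, cur)) break
    cur <- new
  }
  new_seg_mask(cur, conn)
}

#' Dice similarity coefficient
#'
#' `2|a n b| / (|a| + |b|)`; two empty masks score 1 (needed for
#' lesion-free cases).
#'
#' @param a,b binary masks (`seg_mask` or logical arrays), same shape.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop_("mask shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

dice_grid <- function(scores, taus, truth, grow, pet, connectivity, frac) {
  if (!grow) {
    return(vapply(taus, function(tau) dice(scores >= tau, truth),
                  numeric(1)))
  }
  # growing only enlarges a mask, so dice after growing is bounded by
  # 2|T| / (|M| + |T|); taus whose bound cannot beat the best dice found
  # so far (descending tau = smallest masks first) are pruned exactly
  d <- numeric(length(taus))
  o <- order(taus, decreasing = TRUE)
  nt <- sum(truth)
  best <- -Inf
  for (i in o) {
    m <- scores >= taus[i]
    bound <- 2 * nt / (sum(m) + nt)
    if (nt > 0L && bound < best - 1e-12) {
      d[i] <- bound
      next
    }
    if (any(m))
      m <- grow_to_clinical(m, pet, frac = frac,
                            connectivity = connectivity)$mask
    d[i] <- dice(m, truth)
    best <- max(best, d[i])
  }
  d
}

# candidate thresholds: all distinct values when few, else quantiles
# log-spaced toward the upper tail -- anomalous voxels are rare, so the
# operative segmentation thresholds sit in the top percentiles of a map
threshold_grid <- function(vals, grid_size) {
  u <- sort(unique(vals))
  if (length(u) <= grid_size) return(u)
  probs <- c(0, 1 - 10^seq(log10(0.5), log10(1 / length(vals)),
                           length.out = grid_size - 1L))
  unique(stats::quantile(vals, probs = probs, names = FALSE, type = 7))
}

#' Best achievable Dice over a threshold grid
#'
#' Greedy search for the segmentation threshold maximising Dice against the
#' ground truth: a theoretical upper bound on the map's segmentation
#' performance. The grid is all distinct map values when few, otherwise
#' `grid_size` quantile-spaced points; ties go to the lowest threshold.
#'
#' @param m an `anomaly_map` (or array).
#' @param truth ground-truth binary mask.
#' @param grid_size number of candidate thresholds (>= 2).
#' @param grow apply [grow_to_clinical()] after thresholding?
#' @param pet functional volume (required when `grow = TRUE`).
#' @param connectivity component connectivity.
#' @param frac growing fraction (0.4).
#' @return List with `tau`, `dice`, and the searched `taus`/`dices`.
#' @export
best_dice <- function(m, truth, grid_size = 200L, grow = FALSE, pet = NULL,
                      connectivity = 26L, frac = 0.4) {
  if (grid_size < 2L) stop_("'grid_size' must be >= 2")
  if (grow && is.null(pet)) stop_("'pet' needed when grow = TRUE")
  sc <- map_scores(m)
  truth <- as_mask(truth)
  taus <- threshold_grid(as.vector(sc), grid_size)
  d <- dice_grid(sc, taus, truth, grow, pet, connectivity, frac)
  i <- which.max(d)                      # first max = lowest tau on ties
  list(tau = taus[i], dice = d[i], taus = taus, dices = d)
}

#' Best shared threshold across an evaluation set
#'
#' Searches one threshold over the pooled quantile grid of all maps and
#' returns the per-sample Dice at the threshold maximising the mean: the
#' evaluation-set analogue of [best_dice()].
#'
#' @param maps list of anomaly maps (one per sample).
#' @param truths parallel list of ground-truth masks.
#' @param pets parallel list of functional volumes (when `grow = TRUE`).
#' @inheritParams best_dice
#' @return List with `tau`, mean `dice`, and `per_sample` Dice at `tau`.
#' @export
best_dice_set <- function(maps, truths, grid_size = 200L, grow = FALSE,
                          pets = NULL, connectivity = 26L, frac = 0.4) {
  stopifnot(length(maps) == length(truths))
  if (grow && is.null(pets)) stop_("'pets' needed when grow = TRUE")
  pooled <- unlist(lapply(maps, function(m) as.vector(map_scores(m))))
  taus <- threshold_grid(pooled, grid_size)
  D <- vapply(seq_along(maps), function(i) {
    dice_grid(map_scores(maps[[i]]), taus, as_mask(truths[[i]]), grow,
              if (grow) pets[[i]] else NULL, connectivity, frac)
  }, numeric(length(taus)))
  D <- matrix(D, nrow = length(taus))
  mean_d <- rowMeans(D)
  i <- which.max(mean_d)
  list(tau = taus[i], dice = mean_d[i], per_sample = D[i, ])
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over all distinct score thresholds (average
#' precision): `sum((R_k - R_{k-1}) * P_k)` with thresholds descending.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param m anomaly map (or numeric scores).
#' @param truth binary ground truth with at least one positive voxel.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(m, truth) {
  s <- as.vector(map_scores(m))
  y <- as.vector(as_mask(truth))
  if (length(s) != length(y)) stop_("score/truth length mismatch")
  if (!any(y)) stop_("ground truth has no positive voxels; AUPRC undefined")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one operating point per value
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Paired t-test between per-sample metrics of two methods
#'
#' Classical paired t statistic with a two-sided Student-t p-value on
#' `n - 1` degrees of freedom. Zero-variance differences are reported as a
#' degenerate case rather than silently producing NaN.
#'
#' @param scores_a,scores_b equal-length per-sample metric vectors, paired
#'   by sample.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop_("paired vectors must have equal length")
  n <- length(scores_a)
  if (n < 2L) stop_("need at least 2 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p = if (all(d == 0)) 1 else 0,
                df = n - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = n - 1L,
       mean_diff = mean(d), degenerate = FALSE)
}
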