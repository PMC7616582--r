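# Synthetic paired PET/CT phantoms.
#
# The generator emulates the statistical situation the anomaly-detection
# method assumes: a body envelope visible in both modalities; physiological
# hotspots (heart / kidneys / bladder analogues) whose position is explained
# by the anatomical channel; and lesion hotspots placed independently of
# anatomy, present in the functional channel only. Training sets may be
# lesion-contaminated, which is the regime of interest.

.organ_templates <- list(
  list(name = "heart",    centre = c(0.50, 0.38, 0.30), semi = c(0.14, 0.14, 0.10), uptake_frac = 0.55),
  list(name = "kidney_l", centre = c(0.30, 0.60, 0.52), semi = c(0.10, 0.10, 0.09), uptake_frac = 0.75),
  list(name = "kidney_r", centre = c(0.70, 0.60, 0.52), semi = c(0.10, 0.10, 0.09), uptake_frac = 0.75),
  list(name = "bladder",  centre = c(0.50, 0.55, 0.82), semi = c(0.11, 0.11, 0.08), uptake_frac = 0.92),
  list(name = "liver",    centre = c(0.34, 0.42, 0.40), semi = c(0.15, 0.12, 0.09), uptake_frac = 0.08),
  list(name = "spleen",   centre = c(0.68, 0.42, 0.42), semi = c(0.09, 0.09, 0.07), uptake_frac = 0.25)
)

#' Phantom generator configuration
#'
#' @param shape integer length-3 grid size; all dims >= 8.
#' @param n_organs number of physiological hotspot organs (0..6), drawn from
#'   a fixed template list (heart, kidneys, bladder, liver, spleen analogues)
#'   with per-sample jitter in position and size.
#' @param lesion_rate expected number of lesions per sample (Poisson mean);
#'   0 gives lesion-free phantoms.
#' @param lesion_intensity_range lesion intensity as multiples of the
#'   background (soft-tissue) uptake, `c(lo, hi)`.
#' @param physiological_intensity_range range of organ uptake as multiples
#'   of background, `c(lo, hi)`; each organ sits at its own characteristic
#'   level within the range (bladder highest, liver lowest), jittered per
#'   sample.
#' @param noise_sd additive Gaussian noise SD (intensity units), applied
#'   inside the body envelope and truncated at 0 for the functional channel.
#' @param background_uptake baseline functional intensity of soft tissue.
#' @param spacing voxel size in mm.
#' @param seed default generation seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32L, 32L, 64L), n_organs = 3L,
                           lesion_rate = 2,
                           lesion_intensity_range = c(3, 5),
                           physiological_intensity_range = c(4, 8),
                           noise_sd = 0.02,
                           background_uptake = 0.1,
                           spacing = c(2, 2, 3),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_("'shape' must be 3 integers, all >= 8")
  if (n_organs < 0L || n_organs > length(.organ_templates))
    stop_("'n_organs' must be between 0 and ", length(.organ_templates))
  if (lesion_rate < 0) stop_("'lesion_rate' must be >= 0")
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop_("'", nm, "' must be c(lo, hi) with lo <= hi")
  }
  chk_range(lesion_intensity_range, "lesion_intensity_range")
  chk_range(physiological_intensity_range, "physiological_intensity_range")
  if (noise_sd < 0) stop_("'noise_sd' must be >= 0")
  structure(list(shape = shape, n_organs = as.integer(n_organs),
                 lesion_rate = lesion_rate,
                 lesion_intensity_range = lesion_intensity_range,
                 physiological_intensity_range = physiological_intensity_range,
                 noise_sd = noise_sd,
                 background_uptake = background_uptake,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_config")
}

ellipsoid_mask <- function(shape, centre, semi) {
  x2 <- ((seq_len(shape[1]) - centre[1]) / semi[1])^2
  y2 <- ((seq_len(shape[2]) - centre[2]) / semi[2])^2
  z2 <- ((seq_len(shape[3]) - centre[3]) / semi[3])^2
  outer(outer(x2, y2, `+`), z2, `+`) <= 1
}

#' Generate one paired functional/anatomical phantom
#'
#' Deterministic in `(config, seed)`. The anatomical channel shows air (0),
#' a soft-tissue body ellipsoid, and one distinct density per organ; the
#' functional channel shows baseline uptake inside the body, elevated uptake
#' in every organ (co-located with its anatomical density), and spherical
#' lesions (radius 1--4 voxels) placed uniformly inside the body, rejected
#' if they touch an organ, visible in the functional channel only.
#'
#' @param config a [phantom_config()].
#' @param seed generation seed (defaults to `config$seed`).
#' @return A `phantom_sample`: `pet`, `ct` ([volume()]s), `lesion_mask`
#'   (logical array), `organ_labels` (integer array, 0 = none), `organs` and
#'   `lesions` placement records, `seed`.
#' @export
generate_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  b <- config$background_uptake
  with_seed(seed, {
    body_centre <- (shape + 1) / 2
    body_semi <- c(0.42, 0.42, 0.47) * shape
    body <- ellipsoid_mask(shape, body_centre, body_semi)
    ct0 <- array(0, shape); ct0[body] <- 0.30
    pet0 <- array(0, shape); pet0[body] <- b
    labels <- array(0L, shape)
    organs <- list()
    for (i in seq_len(config$n_organs)) {
      tpl <- .organ_templates[[i]]
      centre <- (tpl$centre + runif(3, -0.12, 0.12)) * shape
      semi <- tpl$semi * runif(3, 0.8, 1.2) * shape
      if (any(semi < 1))
        stop_("shape ", paste(shape, collapse = "x"),
              " too small to place organ '", tpl$name,
              "' (semi-axes below one voxel)")
      m <- ellipsoid_mask(shape, centre, semi) & body
      # each organ has a characteristic uptake level within the configured
      # range (tracer pooling differs by organ), with per-sample jitter --
      # so physiological hotspot appearance is explicable from anatomy
      pr <- config$physiological_intensity_range
      frac <- min(max(tpl$uptake_frac + runif(1, -0.08, 0.08), 0), 1)
      uptake <- pr[1] + frac * (pr[2] - pr[1])
      pet0[m] <- b * uptake
      ct0[m] <- 0.45 + 0.07 * i
      labels[m] <- i
      organs[[i]] <- list(name = tpl$name, centre = centre, semi = semi,
                          uptake = uptake, label = i)
    }
    lesion_mask <- array(FALSE, shape)
    lesions <- list()
    n_les <- if (config$lesion_rate > 0) rpois(1, config$lesion_rate) else 0L
    body_idx <- which(body)
    for (j in seq_len(n_les)) {
      for (try in 1:60) {
        r <- sample(1:4, 1)
        centre <- as.numeric(arrayInd(sample(body_idx, 1), shape))
        sph <- ellipsoid_mask(shape, centre, rep(r + 0.01, 3))
        if (!any(sph)) next
        if (any(sph & !body)) next            # must sit inside the body
        if (any(labels[sph] != 0L)) next      # not explained by anatomy
        mult <- runif(1, config$lesion_intensity_range[1],
                      config$lesion_intensity_range[2])
        pet0[sph] <- b * mult
        lesion_mask <- lesion_mask | sph
        lesions[[length(lesions) + 1L]] <-
          list(centre = centre, radius = r, intensity = b * mult)
        break
      }
    }
    pet <- pet0; ct <- ct0
    if (config$noise_sd > 0) {
      nb <- sum(body)
      pet[body] <- pmax(pet[body] + rnorm(nb, 0, config$noise_sd), 0)
      ct[body] <- pmax(ct[body] + rnorm(nb, 0, config$noise_sd), 0)
    }
    structure(list(
      pet = volume(pet, config$spacing, "functional"),
      ct = volume(ct, config$spacing, "anatomical"),
      lesion_mask = lesion_mask, organ_labels = labels,
      body = body, organs = organs, lesions = lesions,
      seed = as.integer(seed)), class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s voxels, %d organs, %d lesions (%d voxels), seed %d\n",
              paste(dim(x$pet$data), collapse = "x"), length(x$organs),
              length(x$lesions), sum(x$lesion_mask), x$seed))
  invisible(x)
}

#' Generate train/validation/test phantom splits
#'
#' Seeds are disjoint across splits and across samples, so two calls with
#' the same arguments give identical datasets. With
#' `contaminate_train = FALSE` the training split is generated with
#' `lesion_rate = 0` (the classical healthy-training regime); the default
#' keeps lesions in the training data, which is the regime this method is
#' designed to tolerate.
#'
#' @param config a [phantom_config()].
#' @param n_train,n_val,n_test split sizes (all >= 1); defaults mirror a
#'   60/11/12 whole-body study design.
#' @param contaminate_train keep lesions in the training split?
#' @param seed base seed; per-sample seeds are `seed + 0:(n-1)` laid out
#'   consecutively across splits.
#' @return A `phantom_dataset` list with `train`, `val`, `test` lists of
#'   [generate_phantom()] samples.
#' @export
make_dataset <- function(config, n_train = 60L, n_val = 11L, n_test = 12L,
                         contaminate_train = TRUE, seed = config$seed) {
  stopifnot(n_train >= 1L, n_val >= 1L, n_test >= 1L)
  base <- as.integer(seed)
  cfg_train <- config
  if (!contaminate_train) cfg_train$lesion_rate <- 0
  gen <- function(cfg, seeds) lapply(seeds, function(s) generate_phantom(cfg, s))
  ds <- list(
    train = gen(cfg_train, base + seq_len(n_train) - 1L),
    val = gen(config, base + n_train + seq_len(n_val) - 1L),
    test = gen(config, base + n_train + n_val + seq_len(n_test) - 1L))
  structure(ds, class = "phantom_dataset", seed = base,
            contaminated = contaminate_train)
}

#' Tabulate a phantom dataset
#'
#' @param ds a [make_dataset()] result.
#' @return data.frame with one row per sample: id, split, seed, lesion count
#'   and lesion voxel count.
#' @export
dataset_manifest <- function(ds) {
  rows <- lapply(names(ds), function(split) {
    do.call(rbind, lapply(seq_along(ds[[split]]), function(i) {
      s <- ds[[split]][[i]]
      data.frame(id = sprintf("%s_%03d", split, i), split = split,
                 seed = s$seed, n_lesions = length(s$lesions),
                 lesion_voxels = sum(s$lesion_mask))
    }))
  })
  do.call(rbind, rows)
}

#' Write a phantom dataset to disk
#'
#' Writes per-sample PET/CT volumes and lesion masks as NIfTI plus a
#' plain-text `manifest.csv` locating them.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame (with path columns), invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset_manifest(ds)
  man$pet_path <- file.path(dir, paste0(man$id, "_pet.nii.gz"))
  man$ct_path <- file.path(dir, paste0(man$id, "_ct.nii.gz"))
  man$mask_path <- file.path(dir, paste0(man$id, "_mask.nii.gz"))
  k <- 0L
  for (split in names(ds)) for (s in ds[[split]]) {
    k <- k + 1L
    write_nifti(s$pet, man$pet_path[k])
    write_nifti(s$ct, man$ct_path[k])
    msk <- RNifti::asNifti(array(as.integer(s$lesion_mask), dim(s$lesion_mask)))
    RNifti::pixdim(msk) <- s$pet$spacing
    RNifti::writeNifti(msk, man$mask_path[k], datatype = "uint8")
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
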