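#' Construct a 3D image volume
#'
#' The basic container of the package: a 3D scalar grid plus voxel spacing
#' and a modality tag. "functional" volumes (PET-like radiotracer uptake)
#' must be non-negative; "anatomical" volumes (CT-like tissue density) carry
#' the structural reference used for conditioning.
#'
#' @param data numeric 3D array; every dimension must be at least 8 and all
#'   values finite.
#' @param spacing numeric length-3 voxel size in mm.
#' @param modality `"functional"` or `"anatomical"`.
#' @return An object of class `vq_volume` with fields `data`, `spacing`,
#'   `modality`.
#' @export
volume <- function(data, spacing = c(1, 1, 1),
                   modality = c("functional", "anatomical")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_("'data' must be a 3D array")
  if (any(dim(data) < 8L))
    stop_("all volume dimensions must be >= 8 (got ",
          paste(dim(data), collapse = "x"), ")")
  if (!all(is.finite(data)))
    stop_("volume contains non-finite values")
  if (modality == "functional" && min(data) < 0)
    stop_("functional volumes must be non-negative")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_("'spacing' must be 3 positive voxel sizes (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 modality = modality),
            class = "vq_volume")
}

#' @export
print.vq_volume <- function(x, ...) {
  cat(sprintf("<vq_volume> %s, %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

as_volume_data <- function(x) {
  if (inherits(x, "vq_volume")) x$data else x
}

#' Write a volume to NIfTI-1
#'
#' Writes `v$data` as float32 with the voxel spacing in the pixdim header
#' field and the modality tag stored in the free-text `descrip` field so
#' that [read_nifti()] can recover it.
#'
#' @param v a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(v, path) {
  stopifnot(inherits(v, "vq_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  img$descrip <- paste0("modality=", v$modality)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param modality fallback modality when the file's `descrip` field does
#'   not carry a `modality=` tag written by [write_nifti()].
#' @return A [volume()].
#' @export
read_nifti <- function(path, modality = "functional") {
  img <- withCallingHandlers(
    tryCatch(RNifti::readNifti(path),
             error = function(e) {
               stop_("cannot parse '", path,
                     "' as NIfTI (bad magic/header fields): ",
                     conditionMessage(e))
             }),
    warning = function(w) invokeRestart("muffleWarning"))
  hdr <- RNifti::niftiHeader(img)
  m <- regmatches(hdr$descrip, regexec("modality=(\\w+)", hdr$descrip))[[1]]
  if (length(m) == 2L && m[2] %in% c("functional", "anatomical"))
    modality <- m[2]
  data <- as.array(img)
  if (length(dim(data)) != 3L)
    stop_("'", path, "' is not a 3D NIfTI volume (dim field = ",
          paste(dim(data), collapse = "x"), ")")
  if (modality == "functional") data[data < 0] <- 0
  volume(data, spacing = RNifti::pixdim(img)[1:3], modality = modality)
}
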