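# NIfTI volume I/O, orientation canonicalization, intensity preprocessing
# and slice decomposition.
#
# Convention: volume data is a 3D array (row, col, slice) — the third axis
# is the axial stack — with spacing (row_mm, col_mm, slice_thickness_mm).
# Masks are integer {0,1} arrays on the same grid, 1 inside the GTV.
# Canonical orientation is head-first ("RAS" in NIfTI terms); feet-first
# acquisitions are stored with a negated slice axis in the NIfTI transform
# and flipped back on read.

#' Construct a volume
#'
#' @param data 3D numeric array `(row, col, slice)`.
#' @param spacing Numeric length-3, voxel size in mm
#'   `(row_mm, col_mm, slice_thickness_mm)`; all strictly positive.
#' @param intensity_state `"HU"` (calibrated CT intensities) or
#'   `"normalized"` (windowed to `[0, 1]`).
#' @param orientation `"head-first"` (canonical) or `"feet-first"`.
#' @return An object of class `gtv_volume`.
#' @export
gtv_volume <- function(data, spacing, intensity_state = c("HU", "normalized"),
                       orientation = c("head-first", "feet-first")) {
  intensity_state <- match.arg(intensity_state)
  orientation <- match.arg(orientation)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (intensity_state == "normalized" &&
      (min(data) < 0 || max(data) > 1))
    stop("normalized volumes must have values in [0, 1]")
  structure(list(data = data, spacing = as.numeric(spacing),
                 intensity_state = intensity_state,
                 orientation = orientation),
            class = "gtv_volume")
}

#' @export
print.gtv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gtv_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, %s, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$intensity_state, x$orientation))
  invisible(x)
}

nifti_with_xform <- function(data, spacing, feet_first) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing[1], spacing[2],
              if (feet_first) -spacing[3] else spacing[3], 1))
  if (feet_first) m[3, 4] <- spacing[3] * (dim(data)[3] - 1)
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

#' Write a volume (or mask) as NIfTI
#'
#' Feet-first volumes are written with flipped slice order and a negated
#' slice axis in the stored transform, mirroring how mixed-orientation
#' acquisitions arrive from scanners; [read_volume()] undoes this.
#' Masks are written as unsigned 8-bit.
#'
#' @param v A `gtv_volume`, or a binary 3D mask array when `mask = TRUE`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param mask Write as unsigned 8-bit label volume.
#' @param spacing,orientation Grid metadata, only used when `v` is a bare
#'   mask array.
#' @export
write_volume <- function(v, path, mask = FALSE, spacing = NULL,
                         orientation = "head-first") {
  if (inherits(v, "gtv_volume")) {
    data <- v$data; spacing <- v$spacing; orientation <- v$orientation
  } else {
    data <- v
    if (is.null(spacing)) stop("spacing required when writing a bare array")
  }
  ff <- identical(orientation, "feet-first")
  if (ff) data <- data[, , dim(data)[3]:1, drop = FALSE]
  img <- nifti_with_xform(if (mask) array(as.integer(data != 0), dim(data))
                          else data,
                          spacing, ff)
  RNifti::writeNifti(img, path,
                     datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Read a NIfTI volume and canonicalize its orientation
#'
#' Reorients the voxel data to the canonical head-first axial convention
#' regardless of how the file was stored, so downstream slice indices always
#' stack the same way.
#'
#' @param path A 3D NIfTI file.
#' @param mask Read as a binary mask (integer `{0,1}` array).
#' @return A `gtv_volume` (head-first) or, for `mask = TRUE`, an integer
#'   array with attribute `spacing`.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("unsupported file: expected a 3D NIfTI, got ",
         length(dim(img)), "D")
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  spacing <- RNifti::pixdim(img)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("unsupported file: missing or invalid voxel spacing")
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (mask) {
    m <- array(as.integer(data != 0), dim(data))
    attr(m, "spacing") <- as.numeric(spacing)
    return(m)
  }
  gtv_volume(data, spacing, intensity_state = "HU")
}

#' Window and normalize CT intensities
#'
#' Clips intensities to the `[lo, hi]` HU window and rescales the window
#' linearly to `[0, 1]`: `(clip(x, lo, hi) - lo) / (hi - lo)`. The divisor
#' is the fixed window width, not a per-image range, so a given normalized
#' value means the same tissue intensity in every image and every domain.
#' No resampling or interpolation is performed.
#'
#' @param v A `gtv_volume` in HU.
#' @param lo,hi Window bounds in HU (default `[-150, 250]`, a soft-tissue
#'   window bracketing lung tumours).
#' @return A `gtv_volume` with `intensity_state = "normalized"`.
#' @export
window_normalize <- function(v, lo = -150, hi = 250) {
  stopifnot(inherits(v, "gtv_volume"))
  if (lo >= hi) stop("window lower bound must be below upper bound")
  if (v$intensity_state != "HU")
    stop("window_normalize expects HU intensities")
  x <- pmin(pmax(v$data, lo), hi)
  out <- v
  out$data <- (x - lo) / (hi - lo)
  out$intensity_state <- "normalized"
  out
}

#' Decompose a volume and mask into 2D slice pairs
#'
#' @param v Normalized `gtv_volume`.
#' @param m Binary mask array on the same grid.
#' @param subject_id Label carried into every row.
#' @param include_empty Keep slices without any mask voxel (default `TRUE`;
#'   empty slices teach a segmentation model to produce empty output).
#' @return A tibble with one row per retained axial slice: `subject_id`,
#'   `slice_index` (0-based, stacking order), `image` and `mask`
#'   (list-columns of 2D arrays), `mask_voxels`.
#' @export
to_slices <- function(v, m, subject_id = "subject", include_empty = TRUE) {
  stopifnot(inherits(v, "gtv_volume"))
  if (v$intensity_state != "normalized")
    stop("to_slices expects a normalized volume")
  if (!identical(dim(v$data), dim(m))) stop("volume/mask grid mismatch")
  S <- dim(v$data)[3]
  rows <- purrr::map(seq_len(S), function(s) {
    msk <- m[, , s]
    tibble::tibble(subject_id = subject_id, slice_index = s - 1L,
                   image = list(v$data[, , s]), mask = list(msk),
                   mask_voxels = sum(msk != 0))
  })
  out <- dplyr::bind_rows(rows)
  if (!include_empty) out <- dplyr::filter(out, .data$mask_voxels > 0L)
  out
}

#' Reassemble a mask volume from slice pairs
#'
#' Inverse of [to_slices()] for the mask channel: stacks the `mask`
#' list-column by `slice_index` into a 3D array.
#'
#' @param slices Tibble from [to_slices()] (all slices present).
#' @param n_slices Total slice count of the original volume.
#' @return Integer 3D mask array.
#' @export
slices_to_mask <- function(slices, n_slices = max(slices$slice_index) + 1L) {
  d2 <- dim(slices$mask[[1]])
  out <- array(0L, c(d2, n_slices))
  for (i in seq_len(nrow(slices)))
    out[, , slices$slice_index[i] + 1L] <- as.integer(slices$mask[[i]] != 0)
  out
}
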