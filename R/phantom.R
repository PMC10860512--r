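# Synthetic two-domain CT phantom generator.
#
# Each subject is an axial stack containing a soft-tissue body disc, two
# low-intensity lung fields, and one tumour: a smoothly deformed ellipsoid
# embedded in a lung field. Domains ("hospitals") differ through abstract
# acquisition knobs — noise level, a global intensity calibration offset,
# slice thickness, tumour-size distribution, patient orientation — not
# through physical scanner simulation: the transfer-learning experiment
# needs a genuine intensity-statistics shift and observer-style boundary
# variability, not anatomy.

#' Domain specification
#'
#' Parameter bundle defining one synthetic acquisition domain.
#'
#' @param name Domain label.
#' @param image_size Square axial slice size in pixels.
#' @param n_slices_range Integer range (min, max) of slices per subject.
#' @param pixel_spacing_mm In-plane voxel size, mm.
#' @param slice_thickness_mm Slice spacing, mm.
#' @param background_hu Soft-tissue plateau (HU).
#' @param lung_hu Lung-field plateau (HU); must be below `background_hu`.
#' @param tumour_hu_range Interval the per-subject tumour intensity is drawn
#'   from (HU); must overlap the preprocessing window.
#' @param noise_sd_hu Additive Gaussian noise level (HU).
#' @param intensity_offset_hu Domain-level calibration shift (HU).
#' @param tumour_radius_range_mm Interval of in-plane tumour radii (mm);
#'   the through-plane semi-axis is 0.7 of the in-plane radius.
#' @param tumour_irregularity Boundary perturbation amplitude in `[0, 1]`
#'   (0 = perfect ellipsoid).
#' @param orientation `"head-first"` or `"feet-first"` storage convention
#'   for written volumes.
#' @return An object of class `gtv_domain_spec`.
#' @export
domain_spec <- function(name = "source", image_size = 64L,
                        n_slices_range = c(8L, 10L), pixel_spacing_mm = 2.5,
                        slice_thickness_mm = 3, background_hu = 40,
                        lung_hu = -800, tumour_hu_range = c(20, 90),
                        noise_sd_hu = 20, intensity_offset_hu = 0,
                        tumour_radius_range_mm = c(8, 14),
                        tumour_irregularity = 0.3,
                        orientation = c("head-first", "feet-first")) {
  orientation <- match.arg(orientation)
  stopifnot(pixel_spacing_mm > 0, slice_thickness_mm > 0,
            noise_sd_hu >= 0, tumour_irregularity >= 0,
            tumour_irregularity <= 1)
  if (lung_hu >= background_hu) stop("lung_hu must be below background_hu")
  if (tumour_radius_range_mm[1] > tumour_radius_range_mm[2])
    stop("tumour_radius_range_mm must be an increasing interval")
  if (tumour_hu_range[1] > 250 || tumour_hu_range[2] < -150)
    stop("tumour_hu_range lies outside the preprocessing window")
  fov <- image_size * pixel_spacing_mm
  if (tumour_radius_range_mm[2] > 0.22 * fov)
    stop("image_size too small to contain the maximum tumour radius")
  min_extent <- n_slices_range[1] * slice_thickness_mm
  if (2 * 0.7 * tumour_radius_range_mm[2] + slice_thickness_mm > min_extent)
    stop("n_slices_range too small to contain the maximum tumour extent")
  structure(list(name = name, image_size = as.integer(image_size),
                 n_slices_range = as.integer(n_slices_range),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 background_hu = background_hu, lung_hu = lung_hu,
                 tumour_hu_range = tumour_hu_range,
                 noise_sd_hu = noise_sd_hu,
                 intensity_offset_hu = intensity_offset_hu,
                 tumour_radius_range_mm = tumour_radius_range_mm,
                 tumour_irregularity = tumour_irregularity,
                 orientation = orientation),
            class = "gtv_domain_spec")
}

#' Observer simulation configuration
#'
#' Each simulated observer displaces the true tumour boundary along its
#' outward normal by a smooth zero-mean random field (scale
#' `boundary_sd_mm`) plus a constant per-observer bias, all in physical mm
#' so observer behaviour is spacing-invariant across domains. Defaults are
#' calibrated so pairwise observer Dice on default-size tumours falls in
#' the 0.7-0.9 band reported for independent expert delineations.
#'
#' @param n_observers Number of observers (>= 2).
#' @param boundary_sd_mm Zero-mean boundary jitter scale, mm (scalar or one
#'   per observer).
#' @param bias_mm Systematic over-/under-contouring per observer, mm
#'   (scalar recycled or one per observer).
#' @param seed Integer seed.
#' @return An object of class `gtv_observer_config`.
#' @export
observer_sim_config <- function(n_observers = 5L, boundary_sd_mm = 2.2,
                                bias_mm = c(-1, -0.5, 0, 0.5, 1),
                                seed = 1L) {
  n_observers <- as.integer(n_observers)
  if (n_observers < 2L) stop("consensus analysis needs n_observers >= 2")
  if (any(boundary_sd_mm < 0)) stop("boundary_sd_mm must be nonnegative")
  boundary_sd_mm <- rep_len(boundary_sd_mm, n_observers)
  bias_mm <- rep_len(bias_mm, n_observers)
  structure(list(n_observers = n_observers, boundary_sd_mm = boundary_sd_mm,
                 bias_mm = bias_mm, seed = as.integer(seed)),
            class = "gtv_observer_config")
}

# Smooth zero-mean random field of unit sd evaluated at points (n x 3, mm):
# a sum of random plane-wave cosines with wavelengths lambda_range (mm).
smooth_field <- function(pts, n_waves = 8L, lambda_range = c(10, 28)) {
  f <- numeric(nrow(pts))
  for (j in seq_len(n_waves)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    k <- 2 * pi / stats::runif(1, lambda_range[1], lambda_range[2])
    phase <- stats::runif(1, 0, 2 * pi)
    f <- f + cos((pts %*% dir) * k + phase)
  }
  as.numeric(f) * sqrt(2 / n_waves)
}

# Direction-dependent radial perturbation on the unit sphere.
sphere_field <- function(dirs, n_waves = 6L) {
  f <- numeric(nrow(dirs))
  for (j in seq_len(n_waves)) {
    k <- stats::rnorm(3) * stats::runif(1, 2, 4)
    phase <- stats::runif(1, 0, 2 * pi)
    f <- f + cos((dirs %*% k) + phase)
  }
  as.numeric(f) * sqrt(2 / n_waves)
}

#' Generate one synthetic subject
#'
#' Builds a CT-like volume (HU), its ground-truth tumour mask, and the
#' subject record. Deterministic for a fixed `(spec, subject_seed)`.
#'
#' @param spec A [domain_spec()].
#' @param subject_seed Integer seed for this subject.
#' @param id Subject label.
#' @return An object of class `gtv_subject` with elements `id`, `volume`
#'   (`gtv_volume`, HU), `truth_mask`, `observer_masks` (empty list),
#'   `domain`, `seed`.
#' @export
generate_subject <- function(spec, subject_seed, id = NULL) {
  stopifnot(inherits(spec, "gtv_domain_spec"))
  set.seed(as.integer(subject_seed))
  n <- spec$image_size
  S <- if (spec$n_slices_range[1] == spec$n_slices_range[2])
    spec$n_slices_range[1] else
    sample(seq(spec$n_slices_range[1], spec$n_slices_range[2]), 1L)
  px <- spec$pixel_spacing_mm; thk <- spec$slice_thickness_mm
  fov <- n * px
  # voxel-centre coordinates (mm), origin at volume centre
  xs <- (seq_len(n) - (n + 1) / 2) * px
  zs <- (seq_len(S) - (S + 1) / 2) * thk

  # body and lung fields (2D templates shared by all slices)
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  body <- (X / (0.35 * fov))^2 + (Y / (0.44 * fov))^2 <= 1
  lungL <- (X / (0.26 * fov))^2 + ((Y + 0.19 * fov) / (0.155 * fov))^2 <= 1
  lungR <- (X / (0.26 * fov))^2 + ((Y - 0.19 * fov) / (0.155 * fov))^2 <= 1
  lung <- (lungL | lungR) & body

  r <- stats::runif(1, spec$tumour_radius_range_mm[1],
                    spec$tumour_radius_range_mm[2])
  cz_half <- 0.7 * r
  side <- sample(c(-1, 1), 1)
  cx <- stats::runif(1, -0.3, 0.3) * 0.26 * fov          # row direction
  cy <- side * 0.19 * fov + stats::runif(1, -0.3, 0.3) * 0.155 * fov
  z_room <- max(0, S * thk / 2 - cz_half - thk / 2)
  cz <- stats::runif(1, -z_room, z_room)
  hu_t <- stats::runif(1, spec$tumour_hu_range[1], spec$tumour_hu_range[2])

  irr <- spec$tumour_irregularity
  wave_k <- matrix(stats::rnorm(18), 6, 3) * stats::runif(6, 2, 4)
  wave_ph <- stats::runif(6, 0, 2 * pi)

  # tumour mask over the bounding box of the (perturbed) ellipsoid
  mask <- array(0L, c(n, n, S))
  rmax <- r * (1 + 0.5 * irr) + px
  ix <- which(abs(xs - cx) <= rmax); iy <- which(abs(xs - cy) <= rmax)
  iz <- which(abs(zs - cz) <= 0.7 * rmax + thk)
  if (length(ix) && length(iy) && length(iz)) {
    g <- expand.grid(i = ix, j = iy, s = iz)
    u <- cbind((xs[g$i] - cx) / r, (xs[g$j] - cy) / r,
               (zs[g$s] - cz) / cz_half)
    rho <- sqrt(rowSums(u^2))
    inside <- rho <= 1e-12
    nz <- rho > 1e-12
    if (any(nz)) {
      dirs <- u[nz, , drop = FALSE] / rho[nz]
      f <- numeric(sum(nz))
      for (j in 1:6)
        f <- f + cos((dirs %*% wave_k[j, ]) + wave_ph[j])
      f <- f * sqrt(2 / 6)
      fac <- pmin(pmax(1 + irr * 0.35 * f, 0.4), 1.8)
      inside[nz] <- rho[nz] <= fac
    }
    mask[cbind(g$i, g$j, g$s)[inside, , drop = FALSE]] <- 1L
  }
  if (sum(mask) == 0L) stop("degenerate configuration: empty tumour mask")
  mask <- array(as.integer(largest_component(array(mask == 1L, dim(mask)))),
                dim(mask))

  vol <- array(-1000, c(n, n, S))
  for (s in seq_len(S)) {
    sl <- matrix(-1000, n, n)
    sl[body] <- spec$background_hu
    sl[lung] <- spec$lung_hu
    vol[, , s] <- sl
  }
  vol[mask == 1L] <- hu_t
  vol <- vol + spec$intensity_offset_hu +
    stats::rnorm(length(vol), 0, spec$noise_sd_hu)

  structure(list(id = if (is.null(id)) sprintf("s%06d", subject_seed %% 1000000L) else id,
                 volume = gtv_volume(vol, c(px, px, thk), "HU",
                                     orientation = spec$orientation),
                 truth_mask = mask, observer_masks = list(),
                 domain = spec$name, seed = as.integer(subject_seed)),
            class = "gtv_subject")
}

#' @export
print.gtv_subject <- function(x, ...) {
  cat(sprintf("<gtv_subject> %s (domain %s): %s voxels tumour, %d observers\n",
              x$id, x$domain, sum(x$truth_mask), length(x$observer_masks)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param spec A [domain_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Master seed; per-subject seeds are derived from it so a
#'   cohort is reproducible and subjects are mutually independent.
#' @param observers Optional [observer_sim_config()]; when supplied, each
#'   subject also receives simulated observer delineations.
#' @param id_prefix Prefix for subject ids.
#' @return List of `gtv_subject` (class `gtv_cohort`).
#' @export
generate_cohort <- function(spec, n, seed, observers = NULL,
                            id_prefix = spec$name) {
  stopifnot(n >= 1)
  seed <- as.integer(seed)
  cohort <- lapply(seq_len(n), function(i) {
    s <- generate_subject(spec, subject_seed = seed + 7919L * (i - 1L),
                          id = sprintf("%s_%03d", id_prefix, i))
    if (!is.null(observers)) {
      ocfg <- observers
      ocfg$seed <- observers$seed + 104729L * (i - 1L)
      s$observer_masks <- simulate_observers(s$truth_mask, ocfg,
                                             spacing = s$volume$spacing)
    }
    s
  })
  structure(cohort, class = "gtv_cohort")
}

#' Simulate correlated observer delineations
#'
#' Displaces the true boundary along its outward normal by a smooth
#' zero-mean random field plus a per-observer constant bias, both in mm:
#' observer `i` marks voxel `v` iff `signed_distance(v) <= bias_i + g_i(v)`,
#' where the signed distance to the truth boundary is negative inside.
#' Each mask is reduced to its largest connected component.
#'
#' @param truth Non-empty binary 3D mask array.
#' @param cfg An [observer_sim_config()].
#' @param spacing Voxel spacing in mm (length 3).
#' @return List of `cfg$n_observers` binary mask arrays.
#' @export
simulate_observers <- function(truth, cfg, spacing) {
  stopifnot(inherits(cfg, "gtv_observer_config"))
  if (sum(truth) == 0L) stop("truth mask is empty")
  d <- dim(truth)
  m <- array(truth != 0, d)
  sd_signed <- mask_edt(m, spacing) - mask_edt(!m, spacing)
  # evaluate the displacement field only near the boundary
  band <- which(abs(sd_signed) <= max(abs(cfg$bias_mm)) +
                  4 * max(cfg$boundary_sd_mm) + max(spacing))
  idx <- arrayInd(band, d)
  pts <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2],
               (idx[, 3] - 1) * spacing[3])
  lapply(seq_len(cfg$n_observers), function(i) {
    set.seed(cfg$seed + 7919L * i)
    g <- if (cfg$boundary_sd_mm[i] > 0)
      cfg$boundary_sd_mm[i] * smooth_field(pts) else numeric(nrow(pts))
    out <- m
    out[band] <- sd_signed[band] <= cfg$bias_mm[i] + g
    if (sum(out) == 0L)
      stop("observer perturbation emptied the mask; ",
           "boundary_sd_mm/bias_mm too aggressive for this tumour size")
    array(as.integer(largest_component(out)), d)
  })
}

#' Write a cohort to disk
#'
#' Writes image/mask NIfTI pairs (plus observer masks where present) and a
#' tab-delimited manifest (id, domain, seed, file paths).
#'
#' @param cohort A `gtv_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    img <- file.path(dir, paste0(s$id, "_image.nii.gz"))
    msk <- file.path(dir, paste0(s$id, "_mask.nii.gz"))
    write_volume(s$volume, img)
    write_volume(s$truth_mask, msk, mask = TRUE,
                 spacing = s$volume$spacing,
                 orientation = s$volume$orientation)
    obs <- character(0)
    if (length(s$observer_masks)) {
      obs <- vapply(seq_along(s$observer_masks), function(k) {
        p <- file.path(dir, sprintf("%s_obs%d.nii.gz", s$id, k))
        write_volume(s$observer_masks[[k]], p, mask = TRUE,
                     spacing = s$volume$spacing,
                     orientation = s$volume$orientation)
        p
      }, character(1))
    }
    tibble::tibble(id = s$id, domain = s$domain, seed = s$seed,
                   image = img, mask = msk,
                   observers = paste(obs, collapse = ";"))
  })
  manifest <- dplyr::bind_rows(rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  mf
}

#' Read a cohort written by [write_cohort()]
#' @param manifest Path to the manifest file.
#' @return A `gtv_cohort`.
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(tab)), function(i) {
    v <- read_volume(tab$image[i])
    m <- read_volume(tab$mask[i], mask = TRUE)
    obs <- list()
    ostr <- as.character(tab$observers[i])
    if (!is.na(ostr) && nzchar(ostr))
      obs <- lapply(strsplit(ostr, ";")[[1]], read_volume, mask = TRUE)
    structure(list(id = tab$id[i], volume = v,
                   truth_mask = array(as.integer(m), dim(m)),
                   observer_masks = lapply(obs, function(o)
                     array(as.integer(o), dim(o))),
                   domain = tab$domain[i], seed = tab$seed[i]),
              class = "gtv_subject")
  })
  structure(cohort, class = "gtv_cohort")
}
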