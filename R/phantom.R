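#' Specify a 3D brain phantom
#'
#' Defines the stated world of the synthetic volumes: an intensity volume on
#' a regular grid plus an integer label map of `n_roi` disjoint axis-aligned
#' ellipsoid "areas" embedded in a noisy background. Each area has its own
#' base intensity, noise SD and spatial correlation length (Gaussian
#' smoothing sigma applied to the white-noise field before scaling). A
#' `signal` plan makes chosen areas carry information about a subject's
#' normalized test score:
#'
#' * `"texture-contrast"`: the area's noise SD becomes
#'   `noise_sd * (1 + beta * score_norm)`;
#' * `"mean-intensity"`: the base intensity becomes
#'   `base_intensity * (1 + beta * score_norm)`;
#' * `"volume"`: the ellipsoid volume is scaled by `(1 + beta * score_norm)`
#'   (radii by its cube root).
#'
#' The defaults are desk-scale: a 64^3 grid at 1 mm isotropic spacing with 12
#' areas — the statistical structure downstream stages consume, not anatomy.
#'
#' @param shape Integer grid size per axis (length 3).
#' @param spacing Voxel spacing in mm (length 3).
#' @param n_roi Number of areas when `geometry` is `NULL`.
#' @param geometry Optional tibble with columns `roi_label`, `cx`, `cy`,
#'   `cz` (centres, voxel units), `rx`, `ry`, `rz` (radii, voxel units).
#' @param texture Optional tibble with columns `roi_label`,
#'   `base_intensity`, `noise_sd`, `smooth_sigma`.
#' @param signal Optional tibble with columns `roi_label`, `property`
#'   (one of `"texture-contrast"`, `"mean-intensity"`, `"volume"`), `test`
#'   (test code, e.g. `"mf"`), `beta` (effect per unit normalized score).
#' @param background List with `base_intensity`, `noise_sd`, `smooth_sigma`
#'   for non-ROI voxels.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(shape = c(32, 32, 32), n_roi = 4)
#' subj <- generate_cohort(cohort_spec(), seed = 1)[1, ]
#' ph <- generate_phantom(subj, spec, seed = 7)
#' table(ph$label[ph$label > 0])
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         n_roi = 12L,
                         geometry = NULL,
                         texture = NULL,
                         signal = NULL,
                         background = list(
                           base_intensity = 40, noise_sd = 10,
                           smooth_sigma = 1
                         )) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(all(shape >= 8), all(spacing > 0))
  if (is.null(geometry)) geometry <- .default_geometry(shape, n_roi)
  k <- nrow(geometry)
  stopifnot(k >= 1, identical(sort(geometry$roi_label), seq_len(k)))
  if (is.null(texture)) {
    texture <- tibble::tibble(
      roi_label = geometry$roi_label,
      # deterministic mild variation across areas
      base_intensity = 100 + 4 * ((geometry$roi_label - 1) %% 5),
      noise_sd = 15,
      smooth_sigma = 1
    )
  }
  if (is.null(signal)) {
    signal <- tibble::tibble(
      roi_label = integer(), property = character(),
      test = character(), beta = numeric()
    )
  }
  if (!all(signal$roi_label %in% geometry$roi_label)) {
    stop("signal plan references unknown ROI labels")
  }
  if (!all(signal$property %in%
    c("texture-contrast", "mean-intensity", "volume"))) {
    stop("unknown signal property")
  }
  stopifnot(all(is.finite(signal$beta)))
  structure(
    list(
      shape = shape, spacing = spacing, geometry = tibble::as_tibble(geometry),
      texture = tibble::as_tibble(texture), signal = tibble::as_tibble(signal),
      background = background
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$shape, collapse = "x"), " grid, ",
    nrow(x$geometry), " ROIs, ", nrow(x$signal), " signal effects\n",
    sep = ""
  )
  invisible(x)
}

# Lay out up to n_roi ellipsoids on a regular sub-grid, radii cycling so
# areas differ in size but never touch.
.default_geometry <- function(shape, n_roi) {
  n_roi <- as.integer(n_roi)
  stopifnot(n_roi >= 1)
  # choose grid dims (gx, gy, gz) with product >= n_roi, as cubic as possible
  gx <- ceiling(n_roi^(1 / 3))
  gy <- ceiling(sqrt(n_roi / gx))
  gz <- ceiling(n_roi / (gx * gy))
  cells <- expand.grid(
    ix = seq_len(gx), iy = seq_len(gy),
    iz = seq_len(gz)
  )[seq_len(n_roi), ]
  cw <- shape / c(gx, gy, gz) # cell width per axis
  rmax <- floor(min(cw) / 2) - 2
  if (rmax < 3) stop("grid too small for ", n_roi, " disjoint ROIs")
  radii_base <- 3 + (seq_len(n_roi) - 1) %% max(1, rmax - 2)
  tibble::tibble(
    roi_label = seq_len(n_roi),
    cx = (cells$ix - 0.5) * cw[1],
    cy = (cells$iy - 0.5) * cw[2],
    cz = (cells$iz - 0.5) * cw[3],
    rx = pmin(radii_base, rmax),
    ry = pmin(radii_base + (seq_len(n_roi) %% 2), rmax),
    rz = pmin(radii_base + (seq_len(n_roi) %% 3), rmax)
  )
}

#' Generate one subject's phantom volumes
#'
#' Realizes the intensity and label volumes of a [phantom_spec()] for one
#' subject. Noise is spatially correlated white noise: one standard-normal
#' field per distinct smoothing sigma, smoothed by a (circular) Gaussian
#' kernel and re-standardized to unit marginal SD, so an area's sample SD
#' equals its (possibly signal-scaled) `noise_sd` in expectation. Areas
#' without planted effects are statistically identical across subjects.
#'
#' @param subject One-row cohort tibble (needs `subject_id` and the
#'   `<test>_norm` column referenced by the signal plan).
#' @param spec A `phantom_spec`.
#' @param seed Integer seed; the same (subject, spec, seed) gives identical
#'   volumes.
#' @return A list of class `phantom`: `intensity` (double 3D array), `label`
#'   (integer 3D array, 0 = background), `spacing`, `subject_id`.
#' @export
generate_phantom <- function(subject, spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), nrow(subject) == 1)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  shape <- spec$shape
  geom <- spec$geometry
  sig <- spec$signal

  score_of <- function(test) {
    col <- paste0(test, "_norm")
    if (is.null(subject[[col]])) stop("subject lacks column ", col)
    subject[[col]]
  }

  # per-area effective geometry/texture after applying the signal plan
  tex <- spec$texture[match(geom$roi_label, spec$texture$roi_label), ]
  eff_sd <- tex$noise_sd
  eff_base <- tex$base_intensity
  geom_eff <- geom
  if (nrow(sig) > 0) {
    for (r in seq_len(nrow(sig))) {
      i <- match(sig$roi_label[r], geom$roi_label)
      s <- score_of(sig$test[r])
      fac <- 1 + sig$beta[r] * s
      if (fac <= 0) stop("signal effect drives a negative scale factor")
      switch(sig$property[r],
        "texture-contrast" = {
          eff_sd[i] <- eff_sd[i] * fac
        },
        "mean-intensity" = {
          eff_base[i] <- eff_base[i] * fac
        },
        "volume" = {
          geom_eff[i, c("rx", "ry", "rz")] <-
            geom_eff[i, c("rx", "ry", "rz")] * fac^(1 / 3)
        }
      )
    }
  }

  label <- .paint_labels(shape, geom_eff)

  sigmas <- unique(c(tex$smooth_sigma, spec$background$smooth_sigma))
  fields <- lapply(sigmas, function(sg) .smooth_noise(shape, sg))
  names(fields) <- as.character(sigmas)

  bg <- spec$background
  intensity <- bg$base_intensity +
    bg$noise_sd * fields[[as.character(bg$smooth_sigma)]]
  for (i in seq_len(nrow(geom))) {
    vox <- which(label == geom$roi_label[i])
    f <- fields[[as.character(tex$smooth_sigma[i])]]
    intensity[vox] <- eff_base[i] + eff_sd[i] * f[vox]
  }

  structure(
    list(
      intensity = intensity, label = label, spacing = spec$spacing,
      subject_id = subject$subject_id
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$subject_id, ", ", paste(dim(x$label), collapse = "x"),
    " grid, ", length(unique(x$label[x$label > 0])), " ROIs\n",
    sep = ""
  )
  invisible(x)
}

# Paint disjoint ellipsoids; reject overlap.
.paint_labels <- function(shape, geom) {
  label <- array(0L, dim = shape)
  ax <- seq_len(shape[1]) - 0.5 # voxel centres in voxel units
  ay <- seq_len(shape[2]) - 0.5
  az <- seq_len(shape[3]) - 0.5
  for (i in seq_len(nrow(geom))) {
    dx2 <- ((ax - geom$cx[i]) / geom$rx[i])^2
    dy2 <- ((ay - geom$cy[i]) / geom$ry[i])^2
    dz2 <- ((az - geom$cz[i]) / geom$rz[i])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    if (!any(inside)) stop("ROI ", geom$roi_label[i], " contains no voxel")
    if (any(label[inside] != 0L)) {
      stop("overlapping ROI geometry at label ", geom$roi_label[i])
    }
    label[inside] <- geom$roi_label[i]
  }
  label
}

# White noise smoothed by a circular (FFT) Gaussian kernel, re-standardized
# to zero mean / unit SD. sigma in voxel units; sigma = 0 returns white
# noise.
.smooth_noise <- function(shape, sigma) {
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  if (sigma > 0) {
    k1 <- function(n) {
      d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # wrapped distances
      k <- exp(-d^2 / (2 * sigma^2))
      k / sum(k)
    }
    kern <- outer(outer(k1(shape[1]), k1(shape[2])), k1(shape[3]))
    x <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) /
      prod(shape)
  }
  (x - mean(x)) / stats::sd(x)
}

#' Write a fixture set to disk
#'
#' Writes one intensity and one label NIfTI volume per subject, the cohort
#' CSV, and a JSON manifest recording the master seed, per-subject seeds, a
#' hash of the phantom spec and the file list. Refuses to overwrite a
#' directory whose manifest records a different spec hash.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec A `phantom_spec`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; subject `i` uses `seed + i`.
#' @return The manifest, invisibly.
#' @export
write_fixture_set <- function(cohort, spec, out_dir, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec_hash <- rlang::hash(spec)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (!identical(prev$spec_hash, spec_hash)) {
      stop(
        "out_dir contains a manifest for a different phantom spec; ",
        "refusing to overwrite"
      )
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  seeds <- integer()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    s <- as.integer(seed) + i
    ph <- generate_phantom(subj, spec, seed = s)
    fi <- file.path(out_dir, paste0(subj$subject_id, "_intensity.nii.gz"))
    fl <- file.path(out_dir, paste0(subj$subject_id, "_labels.nii.gz"))
    write_nifti(ph$intensity, fi, spacing = spec$spacing)
    write_nifti(ph$label, fl, spacing = spec$spacing)
    files <- c(files, fi, fl)
    seeds <- c(seeds, s)
  }
  cohort_path <- file.path(out_dir, "cohort.csv")
  readr::write_csv(cohort, cohort_path)
  manifest <- list(
    seed = as.integer(seed),
    subject_seeds = stats::setNames(as.list(seeds), cohort$subject_id),
    spec_hash = spec_hash,
    files = c(basename(files), basename(cohort_path))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
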