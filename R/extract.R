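#' Extract the full radiomics catalogue for every ROI of one subject
#'
#' Computes the 100 canonical features (shape, first-order, GLCM, GLRLM,
#' GLSZM, GLDM — see [feature_catalog()]) for every labelled region of an
#' intensity/label volume pair. Gray-level discretization uses the fixed bin
#' width with the ROI minimum as offset, applied after any whole-volume
#' standardization you have performed (see [histogram_match()]).
#'
#' @param intensity 3D numeric array (or a `nii_volume` from
#'   [read_nifti()]).
#' @param labels 3D integer array (or `nii_volume`) of the same shape;
#'   0 = background.
#' @param spacing Voxel spacing in mm; taken from the volumes when they are
#'   `nii_volume`s.
#' @param bin_width Discretization bin width (default 25).
#' @param subject_id Identifier stored in the output (default `"subject"`;
#'   taken from a `phantom` input when available).
#' @param expected_labels Optional integer vector; labels listed here but
#'   absent from the volume produce a warning and a row of zeros (the
#'   degenerate convention for an empty region).
#' @return A tibble with one row per ROI: `subject_id`, `roi_label`, then
#'   the 100 feature columns in canonical order.
#' @export
#' @examples
#' subj <- generate_cohort(cohort_spec(), seed = 1)[1, ]
#' ph <- generate_phantom(subj, phantom_spec(shape = c(24, 24, 24), n_roi = 2),
#'   seed = 1
#' )
#' feats <- extract_features(ph)
#' dim(feats) # 2 rows x 102 columns
extract_features <- function(intensity, labels = NULL, spacing = c(1, 1, 1),
                             bin_width = 25, subject_id = "subject",
                             expected_labels = NULL) {
  if (inherits(intensity, "phantom")) {
    ph <- intensity
    intensity <- ph$intensity
    labels <- ph$label
    spacing <- ph$spacing
    if (!is.null(ph$subject_id)) subject_id <- ph$subject_id
  }
  if (inherits(intensity, "nii_volume")) {
    if (inherits(labels, "nii_volume")) check_geometry(intensity, labels)
    spacing <- intensity$spacing
    intensity <- intensity$data
  }
  if (inherits(labels, "nii_volume")) labels <- labels$data
  if (!identical(dim(intensity), dim(labels))) {
    stop("intensity and label volumes have different shapes")
  }
  present <- sort(unique(labels[labels > 0]))
  wanted <- if (is.null(expected_labels)) {
    present
  } else {
    sort(unique(as.integer(expected_labels)))
  }
  absent <- setdiff(wanted, present)
  if (length(absent) > 0) {
    warning(
      "labels absent from volume (zero rows emitted): ",
      paste(absent, collapse = ", ")
    )
  }
  cat_names <- feature_catalog()
  vals <- matrix(0, length(wanted), length(cat_names),
    dimnames = list(NULL, cat_names)
  )
  for (r in seq_along(wanted)) {
    lb <- wanted[r]
    if (lb %in% absent) next # degenerate zero row
    vox <- which(labels == lb)
    coords <- arrayInd(vox, dim(labels)) - 1L
    vals[r, ] <- compute_feature_vector(
      intensity[vox], coords, spacing, bin_width
    )
  }
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = subject_id,
      roi_label = as.integer(wanted)
    ),
    tibble::as_tibble(vals)
  )
}

#' Compute the 100-feature vector for one ROI sample
#'
#' Lower-level entry point used by [extract_features()]: takes the ROI's
#' intensities and voxel coordinates directly.
#'
#' @param x Numeric vector of ROI intensities.
#' @param coords Integer matrix (n x 3) of 0-based voxel indices, unique
#'   rows, aligned with `x`.
#' @param spacing Voxel spacing in mm.
#' @param bin_width Discretization bin width.
#' @return Named numeric vector of length 100 in canonical catalogue order.
#' @export
compute_feature_vector <- function(x, coords, spacing = c(1, 1, 1),
                                   bin_width = 25) {
  stopifnot(length(x) == nrow(coords))
  disc <- discretize_roi(x, bin_width)
  vals <- c(
    shape_features(coords, spacing),
    first_order_features(x, disc, voxel_volume = prod(spacing)),
    glcm_features(coords, disc),
    glrlm_features(coords, disc),
    glszm_features(coords, disc),
    gldm_features(coords, disc)
  )
  stopifnot(identical(names(vals), feature_catalog()))
  if (!all(is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)]
    stop("non-finite features computed: ", paste(bad, collapse = ", "))
  }
  vals
}

#' Extract features for a whole cohort of phantoms
#'
#' Convenience wrapper running [generate_phantom()] + [extract_features()]
#' per subject, optionally standardizing each intensity volume to a
#' reference subject by histogram matching first (as the imaging protocol
#' prescribes).
#'
#' @param cohort Cohort tibble.
#' @param spec A [phantom_spec()].
#' @param seed Master seed; subject `i` uses `seed + i`.
#' @param bin_width Discretization bin width.
#' @param match_reference `NULL` to skip standardization, otherwise the
#'   index of the reference subject (e.g. 1).
#' @return Feature tibble, one row per (subject, ROI).
#' @export
extract_cohort <- function(cohort, spec, seed = 1L, bin_width = 25,
                           match_reference = 1L) {
  ref <- NULL
  if (!is.null(match_reference)) {
    ref <- generate_phantom(cohort[match_reference, ], spec,
      seed = as.integer(seed) + as.integer(match_reference)
    )$intensity
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    ph <- generate_phantom(cohort[i, ], spec, seed = as.integer(seed) + i)
    if (!is.null(ref)) {
      ph$intensity <- histogram_match(ph$intensity, ref)
    }
    extract_features(ph, bin_width = bin_width)
  })
  dplyr::bind_rows(rows)
}
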