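# Texture feature families. Each family works on a 3D gray-level array over
# the ROI bounding box (levels 1..n_levels inside the ROI, 0 outside), built
# by .roi_bins_array(). Direction-dependent families (GLCM, GLRLM) use the
# 13 unique unit-offset directions at distance 1 and average the per-
# direction features over directions that contain at least one pair/run;
# GLSZM and GLDM are direction-free. All entropies use log base 2 with
# 0 log 0 := 0.

.roi_bins_array <- function(coords, bins) {
  coords <- matrix(as.integer(coords), ncol = 3)
  mn <- apply(coords, 2, min)
  local <- sweep(coords, 2, mn)
  dims <- pmax(apply(local, 2, max) + 1L, 1L)
  arr <- array(0L, dim = dims)
  arr[local + 1L] <- as.integer(bins)
  arr
}

.xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Gray-level co-occurrence (GLCM) features
#'
#' The 22 GLCM features of the catalogue. Co-occurrence matrices are built
#' at distance 1 for the 13 unique 3D directions, symmetrized and
#' normalized; features are computed per direction and averaged. An ROI with
#' no voxel pair in any direction (a single voxel) uses the degenerate
#' single-cell matrix at its own gray level.
#'
#' @param coords Integer matrix (n x 3) of 0-based voxel indices.
#' @param disc [discretize_roi()] result aligned with `coords`.
#' @return Named numeric vector of length 22 (`glcm_*`).
#' @export
glcm_features <- function(coords, disc) {
  arr <- .roi_bins_array(coords, disc$bins)
  ng <- disc$n_levels
  counts <- cpp_glcm_counts(arr, ng)
  out <- cpp_glcm_feats(counts, ng)
  if (anyNA(out)) {
    # no voxel pair in any direction: degenerate single-cell matrix
    p <- matrix(0, ng, ng)
    p[disc$bins[1], disc$bins[1]] <- 1
    out <- .glcm_from_matrix(p)
  }
  stats::setNames(as.numeric(out), paste0("glcm_", .glcm_names))
}

# Features of one normalized symmetric co-occurrence matrix.
.glcm_from_matrix <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p) # = JointAverage (symmetric: mu_x = mu_y)
  sigma2 <- sum((i - mu)^2 * p)
  sigma <- sqrt(sigma2)

  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)

  hxy <- -sum(.xlog2x(p))
  hx <- -sum(.xlog2x(px))
  pxy <- tcrossprod(px) # p_x(i) p_y(j)
  hxy1 <- -sum(ifelse(p > 0 & pxy > 0, p * log2(pxy), 0))
  hxy2 <- -sum(.xlog2x(pxy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - 2^(-2 * (hxy2 - hxy)), 0))

  autoc <- sum(i * j * p)
  correlation <- if (sigma2 > 0) (autoc - mu^2) / sigma2 else 1

  c(
    Autocorrelation = autoc,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(.xlog2x(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(ifelse(i != j, p / (i - j)^2, 0)),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = -sum(.xlog2x(p_sum)),
    SumSquares = sigma2
  )
}

#' Gray-level run-length (GLRLM) features
#'
#' The 16 GLRLM features: run-length matrices over the 13 directions
#' (maximal straight runs of equal gray level; gaps in the ROI break runs),
#' features computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16 (`glrlm_*`).
#' @export
glrlm_features <- function(coords, disc) {
  arr <- .roi_bins_array(coords, disc$bins)
  ng <- disc$n_levels
  np <- length(disc$bins)
  counts <- cpp_glrlm_counts(arr, ng)
  out <- cpp_glrlm_feats(counts, ng, np)
  stats::setNames(as.numeric(out), paste0("glrlm_", .glrlm_names))
}

#' Gray-level size-zone (GLSZM) features
#'
#' The 16 GLSZM features. Zones are 26-connected components of equal gray
#' level; a single direction-free matrix of (gray level, zone size) counts.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16 (`glszm_*`).
#' @export
glszm_features <- function(coords, disc) {
  arr <- .roi_bins_array(coords, disc$bins)
  zones <- cpp_glszm_zones(arr, disc$n_levels)
  np <- length(disc$bins)
  nz <- nrow(zones)
  gl <- zones[, 1]
  s <- zones[, 2]
  w <- rep(1 / nz, nz) # each zone one count
  mu_g <- sum(w * gl)
  mu_s <- sum(w * s)
  level_tot <- tapply(rep(1, nz), factor(gl, levels = unique(gl)), sum)
  size_tot <- tapply(rep(1, nz), factor(s, levels = unique(s)), sum)
  p_cell <- as.numeric(table(paste(gl, s))) / nz
  vals <- c(
    SmallAreaEmphasis = sum(w / s^2),
    LargeAreaEmphasis = sum(w * s^2),
    GrayLevelNonUniformity = sum(level_tot^2) / nz,
    GrayLevelNonUniformityNormalized = sum(level_tot^2) / nz^2,
    SizeZoneNonUniformity = sum(size_tot^2) / nz,
    SizeZoneNonUniformityNormalized = sum(size_tot^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(w * (gl - mu_g)^2),
    ZoneVariance = sum(w * (s - mu_s)^2),
    ZoneEntropy = -sum(.xlog2x(p_cell)),
    LowGrayLevelZoneEmphasis = sum(w / gl^2),
    HighGrayLevelZoneEmphasis = sum(w * gl^2),
    SmallAreaLowGrayLevelEmphasis = sum(w / (s^2 * gl^2)),
    SmallAreaHighGrayLevelEmphasis = sum(w * gl^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = sum(w * s^2 / gl^2),
    LargeAreaHighGrayLevelEmphasis = sum(w * s^2 * gl^2)
  )
  stats::setNames(vals, paste0("glszm_", names(vals)))
}

#' Gray-level dependence (GLDM) features
#'
#' The 14 GLDM features. The dependence of a voxel is the number of its
#' 26-neighbours inside the ROI with identical gray level (tolerance 0); the
#' matrix is indexed by gray level and dependence size `j = count + 1`
#' (including the centre, so `j >= 1`).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 14 (`gldm_*`).
#' @export
gldm_features <- function(coords, disc) {
  arr <- .roi_bins_array(coords, disc$bins)
  cm <- cpp_gldm_counts(arr, disc$n_levels)
  nz <- sum(cm)
  p <- cm / nz
  i <- matrix(seq_len(nrow(cm)), nrow(cm), ncol(cm))
  j <- t(matrix(seq_len(ncol(cm)), ncol(cm), nrow(cm)))
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  vals <- c(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(cm)^2) / nz,
    DependenceNonUniformity = sum(colSums(cm)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(cm)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(.xlog2x(p)),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (j^2 * i^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
  stats::setNames(vals, paste0("gldm_", names(vals)))
}
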