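#' The fixed 100-feature radiomics catalogue
#'
#' The pipeline computes a fixed catalogue of exactly 100 features per region
#' of interest, in a canonical order: 14 shape features first, then 18
#' first-order intensity features, then 68 texture features (22 GLCM, 16
#' GLRLM, 16 GLSZM, 14 GLDM). The order matters: sequential correlation-based
#' elimination ([decorrelate()]) walks the catalogue front to back, so shape
#' features are preferentially preserved over correlated texture features.
#'
#' Column names are `<family>_<FeatureName>`, e.g. `shape_MeshVolume`,
#' `glcm_Contrast`.
#'
#' @return Character vector of the 100 canonical feature names, in order.
#' @seealso [feature_families()] for the family used in importance grouping.
#' @export
#' @examples
#' length(feature_catalog())
#' head(feature_catalog())
feature_catalog <- function() {
  c(
    paste0("shape_", .shape_names),
    paste0("firstorder_", .firstorder_names),
    paste0("glcm_", .glcm_names),
    paste0("glrlm_", .glrlm_names),
    paste0("glszm_", .glszm_names),
    paste0("gldm_", .gldm_names)
  )
}

.shape_names <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"
)

.firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "TenthPercentile",
  "NinetiethPercentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

.glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "SumEntropy", "SumSquares"
)

.glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

.glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

.gldm_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

#' Feature-family map used for importance grouping
#'
#' Groups the catalogue (plus `age`) into the five families whose relative
#' Gini importance the pipeline reports: `age`, `volume` (mesh and voxel
#' volume, the quantities classical volumetry measures), `shape` (the
#' remaining 12 shape descriptors), `intensity` (the 18 first-order
#' features) and `texture` (the 68 matrix-based features). Volume is kept
#' apart from shape so its contribution can be judged independently of other
#' geometric descriptors.
#'
#' @return A tibble with columns `feature` and `family`
#'   (101 rows: the catalogue plus `age`).
#' @export
#' @examples
#' dplyr::count(feature_families(), family)
feature_families <- function() {
  feat <- feature_catalog()
  fam <- dplyr::case_when(
    feat %in% c("shape_MeshVolume", "shape_VoxelVolume") ~ "volume",
    startsWith(feat, "shape_") ~ "shape",
    startsWith(feat, "firstorder_") ~ "intensity",
    TRUE ~ "texture"
  )
  tibble::tibble(
    feature = c("age", feat),
    family = factor(c("age", fam),
      levels = c("age", "volume", "shape", "intensity", "texture")
    )
  )
}

#' Destrieux-style label table for the 191 analysis areas
#'
#' Returns the shipped lookup table of the 191 brain areas the analysis
#' protocol was designed around: the 148 cortical regions of the Destrieux
#' parcellation (FreeSurfer `aparc.a2009s` codes, 74 per hemisphere) plus 43
#' standard FreeSurfer `aseg` segmentation structures (15 bilateral
#' subcortical structures and 13 midline/global labels). The non-cortical
#' subset is a reconstruction of a typical whole-brain label set; synthetic
#' phantoms use small label sets of their own and do not depend on this
#' table.
#'
#' @return A tibble with columns `label` (integer code), `hemisphere`
#'   (`"L"`, `"R"` or `NA`), and `name`.
#' @export
#' @examples
#' nrow(destrieux_labels()) # 191
destrieux_labels <- function() {
  path <- system.file("extdata", "destrieux_labels.csv",
    package = "radiomath", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      label = readr::col_integer(),
      hemisphere = readr::col_character(),
      name = readr::col_character()
    )
  )
}
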