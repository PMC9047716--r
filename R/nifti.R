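#' Minimal NIfTI-1 reader and writer
#'
#' The package ships a deliberately small NIfTI-1 implementation (no NIfTI
#' package is assumed): single-file `.nii` / `.nii.gz`, 3D volumes,
#' little-endian or byte-swapped input, datatypes uint8 / int16 / int32 /
#' float32 / float64, and an sform affine. This covers exactly what the
#' pipeline writes (float32 intensities, int16 label maps) and round-trips
#' losslessly.
#'
#' @param path File path; `.gz` suffix toggles gzip compression.
#' @return `read_nifti()` returns a list of class `nii_volume` with elements
#'   `data` (3D array; integer array for integer datatypes), `spacing`
#'   (voxel size in mm), and `affine` (4x4 voxel-to-world matrix).
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @param x 3D numeric or integer array. Integer arrays are stored as int16
#'   when they fit, int32 otherwise; numeric arrays as float32.
#' @param spacing Voxel spacing in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(spacing, 1))`.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(x)) == 3, all(spacing > 0))
  spacing <- rep_len(as.numeric(spacing), 3)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (is.integer(x)) {
    rng <- range(x)
    if (rng[1] >= -32768 && rng[2] <= 32767) {
      datatype <- 4L
      bitpix <- 16L
      size <- 2L
    } else {
      datatype <- 8L
      bitpix <- 32L
      size <- 4L
    }
  } else {
    datatype <- 16L
    bitpix <- 32L
    size <- 4L
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(v, sz = 4L) writeBin(as.integer(v), con, size = sz, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L) # sizeof_hdr
  wc(36) # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dim(x), 1L, 1L, 1L, 1L), 2L) # dim[8]
  wf(c(0, 0, 0)) # intent_p1..p3
  wi(0L, 2L) # intent_code
  wi(datatype, 2L)
  wi(bitpix, 2L)
  wi(0L, 2L) # slice_start
  wf(c(1, spacing, 1, 1, 1, 1)) # pixdim[8]
  wf(352) # vox_offset
  wf(c(1, 0)) # scl_slope, scl_inter
  wi(0L, 2L) # slice_end
  wc(2) # slice_code, xyzt_units
  wf(c(0, 0, 0, 0)) # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L)) # glmax, glmin
  wc(80 + 24) # descrip, aux_file
  wi(c(0L, 2L), 2L) # qform_code = 0, sform_code = 2
  wf(rep(0, 6)) # quatern b,c,d + qoffset x,y,z
  wf(affine[1, ]) # srow_x
  wf(affine[2, ])
  wf(affine[3, ])
  wc(16) # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  wc(4) # extension flag
  if (datatype == 16L) {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  at <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what,
      n = n, size = size,
      endian = endian
    )
  }
  dims <- at(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3D volume: ", path)
  shape <- dims[2:4]
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1)) {
    stop("only 3D volumes are supported: ", path)
  }
  datatype <- at(70, "integer", 1, 2)
  pixdim <- at(76, "numeric", 8, 4)
  vox_offset <- at(108, "numeric", 1, 4)
  scl_slope <- at(112, "numeric", 1, 4)
  scl_inter <- at(116, "numeric", 1, 4)
  sform_code <- at(254, "integer", 1, 2)
  srow <- rbind(
    at(280, "numeric", 4, 4), at(296, "numeric", 4, 4),
    at(312, "numeric", 4, 4), c(0, 0, 0, 1)
  )
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = endian),
    "4" = readBin(con, "integer", n = n, size = 2, endian = endian),
    "8" = readBin(con, "integer", n = n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype)
  )
  if (length(data) < n) stop("truncated NIfTI data: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
    !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  spacing <- pixdim[2:4]
  affine <- if (sform_code > 0) srow else diag(c(spacing, 1))
  structure(
    list(data = array(data, dim = shape), spacing = spacing, affine = affine),
    class = "nii_volume"
  )
}

#' Check that an intensity/label volume pair share a geometry
#'
#' @param image,labels `nii_volume` objects (or lists with `data`,
#'   `spacing`, `affine`).
#' @param tol Maximum tolerated absolute difference between affines, in mm.
#' @return Invisibly `TRUE`; errors on shape or affine mismatch.
#' @export
check_geometry <- function(image, labels, tol = 1e-3) {
  if (!identical(dim(image$data), dim(labels$data))) {
    stop(
      "image/label shape mismatch: ", paste(dim(image$data), collapse = "x"),
      " vs ", paste(dim(labels$data), collapse = "x")
    )
  }
  d <- max(abs(image$affine - labels$affine))
  if (d > tol) {
    stop(
      "image/label affine mismatch: max |delta| = ", format(d),
      " mm exceeds tolerance ", format(tol), " mm"
    )
  }
  invisible(TRUE)
}

#' Read and validate a cohort table
#'
#' Reads the cohort CSV (columns `subject_id`, `grade`, `age`, `sex` and the
#' four raw scores `mf_raw`, `calc_raw`, `ap_raw`, `qc_raw`), rejects missing
#' cells with their row numbers, and adds min-max normalized `*_norm`
#' columns.
#'
#' @param path CSV path.
#' @param tests Test metadata (defaults to [wj3_tests()]).
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, tests = wj3_tests()) {
  co <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "grade", "age", "sex", paste0(tests$test, "_raw"))
  missing_cols <- setdiff(need, names(co))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(co[need]))
  if (length(bad) > 0) {
    stop(
      "cohort table has missing values in rows: ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  for (i in seq_len(nrow(tests))) {
    x <- co[[paste0(tests$test[i], "_raw")]]
    if (any(x < 0 | x > tests$max_items[i])) {
      stop(
        "scores outside [0, ", tests$max_items[i], "] for test ",
        tests$test[i]
      )
    }
  }
  normalize_scores(tibble::as_tibble(co), tests = tests$test)
}
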