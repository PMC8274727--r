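#' @keywords internal
"_PACKAGE"

# Canonical order of the 11 GLCM texture features used throughout the package.
#' Names of the eleven GLCM texture features, in canonical order
#'
#' Contrast (CON), dissimilarity (DIS), homogeneity (HOM), angular second
#' moment (ASM), energy (ENE), maximum probability (MAX), entropy (ENT),
#' mean (MEA), variance (VAR), standard deviation (STD) and correlation (COR).
#' This order fixes the column layout of feature tables.
#'
#' @export
GLCM_FEATURE_NAMES <- c("CON", "DIS", "HOM", "ASM", "ENE", "MAX",
                        "ENT", "MEA", "VAR", "STD", "COR")

#' Construct a slice stack
#'
#' A slice stack is one patient's ordered set of 2D grayscale slices (e.g. a
#' sagittal T2-weighted MRI volume). All slices must share dimensions and all
#' intensities must be finite; integer input is promoted to double.
#'
#' @param patient_id Character scalar identifier.
#' @param slices A list of numeric matrices (row, col), or a 3D array whose
#'   third axis indexes slices.
#' @param pixel_spacing Numeric length-2 (row, col) spacing in mm.
#' @return An object of class \code{slice_stack}.
#' @export
slice_stack <- function(patient_id, slices, pixel_spacing = c(1, 1)) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3L]), function(k) slices[, , k])
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.list(slices), length(slices) >= 1L)
  slices <- lapply(slices, function(s) {
    if (!is.matrix(s)) stop("each slice must be a 2D matrix")
    storage.mode(s) <- "double"
    s
  })
  d <- dim(slices[[1L]])
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]), d))
      stop(sprintf("slice %d dimensions (%dx%d) differ from slice 1 (%dx%d)",
                   k, nrow(slices[[k]]), ncol(slices[[k]]), d[1L], d[2L]))
    if (!all(is.finite(slices[[k]])))
      stop(sprintf("non-finite intensity in slice %d", k))
  }
  structure(list(patient_id = patient_id, slices = slices,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("slice_stack '%s': %d slice(s) of %dx%d\n",
              x$patient_id, length(x$slices), d[1L], d[2L]))
  invisible(x)
}

#' Construct a mask set
#'
#' Per-slice binary core (tumor) and breast-tissue masks aligned to a slice
#' stack. Any nonzero mask value is treated as TRUE. The core must be a subset
#' of the breast mask on every slice and non-empty in at least one slice.
#'
#' @param core,breast Lists of logical/numeric matrices, or 3D arrays.
#' @param stack Optional \code{slice_stack} to validate dimensions against.
#' @return An object of class \code{mask_set}.
#' @export
mask_set <- function(core, breast, stack = NULL) {
  as_masks <- function(m) {
    if (is.array(m) && length(dim(m)) == 3L)
      m <- lapply(seq_len(dim(m)[3L]), function(k) m[, , k])
    lapply(m, function(s) {
      if (!is.matrix(s)) stop("each mask slice must be a 2D matrix")
      matrix(as.logical(s != 0), nrow(s), ncol(s))
    })
  }
  core <- as_masks(core); breast <- as_masks(breast)
  if (length(core) != length(breast))
    stop("core and breast masks have different slice counts")
  if (!is.null(stack)) {
    if (length(core) != length(stack$slices))
      stop(sprintf("mask slice count (%d) != stack slice count (%d)",
                   length(core), length(stack$slices)))
    for (k in seq_along(core))
      if (!identical(dim(core[[k]]), dim(stack$slices[[k]])))
        stop(sprintf("mask dimensions differ from stack at slice %d", k))
  }
  n_violate <- 0L
  for (k in seq_along(core)) {
    if (!identical(dim(core[[k]]), dim(breast[[k]])))
      stop(sprintf("core/breast dimensions differ at slice %d", k))
    n_violate <- n_violate + sum(core[[k]] & !breast[[k]])
  }
  if (n_violate > 0L)
    stop(sprintf("core mask extends outside breast mask (%d pixel(s))",
                 n_violate))
  if (sum(vapply(core, sum, 0)) == 0L)
    stop("core mask is empty on every slice")
  structure(list(core = core, breast = breast), class = "mask_set")
}

#' Construct a patient record
#'
#' Bundles a slice stack, its mask set and a binary response label.
#' Labels follow the responder / non-responder convention: \code{"R"} for
#' responders, \code{"NR"} for non-responders (the positive class downstream).
#'
#' @param patient_id Character scalar.
#' @param label \code{"R"} or \code{"NR"}.
#' @param stack A \code{slice_stack}.
#' @param masks A \code{mask_set} aligned to \code{stack}.
#' @return An object of class \code{patient_record}.
#' @export
patient_record <- function(patient_id, label, stack, masks) {
  if (!(is.character(label) && length(label) == 1L && label %in% c("R", "NR")))
    stop("label must be exactly \"R\" or \"NR\"")
  stopifnot(inherits(stack, "slice_stack"), inherits(masks, "mask_set"))
  if (length(masks$core) != length(stack$slices))
    stop(sprintf("mask slice count (%d) != stack slice count (%d)",
                 length(masks$core), length(stack$slices)))
  for (k in seq_along(stack$slices))
    if (!identical(dim(masks$core[[k]]), dim(stack$slices[[k]])))
      stop(sprintf("mask dimensions differ from stack at slice %d", k))
  structure(list(patient_id = patient_id, label = label,
                 stack = stack, masks = masks),
            class = "patient_record")
}

# ---- volume readers -------------------------------------------------------

read_volume <- function(path) {
  if (dir.exists(path)) return(read_slice_dir(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop(sprintf("'%s' is not a 2D/3D volume", path))
    return(lapply(seq_len(dim(arr)[3L]), function(k) {
      m <- arr[, , k]; storage.mode(m) <- "double"; m
    }))
  }
  stop(sprintf("unsupported volume format: '%s'", path))
}

# Directory of per-slice TIFF/PNG images named with a sortable numeric suffix
# (slice_001.tif, 2.png, ...). Sorted by the trailing integer.
read_slice_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no TIFF/PNG slices found in '%s'", path))
  idx <- suppressWarnings(as.integer(sub(".*?([0-9]+)\\.[A-Za-z]+$", "\\1",
                                         basename(files))))
  if (anyNA(idx))
    stop("slice files must carry a numeric suffix for ordering")
  files <- files[order(idx)]
  lapply(files, function(f) {
    # as.is=TRUE returns raw integer sample values (e.g. 0..65535 for 16-bit)
    # rather than codec-rescaled [0,1]; PNG has no such option and stays 0..1
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]   # drop channels
    storage.mode(img) <- "double"
    img
  })
}

#' Read one patient's image volume, masks and label
#'
#' Accepts NIfTI volumes (\code{.nii}/\code{.nii.gz}) or directories of
#' per-slice TIFF/PNG files with a sortable numeric suffix. Mask values are
#' binarized (any nonzero is TRUE) and validated against the volume: matching
#' slice counts and dimensions, core within breast, core non-empty.
#'
#' @param volume_path Path to the intensity volume.
#' @param core_mask_path,breast_mask_path Paths to the binary mask rasters.
#' @param label Response label, \code{"R"} or \code{"NR"}.
#' @param patient_id Identifier; defaults to the volume's base filename.
#' @return A \code{patient_record}.
#' @export
read_patient <- function(volume_path, core_mask_path, breast_mask_path, label,
                         patient_id = NULL) {
  for (p in c(volume_path, core_mask_path, breast_mask_path))
    if (!file.exists(p)) stop(sprintf("no such file or directory: '%s'", p))
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path),
                      ignore.case = TRUE)
  vol <- read_volume(volume_path)
  stack <- slice_stack(patient_id, vol)
  core <- read_volume(core_mask_path)
  breast <- read_volume(breast_mask_path)
  if (length(core) != length(vol))
    stop(sprintf("core mask has %d slice(s) but volume has %d",
                 length(core), length(vol)))
  if (length(breast) != length(vol))
    stop(sprintf("breast mask has %d slice(s) but volume has %d",
                 length(breast), length(vol)))
  patient_record(patient_id, label, stack, mask_set(core, breast, stack))
}

#' Write a texture feature table to CSV
#'
#' One row per (patient, ROI kind, quantization, distance) cell. Columns:
#' \code{patient_id, label, roi_kind, n_levels, distance} followed by the 11
#' features in the canonical order \code{GLCM_FEATURE_NAMES}. Values are
#' written with full double precision so a read-back reproduces them to at
#' least 12 significant digits.
#'
#' @param rows A data.frame with the schema above (as produced by
#'   \code{\link{extract_feature_table}}).
#' @param path Output CSV path.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("rows must be a non-empty data.frame")
  want <- c("patient_id", "label", "roi_kind", "n_levels", "distance",
            GLCM_FEATURE_NAMES)
  missing <- setdiff(want, names(rows))
  if (length(missing))
    stop(sprintf("feature table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  rows <- rows[, want]
  old <- options(digits = 17); on.exit(options(old))
  ok <- tryCatch({
    utils::write.csv(format(rows, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write feature table to '%s'", path))
  invisible(path)
}

#' Read a texture feature table written by \code{write_feature_table}
#'
#' @param path CSV path.
#' @return A data.frame with the canonical feature-table schema.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("patient_id", "label", "roi_kind", "n_levels", "distance",
            GLCM_FEATURE_NAMES)
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("not a feature table, missing: %s",
                 paste(missing, collapse = ", ")))
  df$patient_id <- as.character(df$patient_id)
  df
}

# ---- writers (used by the synthetic-cohort CLI and fixtures) --------------

mask_to_array <- function(masks) {
  arr <- vapply(masks, function(m) m * 1, matrix(0, nrow(masks[[1L]]),
                                                 ncol(masks[[1L]])))
  array(arr, dim = c(dim(masks[[1L]]), length(masks)))
}

#' Write a patient record to disk as NIfTI volume + masks
#'
#' Intensities are stored as single-precision float, masks as uint8.
#'
#' @param record A \code{patient_record}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (volume, core, breast).
#' @export
write_patient_nifti <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$patient_id
  vol <- array(unlist(record$stack$slices),
               dim = c(dim(record$stack$slices[[1L]]),
                       length(record$stack$slices)))
  paths <- file.path(dir, paste0(id, c("", "_core", "_breast"), ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "float"), paths[1L])
  RNifti::writeNifti(RNifti::asNifti(mask_to_array(record$masks$core),
                                     datatype = "uint8"), paths[2L])
  RNifti::writeNifti(RNifti::asNifti(mask_to_array(record$masks$breast),
                                     datatype = "uint8"), paths[3L])
  invisible(paths)
}

#' Write a patient record as per-slice TIFF files
#'
#' Intensities are stored as 16-bit unsigned TIFF (requires integer
#' intensities in [0, 65535], which the phantom generator produces), masks as
#' 8-bit TIFF, in subdirectories \code{<id>/}, \code{<id>_core/},
#' \code{<id>_breast/} with numeric slice suffixes. Reading the result back
#' with \code{\link{read_patient}} reproduces the record exactly.
#'
#' @inheritParams write_patient_nifti
#' @export
write_patient_tiff <- function(record, dir) {
  id <- record$patient_id
  dirs <- file.path(dir, paste0(id, c("", "_core", "_breast")))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(record$stack$slices)) {
    s <- record$stack$slices[[k]]
    if (any(s != round(s)) || any(s < 0) || any(s > 65535))
      stop("16-bit TIFF export requires integer intensities in [0, 65535]")
    suffix <- sprintf("slice_%03d.tif", k)
    tiff::writeTIFF(s / 65535, file.path(dirs[1L], suffix),
                    bits.per.sample = 16L)
    tiff::writeTIFF(record$masks$core[[k]] * 1, file.path(dirs[2L], suffix),
                    bits.per.sample = 8L)
    tiff::writeTIFF(record$masks$breast[[k]] * 1, file.path(dirs[3L], suffix),
                    bits.per.sample = 8L)
  }
  invisible(dirs)
}
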