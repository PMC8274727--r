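# Phantom cohort generator: elliptical multi-slice tumors with
# Gaussian-random-field texture per region and Rician-like magnitude noise.

#' Texture parameters for one phantom region
#'
#' The region's texture is a Gaussian random field: white noise smoothed with
#' a Gaussian kernel of scale \code{smoothing_sigma} (pixels), rescaled to
#' \code{mean_intensity} +/- \code{intensity_sd}. Larger smoothing gives
#' smoother texture, hence lower GLCM contrast and higher homogeneity; the
#' single scalar is the separability knob for phantom experiments.
#'
#' @param smoothing_sigma Gaussian blur scale in pixels (>= 0; 0 = raw noise).
#' @param mean_intensity Region mean, arbitrary units.
#' @param intensity_sd Region standard deviation, arbitrary units (>= 0).
#' @return A \code{texture_params} object.
#' @export
texture_params <- function(smoothing_sigma, mean_intensity, intensity_sd) {
  stopifnot(smoothing_sigma >= 0, intensity_sd >= 0)
  structure(list(smoothing_sigma = smoothing_sigma,
                 mean_intensity = mean_intensity,
                 intensity_sd = intensity_sd),
            class = "texture_params")
}

#' Phantom cohort configuration
#'
#' Defaults emulate the study cohort the pipeline targets: 102 patients with
#' an 81\%/19\% responder/non-responder imbalance (83 R, 19 NR), multi-slice
#' elliptical tumors inside a breast-tissue ellipse, class-dependent core
#' texture (non-responders rougher than responders), a peritumoral band with
#' its own texture, and Rician-like noise.
#'
#' @param n_R,n_NR Patients per class (responders / non-responders).
#' @param slices_per_patient Integer range (min, max) of slices.
#' @param image_shape (rows, cols) of each slice; must accommodate the tumor
#'   plus a 15-pixel margin inside the breast ellipse.
#' @param tumor_axes_range Range (min, max) of tumor semi-axes in pixels.
#' @param core_params,margin_params Named lists with elements \code{R} and
#'   \code{NR}, each a \code{\link{texture_params}}.
#' @param background_params \code{texture_params} for breast tissue outside
#'   the core and band.
#' @param noise_sigma Rician-like noise scale, arbitrary units.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return A \code{cohort_config} object.
#' @export
cohort_config <- function(n_R = 83L, n_NR = 19L,
                          slices_per_patient = c(3L, 5L),
                          image_shape = c(96L, 96L),
                          tumor_axes_range = c(8, 14),
                          core_params = list(
                            R  = texture_params(2.5, 420, 60),
                            NR = texture_params(0.8, 420, 60)),
                          margin_params = list(
                            R  = texture_params(1.5, 300, 50),
                            NR = texture_params(1.5, 300, 50)),
                          background_params = texture_params(1.5, 200, 40),
                          noise_sigma = 10,
                          seed = 1L) {
  stopifnot(n_R + n_NR >= 2, length(image_shape) == 2L,
            all(c("R", "NR") %in% names(core_params)),
            all(c("R", "NR") %in% names(margin_params)))
  # tumor + 15 px band + clearance must fit in the breast ellipse
  if (min(image_shape) < 2 * (max(tumor_axes_range) + 15 + 6))
    stop("image_shape too small for the tumor plus a 15-pixel margin")
  structure(list(n_R = as.integer(n_R), n_NR = as.integer(n_NR),
                 slices_per_patient = as.integer(slices_per_patient),
                 image_shape = as.integer(image_shape),
                 tumor_axes_range = tumor_axes_range,
                 core_params = core_params, margin_params = margin_params,
                 background_params = background_params,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Rasterize a rotated ellipse
#'
#' A pixel belongs to the mask iff its center lies inside the ellipse with
#' semi-axes \code{axes} rotated by \code{angle} degrees about \code{center}
#' (row/col coordinates, 1-based as usual in R).
#'
#' @param shape (rows, cols) of the raster.
#' @param center (row, col) of the ellipse center.
#' @param axes Semi-axes (a, b) in pixels, both > 0.
#' @param angle Rotation in degrees.
#' @return A logical matrix.
#' @export
make_elliptical_mask <- function(shape, center, axes, angle = 0) {
  stopifnot(length(shape) == 2L, length(center) == 2L, length(axes) == 2L,
            all(axes > 0))
  th <- angle * pi / 180
  # exact extents of the rotated ellipse along the raster axes
  ext_r <- sqrt((axes[1L] * cos(th))^2 + (axes[2L] * sin(th))^2)
  ext_c <- sqrt((axes[1L] * sin(th))^2 + (axes[2L] * cos(th))^2)
  if (center[1L] - ext_r < 1 || center[1L] + ext_r > shape[1L] ||
      center[2L] - ext_c < 1 || center[2L] + ext_c > shape[2L])
    stop("ellipse extends beyond the raster")
  r <- matrix(seq_len(shape[1L]) - center[1L], shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]) - center[2L], shape[1L], shape[2L],
               byrow = TRUE)
  u <- r * cos(th) + c_ * sin(th)
  v <- -r * sin(th) + c_ * cos(th)
  (u / axes[1L])^2 + (v / axes[2L])^2 <= 1
}

# Separable Gaussian smoothing with edge replication; sigma = 0 is identity.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {           # along rows
    top <- m[rep(1L, half), , drop = FALSE]
    bot <- m[rep(nrow(m), half), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(mat))))
}

# A standardized Gaussian random field over the whole slice (mean 0, sd 1
# empirically), so region scaling does not depend on region size.
random_field <- function(shape, sigma) {
  z <- gaussian_smooth(matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L]),
                       sigma)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

region_fill <- function(shape, params) {
  if (params$intensity_sd == 0)
    return(matrix(params$mean_intensity, shape[1L], shape[2L]))
  params$mean_intensity +
    params$intensity_sd * random_field(shape, params$smoothing_sigma)
}

#' Generate one phantom patient
#'
#' Builds a multi-slice stack in which the breast is a large ellipse, the
#' tumor core a smaller ellipse kept at least 15 pixels clear of the breast
#' boundary (so all margin bands fit), a ~15-pixel band around the core
#' carries the margin texture, and the rest of the breast the background
#' texture. Rician-like noise (magnitude of the signal plus two independent
#' Gaussian perturbations of scale \code{noise_sigma}) is applied to the
#' whole image, and intensities are rounded to integers as in real scanner
#' output.
#'
#' @param class_label \code{"R"} or \code{"NR"}; selects the class's core and
#'   margin texture parameters.
#' @param config A \code{\link{cohort_config}}.
#' @param seed Optional integer; when given, the record is a pure function of
#'   (label, config, seed).
#' @param patient_id Identifier (default derived from label and seed).
#' @return A \code{patient_record}.
#' @export
generate_patient <- function(class_label, config, seed = NULL,
                             patient_id = NULL) {
  stopifnot(class_label %in% c("R", "NR"), inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(patient_id))
    patient_id <- sprintf("P_%s_%s", class_label,
                          if (is.null(seed)) "x" else seed)
  shape <- config$image_shape
  breast_center <- (shape + 1) / 2
  breast_axes <- shape / 2 - 3
  breast <- make_elliptical_mask(shape, breast_center, breast_axes)

  # sample tumor geometry until the core keeps >= 15 px clearance inside the
  # breast (checked exactly: the 15-px disc dilation must stay in the breast)
  core2d <- NULL
  for (try in 1:25) {
    axes <- sort(stats::runif(2, config$tumor_axes_range[1L],
                              config$tumor_axes_range[2L]), decreasing = TRUE)
    jitter_max <- pmax(0, breast_axes - max(axes) - 18)
    center <- breast_center + stats::runif(2, -1, 1) * pmin(jitter_max, 10)
    angle <- stats::runif(1, 0, 180)
    cand <- tryCatch(make_elliptical_mask(shape, center, axes, angle),
                     error = function(e) NULL)
    if (is.null(cand) || sum(cand) == 0L) next
    if (all(breast[dilate_disc(cand, 15)])) { core2d <- cand; break }
  }
  if (is.null(core2d))
    stop("could not place a tumor with 15-pixel clearance after 25 attempts")

  n_slices <- sample(seq(config$slices_per_patient[1L],
                         config$slices_per_patient[2L]), 1L)
  band2d <- dilate_disc(core2d, 15) & !core2d & breast
  cp <- config$core_params[[class_label]]
  mp <- config$margin_params[[class_label]]
  slices <- core <- brst <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    img <- matrix(0, shape[1L], shape[2L])
    bg <- region_fill(shape, config$background_params)
    img[breast] <- bg[breast]
    mg <- region_fill(shape, mp)
    img[band2d] <- mg[band2d]
    co <- region_fill(shape, cp)
    img[core2d] <- co[core2d]
    if (config$noise_sigma > 0) {
      n1 <- matrix(stats::rnorm(prod(shape), sd = config$noise_sigma),
                   shape[1L], shape[2L])
      n2 <- matrix(stats::rnorm(prod(shape), sd = config$noise_sigma),
                   shape[1L], shape[2L])
      img <- sqrt((img + n1)^2 + n2^2)
    }
    img <- pmin(pmax(round(img), 0), 65535)
    slices[[k]] <- img
    core[[k]] <- core2d
    brst[[k]] <- breast
  }
  patient_record(patient_id, class_label,
                 slice_stack(patient_id, slices),
                 mask_set(core, brst))
}

#' Generate a phantom cohort
#'
#' Exactly \code{n_R} responders and \code{n_NR} non-responders, in an order
#' shuffled by the configuration seed; fully reproducible from the
#' configuration alone.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A list of \code{patient_record}s.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  labels <- sample(c(rep("R", config$n_R), rep("NR", config$n_NR)))
  seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
  lapply(seq_along(labels), function(i)
    generate_patient(labels[i], config, seed = seeds[i],
                     patient_id = sprintf("P%03d_%s", i, labels[i])))
}

#' Write a phantom cohort to disk
#'
#' Per-patient NIfTI volume + core/breast masks (or per-slice 16-bit TIFF
#' directories) and a \code{labels.csv} with columns patient_id, label.
#'
#' @param records List of \code{patient_record}s.
#' @param dir Output directory.
#' @param format \code{"nifti"} or \code{"tiff"}.
#' @return Invisibly, the labels.csv path.
#' @export
write_cohort <- function(records, dir, format = c("nifti", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in records)
    switch(format,
           nifti = write_patient_nifti(rec, dir),
           tiff = write_patient_tiff(rec, dir))
  labels <- data.frame(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    label = vapply(records, `[[`, "", "label"))
  path <- file.path(dir, "labels.csv")
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
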