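# Quantization, masked direction-averaged slice-pooled GLCMs, the 11 texture
# features, and sliding-window feature maps.

ALLOWED_LEVELS <- c(16L, 32L, 64L, 128L, 256L)

#' Quantize in-ROI intensities to discrete grey levels
#'
#' Grey-level binning happens after ROI selection so tissue outside the ROI
#' never influences the bins. The range [lo, hi] is the min/max of in-ROI
#' intensities pooled over all slices; bins are equal-width;
#' label = floor(N_g (x - lo)/(hi - lo)) clamped to N_g - 1. A constant ROI
#' (hi = lo) maps entirely to level 0. Out-of-ROI pixels carry NA.
#'
#' @param stack A \code{slice_stack}.
#' @param roi Per-slice logical masks (list, or single matrix).
#' @param n_levels Number of grey levels N_g, one of 16, 32, 64, 128, 256
#'   (other positive values are accepted for testing).
#' @return A \code{quantized_roi}: per-slice integer label matrices (0-based,
#'   NA outside the ROI), \code{n_levels} and the \code{roi}.
#' @export
quantize <- function(stack, roi, n_levels) {
  if (is.matrix(roi)) roi <- list(roi)
  slices <- if (inherits(stack, "slice_stack")) stack$slices
            else if (is.matrix(stack)) list(stack) else stack
  stopifnot(length(slices) == length(roi), n_levels >= 2)
  vals <- unlist(lapply(seq_along(slices),
                        function(k) slices[[k]][roi[[k]]]))
  if (length(vals) == 0L) stop("empty ROI")
  lo <- min(vals); hi <- max(vals)
  labels <- lapply(seq_along(slices), function(k) {
    lab <- matrix(NA_integer_, nrow(slices[[k]]), ncol(slices[[k]]))
    x <- slices[[k]][roi[[k]]]
    l <- if (hi > lo) pmin(floor(n_levels * (x - lo) / (hi - lo)),
                           n_levels - 1)
         else rep(0L, length(x))
    lab[roi[[k]]] <- as.integer(l)
    lab
  })
  structure(list(labels = labels, n_levels = as.integer(n_levels),
                 roi = roi, range = c(lo, hi)),
            class = "quantized_roi")
}

# Accumulate raw symmetric co-occurrence counts for one slice and one offset
# (dr, dc): pairs where BOTH pixels are in-ROI, plus the transposed pairs.
glcm_counts_slice <- function(lab, dr, dc, n_levels) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L)
    return(matrix(0, n_levels, n_levels))
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(matrix(0, n_levels, n_levels))
  i <- a[keep]; j <- b[keep]
  counts <- matrix(tabulate(i * n_levels + j + 1L, n_levels * n_levels),
                   n_levels, n_levels, byrow = TRUE)
  counts + t(counts)
}

#' Compute a masked, direction-averaged, slice-pooled GLCM
#'
#' For each slice and each offset in \code{directions} (default the four
#' standard 2D directions (0,d), (d,0), (d,d), (d,-d)), pixel pairs with both
#' ends inside the ROI are counted; transposed counts are added so the matrix
#' is symmetric; counts are accumulated over all directions and slices and
#' normalized once at the end. Pooling the four directions before
#' normalization is what makes the downstream features directionally
#' invariant; pooling slices weights each slice by its pair count.
#'
#' @param q A \code{quantized_roi} from \code{\link{quantize}}.
#' @param d Offset distance in pixels (>= 1).
#' @param directions A list of (dr, dc) offsets overriding the default four.
#' @return A \code{glcm} object: probability matrix \code{P} (N_g x N_g,
#'   summing to 1), \code{n_levels}, \code{d}, \code{directions},
#'   \code{pooled_slices}.
#' @export
compute_glcm <- function(q, d, directions = NULL) {
  stopifnot(inherits(q, "quantized_roi"), d >= 1)
  if (is.null(directions))
    directions <- list(c(0, d), c(d, 0), c(d, d), c(d, -d))
  n <- q$n_levels
  counts <- matrix(0, n, n)
  for (lab in q$labels)
    for (off in directions)
      counts <- counts + glcm_counts_slice(lab, off[1L], off[2L], n)
  total <- sum(counts)
  if (total == 0)
    stop(sprintf("insufficient pairs: no in-ROI pixel pairs at distance %d", d))
  structure(list(P = counts / total, n_levels = n, d = d,
                 directions = directions,
                 pooled_slices = length(q$labels) > 1L),
            class = "glcm")
}

#' Compute the 11 texture features from a GLCM
#'
#' With P(i, j) the co-occurrence probabilities over grey levels
#' i, j = 0..N_g-1 (0-based indices):
#' contrast CON = sum P (i-j)^2; dissimilarity DIS = sum P |i-j|;
#' homogeneity HOM = sum P / (1 + (i-j)^2); angular second moment
#' ASM = sum P^2; energy ENE = sqrt(ASM); maximum probability MAX = max P;
#' entropy ENT = -sum P ln P over P > 0; mean MEA = sum i P(i,j);
#' variance VAR = sum (i - MEA)^2 P(i,j); STD = sqrt(VAR); correlation
#' COR = sum (i - MEA)(j - MEA) P / VAR (row and column marginals coincide by
#' symmetry). When the ROI is constant (STD = 0) COR is undefined and
#' reported as NA with a warning, never as 0.
#'
#' @param G A \code{glcm} object (or a bare probability matrix).
#' @return Named numeric vector of the 11 features in canonical order.
#' @export
compute_features <- function(G) {
  P <- if (inherits(G, "glcm")) G$P else G
  n <- nrow(P)
  idx <- 0:(n - 1)
  I <- matrix(idx, n, n)           # row index i
  J <- matrix(idx, n, n, byrow = TRUE)
  D <- I - J
  CON <- sum(P * D^2)
  DIS <- sum(P * abs(D))
  HOM <- sum(P / (1 + D^2))
  ASM <- sum(P^2)
  ENE <- sqrt(ASM)
  MAXP <- max(P)
  pos <- P > 0
  ENT <- -sum(P[pos] * log(P[pos]))
  MEA <- sum(I * P)
  VARF <- sum((I - MEA)^2 * P)
  STD <- sqrt(VARF)
  COR <- if (STD > 0) sum((I - MEA) * (J - MEA) * P) / VARF else {
    warning("zero grey-level variance: correlation undefined (NA)")
    NA_real_
  }
  c(CON = CON, DIS = DIS, HOM = HOM, ASM = ASM, ENE = ENE, MAX = MAXP,
    ENT = ENT, MEA = MEA, VAR = VARF, STD = STD, COR = COR)
}

#' Extract one patient's texture feature vector
#'
#' Convenience wrapper: select the ROI, quantize, pool the GLCM over slices
#' and the four directions, and compute the 11 features.
#'
#' @param record A \code{patient_record}.
#' @param roi_kind \code{"core"} or \code{"margin5"/"margin10"/"margin15"}.
#' @param n_levels Grey levels.
#' @param d Offset distance (restricted to 1 for margin ROIs by the pipeline).
#' @return Named numeric feature vector.
#' @export
patient_features <- function(record, roi_kind, n_levels, d) {
  roi <- select_roi(record, roi_kind)
  if (sum(vapply(roi, sum, 0)) == 0)
    stop(sprintf("empty ROI '%s' for patient %s", roi_kind,
                 record$patient_id))
  compute_features(compute_glcm(quantize(record$stack, roi, n_levels), d))
}

#' Build the cohort feature table for one (ROI, quantization, distance) cell
#'
#' @param records List of \code{patient_record}s.
#' @param roi_kind,n_levels,d As in \code{\link{patient_features}}.
#' @return A data.frame in the canonical feature-table schema.
#' @export
extract_feature_table <- function(records, roi_kind, n_levels, d) {
  rows <- lapply(records, function(rec) {
    fv <- patient_features(rec, roi_kind, n_levels, d)
    cbind(data.frame(patient_id = rec$patient_id, label = rec$label,
                     roi_kind = roi_kind, n_levels = n_levels, distance = d,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Sliding-window texture feature map
#'
#' At each in-ROI pixel, the chosen feature is computed from a GLCM over the
#' window x window neighborhood intersected with the ROI. Quantization bounds
#' come from the global ROI (the whole-slice in-ROI range), not per window,
#' so grey levels mean the same thing across the map. Pixels outside the ROI,
#' or whose neighborhood yields fewer than one valid pair, are NA.
#'
#' @param slice A 2D numeric matrix.
#' @param roi Logical matrix, same shape.
#' @param feature One of the 11 feature names.
#' @param n_levels Grey levels.
#' @param d Offset distance.
#' @param window Odd window size >= 3 (default 5).
#' @return A numeric matrix, NA outside the ROI.
#' @export
compute_feature_map <- function(slice, roi, feature, n_levels, d = 1,
                                window = 5) {
  stopifnot(feature %in% GLCM_FEATURE_NAMES, window >= 3, window %% 2 == 1)
  q <- quantize(slice, roi, n_levels)     # global quantization bounds
  lab <- q$labels[[1L]]
  half <- (window - 1) / 2
  out <- matrix(NA_real_, nrow(slice), ncol(slice))
  for (r in seq_len(nrow(slice))) for (c_ in seq_len(ncol(slice))) {
    if (!roi[r, c_]) next
    rr <- max(1, r - half):min(nrow(slice), r + half)
    cc <- max(1, c_ - half):min(ncol(slice), c_ + half)
    sub <- lab[rr, cc, drop = FALSE]
    counts <- matrix(0, n_levels, n_levels)
    for (off in list(c(0, d), c(d, 0), c(d, d), c(d, -d)))
      counts <- counts + glcm_counts_slice(sub, off[1L], off[2L], n_levels)
    if (sum(counts) < 4) next   # < 2 valid pairs (each pair counted twice)
    fv <- suppressWarnings(compute_features(counts / sum(counts)))
    out[r, c_] <- fv[[feature]]
  }
  out
}
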