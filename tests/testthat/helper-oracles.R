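# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive pair-enumeration GLCM oracle: loops over every pixel and every
# direction, counting (i, j) and (j, i) when both ends are in-ROI. Kept
# deliberately naive and separate from the package implementation.
brute_glcm <- function(label_slices, d, n_levels,
                       directions = list(c(0, d), c(d, 0), c(d, d),
                                         c(d, -d))) {
  counts <- matrix(0, n_levels, n_levels)
  for (lab in label_slices) {
    nr <- nrow(lab); nc <- ncol(lab)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (is.na(lab[r, cc])) next
      for (off in directions) {
        r2 <- r + off[1L]; c2 <- cc + off[2L]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(lab[r2, c2])) next
        i <- lab[r, cc] + 1L; j <- lab[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  if (sum(counts) == 0) stop("oracle: no valid pairs")
  counts / sum(counts)
}

# Literal straight-from-formula feature oracle (explicit double loops).
literal_features <- function(P) {
  n <- nrow(P)
  CON <- DIS <- HOM <- ASM <- ENT <- MEA <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]; di <- (i - 1) - (j - 1)
    CON <- CON + p * di^2
    DIS <- DIS + p * abs(di)
    HOM <- HOM + p / (1 + di^2)
    ASM <- ASM + p^2
    if (p > 0) ENT <- ENT - p * log(p)
    MEA <- MEA + (i - 1) * p
  }
  VARF <- 0
  for (i in 1:n) for (j in 1:n) VARF <- VARF + ((i - 1) - MEA)^2 * P[i, j]
  COR <- NA_real_
  if (VARF > 0) {
    s <- 0
    for (i in 1:n) for (j in 1:n)
      s <- s + ((i - 1) - MEA) * ((j - 1) - MEA) * P[i, j]
    COR <- s / VARF
  }
  c(CON = CON, DIS = DIS, HOM = HOM, ASM = ASM, ENE = sqrt(ASM),
    MAX = max(P), ENT = ENT, MEA = MEA, VAR = VARF, STD = sqrt(VARF),
    COR = COR)
}

# A random symmetric normalized GLCM for formula tests.
random_glcm <- function(n_levels) {
  M <- matrix(stats::runif(n_levels^2), n_levels, n_levels)
  M <- M + t(M)
  M / sum(M)
}

# A quantized_roi built directly from a 0-based label matrix (NA outside).
as_qroi <- function(lab, n_levels) {
  structure(list(labels = if (is.list(lab)) lab else list(lab),
                 n_levels = as.integer(n_levels),
                 roi = lapply(if (is.list(lab)) lab else list(lab),
                              function(m) !is.na(m)),
                 range = c(0, n_levels - 1)),
            class = "quantized_roi")
}

# A 2-level checkerboard label matrix.
checkerboard <- function(nr, nc) {
  outer(seq_len(nr), seq_len(nc), function(r, c) as.integer((r + c) %% 2))
}

# A minimal patient record from explicit matrices.
toy_record <- function(slices, core, breast, label = "NR", id = "toy") {
  if (is.matrix(slices)) slices <- list(slices)
  if (is.matrix(core)) core <- list(core)
  if (is.matrix(breast)) breast <- list(breast)
  patient_record(id, label, slice_stack(id, slices), mask_set(core, breast))
}

# A labeled feature table with all 11 columns: noise everywhere except an
# optional planted separating feature.
noise_feature_table <- function(n_per_class, planted = NULL, gap = 6) {
  n <- 2 * n_per_class
  lab <- rep(c("R", "NR"), each = n_per_class)
  tab <- data.frame(patient_id = sprintf("p%02d", seq_len(n)), label = lab,
                    stringsAsFactors = FALSE)
  for (f in GLCM_FEATURE_NAMES) tab[[f]] <- stats::rnorm(n)
  if (!is.null(planted))
    for (f in planted)
      tab[[f]] <- stats::rnorm(n, mean = ifelse(lab == "NR", gap, 0), sd = 1)
  tab
}

# Light phantom geometry for tests that only exercise counts or labels.
light_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(64L, 64L), tumor_axes_range = c(6, 9),
         slices_per_patient = c(2L, 3L)),
    list(...))
  do.call(cohort_config, args)
}
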