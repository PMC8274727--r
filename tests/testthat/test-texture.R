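test_that("quantization follows the equal-width binning rule", {
  # constant ROI: every label 0
  q <- quantize(matrix(7, 5, 5), matrix(TRUE, 5, 5), 32)
  expect_true(all(q$labels[[1L]] == 0L))
  # endpoints map to the extreme bins
  m <- matrix(c(0, 255, 0, 255), 2, 2)
  q2 <- quantize(m, matrix(TRUE, 2, 2), 16)
  expect_setequal(unique(as.vector(q2$labels[[1L]])), c(0L, 15L))
  # out-of-ROI intensities never influence the bins
  m3 <- matrix(c(10, 20, 1e6, -1e6), 2, 2)
  roi3 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  q3 <- quantize(m3, roi3, 16)
  expect_identical(q3$range, c(10, 20))
  expect_true(all(is.na(q3$labels[[1L]][!roi3])))
  expect_error(quantize(m3, matrix(FALSE, 2, 2), 16), "empty ROI")
})

test_that("uniform intensities fill every bin roughly evenly", {
  set.seed(1)
  m <- matrix(stats::runif(64 * 64), 64, 64)
  roi <- matrix(TRUE, 64, 64)
  q <- quantize(m, roi, 32)
  labs <- as.vector(q$labels[[1L]])
  expect_setequal(sort(unique(labs)), 0:31)
  # direct binning-formula oracle applied pixel-wise
  lo <- min(m); hi <- max(m)
  oracle <- pmin(floor(32 * (m - lo) / (hi - lo)), 31)
  expect_identical(q$labels[[1L]], matrix(as.integer(oracle), 64, 64))
  p <- suppressWarnings(stats::chisq.test(table(labs))$p.value)
  expect_gt(p, 0.001)
})

test_that("checkerboard and constant-label GLCMs match analytic values", {
  lab <- checkerboard(8, 8)
  q <- as_qroi(lab, 2)
  # horizontal-only direction set: all pairs discordant
  Gh <- compute_glcm(q, 1, directions = list(c(0, 1)))
  expect_equal(Gh$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # 4-direction pooling: diagonal pairs concordant, axial pairs discordant
  G4 <- compute_glcm(q, 1)
  expect_gt(G4$P[1, 1] + G4$P[2, 2], 0)
  expect_gt(G4$P[1, 2], 0)
  expect_equal(sum(G4$P), 1, tolerance = 1e-12)

  const <- as_qroi(matrix(0L, 6, 6), 4)
  Gc <- compute_glcm(const, 2)
  expect_equal(Gc$P[1, 1], 1)
  expect_equal(sum(Gc$P), 1)
})

test_that("masked GLCMs match the exhaustive pair-enumeration oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n_levels <- sample(c(4, 8, 16), 1)
    lab <- matrix(sample(0:(n_levels - 1), 16 * 16, TRUE), 16, 16)
    roi <- matrix(stats::runif(256) < 0.6, 16, 16)
    lab[!roi] <- NA
    if (sum(roi) < 10) next
    d <- sample(c(1, 3), 1)
    got <- compute_glcm(as_qroi(lab, n_levels), d)
    expect_equal(got$P, brute_glcm(list(lab), d, n_levels),
                 tolerance = 1e-12)
  }
})

test_that("slice pooling accumulates counts before normalizing", {
  lab1 <- matrix(0L, 4, 4)               # 48 symmetric pairs at d=1 horiz+vert
  lab2 <- checkerboard(4, 4)
  got <- compute_glcm(as_qroi(list(lab1, lab2), 2), 1,
                      directions = list(c(0, 1), c(1, 0)))
  expect_equal(got$P, brute_glcm(list(lab1, lab2), 1, 2,
                                 directions = list(c(0, 1), c(1, 0))),
               tolerance = 1e-12)
  expect_true(got$pooled_slices)
})

test_that("analytic feature limits: delta and two-cell matrices", {
  delta <- matrix(0, 4, 4); delta[1, 1] <- 1
  f <- suppressWarnings(compute_features(delta))
  expect_equal(f[["CON"]], 0); expect_equal(f[["DIS"]], 0)
  expect_equal(f[["HOM"]], 1); expect_equal(f[["ASM"]], 1)
  expect_equal(f[["ENE"]], 1); expect_equal(f[["MAX"]], 1)
  expect_equal(f[["ENT"]], 0); expect_equal(f[["MEA"]], 0)
  expect_equal(f[["VAR"]], 0); expect_equal(f[["STD"]], 0)
  expect_true(is.na(f[["COR"]]))
  expect_warning(compute_features(delta), "correlation undefined")

  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g <- compute_features(two)
  expect_equal(g[["CON"]], 1); expect_equal(g[["DIS"]], 1)
  expect_equal(g[["HOM"]], 0.5); expect_equal(g[["ASM"]], 0.5)
  expect_equal(g[["ENE"]], sqrt(0.5)); expect_equal(g[["MAX"]], 0.5)
  expect_equal(g[["ENT"]], log(2)); expect_equal(g[["MEA"]], 0.5)
  expect_equal(g[["VAR"]], 0.25); expect_equal(g[["STD"]], 0.5)
  expect_equal(g[["COR"]], -1)
})

test_that("features match the literal-formula oracle on random GLCMs", {
  set.seed(11)
  for (rep in 1:50) {
    P <- random_glcm(sample(c(4, 8, 16), 1))
    got <- compute_features(P)
    want <- literal_features(P)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(got[["ENE"]], sqrt(got[["ASM"]]), tolerance = 1e-12)
    expect_equal(got[["STD"]], sqrt(got[["VAR"]]), tolerance = 1e-12)
    expect_true(got[["HOM"]] > 0 && got[["HOM"]] <= 1)
    expect_true(got[["MAX"]] > 0 && got[["MAX"]] <= 1)
    expect_true(got[["COR"]] >= -1 - 1e-12 && got[["COR"]] <= 1 + 1e-12)
  }
})

test_that("contrast falls and homogeneity rises with smoother texture", {
  set.seed(13)
  sigmas <- c(0.3, 0.8, 1.5, 2.5, 4)
  stats_by_sigma <- t(vapply(sigmas, function(sg) {
    cfg <- light_cohort_config(
      n_R = 5L, n_NR = 5L, slices_per_patient = c(1L, 1L),
      core_params = list(R = texture_params(sg, 420, 60),
                         NR = texture_params(sg, 420, 60)),
      noise_sigma = 0, seed = 1000 + round(10 * sg))
    coh <- generate_cohort(cfg)
    tab <- extract_feature_table(coh, "core", 32, 1)
    c(CON = mean(tab$CON), HOM = mean(tab$HOM))
  }, c(CON = 0, HOM = 0)))
  expect_true(all(diff(stats_by_sigma[, "CON"]) < 0))
  expect_true(all(diff(stats_by_sigma[, "HOM"]) > 0))
})

test_that("margin ROIs with too few pairs raise an insufficient-pairs error", {
  lab <- matrix(NA_integer_, 8, 8)
  lab[1, 1] <- 0L                        # single pixel: no pair at any d
  expect_error(compute_glcm(as_qroi(lab, 4), 1), "insufficient pairs")
})

test_that("feature maps agree with a per-pixel brute-force reference", {
  set.seed(5)
  slice <- matrix(stats::runif(81, 0, 100), 9, 9)
  roi <- matrix(TRUE, 9, 9); roi[1, ] <- FALSE
  got <- compute_feature_map(slice, roi, "CON", n_levels = 4, d = 1,
                             window = 3)
  q <- quantize(slice, roi, 4)
  lab <- q$labels[[1L]]
  for (r in 1:9) for (cc in 1:9) {
    if (!roi[r, cc]) {
      expect_true(is.na(got[r, cc]))
      next
    }
    rr <- max(1, r - 1):min(9, r + 1)
    ccw <- max(1, cc - 1):min(9, cc + 1)
    sub <- lab[rr, ccw, drop = FALSE]
    P <- tryCatch(brute_glcm(list(sub), 1, 4), error = function(e) NULL)
    if (is.null(P)) expect_true(is.na(got[r, cc]))
    else expect_equal(got[r, cc],
                      suppressWarnings(literal_features(P))[["CON"]],
                      tolerance = 1e-10)
  }
})

test_that("feature-map limits: constant homogeneity map, bounded MAX map", {
  slice <- matrix(50, 7, 7)
  roi <- matrix(TRUE, 7, 7)
  hom <- compute_feature_map(slice, roi, "HOM", n_levels = 16, window = 3)
  expect_true(all(hom[roi] == 1))
  set.seed(2)
  noisy <- matrix(stats::runif(49), 7, 7)
  mx <- compute_feature_map(noisy, roi, "MAX", n_levels = 4, window = 3)
  expect_true(all(mx[roi] > 0 & mx[roi] <= 1, na.rm = TRUE))
})
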