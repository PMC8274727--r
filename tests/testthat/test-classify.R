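sep_cloud <- function(n = 20, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(2 * n), ncol = 2),
             matrix(stats::rnorm(2 * n, mean = gap), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("R", "NR"), each = n))
}

test_that("standardization uses training statistics only", {
  train <- matrix(c(8, 10, 12, 1, 2, 3), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  st <- standardize(train, matrix(c(12, 2), 1, 2))
  expect_equal(as.numeric(st$apply[1, 1]), (12 - 10) / 2)  # mean 10, sd 2
  back <- standardize(train, train)
  expect_equal(colMeans(back$apply), c(a = 0, b = 0))
  expect_equal(apply(back$apply, 2, stats::sd), c(a = 1, b = 1))
  # constant column: centered, scale forced to 1, warned
  cst <- matrix(c(5, 5, 5, 1, 2, 3), ncol = 2,
                dimnames = list(NULL, c("c", "d")))
  expect_warning(st2 <- standardize(cst), "zero-variance")
  expect_equal(st2$train[, 1], rep(0, 3))
})

test_that("balanced subsets hold all minority rows plus a matched draw", {
  labels <- c(rep("R", 83), rep("NR", 19))
  set.seed(3)
  subs <- balance_subsample(labels, n_subsets = 10)
  expect_length(subs, 10L)
  for (s in subs) {
    expect_length(s, 38L)                          # 19 R + 19 NR
    expect_identical(sum(labels[s] == "NR"), 19L)
    expect_identical(sum(labels[s] == "R"), 19L)
    expect_true(all(which(labels == "NR") %in% s))
    expect_false(any(duplicated(s)))
  }
  # already balanced: each subset is the whole data
  expect_identical(sort(balance_subsample(rep(c("R", "NR"), 5), 1)[[1L]]),
                   1:10)
  expect_error(balance_subsample(rep("R", 10), 1), "both classes")
  set.seed(77); a <- balance_subsample(labels, 5)
  set.seed(77); b <- balance_subsample(labels, 5)
  expect_identical(a, b)
})

test_that("FLD separates well-separated clouds and matches 1-D closed form", {
  d <- sep_cloud()
  st <- standardize(d$X)
  m <- fld_fit(st$train, d$y)
  expect_identical(predict(m, st$train)$label, d$y)

  # 1-D: weight reduces to sign(mu_NR - mu_R), threshold at the grand midpoint
  x1 <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1, dimnames = list(NULL, "f"))
  y1 <- c("R", "R", "R", "NR", "NR", "NR")
  m1 <- fld_fit(x1, y1)
  w <- as.numeric(m1$params$w)
  expect_gt(w, 0)
  expect_equal(m1$params$threshold / w, (1 + 11) / 2)
  expect_identical(predict(m1, x1)$label, y1)
  expect_identical(predict(m1, matrix(5.9, 1, 1))$label, "R")
  expect_identical(predict(m1, matrix(6.1, 1, 1))$label, "NR")
})

test_that("FLD axis agrees with the reference discriminant direction", {
  d <- sep_cloud(n = 30, gap = 3, seed = 9)
  st <- standardize(d$X)
  m <- fld_fit(st$train, d$y)
  ref <- MASS::lda(x = st$train, grouping = factor(d$y))
  w_ref <- ref$scaling[, 1]
  cosang <- sum(m$params$w * w_ref) /
    sqrt(sum(m$params$w^2) * sum(w_ref^2))
  expect_gt(abs(cosang), 1 - 1e-6)
})

test_that("identical class means give chance-level FLD accuracy", {
  set.seed(17)
  X <- matrix(stats::rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("R", "NR"), 50)
  m <- fld_fit(X, y)
  acc <- mean(predict(m, X)$label == y)
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 100))
  expect_lt(acc, 0.5 + 2.5 * 1.96 * sqrt(0.25 / 100))
})

test_that("SVMs fit separable data, and only RBF solves XOR", {
  d <- sep_cloud()
  st <- standardize(d$X)
  mlin <- svm_fit(st$train, d$y, "linear", C = 2^10)
  expect_identical(predict(mlin, st$train)$label, d$y)

  xor_X <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  xor_X <- rbind(xor_X, xor_X + 0.05)              # 8 points
  xor_y <- rep(c("R", "NR", "NR", "R"), 2)
  lin <- svm_fit(xor_X, xor_y, "linear", C = 2^5)
  expect_lte(mean(predict(lin, xor_X)$label == xor_y), 0.75)
  rbf <- svm_fit(xor_X, xor_y, "rbf", C = 2^5, gamma = 2^0)
  expect_identical(predict(rbf, xor_X)$label, xor_y)
})

test_that("duplicating separable training rows keeps the SVM boundary", {
  d <- sep_cloud(n = 10, gap = 8)
  st <- standardize(d$X)
  m1 <- svm_fit(st$train, d$y, "linear", C = 2^8)
  m2 <- svm_fit(rbind(st$train, st$train), c(d$y, d$y), "linear", C = 2^8)
  grid <- as.matrix(expand.grid(a = seq(-2, 4, 0.5), b = seq(-2, 4, 0.5)))
  expect_identical(predict(m1, grid)$label, predict(m2, grid)$label)
})

test_that("kNN follows its stated distance and vote tie rules", {
  train <- matrix(c(0, 1, 2, 3, 0, 0, 0, 0), ncol = 2)
  y <- c("NR", "R", "R", "NR")
  # test point identical to a training NR point
  got <- knn_fit_predict(train, y, c(0, 0), k = 1)
  expect_identical(got$label, "NR")
  expect_equal(got$score, 1)
  # 2-2 vote tie goes to NR, score one half
  got4 <- knn_fit_predict(train, y, c(1.5, 0), k = 4)
  expect_identical(got4$label, "NR")
  expect_equal(got4$score, 0.5)
  expect_error(knn_fit_predict(train, y, c(0, 0), k = 5), "exceeds")
})

test_that("kNN matches a brute-force neighbor sort on listed points", {
  set.seed(23)
  train <- matrix(stats::rnorm(20), ncol = 2)
  y <- sample(c("R", "NR"), 10, TRUE)
  for (rep in 1:5) {
    x <- stats::rnorm(2)
    d <- sqrt(colSums((t(train) - x)^2))
    nn <- order(d)[1:3]
    want <- mean(y[nn] == "NR")
    got <- knn_fit_predict(train, y, x, 3)
    expect_equal(got$score, want)
  }
})

test_that("training-row permutation leaves predictions unchanged", {
  d <- sep_cloud(n = 15, gap = 2, seed = 4)
  st <- standardize(d$X)
  test_pts <- matrix(stats::rnorm(20), ncol = 2,
                     dimnames = list(NULL, c("f1", "f2")))
  perm <- sample(nrow(st$train))
  for (fam in c("FLD", "SVM-Lin", "SVM-RBF")) {
    m1 <- glcmrad:::fit_family(fam, st$train, d$y,
                               list(C = 4, gamma = 0.5))
    m2 <- glcmrad:::fit_family(fam, st$train[perm, ], d$y[perm],
                               list(C = 4, gamma = 0.5))
    expect_identical(predict(m1, test_pts)$label, predict(m2, test_pts)$label)
    # the solver's iteration order perturbs SVM scores slightly; FLD is exact
    expect_equal(predict(m1, test_pts)$score, predict(m2, test_pts)$score,
                 tolerance = if (fam == "FLD") 1e-10 else 1e-2)
  }
  # kNN with distinct distances is also order-invariant
  k1 <- glcmrad:::knn_model(st$train, d$y, 3)
  k2 <- glcmrad:::knn_model(st$train[perm, ], d$y[perm], 3)
  expect_equal(predict(k1, test_pts)$score, predict(k2, test_pts)$score)
})

test_that("decision scores are monotone with the predicted label", {
  d <- sep_cloud(n = 12, gap = 3, seed = 6)
  st <- standardize(d$X)
  pts <- matrix(stats::rnorm(40, mean = 1.5), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
  for (fam in c("FLD", "SVM-Lin", "SVM-RBF", "kNN")) {
    m <- glcmrad:::fit_family(fam, st$train, d$y, list(C = 4, gamma = 1,
                                                       k = 3))
    pr <- predict(m, pts)
    thr_ok <- if (m$tie_ge) (pr$score >= 0) == (pr$label == "NR")
              else (pr$score > 0) == (pr$label == "NR")
    expect_true(all(thr_ok))
  }
})
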