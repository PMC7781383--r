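# Sparse PLS-DA: soft thresholding, fitting, prediction, loading filter.

test_that("soft thresholding keeps the largest entries and shrinks by lambda", {
  w <- soft_threshold_keep(c(0.9, 0.5, 0.1), 2)
  ref <- c(0.8, 0.4, 0) / sqrt(0.8^2 + 0.4^2)
  expect_equal(w, ref, tolerance = 1e-12)

  v <- c(-0.3, 1.2, 0.4, -2)
  expect_equal(soft_threshold_keep(v, 4), v / sqrt(sum(v^2)),
               tolerance = 1e-12)

  expect_equal(sum(soft_threshold_keep(rnorm(10), 1) != 0), 1)
  expect_error(soft_threshold_keep(rep(0, 3), 1), "all-zero")
  expect_error(soft_threshold_keep(1:3, 4), "keep")
})

test_that("soft thresholding matches brute-force lambda enumeration", {
  withr::with_seed(101, {
    for (i in 1:50) {
      p <- sample(3:12, 1)
      v <- rnorm(p)
      while (anyDuplicated(abs(v))) v <- rnorm(p)   # distinct magnitudes
      keep <- sample(seq_len(p - 1), 1)
      # oracle: smallest lambda among {0, |v|} leaving <= keep nonzeros
      cand <- sort(c(0, abs(v)))
      lam <- cand[which(vapply(cand, function(l)
        sum(pmax(abs(v) - l, 0) > 0), 0L) <= keep)[1]]
      ref <- sign(v) * pmax(abs(v) - lam, 0)
      ref <- ref / sqrt(sum(ref^2))
      expect_equal(soft_threshold_keep(v, keep), ref, tolerance = 1e-12)
    }
  })
})

test_that("boundary ties resolve to the first index", {
  w <- soft_threshold_keep(c(0.5, 0.5, 0.3), 1)
  expect_equal(w, c(1, 0, 0))
})

test_that("a single perfectly informative column gets loading one", {
  y <- rep(c("neg", "pos"), each = 5)
  x <- matrix(ifelse(y == "pos", 1, -1), ncol = 1,
              dimnames = list(paste0("s", 1:10), "ind"))
  m <- splsda_fit(x, y)
  expect_equal(unname(m$x_loadings[1, 1]), 1)
  expect_gt(min(m$scores[y == "pos", 1]), max(m$scores[y == "neg", 1]))
})

test_that("dense one-component fit matches the SVD oracle", {
  withr::with_seed(202, {
    for (i in 1:20) {
      tc <- toy_classed_matrix(n = 20, p = 8, shift = runif(1, 0, 2),
                               seed = sample.int(1e6, 1))
      m <- splsda_fit(tc$X, tc$y)
      ynum <- ifelse(tc$y == "pos", 1, -1)
      Y <- matrix(ynum - mean(ynum), ncol = 1)
      v <- svd(crossprod(Y, tc$X))$v[, 1]
      expect_gt(abs(sum(m$x_loadings[, 1] * v)), 1 - 1e-8)
    }
  })
})

test_that("keepX controls sparsity and is clamped with a warning", {
  tc <- toy_classed_matrix()
  m1 <- splsda_fit(tc$X, tc$y, keepX = 1)
  expect_equal(sum(m1$x_loadings[, 1] != 0), 1)
  expect_warning(m2 <- splsda_fit(tc$X, tc$y, keepX = 99), "clamped")
  expect_equal(sum(m2$x_loadings[, 1] != 0), ncol(tc$X))
})

test_that("loadings obey the unit-norm and sign-convention invariants", {
  tc <- toy_classed_matrix(n = 30, p = 12)
  for (k in c(1, 4, 12)) {
    m <- splsda_fit(tc$X, tc$y, keepX = k)
    expect_equal(sum(m$x_loadings[, 1]^2), 1, tolerance = 1e-12)
    expect_equal(sum(m$x_loadings[, 1] != 0), k)
    expect_gt(mean(m$scores[tc$y == "pos", 1]),
              mean(m$scores[tc$y == "neg", 1]))
  }
})

test_that("swapping class labels flips loadings only in sign", {
  tc <- toy_classed_matrix(n = 24, p = 6)
  y_swapped <- factor(ifelse(tc$y == "pos", "neg", "pos"),
                      levels = c("neg", "pos"))
  m1 <- splsda_fit(tc$X, tc$y)
  m2 <- splsda_fit(tc$X, y_swapped)
  # the sign convention re-anchors to the new positive class, so the
  # loading vector is reproduced exactly up to the documented sign rule
  expect_equal(abs(m1$x_loadings), abs(m2$x_loadings), tolerance = 1e-9)
  expect_gt(mean(m2$scores[y_swapped == "pos", 1]),
            mean(m2$scores[y_swapped == "neg", 1]))
})

test_that("permuting feature columns permutes loadings identically", {
  tc <- toy_classed_matrix(n = 20, p = 7)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  m1 <- splsda_fit(tc$X, tc$y, keepX = 3)
  m2 <- splsda_fit(tc$X[, perm], tc$y, keepX = 3)
  expect_equal(m1$x_loadings[colnames(tc$X)[perm], 1],
               m2$x_loadings[, 1], tolerance = 1e-10)
})

test_that("prediction reproduces training scores and centres at zero", {
  tc <- toy_classed_matrix(n = 20, p = 8)
  m <- splsda_fit(tc$X, tc$y, n_components = 2, keepX = c(5, 8))
  expect_equal(predict_scores(m, tc$X), m$scores, tolerance = 1e-10)
  zero <- matrix(0, 1, 8, dimnames = list("z", colnames(tc$X)))
  expect_equal(unname(predict_scores(m, zero)), matrix(0, 1, 2),
               tolerance = 1e-12)
  dup <- tc$X[c(3, 3), ]
  rownames(dup) <- c("a", "b")
  sc <- predict_scores(m, dup)
  expect_equal(sc["a", ], sc["b", ])
  expect_error(predict_scores(m, tc$X[, 1:4]), "absent")
})

test_that("loading filter zeroes small loadings and recomputes statistics", {
  tc <- toy_classed_matrix(n = 30, p = 6)
  m <- splsda_fit(tc$X, tc$y)
  # cutoff 0: unchanged (renormalization is a no-op on unit-norm loadings)
  m0 <- filter_by_loading(m, 0)
  expect_equal(m0$x_loadings, m$x_loadings, tolerance = 1e-12)
  expect_equal(m0$class_stats, m$class_stats, tolerance = 1e-12)

  # crafted loadings: pattern survives per the cutoff
  m$x_loadings[, 1] <- c(0.5, 0.03, -0.86, 0, 0, 0)
  mf <- filter_by_loading(m, 0.04)
  expect_equal(unname(mf$x_loadings[, 1] != 0),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(mf$x_loadings[, 1]^2), 1, tolerance = 1e-12)
  expect_equal(unname(mf$n_retained), 2)

  expect_error(filter_by_loading(m, 1), "every variable")
})

test_that("a small-enough cutoff leaves held-out calls unchanged", {
  withr::with_seed(77, {
    tc <- toy_classed_matrix(n = 40, p = 10, shift = 3)
    tr <- seq_len(30)
    te <- 31:40
  })
  m <- splsda_fit(tc$X[tr, ], tc$y[tr])
  sc_full <- predict_scores(m, tc$X[te, ])[, 1]
  calls_full <- classify_nearest_zero(sc_full, m$class_stats)$call
  mf <- filter_by_loading(m, 1e-6)
  sc_filt <- predict_scores(mf, tc$X[te, ])[, 1]
  calls_filt <- classify_nearest_zero(sc_filt, mf$class_stats)$call
  expect_equal(calls_full, calls_filt)
})

test_that("dense and sparse fits agree with the reference sPLS-DA package", {
  skip_if_not_installed("mixOmics")
  tc <- toy_classed_matrix(n = 30, p = 10, shift = 1.5, seed = 5)
  ref <- mixOmics::splsda(tc$X, tc$y, ncomp = 1, keepX = 10)
  mine <- splsda_fit(tc$X, tc$y)
  expect_gt(abs(sum(ref$loadings$X[, 1] * mine$x_loadings[, 1])),
            1 - 1e-6)
  ref3 <- mixOmics::splsda(tc$X, tc$y, ncomp = 1, keepX = 3)
  mine3 <- splsda_fit(tc$X, tc$y, keepX = 3)
  expect_setequal(names(which(ref3$loadings$X[, 1] != 0)),
                  names(which(mine3$x_loadings[, 1] != 0)))
})

test_that("single-class fits are refused", {
  tc <- toy_classed_matrix()
  expect_error(splsda_fit(tc$X, rep("pos", nrow(tc$X))), "both classes")
})

test_that("keepX tuning returns a grid value with named errors", {
  tc <- toy_classed_matrix(n = 24, p = 8, shift = 3)
  fm <- feature_matrix(tc$X + 20)   # raw-scale features
  tuned <- tune_keepx(fm, tc$y, grid = c(2, 4, 8))
  expect_true(tuned$keepX %in% c(2, 4, 8))
  expect_named(tuned$errors, c("2", "4", "8"))
  expect_true(all(tuned$errors >= 0 & tuned$errors <= 1))
})

test_that("models survive a JSON round trip", {
  tc <- toy_classed_matrix(n = 20, p = 6)
  fm <- fit_standardizer(feature_matrix(tc$X + 20))
  m <- splsda_fit(fm$values, tc$y, keepX = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path, standardizer = fm$standardization)
  m2 <- load_model(path)
  expect_equal(m2$x_loadings, m$x_loadings, tolerance = 1e-12)
  expect_equal(m2$class_stats$mean, m$class_stats$mean, tolerance = 1e-12)
  expect_equal(m2$standardization$mean, fm$standardization$mean,
               tolerance = 1e-12)
  sc1 <- predict_scores(m, fm$values)
  sc2 <- predict_scores(m2, fm$values)
  expect_equal(sc1, sc2, tolerance = 1e-12)
})
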