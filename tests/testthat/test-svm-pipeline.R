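# Split, grid search, threshold search, prediction and serialization.

test_that("split_half stratifies, is disjoint and deterministic", {
  y <- rep(c(1, -1), each = 10)
  sp <- split_half(y, seed = 1)
  expect_equal(sum(y[sp$train] == 1), 5)
  expect_equal(sum(y[sp$train] == -1), 5)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:20)
  expect_identical(split_half(y, seed = 1), sp)
  expect_false(identical(split_half(y, seed = 2), sp))

  # odd class sizes: sub-training takes the ceiling (4+3 of 7+5)
  y2 <- rep(c(1, -1), c(7, 5))
  sp2 <- split_half(y2, seed = 3)
  expect_equal(sum(y2[sp2$train] == 1), 4)
  expect_equal(sum(y2[sp2$train] == -1), 3)
  expect_setequal(c(sp2$train, sp2$validation), 1:12)

  expect_error(split_half(c(1, 1, 1, -1)), "at least 2")
})

test_that("the SMO fit separates separable data and respects the margin", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(60, 3), 15), matrix(rnorm(60, -3), 15))
  })
  y <- rep(c(1, -1), each = 15)
  fit <- rbf_svm_fit(X, y, C = 10, gamma = 0.1)
  sc <- rbf_svm_decision(fit, X)
  expect_equal(ifelse(sc >= 0, 1, -1), y)
  # a training point of a separable fit predicts its own label
  expect_gt(min(y * sc), 0)
  expect_error(rbf_svm_fit(X, rep(1, 30), C = 1, gamma = 1), "single class")
})

test_that("grid search finds a zero-error point on separable data", {
  withr::with_seed(42, {
    X <- rbind(matrix(rnorm(80, 2.5), 20), matrix(rnorm(80, -2.5), 20))
  })
  y <- rep(c(1L, -1L), each = 20)
  sp <- split_half(y, seed = 1)
  cfg <- fast_config(1)
  gs <- grid_search_fit(X[sp$train, ], y[sp$train],
                        X[sp$validation, ], y[sp$validation], cfg)
  expect_equal(gs$error, 0)
  expect_true(gs$C %in% cfg$C_grid)
  expect_true(gs$gamma %in% cfg$gamma_grid)

  # 1x1 grid returns exactly that point
  cfg1 <- training_config(C_grid = 4, gamma_grid = 0.125, repeats = 1, seed = 1)
  gs1 <- grid_search_fit(X[sp$train, ], y[sp$train],
                         X[sp$validation, ], y[sp$validation], cfg1)
  expect_equal(gs1$C, 4)
  expect_equal(gs1$gamma, 0.125)
})

test_that("permuted labels give chance-level validation error", {
  withr::with_seed(43, {
    errs <- vapply(1:20, function(i) {
      X <- matrix(rnorm(200 * 4), 200, 4)
      y <- sample(rep(c(1L, -1L), each = 100))
      sp <- split_half(y, seed = i)
      cfg <- training_config(C_grid = 2^c(0, 4), gamma_grid = 2^c(-4, 0),
                             repeats = 1, seed = i)
      grid_search_fit(X[sp$train, ], y[sp$train],
                      X[sp$validation, ], y[sp$validation], cfg)$error
    }, 0)
  })
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("threshold search recovers planted features and is deterministic", {
  withr::with_seed(44, {
    d <- make_labeled_matrix(50, 50, 30, shift_cols = 1:4, shift = 2)
  })
  cfg <- fast_config(7, repeats = 2L)
  m1 <- select_threshold_and_train(d$X, d$y, cfg)
  expect_true(all(0:3 %in% m1$selected))
  expect_s3_class(m1, "uriexc_model")
  expect_equal(nrow(m1$error_table), length(unique(m1$error_table$threshold)))

  # end-to-end determinism at the serialization level
  m2 <- select_threshold_and_train(d$X, d$y, cfg)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(m1, f1); write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # single-candidate threshold list is chosen as-is
  cfg1 <- training_config(threshold_candidates = 0.05,
                          C_grid = 2, gamma_grid = 0.1, repeats = 1, seed = 1)
  m3 <- select_threshold_and_train(d$X, d$y, cfg1)
  expect_equal(m3$threshold, 0.05)
})

test_that("the per-threshold error table is cell-reproducible from its seed", {
  withr::with_seed(45, {
    d <- make_labeled_matrix(30, 30, 10, shift_cols = 1, shift = 2)
  })
  cfg <- training_config(C_grid = 2^c(0, 4), gamma_grid = 2^c(-4, 0),
                         repeats = 2, seed = 9)
  m <- select_threshold_and_train(d$X, d$y, cfg)
  thresholds <- m$error_table$threshold
  ti <- which(is.finite(m$error_table$avg_error))[1]
  r <- 2L
  report <- rank_features(d$X, d$y)
  sel <- filter_by_threshold(report, thresholds[ti])
  sub <- d$X[, sel + 1L, drop = FALSE]
  sp <- split_half(d$y, seed = uriexc:::cell_seed(cfg$seed, ti, r))
  scaler <- uriexc:::fit_scaler(sub[sp$train, , drop = FALSE], cfg$scaling)
  gs <- grid_search_fit(uriexc:::apply_scaler(scaler, sub[sp$train, , drop = FALSE]),
                        d$y[sp$train],
                        uriexc:::apply_scaler(scaler, sub[sp$validation, , drop = FALSE]),
                        d$y[sp$validation], cfg)
  expect_identical(gs$error, unname(m$validation_errors[ti, r]))
})

test_that("prediction is permutation-equivariant and round-trips", {
  withr::with_seed(46, {
    d <- make_labeled_matrix(40, 40, 8, shift_cols = 1:2, shift = 2.5)
  })
  rownames(d$X) <- paste0("P", seq_len(nrow(d$X)))
  m <- select_threshold_and_train(d$X, d$y, fast_config(3, repeats = 2L))
  pred <- predict(m, d$X)
  perm <- sample(nrow(d$X))
  pred_perm <- predict(m, d$X[perm, ])
  expect_equal(pred_perm$score, pred$score[perm], tolerance = 1e-12)
  expect_identical(pred_perm$protein_id, pred$protein_id[perm])

  jf <- withr::local_tempfile(fileext = ".json")
  write_model(m, jf)
  m_back <- read_model(jf)
  expect_equal(predict(m_back, d$X)$score, pred$score, tolerance = 1e-12)

  # registry mismatch is refused
  X2 <- d$X
  attr(X2, "registry_version") <- "other"
  m$registry_version <- "uriexc-registry-243-v1"
  expect_error(predict(m, X2), "registry mismatch")
})
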