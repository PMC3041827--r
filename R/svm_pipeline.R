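# Training procedure: per-threshold F-score filtering, repeated stratified
# half-splits, exhaustive (C, gamma) grid search, threshold choice by lowest
# average validation error, and a final retrain on all data.

#' Training configuration
#'
#' @param threshold_candidates non-negative F-score thresholds to try;
#'   `NULL` (default) uses the empirical quantiles 0, 0.1, ..., 0.9 of the
#'   observed finite F-score distribution.
#' @param C_grid,gamma_grid positive grids for the soft-margin cost and the
#'   RBF width; defaults are the canonical log2 grids `2^(-5..15 by 2)` and
#'   `2^(-15..3 by 2)`.
#' @param repeats number of random half-splits per threshold (default 5).
#' @param split_fraction sub-training fraction of each class (default 0.5;
#'   the sub-training set receives the ceiling on odd class sizes).
#' @param seed integer master seed; every split seed derives from it.
#' @param scaling `"minmax"` (default), `"zscore"` or `"none"`; fitted on
#'   the (sub-)training rows only.
#' @param class_weight optional `c(positive = , negative = )` cost
#'   multipliers; default unweighted.
#' @return `training_config` list.
#' @export
training_config <- function(threshold_candidates = NULL,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            repeats = 5L, split_fraction = 0.5, seed = 1L,
                            scaling = c("minmax", "zscore", "none"),
                            class_weight = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(length(C_grid) >= 1L, all(C_grid > 0),
            length(gamma_grid) >= 1L, all(gamma_grid > 0),
            repeats >= 1L, split_fraction > 0, split_fraction < 1)
  if (!is.null(threshold_candidates)) {
    stopifnot(all(threshold_candidates >= 0))
  }
  structure(list(threshold_candidates = threshold_candidates,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 repeats = as.integer(repeats),
                 split_fraction = split_fraction, seed = as.integer(seed),
                 scaling = scaling, class_weight = class_weight),
            class = "training_config")
}

# deterministic per-(threshold, repeat) split seed, < 2^31
cell_seed <- function(seed, threshold_index, repeat_index) {
  as.integer((as.numeric(seed) * 48271 + threshold_index * 69427 +
                repeat_index * 6007) %% 2147483647)
}

#' Stratified half-split
#'
#' Splits rows into disjoint sub-training and sub-validation sets, stratified
#' by class; with `fraction = 0.5` and an odd class size the sub-training set
#' gets the extra row. Deterministic given the seed.
#'
#' @param labels class label vector (any encoding accepted by
#'   [rank_features()]); each class needs >= 2 rows.
#' @param seed integer seed.
#' @param fraction sub-training fraction per class.
#' @return list with integer row indices `train` and `validation`.
#' @export
split_half <- function(labels, seed = 1L, fraction = 0.5) {
  y <- as_class_labels(labels)
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L) {
    stop("each class needs at least 2 rows to split")
  }
  withr::with_seed(as.integer(seed), {
    train <- unlist(lapply(c(1L, -1L), function(cls) {
      idx <- which(y == cls)
      take <- ceiling(length(idx) * fraction)
      sort(sample(idx, take))
    }))
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(y), train))
}

#' Grid search for (C, gamma) on one split
#'
#' Exhaustive search over the configured grids; for each candidate an SVM is
#' fitted on the sub-training rows and scored by misclassification fraction
#' on the sub-validation rows. Ties break toward smaller `C`, then smaller
#' `gamma`.
#'
#' @param X_train,y_train scaled sub-training matrix and labels.
#' @param X_val,y_val scaled sub-validation matrix and labels.
#' @param config a [training_config()].
#' @return list with `C`, `gamma`, `error` (best validation error).
#' @export
grid_search_fit <- function(X_train, y_train, X_val, y_val, config) {
  y_train <- as_class_labels(y_train)
  y_val <- as_class_labels(y_val)
  if (length(unique(y_train)) < 2L) stop("sub-training set contains a single class")
  d2_tr <- pmax(outer(rowSums(X_train^2), rowSums(X_train^2), "+") -
                  2 * tcrossprod(X_train), 0)
  d2_va <- pmax(outer(rowSums(X_val^2), rowSums(X_train^2), "+") -
                  2 * tcrossprod(X_val, X_train), 0)
  best <- list(C = NA_real_, gamma = NA_real_, error = Inf)
  for (g in sort(config$gamma_grid)) {
    K_tr <- exp(-g * d2_tr)
    K_va <- exp(-g * d2_va)
    for (C in sort(config$C_grid)) {
      cw <- config$class_weight
      cpos <- if (is.null(cw)) C else C * cw[["positive"]]
      cneg <- if (is.null(cw)) C else C * cw[["negative"]]
      sol <- .smo_solve(K_tr, y_train, cpos, cneg)
      scores <- drop(K_va %*% (sol$alpha * y_train)) + sol$b
      pred <- ifelse(scores >= 0, 1L, -1L)
      err <- mean(pred != y_val)
      better <- err < best$error ||
        (err == best$error && (C < best$C ||
                                 (C == best$C && g < best$gamma)))
      if (better) best <- list(C = C, gamma = g, error = err)
    }
  }
  best
}

default_thresholds <- function(f_scores) {
  finite <- f_scores[is.finite(f_scores)]
  if (length(finite) == 0L) return(0)
  sort(unique(unname(stats::quantile(finite, probs = seq(0, 0.9, by = 0.1)))))
}

#' Threshold search and final training
#'
#' For each candidate F-score threshold: keep the features at or above it,
#' run `repeats` random stratified half-splits, grid-search (C, gamma) on
#' each sub-training set and record the sub-validation error; average the
#' errors. The threshold with the lowest average error wins (ties go to the
#' smaller threshold, i.e. more features). The final classifier is retrained
#' on all rows with the winning feature set and the best (C, gamma) from one
#' more repeated-split grid search on the full data.
#'
#' @param matrix proteins x features numeric matrix (registry order;
#'   `attr(, "registry_version")` is propagated into the model).
#' @param labels class labels.
#' @param config a [training_config()].
#' @return `uriexc_model` list: `selected` (0-based feature indices),
#'   `threshold`, `scaler`, `C`, `gamma`, `fit` (support-vector state),
#'   `error_table` (per-threshold average validation errors),
#'   `validation_errors` (threshold x repeat matrix), `registry_version`,
#'   `seed`, `feature_report`.
#' @export
select_threshold_and_train <- function(matrix, labels, config = training_config()) {
  stopifnot(is.matrix(matrix), inherits(config, "training_config"))
  y <- as_class_labels(labels)
  report <- rank_features(matrix, y)
  thresholds <- config$threshold_candidates
  if (is.null(thresholds)) thresholds <- default_thresholds(report$f_score)
  thresholds <- sort(thresholds)

  err_mat <- matrix(NA_real_, nrow = length(thresholds), ncol = config$repeats,
                    dimnames = list(NULL, paste0("repeat", seq_len(config$repeats))))
  n_feat <- integer(length(thresholds))
  any_ok <- FALSE
  for (ti in seq_along(thresholds)) {
    sel <- tryCatch(filter_by_threshold(report, thresholds[ti]),
                    error = function(e) NULL)
    if (is.null(sel)) next
    any_ok <- TRUE
    n_feat[ti] <- length(sel)
    sub <- matrix[, sel + 1L, drop = FALSE]
    for (r in seq_len(config$repeats)) {
      sp <- split_half(y, seed = cell_seed(config$seed, ti, r),
                       fraction = config$split_fraction)
      scaler <- fit_scaler(sub[sp$train, , drop = FALSE], config$scaling)
      X_tr <- apply_scaler(scaler, sub[sp$train, , drop = FALSE])
      X_va <- apply_scaler(scaler, sub[sp$validation, , drop = FALSE])
      gs <- grid_search_fit(X_tr, y[sp$train], X_va, y[sp$validation], config)
      err_mat[ti, r] <- gs$error
    }
  }
  if (!any_ok) stop("every candidate threshold leaves an empty feature set")
  avg <- rowMeans(err_mat)
  avg[is.na(avg)] <- Inf
  win <- which.min(avg)  # ties resolve to the smallest threshold
  threshold <- thresholds[win]
  selected <- filter_by_threshold(report, threshold)

  sub <- matrix[, selected + 1L, drop = FALSE]
  scaler <- fit_scaler(sub, config$scaling)
  X_all <- apply_scaler(scaler, sub)
  # final (C, gamma): repeated-split grid search on the full data
  final_votes <- lapply(seq_len(config$repeats), function(r) {
    sp <- split_half(y, seed = cell_seed(config$seed, length(thresholds) + 1L, r),
                     fraction = config$split_fraction)
    grid_search_fit(X_all[sp$train, , drop = FALSE], y[sp$train],
                    X_all[sp$validation, , drop = FALSE], y[sp$validation],
                    config)
  })
  cand <- do.call(rbind, lapply(final_votes, as.data.frame))
  agg <- stats::aggregate(error ~ C + gamma, data = cand, FUN = mean)
  agg <- agg[order(agg$error, agg$C, agg$gamma), , drop = FALSE]
  C_final <- agg$C[1]; gamma_final <- agg$gamma[1]

  fit <- rbf_svm_fit(X_all, y, C = C_final, gamma = gamma_final,
                     class_weight = config$class_weight)
  structure(list(
    selected = selected, threshold = threshold, scaler = scaler,
    C = C_final, gamma = gamma_final, fit = fit,
    error_table = data.frame(threshold = thresholds, n_features = n_feat,
                             avg_error = ifelse(is.finite(avg), avg, NA_real_)),
    validation_errors = err_mat,
    registry_version = attr(matrix, "registry_version"),
    seed = config$seed,
    feature_report = report
  ), class = "uriexc_model")
}

#' @export
print.uriexc_model <- function(x, ...) {
  cat(sprintf(
    "<uriexc_model> %d/%d features (F-score threshold %.4g), C=%g gamma=%g\n",
    length(x$selected), nrow(x$feature_report), x$threshold, x$C, x$gamma))
  invisible(x)
}

#' Predict with a trained model
#'
#' Applies the stored scaling and selected-feature projection, then the
#' decision function. A row is labeled positive when its score is >= 0.
#'
#' @param object a `uriexc_model`.
#' @param matrix proteins x features matrix in full registry order; its
#'   `registry_version` attribute (when present) must match the model's.
#' @param ... unused.
#' @return data.frame: `protein_id`, `score`, `label` (+1/-1).
#' @export
predict.uriexc_model <- function(object, matrix, ...) {
  stopifnot(is.matrix(matrix))
  rv <- attr(matrix, "registry_version")
  if (!is.null(rv) && !is.null(object$registry_version) &&
      !identical(rv, object$registry_version)) {
    stop(sprintf("registry mismatch: model %s vs input %s",
                 object$registry_version, rv))
  }
  sub <- matrix[, object$selected + 1L, drop = FALSE]
  X <- apply_scaler(object$scaler, sub)
  scores <- rbf_svm_decision(object$fit, X)
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(matrix)))
  data.frame(protein_id = ids, score = scores,
             label = ifelse(scores >= 0, 1L, -1L), stringsAsFactors = FALSE)
}

#' Serialize a trained model to JSON
#'
#' Numeric state is written at full precision; [read_model()] restores an
#' equivalent model whose predictions match to machine precision.
#'
#' @param model a `uriexc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "uriexc-model-v1",
    registry_version = model$registry_version,
    seed = model$seed,
    threshold = model$threshold,
    selected = model$selected,
    scaler = model$scaler[c("center", "scale", "method")],
    C = model$C, gamma = model$gamma,
    fit = list(coef = model$fit$coef, b = model$fit$b,
               sv = unname(model$fit$sv)),
    error_table = model$error_table,
    validation_errors = unname(model$validation_errors)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return a `uriexc_model` (without the training-time feature report).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(p$format, "uriexc-model-v1"))
  fit <- structure(list(coef = p$fit$coef, sv = as.matrix(p$fit$sv),
                        b = p$fit$b, C = p$C, gamma = p$gamma),
                   class = "rbf_svm")
  structure(list(selected = as.integer(p$selected), threshold = p$threshold,
                 scaler = p$scaler, C = p$C, gamma = p$gamma, fit = fit,
                 error_table = p$error_table,
                 validation_errors = p$validation_errors,
                 registry_version = p$registry_version, seed = p$seed),
            class = "uriexc_model")
}
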