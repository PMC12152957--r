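# Analysis stages: relative-energy curation, per-feature trend summaries,
# gradient-boosted regression on the five-feature encoding, and feature
# ablation.

#' Recompute relative energies from single-point energies
#'
#' Within each ring-count group, the relative energy of a molecule is its
#' single-point energy difference from the most stable molecule of the same
#' size, converted from Hartree to kcal/mol (627.5095 kcal/mol per Hartree).
#' Every group therefore contains at least one exact zero and no negative
#' values.
#'
#' @param records data frame with columns `spe` (Hartree, neutral species) and
#'   `n_rings`.
#' @return `records` with the `e_rel` column (re)computed.
#' @export
compute_e_rel <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("spe", "n_rings") %in% names(records)))
  records$e_rel <- NA_real_
  for (g in unique(records$n_rings)) {
    rows <- which(records$n_rings == g)
    spe <- records$spe[rows]
    if (!length(rows) || all(is.na(spe))) {
      warning("empty ring-count group ", g, " skipped")
      next
    }
    records$e_rel[rows] <- (spe - min(spe, na.rm = TRUE)) * HARTREE_TO_KCAL
  }
  records
}

#' Per-level distribution summary of a property against a feature
#'
#' The tabular counterpart of the distribution plots: for every level of a
#' structural feature, the count, minimum, quartiles, median and maximum of a
#' property.  For the B-N separation feature the odd/even parity is reported
#' alongside, since odd and even separations form two distinct series.  To
#' remove size dependence the summary can be restricted to one ring count
#' (the convention used for all positional features is `n_rings = 6`).
#'
#' @param records data frame holding both the feature and property columns
#'   (e.g. a feature table merged with a property table).
#' @param feature feature column name.
#' @param property property column name.
#' @param restrict_n_rings if non-NULL, keep only records with this ring
#'   count.
#' @return A data frame with columns `feature`, `level` (and `parity` when
#'   `feature == "n_SP"`), `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
trend_summary <- function(records, feature, property,
                          restrict_n_rings = NULL) {
  stopifnot(is.data.frame(records))
  if (!feature %in% names(records))
    stop("unknown feature column: ", feature, call. = FALSE)
  if (!property %in% names(records))
    stop("unknown property column: ", property, call. = FALSE)
  if (!is.null(restrict_n_rings))
    records <- records[records$n_rings == restrict_n_rings, , drop = FALSE]
  levels <- sort(unique(records[[feature]]))
  out <- do.call(rbind, lapply(levels, function(lv) {
    x <- records[[property]][records[[feature]] == lv]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(feature = feature, level = lv, n = length(x),
               min = min(x), q1 = q[1], median = q[2], q3 = q[3],
               max = max(x))
  }))
  if (feature == "n_SP")
    out$parity <- ifelse(out$level %% 2 == 0, "even", "odd")
  rownames(out) <- NULL
  out
}

# default 6-component encoding of the five structural features
.default_features <- c("n_rings", "n_LL", "b_inner", "n_inner", "n_SP",
                       "n_DR")

# coefficient of determination; a constant target has no explainable
# variance, reported explicitly as 0
.rsq <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(0)
  1 - sum((obs - pred)^2) / sst
}

.mae <- function(obs, pred) mean(abs(obs - pred))

.fit_gbm <- function(x, y, nrounds, params) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Train and evaluate a gradient-boosted regressor on the structural features
#'
#' Fits a gradient-boosted tree ensemble to predict a molecular property from
#' the 6-component encoding of the five structural features and nothing else.
#' The data are split 75:25 (train/test) at random; 5-fold cross-validation is
#' performed on the training portion and test metrics are reported on the
#' held-out 25%.  Hyperparameters default to the library's standard settings
#' with a fixed seed -- the scientific question is feature sufficiency, not
#' tuning.
#'
#' @param data data frame containing the feature columns and the target.
#' @param target name of the numeric target column (e.g. `"gap"` or
#'   `"e_rel"`).
#' @param features feature column names (default: the 6-component encoding).
#' @param train_frac training fraction of the random split.
#' @param folds number of cross-validation folds on the training portion.
#' @param seed integer seed controlling the split, fold assignment and
#'   fitting.
#' @param nrounds boosting rounds.
#' @param params list of booster parameters passed to xgboost (defaults:
#'   `eta = 0.1`, `max_depth = 6`, single thread for reproducibility).
#' @return An object of class `bn_gbm` with the fitted model, test MAE and
#'   R-squared, the per-fold cross-validation table, the feature-importance
#'   ranking (gain), split indices and the seed.
#' @export
train_and_evaluate <- function(data, target, features = .default_features,
                               train_frac = 0.75, folds = 5, seed = 1L,
                               nrounds = 400, params = list()) {
  stopifnot(is.data.frame(data), target %in% names(data),
            all(features %in% names(data)))
  if (!is.numeric(data[[target]]))
    stop("target must be numeric", call. = FALSE)
  if (anyNA(data[, c(features, target)]))
    stop("missing values in features or target", call. = FALSE)
  if (nrow(data) < 100)
    stop("need at least 100 records", call. = FALSE)

  params <- utils::modifyList(
    list(objective = "reg:squarederror", eta = 0.1, max_depth = 6,
         nthread = 1, seed = seed),
    params)

  n <- nrow(data)
  y <- data[[target]]
  x <- data[, features, drop = FALSE]

  .with_seed(seed, {
    test_idx <- sort(sample.int(n, size = round((1 - train_frac) * n)))
    train_idx <- setdiff(seq_len(n), test_idx)
    fold_of <- sample(rep_len(seq_len(folds), length(train_idx)))

    if (stats::var(y) == 0) {
      # degenerate target: no model needed, predictions are the constant
      const <- y[1]
      metrics <- data.frame(set = "test", mae = 0, r2 = 0)
      fit <- NULL
      pred_test <- rep(const, length(test_idx))
      cv <- data.frame(fold = seq_len(folds), mae = 0, r2 = 0)
      importance <- data.frame(feature = features,
                               gain = rep(0, length(features)))
    } else {
      cv <- do.call(rbind, lapply(seq_len(folds), function(f) {
        hold <- train_idx[fold_of == f]
        fit_f <- .fit_gbm(x[setdiff(train_idx, hold), , drop = FALSE],
                          y[setdiff(train_idx, hold)], nrounds, params)
        p <- stats::predict(fit_f,
                            xgboost::xgb.DMatrix(
                              as.matrix(x[hold, , drop = FALSE])))
        data.frame(fold = f, mae = .mae(y[hold], p),
                   r2 = .rsq(y[hold], p))
      }))
      fit <- .fit_gbm(x[train_idx, , drop = FALSE], y[train_idx], nrounds,
                      params)
      pred_test <- stats::predict(
        fit, xgboost::xgb.DMatrix(as.matrix(x[test_idx, , drop = FALSE])))
      imp <- xgboost::xgb.importance(model = fit)
      importance <- data.frame(feature = imp$Feature, gain = imp$Gain)
    }

    structure(
      list(target = target, features = features, model = fit,
           test_mae = .mae(y[test_idx], pred_test),
           test_r2 = .rsq(y[test_idx], pred_test),
           cv = cv, importance = importance,
           split = list(train = train_idx, test = test_idx,
                        fractions = c(train = train_frac,
                                      test = 1 - train_frac)),
           seed = seed, nrounds = nrounds, params = params,
           n = n),
      class = "bn_gbm")
  })
}

#' @export
print.bn_gbm <- function(x, ...) {
  cat(sprintf("<bn_gbm> target = %s | n = %d (%.0f:%.0f split)\n",
              x$target, x$n, 100 * x$split$fractions["train"],
              100 * x$split$fractions["test"]))
  cat(sprintf("  test  MAE = %.4f   R^2 = %.4f\n", x$test_mae, x$test_r2))
  cat(sprintf("  CV    MAE = %.4f   R^2 = %.4f  (%d folds)\n",
              mean(x$cv$mae), mean(x$cv$r2), nrow(x$cv)))
  invisible(x)
}

#' @export
summary.bn_gbm <- function(object, ...) {
  print(object)
  cat("  feature importance (gain):\n")
  imp <- object$importance[order(-object$importance$gain), ]
  for (i in seq_len(nrow(imp)))
    cat(sprintf("    %-8s %.4f\n", imp$feature[i], imp$gain[i]))
  invisible(object)
}

#' @export
predict.bn_gbm <- function(object, newdata, ...) {
  if (is.null(object$model))
    stop("degenerate fit (constant target) has no model", call. = FALSE)
  stopifnot(all(object$features %in% names(newdata)))
  stats::predict(object$model, xgboost::xgb.DMatrix(
    as.matrix(newdata[, object$features, drop = FALSE])))
}

#' Feature ablation study
#'
#' Retrains the regressor once per dropped feature (the two inner/outer flags
#' count as one feature and are dropped together) using the same split and
#' seed, and tabulates the change in held-out error.  The feature whose
#' removal degrades the error most is the most influential one.
#'
#' @inheritParams train_and_evaluate
#' @return A data frame with columns `dropped`, `test_mae`, `test_r2`,
#'   `delta_mae` (increase in MAE over the all-feature baseline); the first
#'   row is the baseline (`dropped = "none"`).
#' @export
ablation_study <- function(data, target, features = .default_features,
                           seed = 1L, ...) {
  groups <- list(none = character())
  for (f in setdiff(features, c("b_inner", "n_inner")))
    groups[[f]] <- f
  if (all(c("b_inner", "n_inner") %in% features))
    groups[["inner_outer"]] <- c("b_inner", "n_inner")

  rows <- lapply(names(groups), function(g) {
    keep <- setdiff(features, groups[[g]])
    fit <- train_and_evaluate(data, target, features = keep, seed = seed, ...)
    data.frame(dropped = g, test_mae = fit$test_mae, test_r2 = fit$test_r2)
  })
  out <- do.call(rbind, rows)
  out$delta_mae <- out$test_mae - out$test_mae[out$dropped == "none"]
  out
}
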