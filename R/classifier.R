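#' Optimal discretization cutoff by balanced accuracy
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' values plus one candidate below the minimum and one above the maximum.
#' Each candidate is scored direction-agnostically as
#' `max(BA, 1 - BA)` with `BA = (sensitivity + specificity) / 2` for the
#' indicator `value > cutoff` (positive = case); the logistic coefficient
#' sign later absorbs the orientation. The smallest candidate achieving the
#' maximal score is returned.
#'
#' @param values numeric per-sample promoter coverages.
#' @param labels case/control labels (both classes required).
#' @return list with `cutoff` and `score` (the balanced accuracy achieved).
#' @export
optimal_cutoff <- function(values, labels) {
  y <- .case_indicator(labels)
  if (length(values) != length(y)) abort("values and labels differ in length")
  cand <- .candidate_cutpoints(values)
  n1 <- sum(y)
  n0 <- sum(!y)
  score <- vapply(cand, function(cc) {
    pred <- values > cc
    ba <- (sum(pred & y) / n1 + sum(!pred & !y) / n0) / 2
    max(ba, 1 - ba)
  }, 0)
  best <- max(score)
  i <- which(score >= best - 1e-12)[1]  # smallest candidate on ties
  list(cutoff = cand[i], score = score[i])
}

#' Learn discretization rules for a set of features
#'
#' Applies [optimal_cutoff()] per feature column of a coverage table.
#'
#' @param cov coverage tibble with a `label` column.
#' @param features feature column names (default: all promoter columns).
#' @return tibble (feature, cutoff, score).
#' @export
discretization_rules <- function(cov, features = NULL) {
  features <- features %||% coverage_features(cov)
  m <- .cov_values(cov, features)
  res <- lapply(features, function(f) optimal_cutoff(m[, f], cov$label))
  tibble(feature = features,
         cutoff = map_dbl(res, "cutoff"),
         score = map_dbl(res, "score"))
}

#' Binarize coverages with discretization rules
#'
#' An entry becomes 1 iff its value is strictly greater than the feature's
#' cutoff; a value exactly equal to the cutoff becomes 0.
#'
#' @param cov coverage tibble (or plain tibble of feature columns).
#' @param rules tibble (feature, cutoff); a rule is required for every
#'   feature column being binarized.
#' @param features columns to binarize (default: all rule features).
#' @return `cov` with the chosen columns replaced by 0/1 integers.
#' @export
binarize <- function(cov, rules, features = NULL) {
  features <- features %||% intersect(names(cov), rules$feature)
  missing_rule <- setdiff(features, rules$feature)
  if (length(missing_rule) > 0) {
    abort(paste0("no discretization rule for feature(s): ",
                 paste(missing_rule, collapse = ", ")))
  }
  missing_col <- setdiff(features, names(cov))
  if (length(missing_col) > 0) {
    abort(paste0("feature(s) absent from data: ",
                 paste(missing_col, collapse = ", ")))
  }
  for (f in features) {
    cut <- rules$cutoff[match(f, rules$feature)]
    cov[[f]] <- as.integer(cov[[f]] > cut)
  }
  cov
}

#' Logistic regression fit (maximum likelihood)
#'
#' Fits by iteratively reweighted least squares via [stats::glm.fit()]
#' (epsilon 1e-10, at most 100 iterations). Constant features are dropped
#' with a warning. Complete separation — non-convergence or diverging
#' coefficients with fitted probabilities at 0/1 — is flagged and the
#' coefficients are rescaled so the largest |beta| is 15 (preserving the
#' separating direction), with a warning.
#'
#' @param design numeric matrix (or tibble) of features; may have 0 columns
#'   for the intercept-only model.
#' @param labels case/control labels (both classes required).
#' @return object of class `logistic_fit`: list(intercept, coefficients,
#'   aic, converged, separation, fitted).
#' @export
fit_logistic <- function(design, labels) {
  y <- .case_indicator(labels)
  x <- as.matrix(design)
  if (ncol(x) > 0) {
    storage.mode(x) <- "double"
    const <- apply(x, 2, function(v) length(unique(v)) == 1)
    if (any(const)) {
      warn(paste0("dropping constant feature(s): ",
                  paste(colnames(x)[const], collapse = ", ")))
      x <- x[, !const, drop = FALSE]
    }
  }
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(
    xm, as.numeric(y), family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  sep <- (!fit$converged && any(abs(beta) > 15)) ||
    (any(abs(beta) > 15) && any(fit$fitted.values > 1 - 1e-8) &&
       any(fit$fitted.values < 1e-8))
  if (sep) {
    warn("complete separation detected; coefficients capped at |beta| <= 15")
    # rescale proportionally so the largest |beta| is 15: keeps every
    # predicted class on the separating side it was on
    beta <- beta * (15 / max(abs(beta)))
  }
  structure(list(intercept = unname(beta[1]),
                 coefficients = beta[-1],
                 aic = fit$aic,
                 converged = fit$converged,
                 separation = sep,
                 fitted = as.numeric(xm %*% beta)),
            class = "logistic_fit")
}

# AIC of a logistic model on a feature subset; used by the stepwise search.
.logit_aic <- function(xm, y) {
  fit <- suppressWarnings(stats::glm.fit(
    xm, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  fit$aic
}

#' Bidirectional stepwise feature selection by AIC
#'
#' Starting from the intercept-only model, repeatedly takes the single add
#' or drop move with the largest AIC decrease; stops when no move improves
#' the AIC or `max_features` is reached. Deterministic: ties are broken by
#' candidate order (additions in column order, then drops in selection
#' order).
#'
#' @param design numeric 0/1 matrix (or tibble) of candidate features.
#' @param labels case/control labels.
#' @param max_features cap on the selected subset size (default 15).
#' @return character vector of selected feature names, in selection order.
#' @export
stepwise_select <- function(design, labels, max_features = 15) {
  x <- as.matrix(design)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (ncol(x) == 0 || max_features <= 0) return(character())
  y <- as.numeric(.case_indicator(labels))

  current <- character()
  aic_now <- .logit_aic(matrix(1, nrow(x), 1), y)
  repeat {
    moves <- list()
    if (length(current) < max_features) {
      for (f in setdiff(colnames(x), current)) {
        moves[[length(moves) + 1]] <- list(op = "add", feature = f)
      }
    }
    for (f in current) {
      moves[[length(moves) + 1]] <- list(op = "drop", feature = f)
    }
    if (length(moves) == 0) break
    aics <- vapply(moves, function(mv) {
      feats <- if (mv$op == "add") c(current, mv$feature) else
        setdiff(current, mv$feature)
      .logit_aic(cbind(1, x[, feats, drop = FALSE]), y)
    }, 0)
    best <- which(aics < aic_now - 1e-9)
    if (length(best) == 0) break
    i <- best[which.min(aics[best])]
    # which.min returns the first minimum, i.e. earliest candidate on ties
    mv <- moves[[i]]
    current <- if (mv$op == "add") c(current, mv$feature) else
      setdiff(current, mv$feature)
    aic_now <- aics[i]
  }
  current
}

#' Leave-one-out cross-validated probabilities
#'
#' Each sample is withheld in turn and predicted from a logistic model
#' refit on the remaining samples. By default the feature subset (and any
#' upstream discretization cutoffs) stay fixed from the full training
#' cohort and only the coefficients are refit per fold; with
#' `strict = TRUE` the stepwise selection is re-run inside each fold over
#' all columns of `design`. Folds whose training part is single-class fall
#' back to the full-data fit with a warning.
#'
#' @param design binary design matrix/tibble (all candidate features).
#' @param labels case/control labels (n >= 3).
#' @param features fixed feature subset (default-mode folds use exactly
#'   these).
#' @param strict re-run [stepwise_select()] within each fold.
#' @param max_features passed to the per-fold selection in strict mode.
#' @return numeric vector of out-of-fold probabilities, one per sample.
#' @export
loocv_probabilities <- function(design, labels, features = NULL,
                                strict = FALSE, max_features = 15) {
  x <- as.matrix(design)
  storage.mode(x) <- "double"
  y <- .case_indicator(labels)
  n <- nrow(x)
  if (n < 3) abort("LOOCV requires at least 3 samples")
  features <- features %||% colnames(x)
  full_fit <- NULL
  probs <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (!any(yi) || all(yi)) {
      warn(sprintf("fold %d is single-class after withholding; using the full-data fit", i))
      if (is.null(full_fit)) {
        full_fit <- suppressWarnings(
          fit_logistic(x[, features, drop = FALSE], y))
      }
      feats <- names(full_fit$coefficients)
      lp <- full_fit$intercept + sum(full_fit$coefficients * x[i, feats])
      probs[i] <- stats::plogis(lp)
      next
    }
    feats <- if (strict) {
      stepwise_select(x[-i, , drop = FALSE], yi, max_features)
    } else {
      features
    }
    fit <- suppressWarnings(
      fit_logistic(x[-i, feats, drop = FALSE], yi))
    kept <- names(fit$coefficients)
    lp <- fit$intercept +
      if (length(kept)) sum(fit$coefficients * x[i, kept]) else 0
    probs[i] <- stats::plogis(lp)
  }
  probs
}
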