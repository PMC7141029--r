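#' Construct a promoter classifier
#'
#' A discretized logistic classifier over promoter coverage features
#' (optionally plus a raw clinical covariate such as `bmi`): an ordered
#' feature list, one discretization cutoff per promoter feature, one
#' logistic coefficient per feature, an intercept, and a probability
#' threshold for calling a sample positive.
#'
#' @param name classifier name.
#' @param features ordered character vector of feature ids (gene symbols /
#'   promoter ids; may include `"bmi"`).
#' @param coefficients named numeric vector, one per feature.
#' @param intercept numeric intercept (log-odds at the all-zero indicator
#'   vector).
#' @param rules tibble (feature, cutoff, optionally window) of
#'   discretization rules for the promoter features; cutoffs may be `NA`
#'   when only discretized input will be scored.
#' @param probability_threshold probability above which a sample is called
#'   positive (in (0, 1)).
#' @param provenance optional list (training checksum, seed, notes).
#' @return object of class `promoter_classifier`.
#' @export
promoter_classifier <- function(name, features, coefficients, intercept,
                                rules = NULL, probability_threshold = 0.5,
                                provenance = list()) {
  features <- as.character(features)
  if (length(coefficients) != length(features)) {
    abort("need exactly one coefficient per feature")
  }
  names(coefficients) <- features
  .check_scalar_number(probability_threshold, "probability_threshold", 0, 1)
  if (is.null(rules)) {
    rules <- tibble(feature = setdiff(features, "bmi"), cutoff = NA_real_)
  }
  promoter_feats <- setdiff(features, "bmi")
  if (!all(promoter_feats %in% rules$feature)) {
    abort("every promoter feature needs a discretization rule entry")
  }
  structure(list(name = name, features = features,
                 coefficients = coefficients,
                 intercept = as.numeric(intercept),
                 rules = as_tibble(rules),
                 probability_threshold = probability_threshold,
                 provenance = provenance),
            class = "promoter_classifier")
}

#' @export
print.promoter_classifier <- function(x, ...) {
  cat(sprintf("<promoter_classifier> '%s': %d feature(s), intercept %.3f, threshold %.3g\n",
              x$name, length(x$features), x$intercept,
              x$probability_threshold))
  invisible(x)
}

#' Predict with a promoter classifier
#'
#' Computes the linear predictor `beta0 + sum(beta_i x_i)`, the probability
#' `1 / (1 + exp(-lp))`, and the predicted label (positive iff probability
#' strictly exceeds the classifier's threshold). Feature columns may be
#' already-discretized 0/1 indicators, or raw coverages which are binarized
#' with the classifier's cutoffs (`discretized = FALSE`); by default the
#' input is treated as discretized when all promoter-feature values are
#' 0/1.
#'
#' @param object a `promoter_classifier`.
#' @param newdata tibble/data.frame/matrix with one column per classifier
#'   feature (promoter features named by feature id, or by the rule's
#'   `window` column if present).
#' @param discretized logical or `NULL` (auto-detect).
#' @param ... unused.
#' @return tibble (linear_predictor, probability, predicted_label), one row
#'   per input row.
#' @export
predict.promoter_classifier <- function(object, newdata, discretized = NULL,
                                        ...) {
  nd <- as_tibble(as.data.frame(newdata))
  # map window-level columns to feature names where needed
  if ("window" %in% names(object$rules)) {
    for (k in seq_len(nrow(object$rules))) {
      f <- object$rules$feature[k]
      w <- object$rules$window[k]
      if (!f %in% names(nd) && !is.na(w) && w %in% names(nd)) {
        nd[[f]] <- nd[[w]]
      }
    }
  }
  missing_f <- setdiff(object$features, names(nd))
  if (length(missing_f) > 0) {
    abort(paste0("missing feature(s) in newdata: ",
                 paste(missing_f, collapse = ", ")))
  }
  promoter_feats <- setdiff(object$features, "bmi")
  vals <- as.matrix(nd[, object$features, drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.null(discretized)) {
    pv <- vals[, promoter_feats, drop = FALSE]
    discretized <- length(pv) == 0 || all(pv %in% c(0, 1))
  }
  if (!discretized && length(promoter_feats) > 0) {
    cuts <- object$rules$cutoff[match(promoter_feats, object$rules$feature)]
    if (any(is.na(cuts))) {
      abort("raw input supplied but discretization cutoffs are missing")
    }
    vals[, promoter_feats] <-
      t(t(vals[, promoter_feats, drop = FALSE]) > cuts) + 0
  }
  lp <- object$intercept +
    as.numeric(vals %*% object$coefficients[object$features])
  prob <- stats::plogis(lp)
  tibble(linear_predictor = lp, probability = prob,
         predicted_label = ifelse(prob > object$probability_threshold,
                                  "case", "control"))
}

#' The published 12-gene macrosomia classifier
#'
#' The set-A macrosomia classifier with the printed intercept 2.180 and
#' gene coefficients (SMC3 +0.605, MASTL -1.204, CREM +1.366, C1QTNF12
#' -1.295, MLXIP -0.471, MAP3K9 -0.811, IGSF6 -1.284, APC2 -1.347, GPM6A
#' -0.504, TMEM128 +1.048, NIPBL -0.057, TMEM184A -1.652). The per-gene
#' discretization cutoffs and the probability threshold were published only
#' in supplementary tables and must be supplied by the user to score raw
#' coverages; when omitted, the threshold defaults to 0.5 with a warning
#' and only already-discretized input can be scored.
#'
#' @param cutoffs optional named numeric vector of per-gene RPKM cutoffs.
#' @param probability_threshold optional probability threshold.
#' @return a [promoter_classifier()].
#' @export
published_ma_classifier <- function(cutoffs = NULL,
                                    probability_threshold = NULL) {
  coefs <- c(SMC3 = 0.605, MASTL = -1.204, CREM = 1.366, C1QTNF12 = -1.295,
             MLXIP = -0.471, MAP3K9 = -0.811, IGSF6 = -1.284, APC2 = -1.347,
             GPM6A = -0.504, TMEM128 = 1.048, NIPBL = -0.057,
             TMEM184A = -1.652)
  if (is.null(cutoffs) || is.null(probability_threshold)) {
    warn(paste0("per-gene cutoffs and probability threshold of the published",
                " macrosomia classifier are not public; threshold defaults",
                " to 0.5 and raw coverages cannot be scored without",
                " user-supplied cutoffs"))
  }
  rules <- tibble(feature = names(coefs),
                  cutoff = if (is.null(cutoffs)) NA_real_ else
                    as.numeric(cutoffs[names(coefs)]))
  promoter_classifier(
    name = "C_MA-A", features = names(coefs), coefficients = coefs,
    intercept = 2.180, rules = rules,
    probability_threshold = probability_threshold %||% 0.5,
    provenance = list(source = "published 12-gene macrosomia set-A classifier"))
}

#' Serialize / deserialize a promoter classifier as JSON
#'
#' Round-trips losslessly (numbers written at full precision).
#'
#' @param classifier a `promoter_classifier`.
#' @param path JSON file path.
#' @return `write_classifier`: the path, invisibly; `read_classifier`: the
#'   classifier.
#' @export
write_classifier <- function(classifier, path) {
  x <- list(name = classifier$name,
            features = classifier$features,
            coefficients = as.list(classifier$coefficients),
            intercept = classifier$intercept,
            rules = classifier$rules,
            probability_threshold = classifier$probability_threshold,
            provenance = classifier$provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- as_tibble(x$rules)
  if (!"cutoff" %in% names(rules)) rules$cutoff <- NA_real_
  rules$cutoff <- as.numeric(rules$cutoff)
  promoter_classifier(
    name = x$name, features = as.character(x$features),
    coefficients = unlist(x$coefficients)[as.character(x$features)],
    intercept = x$intercept, rules = rules,
    probability_threshold = x$probability_threshold,
    provenance = as.list(x$provenance))
}
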