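#' Discovery stage: differential promoter profiling
#'
#' Selects the discovery subset of the training cohort — the first
#' `n_per_group` cases and controls in metadata order (the analogue of the
#' gestational-age-matched 10 vs 10 discovery design) — and runs
#' [select_differential()] on it. The discovery sample ids are attached as
#' the `discovery_ids` attribute so the training stage can reuse them (the
#' discovery samples are part of the training cohort).
#'
#' @param cov coverage tibble (training cohort, `label` column present).
#' @param windows optional window tibble for gene symbols.
#' @param n_per_group discovery group size (default 10).
#' @param fdr_max,lfc_min,pseudocount passed to [select_differential()].
#' @return differential tibble with attribute `discovery_ids`.
#' @export
run_discovery <- function(cov, windows = NULL, n_per_group = 10,
                          fdr_max = 0.1, lfc_min = 1.0, pseudocount = 0.01) {
  y <- .case_indicator(cov$label)
  case_ids <- cov$sample_id[y]
  ctrl_ids <- cov$sample_id[!y]
  if (length(case_ids) < n_per_group || length(ctrl_ids) < n_per_group) {
    abort(sprintf("discovery needs %d samples per group; have %d cases and %d controls",
                  n_per_group, length(case_ids), length(ctrl_ids)))
  }
  ids <- c(case_ids[seq_len(n_per_group)], ctrl_ids[seq_len(n_per_group)])
  sub <- cov[cov$sample_id %in% ids, , drop = FALSE]
  out <- select_differential(sub, fdr_max = fdr_max, lfc_min = lfc_min,
                             pseudocount = pseudocount, windows = windows)
  attr(out, "discovery_ids") <- ids
  out
}

# Transcript -> gene reduction: for each gene keep the transcript with the
# smallest p (ties by table order), returning tibble(feature, window).
.gene_reduce <- function(differential, candidates = NULL) {
  d <- differential
  if (!is.null(candidates)) d <- d[d$window %in% candidates, , drop = FALSE]
  d <- d[order(d$p_value), , drop = FALSE]
  d <- d[!duplicated(d$gene_symbol), , drop = FALSE]
  tibble(feature = d$gene_symbol, window = d$window)
}

# Shared training path: cutoffs -> binarize -> stepwise -> fit -> LOOCV ->
# ROC -> threshold. `feature_map` is tibble(feature, window).
.train_path <- function(cov, feature_map, max_features = 15,
                        loocv_mode = c("fixed", "strict"), name = "classifier",
                        extra_covariates = character()) {
  loocv_mode <- match.arg(loocv_mode)
  y <- .case_indicator(cov$label)
  m <- .cov_values(cov, feature_map$window)
  colnames(m) <- feature_map$feature

  rules <- discretization_rules(
    dplyr::bind_cols(cov[, intersect(.meta_cols, names(cov))],
                     as_tibble(m, .name_repair = "minimal")),
    features = feature_map$feature)
  cuts <- rules$cutoff[match(colnames(m), rules$feature)]
  xb <- t(t(m) > cuts) + 0

  for (cv in extra_covariates) xb <- cbind(xb, cv = cov[[cv]])
  if (length(extra_covariates)) {
    colnames(xb)[ncol(xb) - rev(seq_along(extra_covariates)) + 1] <-
      extra_covariates
  }

  feats <- stepwise_select(xb, y, max_features = max_features)
  fit <- suppressWarnings(fit_logistic(xb[, feats, drop = FALSE], y))

  probs <- suppressWarnings(
    if (loocv_mode == "strict") {
      .strict_loocv(cov, y, max_features, extra_covariates)
    } else {
      loocv_probabilities(xb, y, features = feats)
    })
  roc <- roc_analysis(probs, y)

  kept <- names(fit$coefficients)
  rules_out <- rules[match(setdiff(kept, extra_covariates), rules$feature), ,
                     drop = FALSE]
  rules_out$window <-
    feature_map$window[match(rules_out$feature, feature_map$feature)]
  clf <- promoter_classifier(
    name = name, features = kept,
    coefficients = fit$coefficients, intercept = fit$intercept,
    rules = rules_out[, c("feature", "window", "cutoff")],
    probability_threshold = min(max(roc$threshold, 1e-6), 1 - 1e-6),
    provenance = list(training_samples = cov$sample_id,
                      loocv_mode = loocv_mode,
                      n_candidates = nrow(feature_map)))
  list(classifier = clf, roc = roc, loocv_probabilities = probs,
       rules = rules, separation = fit$separation)
}

# Strict LOOCV: the whole pipeline — differential screening, gene
# reduction, cutoffs, stepwise — is re-run inside every fold, so the
# held-out sample never informs feature choice.
.strict_loocv <- function(cov, y, max_features, extra_covariates,
                          n_candidates = 30) {
  n <- nrow(cov)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    sub <- cov[-i, , drop = FALSE]
    diff_i <- select_differential(sub, fdr_max = 0.1, lfc_min = 1.0)
    cand <- diff_i$window[diff_i$selected]
    if (length(cand) == 0) {
      cand <- utils::head(diff_i$window, n_candidates)
    }
    fm <- .gene_reduce(diff_i, cand)
    fm <- utils::head(fm, n_candidates)
    m <- .cov_values(sub, fm$window)
    colnames(m) <- fm$feature
    rules <- discretization_rules(
      dplyr::bind_cols(sub[, intersect(.meta_cols, names(sub))],
                       as_tibble(m, .name_repair = "minimal")),
      features = fm$feature)
    cuts <- rules$cutoff[match(colnames(m), rules$feature)]
    xb <- t(t(m) > cuts) + 0
    for (cvv in extra_covariates) xb <- cbind(xb, sub[[cvv]])
    if (length(extra_covariates)) {
      colnames(xb)[ncol(xb) - rev(seq_along(extra_covariates)) + 1] <-
        extra_covariates
    }
    feats <- stepwise_select(xb, y[-i], max_features = max_features)
    fit <- fit_logistic(xb[, feats, drop = FALSE], y[-i])
    kept <- names(fit$coefficients)
    newx <- as.numeric(.cov_values(cov[i, , drop = FALSE], fm$window))
    names(newx) <- fm$feature
    xi <- as.numeric(newx > cuts)
    names(xi) <- fm$feature
    xi <- c(xi, unlist(cov[i, extra_covariates, drop = TRUE]))
    names(xi) <- c(fm$feature, extra_covariates)
    lp <- fit$intercept +
      if (length(kept)) sum(fit$coefficients * xi[kept]) else 0
    probs[i] <- stats::plogis(lp)
  }
  probs
}

#' Training stage: build a discretized stepwise logistic classifier
#'
#' Candidate promoters are the selected windows of the discovery table,
#' reduced to one transcript per gene (smallest discovery p). Cutoffs are
#' learned on the training cohort by balanced accuracy, coverages are
#' binarized, features chosen by bidirectional AIC stepwise selection, and
#' the model is assessed by LOOCV and ROC. The probability threshold is the
#' balanced-accuracy-optimal threshold on the LOOCV probabilities.
#'
#' @param cov training-cohort coverage tibble.
#' @param differential table from [run_discovery()] /
#'   [select_differential()].
#' @param max_features stepwise cap (default 15).
#' @param loocv_mode `"fixed"` (cutoffs and feature subset frozen from the
#'   full training cohort; coefficients refit per fold) or `"strict"`
#'   (screening, cutoffs and selection re-run per fold).
#' @param name classifier name.
#' @return list(classifier, roc, loocv_probabilities, rules, separation).
#' @export
run_training <- function(cov, differential, max_features = 15,
                         loocv_mode = c("fixed", "strict"),
                         name = "set-A classifier") {
  if (nrow(differential) == 0 || !any(differential$selected)) {
    abort(paste0("no promoters selected at the discovery stage; relax ",
                 "fdr_max / lfc_min or increase depth"))
  }
  fm <- .gene_reduce(differential, differential$window[differential$selected])
  .train_path(cov, fm, max_features = max_features, loocv_mode = loocv_mode,
              name = name)
}

#' Validation stage: apply a frozen classifier to independent cohorts
#'
#' The model is applied unchanged (cutoffs, features, coefficients,
#' threshold). Validation samples must be disjoint from the training
#' samples recorded in the classifier's provenance. If the coverage table
#' has several values in its `cohort` column, one `roc_result` per cohort
#' is returned.
#'
#' @param cov validation coverage tibble.
#' @param classifier a trained [promoter_classifier()].
#' @return a `roc_result`, or a named list of them (one per cohort).
#' @export
run_validation <- function(cov, classifier) {
  if (nrow(cov) == 0) abort("empty validation cohort")
  train_ids <- classifier$provenance$training_samples
  overlap <- intersect(cov$sample_id, train_ids)
  if (length(overlap) > 0) {
    abort(paste0("validation samples overlap the training cohort: ",
                 paste(utils::head(overlap, 5), collapse = ", ")))
  }
  eval_one <- function(sub) {
    pred <- stats::predict(classifier, sub)
    roc_analysis(pred$probability, sub$label)
  }
  cohorts <- unique(cov$cohort %||% "validation")
  if (length(cohorts) <= 1) return(eval_one(cov))
  out <- lapply(cohorts, function(ch)
    eval_one(cov[cov$cohort == ch, , drop = FALSE]))
  names(out) <- cohorts
  out
}

#' Tissue-gene-set classifiers (set-P / set-W / set-PW)
#'
#' Runs the same training path with the candidate pool restricted to the
#' promoters of a supplied gene list (placenta-specific for set-P,
#' whole-blood-specific for set-W, their union for set-PW) instead of the
#' differential survivors. Transcripts are ranked and reduced per gene by a
#' Wilcoxon screen on the training cohort.
#'
#' @param cov training coverage tibble.
#' @param gene_list character vector of transcript ids (or gene symbols if
#'   `windows` given) defining the candidate pool; must be nonempty.
#' @param windows optional window tibble to translate gene symbols.
#' @param set_name label recorded in the model ("P", "W", "PW", ...).
#' @inheritParams run_training
#' @return as [run_training()].
#' @export
run_geneset_classifier <- function(cov, gene_list, windows = NULL,
                                   max_features = 15,
                                   loocv_mode = c("fixed", "strict"),
                                   set_name = "P") {
  if (length(gene_list) == 0) abort("empty gene list")
  pool <- intersect(gene_list, coverage_features(cov))
  if (length(pool) == 0 && !is.null(windows)) {
    pool <- intersect(
      windows$transcript_id[windows$gene_symbol %in% gene_list],
      coverage_features(cov))
  }
  if (length(pool) == 0) {
    abort("no gene-list promoters present in the coverage table")
  }
  screen <- select_differential(cov, windows = windows)
  fm <- .gene_reduce(screen, pool)
  res <- .train_path(cov, fm, max_features = max_features,
                     loocv_mode = loocv_mode,
                     name = paste0("set-", set_name, " classifier"))
  res$classifier$provenance$gene_list <- set_name
  res
}

#' Combine a promoter classifier with BMI
#'
#' Appends pre-pregnancy BMI as a raw (undiscretized) covariate to the
#' binary promoter design of an already-trained classifier, refits the
#' logistic coefficients on the training cohort, re-evaluates with fixed-
#' subset LOOCV, and reports the DeLong paired comparison against the
#' promoter-only model.
#'
#' @param cov training coverage tibble (must contain `bmi`).
#' @param trained result of [run_training()].
#' @return list(classifier, roc, comparison_p, roc_promoter_only).
#' @export
run_bmi_combination <- function(cov, trained) {
  if (!"bmi" %in% names(cov)) abort("metadata has no `bmi` column")
  if (any(is.na(cov$bmi))) {
    abort(paste0("missing BMI for sample(s): ",
                 paste(cov$sample_id[is.na(cov$bmi)], collapse = ", ")))
  }
  clf <- trained$classifier
  y <- .case_indicator(cov$label)
  promoter_feats <- setdiff(clf$features, "bmi")
  rules <- clf$rules
  m <- .cov_values(cov, rules$window[match(promoter_feats, rules$feature)])
  colnames(m) <- promoter_feats
  cuts <- rules$cutoff[match(promoter_feats, rules$feature)]
  xb <- t(t(m) > cuts) + 0
  xb <- cbind(xb, bmi = cov$bmi)

  fit <- suppressWarnings(fit_logistic(xb, y))
  probs <- suppressWarnings(
    loocv_probabilities(xb, y, features = colnames(xb)))
  roc <- roc_analysis(probs, y)
  kept <- names(fit$coefficients)
  rules_out <- rules[match(setdiff(kept, "bmi"), rules$feature), ,
                     drop = FALSE]
  combined <- promoter_classifier(
    name = paste0(clf$name, " + BMI"), features = kept,
    coefficients = fit$coefficients, intercept = fit$intercept,
    rules = rules_out,
    probability_threshold = min(max(roc$threshold, 1e-6), 1 - 1e-6),
    provenance = c(clf$provenance, list(bmi_combined = TRUE)))
  list(classifier = combined, roc = roc,
       comparison_p = compare_auc(roc, trained$roc),
       roc_promoter_only = trained$roc)
}

#' Gene-set metagene profiles and central/flank summary
#'
#' Computes TSS metagene profiles for each supplied gene set (typically
#' top500, bottom500, a tissue-specific set and the unexpressed set) and a
#' per-set central/flank depth-ratio summary — the negative-correlation
#' check between expression and promoter read depth.
#'
#' @param samples named list of fragment sets.
#' @param windows window tibble for the full universe.
#' @param gene_sets named list of transcript-id vectors.
#' @param bin_size optional bp bin width for the profiles.
#' @return list(profiles = combined profile tibble, summary = tibble
#'   (gene_set, n_genes, central_flank_ratio)).
#' @export
run_expression_validation <- function(samples, windows, gene_sets,
                                      bin_size = NULL) {
  if (length(gene_sets) == 0 || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a nonempty named list")
  }
  profiles <- lapply(names(gene_sets), function(nm) {
    metagene_profile(samples, windows, gene_set = gene_sets[[nm]],
                     bin_size = bin_size, gene_set_name = nm)
  })
  summary <- tibble(
    gene_set = names(gene_sets),
    n_genes = map_int(profiles, function(p) p$n_genes[1]),
    central_flank_ratio = map_dbl(profiles, central_flank_ratio))
  list(profiles = bind_rows(profiles), summary = summary)
}
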