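#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by full enumeration of the rank-sum null distribution when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param case_values,control_values numeric vectors (each nonempty).
#' @return two-sided p-value in \[0, 1\].
#' @export
wilcoxon_rank_sum_p <- function(case_values, control_values) {
  m <- length(case_values)
  n <- length(control_values)
  if (m == 0 || n == 0) abort("both groups must be nonempty")
  z <- c(case_values, control_values)
  r <- rank(z)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(z) > 0
  if (!ties && m + n <= 20) {
    p <- if (u > m * n / 2) {
      2 * stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, m, n)
    }
    return(min(1, p))
  }
  nt <- table(r)
  sigma2 <- (m * n / 12) *
    ((m + n + 1) - sum(nt^3 - nt) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(1)
  dev <- u - m * n / 2
  dev <- dev - sign(dev) * 0.5  # continuity correction
  min(1, 2 * stats::pnorm(-abs(dev) / sqrt(sigma2)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and
#' mapped back to the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return FDR (q) values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change of group mean coverages
#'
#' `log2((mean_case + pseudocount) / (mean_control + pseudocount))`; the
#' small pseudocount keeps the ratio finite and sign-stable when a group
#' mean is zero.
#'
#' @param mean_case,mean_control nonnegative group means (RPKM).
#' @param pseudocount added to both means (default 0.01 RPKM).
#' @return log2 fold change, case over control.
#' @export
log2_fold_change <- function(mean_case, mean_control, pseudocount = 0.01) {
  if (any(mean_case < 0) || any(mean_control < 0)) {
    abort("means must be nonnegative")
  }
  if (any(mean_case + pseudocount == 0) || any(mean_control + pseudocount == 0)) {
    abort("zero mean with zero pseudocount: log2 fold change undefined")
  }
  log2((mean_case + pseudocount) / (mean_control + pseudocount))
}

#' Differential promoter coverage between cases and controls
#'
#' For every promoter column of a coverage table: Wilcoxon rank-sum p-value
#' (case vs control), arithmetic group means, log2 fold change with
#' pseudocount, BH FDR across promoters, and the selection flag
#' `fdr <= fdr_max & |log2FC| >= lfc_min`. Output is sorted by p-value,
#' then by |log2FC| descending.
#'
#' @param cov coverage tibble with a `label` column (`case`/`control`),
#'   at least 2 samples per group.
#' @param fdr_max,lfc_min selection thresholds (defaults 0.1 and 1).
#' @param pseudocount see [log2_fold_change()].
#' @param windows optional window tibble supplying gene symbols.
#' @return tibble (window, gene_symbol, mean_case, mean_control,
#'   log2_fold_change, p_value, fdr, selected).
#' @export
select_differential <- function(cov, fdr_max = 0.1, lfc_min = 1.0,
                                pseudocount = 0.01, windows = NULL) {
  y <- .case_indicator(cov$label)
  if (sum(y) < 2 || sum(!y) < 2) {
    abort("at least 2 samples per group are required")
  }
  m <- .cov_values(cov)
  mean_case <- colMeans(m[y, , drop = FALSE])
  mean_control <- colMeans(m[!y, , drop = FALSE])
  p <- apply(m, 2, function(v) wilcoxon_rank_sum_p(v[y], v[!y]))
  lfc <- log2_fold_change(mean_case, mean_control, pseudocount)
  fdr <- bh_adjust(p)
  out <- tibble(window = colnames(m),
                gene_symbol = colnames(m),
                mean_case = unname(mean_case),
                mean_control = unname(mean_control),
                log2_fold_change = unname(lfc),
                p_value = unname(p), fdr = unname(fdr),
                selected = unname(fdr <= fdr_max & abs(lfc) >= lfc_min))
  if (!is.null(windows)) {
    map <- windows$gene_symbol[match(out$window, windows$transcript_id)]
    out$gene_symbol <- ifelse(is.na(map), out$window, map)
  }
  arrange(out, .data$p_value, desc(abs(.data$log2_fold_change)))
}

#' Column z-scores of a coverage table (heatmap export)
#'
#' Standardizes each promoter column to mean 0, sd 1 across samples.
#' Zero-variance columns are emitted as all zeros with a warning.
#'
#' @param cov coverage tibble (>= 2 samples).
#' @param features optional subset of promoter columns (e.g. the selected
#'   windows of [select_differential()]).
#' @return tibble: sample_id plus standardized promoter columns.
#' @export
zscore_matrix <- function(cov, features = NULL) {
  if (nrow(cov) < 2) abort("at least 2 samples are required")
  m <- .cov_values(cov, features)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warn(paste0("zero-variance column(s) emitted as zeros: ",
                paste(utils::head(colnames(m)[zero], 5), collapse = ", ")))
    sd[zero] <- 1
  }
  z <- sweep(sweep(m, 2, mu), 2, sd, "/")
  z[, zero] <- 0
  dplyr::bind_cols(tibble(sample_id = cov$sample_id),
                   as_tibble(z, .name_repair = "minimal"))
}

#' Write a differential table as TSV
#' @param differential tibble from [select_differential()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_differential_tsv <- function(differential, path) {
  readr::write_tsv(differential, path)
  invisible(path)
}
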