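#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of mid-ranks; ties receive average ranks. Undefined
#' when either vector has zero rank variance (constant input), in which case
#' `NA` is returned with a warning — downstream redundancy summaries exclude
#' such features rather than treating them as 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

## coerce a feature table (data.frame or matrix, rows = lesions) to a
## numeric matrix with feature column names
as_feature_matrix <- function(tab) {
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) stop("feature table must have column names")
  m
}

#' Cross-correlation matrix between two feature sets
#'
#' Spearman rho between every feature (column) of `a` and every feature of
#' `b`, over the same lesions in the same order. Per-`a`-feature maximum
#' absolute rho is recorded for redundancy classification; features with
#' undefined rho against some comparison feature have those cells `NA` and
#' are excluded from the maximum.
#'
#' @param a,b feature tables (rows = lesions, columns = named features).
#' @return object of class `correlation_report`: `rho` (|a| x |b|),
#'   `max_abs_rho` per `a` feature, `n_lesions`.
#' @export
cross_correlation_matrix <- function(a, b) {
  A <- as_feature_matrix(a); B <- as_feature_matrix(b)
  if (nrow(A) != nrow(B)) stop("feature tables cover different lesions")
  if (nrow(A) < 3L) stop("need at least 3 lesions")
  rho <- suppressWarnings(stats::cor(A, B, method = "spearman"))
  max_abs <- apply(abs(rho), 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  structure(list(rho = rho, max_abs_rho = max_abs, n_lesions = nrow(A)),
            class = "correlation_report")
}

## verbal strength labels for |rho|
rho_strength <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.3, 0.5, 0.7, Inf),
      labels = c("negligible", "low", "moderate", "high"), right = TRUE)
}

#' Classify dynamic features as redundant against the static set
#'
#' A dynamic feature is redundant when its maximum absolute Spearman rho
#' against any static feature exceeds `threshold`; non-redundant features
#' are the candidates carrying information beyond the static set.
#'
#' @param report a [cross_correlation_matrix()] result with dynamic features
#'   as rows.
#' @param threshold redundancy cut-off, default 0.7.
#' @return data.frame: feature, max_abs_rho, strength, redundant.
#' @export
classify_dynamic_redundancy <- function(report, threshold = 0.7) {
  stopifnot(inherits(report, "correlation_report"))
  r <- report$max_abs_rho
  data.frame(feature = names(r) %||% rownames(report$rho),
             max_abs_rho = unname(r),
             strength = rho_strength(r),
             redundant = !is.na(r) & r > threshold,
             row.names = NULL)
}

#' Classify parametric features as redundant against their static twins
#'
#' Parametric and static features share definitions, so only corresponding
#' (same-name) pairs are correlated; a parametric feature is redundant when
#' its signed Spearman rho with its static twin exceeds `threshold`.
#'
#' @param static,parametric feature tables with identical feature name sets
#'   over the same lesions.
#' @param threshold redundancy cut-off, default 0.7.
#' @return data.frame: feature, rho, strength, redundant.
#' @export
classify_parametric_redundancy <- function(static, parametric,
                                           threshold = 0.7) {
  S <- as_feature_matrix(static); P <- as_feature_matrix(parametric)
  if (!setequal(colnames(S), colnames(P)))
    stop("feature name sets differ between static and parametric tables")
  P <- P[, colnames(S), drop = FALSE]
  rho <- vapply(colnames(S), function(f)
    suppressWarnings(stats::cor(S[, f], P[, f], method = "spearman")),
    numeric(1))
  data.frame(feature = colnames(S), rho = unname(rho),
             strength = rho_strength(rho),
             redundant = !is.na(rho) & rho > threshold,
             row.names = NULL)
}

#' Frame-duration robustness of dynamic features
#'
#' Correlates each dynamic feature's values between the two framings of the
#' same acquisition (e.g. sixteen 150 s frames vs eight 300 s frames).
#' A feature is robust to frame duration when rho exceeds `threshold`.
#'
#' @param f150,f300 dynamic feature tables with the same feature names over
#'   the same lesions.
#' @param threshold robustness cut-off, default 0.7.
#' @return data.frame: feature, rho, robust.
#' @export
frame_duration_robustness <- function(f150, f300, threshold = 0.7) {
  A <- as_feature_matrix(f150); B <- as_feature_matrix(f300)
  if (!setequal(colnames(A), colnames(B)))
    stop("dynamic feature names differ between framings")
  B <- B[, colnames(A), drop = FALSE]
  rho <- vapply(colnames(A), function(f)
    suppressWarnings(stats::cor(A[, f], B[, f], method = "spearman")),
    numeric(1))
  data.frame(feature = colnames(A), rho = unname(rho),
             robust = !is.na(rho) & rho > threshold,
             row.names = NULL)
}

## tidy (family, feature, value) rows -> one named row for a feature table
feature_row <- function(df) {
  stats::setNames(df$value, paste(df$family, df$feature, sep = "_"))
}

#' Run the full cohort analysis on simulated phantom lesions
#'
#' End-to-end orchestration on a [simulate_cohort()] list: population-based
#' bin widths (static, parametric, and per dynamic frame for both framings),
#' the four feature tables (static 90, parametric 90, dynamic 38 at 150 s
#' and at 300 s per lesion), and the three correlation reports (parametric
#' redundancy, dynamic redundancy against the static set, frame-duration
#' robustness). Deterministic for a fixed cohort.
#'
#' @param cohort list of phantoms from [simulate_cohort()].
#' @param settings a [parametric_settings()].
#' @param threshold redundancy/robustness cut-off, default 0.7.
#' @param out_dir optional directory; when given, the tables and reports are
#'   written there as TSV files.
#' @return list of class `cohort_analysis`: `tables` (static, parametric,
#'   dyn150, dyn300), `widths`, `reports` (parametric_redundancy,
#'   dynamic_redundancy, robustness), `threshold`.
#' @export
run_cohort <- function(cohort, settings = parametric_settings(),
                       threshold = 0.7, out_dir = NULL) {
  n <- length(cohort)
  if (n < 3L) stop("cohort analysis needs at least 3 lesions")
  ## parametric images once per lesion
  par_imgs <- lapply(cohort, function(ph)
    compute_parametric_image(ph$series, ph$plasma, settings))
  ## population-based widths on the cohort VOI values
  static_vals <- lapply(cohort, function(ph)
    extract_voi_values(ph$static, ph$mask)$value)
  mrglc_vals <- lapply(seq_len(n), function(i)
    extract_voi_values(par_imgs[[i]]$mrglc, cohort[[i]]$mask)$value)
  w_static <- population_width(static_vals)
  w_param <- population_width(mrglc_vals)
  nt150 <- n_frames(cohort[[1]]$schedule)
  frame_vals <- function(series_list, t)
    lapply(seq_len(n), function(i)
      extract_voi_values(get_frame(series_list[[i]], t),
                         cohort[[i]]$mask)$value)
  s150 <- lapply(cohort, `[[`, "series")
  s300 <- lapply(s150, sum_frames, group_size = 2L)
  w150 <- vapply(seq_len(nt150), function(t)
    population_width(frame_vals(s150, t)), numeric(1))
  w300 <- vapply(seq_len(nt150 / 2L), function(t)
    population_width(frame_vals(s300, t)), numeric(1))
  ## per-lesion feature vectors
  tab <- function(rows) {
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("lesion_%02d", seq_len(n))
    m
  }
  static_tab <- tab(lapply(seq_len(n), function(i)
    feature_row(extract_static_feature_set(cohort[[i]]$static,
                                           cohort[[i]]$mask, w_static))))
  param_tab <- tab(lapply(seq_len(n), function(i)
    feature_row(extract_static_feature_set(par_imgs[[i]]$mrglc,
                                           cohort[[i]]$mask, w_param))))
  dyn150_tab <- tab(lapply(seq_len(n), function(i)
    feature_row(extract_dynamic_feature_set(s150[[i]], cohort[[i]]$mask,
                                            w150))))
  dyn300_tab <- tab(lapply(seq_len(n), function(i)
    feature_row(extract_dynamic_feature_set(s300[[i]], cohort[[i]]$mask,
                                            w300))))
  reports <- list(
    parametric_redundancy =
      classify_parametric_redundancy(static_tab, param_tab, threshold),
    dynamic_redundancy =
      classify_dynamic_redundancy(
        cross_correlation_matrix(dyn150_tab, static_tab), threshold),
    robustness =
      frame_duration_robustness(dyn150_tab, dyn300_tab, threshold)
  )
  out <- structure(list(
    tables = list(static = static_tab, parametric = param_tab,
                  dyn150 = dyn150_tab, dyn300 = dyn300_tab),
    widths = list(static = w_static, parametric = w_param,
                  frames_150 = w150, frames_300 = w300),
    reports = reports, threshold = threshold),
    class = "cohort_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      col.names = NA)
    wt(static_tab, "features_static.tsv")
    wt(param_tab, "features_parametric.tsv")
    wt(dyn150_tab, "features_dyn150.tsv")
    wt(dyn300_tab, "features_dyn300.tsv")
    utils::write.table(reports$dynamic_redundancy,
                       file.path(out_dir, "redundancy_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(reports$robustness,
                       file.path(out_dir, "robustness_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  n <- nrow(x$tables$static)
  cat(sprintf("<cohort_analysis> %d lesions\n", n))
  cat(sprintf("  features: static %d, parametric %d, dynamic %d (per framing)\n",
              ncol(x$tables$static), ncol(x$tables$parametric),
              ncol(x$tables$dyn150)))
  rp <- x$reports
  cat(sprintf("  parametric redundant: %d/%d (rho > %.2f)\n",
              sum(rp$parametric_redundancy$redundant),
              nrow(rp$parametric_redundancy), x$threshold))
  cat(sprintf("  dynamic redundant:    %d/%d\n",
              sum(rp$dynamic_redundancy$redundant),
              nrow(rp$dynamic_redundancy)))
  cat(sprintf("  frame-duration robust: %d/%d\n",
              sum(rp$robustness$robust), nrow(rp$robustness)))
  invisible(x)
}
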