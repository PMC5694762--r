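record_features <- function(records, features) {
  if (is.matrix(records)) {
    if (ncol(records) != 2L) stop_config("feature matrix must have 2 columns")
    return(records)
  }
  if (!is.data.frame(records) || !all(features %in% names(records)))
    stop_config("records must contain columns %s",
                paste(features, collapse = ", "))
  if ("valid" %in% names(records))
    records <- records[records$valid, , drop = FALSE]
  as.matrix(records[, features])
}

#' Fisher linear discriminant for control vs treated cells
#'
#' Projects the two-dimensional per-cell feature data -- by default
#' `(mean mass, MAR)` -- onto the single axis that best separates the
#' control and treated populations: the Fisher discriminant
#' \eqn{w \propto S_w^{-1}(\mu_c - \mu_t)} with pooled within-class
#' covariance \eqn{S_w} and equal priors. The sign of `w` is fixed so the
#' treated-class mean projects at or below the control-class mean, and the
#' threshold `offset` is the midpoint of the projected class means. A small
#' ridge (1e-6 times the mean covariance diagonal) is added with a warning
#' when \eqn{S_w} is near-singular, e.g. when one feature is constant.
#'
#' @param control,treated MAR record data.frames (or 2-column matrices).
#' @param features Which two record columns to use. The default pairs mean
#'   mass with raw MAR; set
#'   `c("mean_mass_pg", "mar_per_mass_per_h")` to discriminate on MAR/mass
#'   instead.
#' @return An object of class `ssmr_lda`: `weights` (unit length), `offset`,
#'   projected class means, and the feature names.
#' @export
fit_lda <- function(control, treated,
                    features = c("mean_mass_pg", "mar_pg_per_h")) {
  xc <- record_features(control, features)
  xt <- record_features(treated, features)
  if (nrow(xc) < 2L || nrow(xt) < 2L)
    stop_config("LDA requires at least 2 records per class")
  mu_c <- colMeans(xc)
  mu_t <- colMeans(xt)
  sw <- ((nrow(xc) - 1L) * stats::cov(xc) +
         (nrow(xt) - 1L) * stats::cov(xt)) / (nrow(xc) + nrow(xt) - 2L)
  if (!is.finite(rcond(sw)) || rcond(sw) < 1e-10) {
    eps <- 1e-6 * sum(diag(sw)) / 2
    if (eps == 0) eps <- 1e-12
    sw <- sw + diag(eps, 2L)
    warning("near-singular pooled covariance; ridge ", signif(eps, 3),
            " added")
  }
  w <- solve(sw, mu_c - mu_t)
  if (sum(w * (mu_c - mu_t)) < 0) w <- -w   # treated projects low
  w <- w / sqrt(sum(w^2))
  proj_c <- sum(w * mu_c)
  proj_t <- sum(w * mu_t)
  structure(list(weights = stats::setNames(w, features),
                 offset = (proj_c + proj_t) / 2,
                 projected_mean_control = proj_c,
                 projected_mean_treated = proj_t,
                 features = features),
            class = "ssmr_lda")
}

#' Project records onto a fitted discriminant axis
#'
#' @param model An `ssmr_lda` from [fit_lda()].
#' @param records MAR records or a 2-column feature matrix.
#' @return Numeric vector of projections (treated-like cells project low).
#' @export
project_lda <- function(model, records) {
  if (!inherits(model, "ssmr_lda"))
    stop_config("'model' must be created by fit_lda()")
  x <- record_features(records, model$features)
  drop(x %*% model$weights)
}

#' ROC curve and AUC by pair counting
#'
#' Scores must be oriented so that higher means more treated-like (the
#' positive class). The AUC is computed with the Mann-Whitney construction
#' \deqn{\mathrm{AUC} = \frac{\#\{t > c\} + \tfrac12\,\#\{t = c\}}{n_c n_t}}
#' over all control/treated score pairs, which equals the trapezoidal area
#' under the emitted ROC curve exactly. 0.5 means the treated population is
#' indistinguishable from control; 1 means perfect single-cell separation.
#'
#' @param scores_control,scores_treated Numeric score vectors (non-empty).
#' @return An object of class `ssmr_roc`: data.frame `roc` with columns
#'   `threshold, fpr, tpr` (including the (0,0) and (1,1) endpoints), and
#'   `auc`.
#' @export
roc_auc <- function(scores_control, scores_treated) {
  if (length(scores_control) == 0L || length(scores_treated) == 0L)
    stop_config("both score vectors must be non-empty")
  nc <- length(scores_control)
  nt <- length(scores_treated)
  gt <- sum(outer(scores_treated, scores_control, ">"))
  eq <- sum(outer(scores_treated, scores_control, "=="))
  auc <- (gt + 0.5 * eq) / (nc * nt)

  thr <- sort(unique(c(scores_control, scores_treated)), decreasing = TRUE)
  fpr <- vapply(thr, function(s) mean(scores_control >= s), numeric(1))
  tpr <- vapply(thr, function(s) mean(scores_treated >= s), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(roc = roc, auc = auc), class = "ssmr_roc")
}

#' @export
print.ssmr_roc <- function(x, ...) {
  cat(sprintf("ROC with %d points; AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' LDA + ROC classification of one control/treated pair
#'
#' Fits the discriminant on the two populations, projects every cell, and
#' scores the separation by ROC/AUC with treated as the positive class
#' (projections are negated so higher score = more treated-like).
#'
#' @inheritParams fit_lda
#' @return A list of class `ssmr_classifier`: the `lda` model, the `roc`
#'   result, `auc`, and the per-cell scores.
#' @export
classify_pair <- function(control, treated,
                          features = c("mean_mass_pg", "mar_pg_per_h")) {
  lda <- fit_lda(control, treated, features = features)
  sc <- -project_lda(lda, control)
  st <- -project_lda(lda, treated)
  roc <- roc_auc(sc, st)
  structure(list(lda = lda, roc = roc, auc = roc$auc,
                 scores_control = sc, scores_treated = st),
            class = "ssmr_classifier")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value (a thin wrapper around [stats::t.test()]). When both
#' groups have zero variance, equal means give p = 1 by convention and
#' different means are rejected as degenerate.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return An object of class `ssmr_welch`: `t_statistic`, `welch_df`,
#'   `p_raw`, group sizes.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_config("Welch's test requires at least 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(structure(list(t_statistic = 0, welch_df = NA_real_, p_raw = 1,
                            n_x = length(x), n_y = length(y)),
                       class = "ssmr_welch"))
    stop_config("degenerate: zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t_statistic = unname(tt$statistic),
                 welch_df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 n_x = length(x), n_y = length(y)),
            class = "ssmr_welch")
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1;
#' equivalently, the family-wise alpha threshold becomes `alpha / m` per
#' comparison (0.05 over 9 comparisons gives 0.0056 to two significant
#' figures).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Family size; must be at least the number of p-values supplied.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values, m) {
  m <- check_count(m, "m", lower = 1L)
  if (m < length(p_values))
    stop_config("family size m (%d) is smaller than the number of p-values (%d)",
                m, length(p_values))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Call a condition sensitive or resistant
#'
#' Runs Welch's t-test on MAR per mass (treated vs control), Bonferroni
#' corrects over the analysis family, and calls the sample sensitive when
#' the corrected p falls below `alpha` -- equivalently when the raw p beats
#' the `alpha / m` per-comparison threshold. The LDA/ROC AUC for the pair is
#' attached as evidence.
#'
#' @param control,treated MAR record data.frames; `treated` may not be
#'   missing.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Bonferroni family size: the number of treatment comparisons in
#'   the analysis.
#' @param sample_id,condition Labels carried into the call.
#' @param on Column tested; `mar_per_mass_per_h` by default, `mar_pg_per_h`
#'   for raw MAR.
#' @return An object of class `ssmr_call`: labels, `call`
#'   ("sensitive"/"resistant"), `t_statistic`, `welch_df`, `p_raw`,
#'   `p_corrected`, `m`, `alpha`, `auc`.
#' @export
call_sensitivity <- function(control, treated, alpha = 0.05, m = 1L,
                             sample_id = "sample", condition = "treated",
                             on = "mar_per_mass_per_h") {
  if (is.null(control) || !is.data.frame(control) || nrow(control) == 0L)
    stop_config("missing control condition")
  if (is.null(treated) || !is.data.frame(treated) || nrow(treated) == 0L)
    stop_config("missing treated condition")
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  ctl <- control[control$valid, , drop = FALSE]
  trt <- treated[treated$valid, , drop = FALSE]
  wt <- welch_test(trt[[on]], ctl[[on]])
  p_corr <- bonferroni(wt$p_raw, m)
  cls <- classify_pair(ctl, trt)
  structure(list(sample_id = sample_id, condition = condition,
                 call = if (p_corr < alpha) "sensitive" else "resistant",
                 t_statistic = wt$t_statistic, welch_df = wt$welch_df,
                 p_raw = wt$p_raw, p_corrected = p_corr,
                 m = m, alpha = alpha, auc = cls$auc),
            class = "ssmr_call")
}

#' @export
print.ssmr_call <- function(x, ...) {
  cat(sprintf(paste0("%s / %s: %s\n",
                     "  Welch t = %.3f (df %.2f), p = %.3g, ",
                     "Bonferroni (m = %d) p = %.3g; AUC = %.3f\n"),
              x$sample_id, x$condition, toupper(x$call),
              x$t_statistic, x$welch_df, x$p_raw, x$m, x$p_corrected, x$auc))
  invisible(x)
}
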