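#' ANCOVA group effect with mental-age covariates
#'
#' Fits the linear model `outcome ~ group + vma + nvma` (optionally plus the
#' `group:vma` and `group:nvma` interactions) with sum-to-zero coding for
#' the group factor, and returns the group main effect's F test and partial
#' eta squared. With interactions present the main effect is assessed with
#' Type III sums of squares (the group main-effect column is dropped from
#' the full design while the interaction columns are retained), which is
#' the only decomposition under which the main effect remains meaningful;
#' Type II (interactions involving the group removed before testing it) is
#' available via `ss_type`.
#'
#' With two groups and two covariates the residual degrees of freedom are
#' n - 6 with interactions and n - 4 without.
#'
#' @param data Data frame with the outcome, a two-level group column, and
#'   the covariate columns.
#' @param outcome Name of the outcome column (string).
#' @param group Name of the group column (string; coerced to factor, must
#'   have two levels).
#' @param covariates Character vector of covariate column names.
#' @param include_interactions Include group x covariate interactions.
#' @param ss_type `"III"` (default) or `"II"`.
#' @return An object of class `gaze_ancova`; see [tidy.gaze_ancova()].
#' @export
ancova_group_effect <- function(data, outcome, group = "group",
                                covariates = c("vma_months", "nvma_months"),
                                include_interactions = TRUE,
                                ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  cols <- c(outcome, group, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Column(s) not found: ", paste(missing, collapse = ", ")),
          class = "gazenet_format_error")
  }
  df <- data[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  df[[group]] <- factor(df[[group]])
  if (nlevels(df[[group]]) != 2) {
    abort("Group must have exactly two levels.", class = "gazenet_data_error")
  }
  n_terms <- 1 + 1 + length(covariates) +
    if (include_interactions) length(covariates) else 0
  if (nrow(df) < n_terms + 2) {
    abort("Too few complete cases for the requested model.",
          class = "gazenet_data_error")
  }
  rhs <- paste(c(group, covariates), collapse = " + ")
  if (include_interactions) {
    rhs <- paste(rhs, paste(group, covariates, sep = ":", collapse = " + "),
                 sep = " + ")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  contr <- setNames(list("contr.sum"), group)
  fit <- lm(fml, data = df, contrasts = contr)
  X <- stats::model.matrix(fit)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design is rank deficient; collinear term(s): ",
                 paste(aliased, collapse = ", ")),
          class = "gazenet_data_error")
  }
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  grp_main <- which(labels == group)
  inter_terms <- grep(":", labels)
  y <- stats::model.response(stats::model.frame(fit))
  sse <- function(Xm) {
    f <- stats::lm.fit(Xm, y)
    sum(f$residuals^2)
  }
  sse_full <- sum(stats::residuals(fit)^2)
  df_resid <- stats::df.residual(fit)
  if (ss_type == "III" || !include_interactions) {
    X_red <- X[, asg != grp_main, drop = FALSE]
    ss_group <- sse(X_red) - sse_full
  } else {
    # Type II: evaluate the group effect in the model with no group-containing
    # interactions, against the full model's residual variance
    keep_full <- !(asg %in% inter_terms[grepl(group, labels[inter_terms], fixed = TRUE)])
    X_f2 <- X[, keep_full, drop = FALSE]
    X_r2 <- X[, keep_full & asg != grp_main, drop = FALSE]
    ss_group <- sse(X_r2) - sse(X_f2)
  }
  df1 <- sum(asg == grp_main)
  f_stat <- (ss_group / df1) / (sse_full / df_resid)
  p <- pf(f_stat, df1, df_resid, lower.tail = FALSE)
  structure(
    list(outcome = outcome, group = group, covariates = covariates,
         include_interactions = include_interactions, ss_type = ss_type,
         statistic = f_stat, df1 = df1, df2 = df_resid, p.value = p,
         partial_eta_sq = ss_group / (ss_group + sse_full),
         ss_group = ss_group, ss_resid = sse_full,
         n = nrow(df), model = fit),
    class = "gaze_ancova"
  )
}

#' @export
print.gaze_ancova <- function(x, ...) {
  cat(sprintf("<gaze_ancova> %s ~ %s + %s%s  [Type %s]\n",
              x$outcome, x$group, paste(x$covariates, collapse = " + "),
              if (x$include_interactions) " (+ group interactions)" else "",
              x$ss_type))
  cat(sprintf("  group effect: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.3f, n = %d\n",
              x$df1, x$df2, x$statistic, x$p.value, x$partial_eta_sq, x$n))
  invisible(x)
}

#' Tidy an ANCOVA group-effect fit
#'
#' @param x A `gaze_ancova` object.
#' @param ... Unused.
#' @return One-row tibble: `outcome, term, statistic, df1, df2, p.value,
#'   partial.eta.sq`.
#' @method tidy gaze_ancova
#' @export
tidy.gaze_ancova <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, term = x$group, statistic = x$statistic,
                 df1 = x$df1, df2 = x$df2, p.value = x$p.value,
                 partial.eta.sq = x$partial_eta_sq)
}

#' @rdname tidy.gaze_ancova
#' @return `glance()`: one-row tibble of model-level summaries.
#' @method glance gaze_ancova
#' @export
glance.gaze_ancova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, nobs = x$n, df.residual = x$df2,
                 ss.type = x$ss_type,
                 interactions = x$include_interactions)
}

#' One-sample t-test with Cohen's d
#'
#' Two-sided one-sample t-test against `mu` (default 0.50, the no-bias value
#' of the left/right eye ratio), with the standardized mean difference
#' `d = (mean - mu) / sd`.
#'
#' @param values Numeric vector (NAs dropped).
#' @param mu Null value.
#' @return One-row tibble `estimate, sd, n, statistic, df, p.value,
#'   cohens_d`. With fewer than two values or zero variance the test
#'   statistics are `NA` (reported, not an error).
#' @export
one_sample_t <- function(values, mu = 0.50) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2 || sd(values) == 0) {
    return(tibble::tibble(estimate = if (n > 0) mean(values) else NA_real_,
                          sd = if (n > 1) sd(values) else NA_real_, n = n,
                          statistic = NA_real_, df = n - 1,
                          p.value = NA_real_, cohens_d = NA_real_))
  }
  tt <- stats::t.test(values, mu = mu)
  tibble::tibble(estimate = mean(values), sd = sd(values), n = n,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value,
                 cohens_d = (mean(values) - mu) / sd(values))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors (pairwise complete cases used).
#' @return One-row tibble `r, n, statistic, p.value`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    abort("pearson_r() needs at least 3 pairs with non-zero variance.",
          class = "gazenet_data_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 statistic = unname(ct$statistic), p.value = ct$p.value)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Transforms each correlation with `atanh` and compares
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'            {\sqrt{1/(n_1-3) + 1/(n_2-3)}}.}
#' Both the two-sided p and the one-sided p for the alternative
#' \eqn{r_1 > r_2} are returned; studies comparing a-priori-directional
#' correlation differences sometimes report the one-sided value, so both are
#' always shown.
#'
#' @param r1,r2 Correlations in (-1, 1).
#' @param n1,n2 Sample sizes, each greater than 3.
#' @return One-row tibble (vectorized over inputs): `z, p_one_sided,
#'   p_two_sided`.
#' @examples
#' fisher_compare(0.841, 20, 0.535, 21)
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    abort("Correlations must lie strictly inside (-1, 1): atanh(1) is infinite.",
          class = "gazenet_data_error")
  }
  if (any(c(n1, n2) <= 3)) {
    abort("Both sample sizes must exceed 3.", class = "gazenet_data_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z,
                 p_one_sided = pnorm(z, lower.tail = FALSE),
                 p_two_sided = 2 * pnorm(-abs(z)))
}

#' Correlation of fixation time with centrality, compared between groups
#'
#' For each AOI, correlates the per-participant percentage of fixation time
#' with the standardized weighted degree centrality within each group, then
#' compares the two correlations with [fisher_compare()] (first group level
#' minus second). Uncorrected p-values; any correction policy is left to
#' the caller and should be stated when reporting.
#'
#' @param metrics Per-participant metrics table from [fixation_metrics()].
#' @param centrality Cohort centrality table from [aoi_centrality()].
#' @param metadata Participant metadata with `id` and a two-level `group`.
#' @return Tibble with one row per AOI: per-group `r`, `n`, `p`, and the
#'   comparison `z`, `p_one_sided`, `p_two_sided`.
#' @export
compare_aoi_correlations <- function(metrics, centrality, metadata) {
  metadata <- dplyr::mutate(metadata, group = factor(.data$group))
  lv <- levels(metadata$group)
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(paste0("pct_", AOI_NAMES)),
                        names_to = "aoi", values_to = "pct",
                        names_prefix = "pct_") |>
    dplyr::inner_join(centrality, by = c("participant", "aoi")) |>
    dplyr::inner_join(dplyr::select(metadata, participant = "id", "group"),
                      by = "participant")
  per_group <- long |>
    dplyr::group_by(.data$aoi, .data$group) |>
    dplyr::summarise(pearson_r(.data$pct, .data$c_dw), .groups = "drop")
  wide <- per_group |>
    dplyr::mutate(g = ifelse(.data$group == lv[1], "1", "2")) |>
    dplyr::select("aoi", "g", "r", "n", "p.value") |>
    tidyr::pivot_wider(names_from = "g", values_from = c("r", "n", "p.value"),
                       names_sep = "")
  dplyr::bind_cols(
    wide,
    fisher_compare(wide$r1, wide$n1, wide$r2, wide$n2)
  ) |>
    dplyr::mutate(group1 = lv[1], group2 = lv[2], .after = "aoi") |>
    dplyr::arrange(match(.data$aoi, AOI_NAMES))
}
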