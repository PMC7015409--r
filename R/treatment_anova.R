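#' One-way ANOVA with percent total treatment variation
#'
#' Standard one-way decomposition of the total sum of squares of a response
#' into a between-level (treatment) and a within-level (error) component,
#' with F = MS_treatment / MS_error and p from the F distribution. The
#' percent total treatment variation (%TTV) summarises the share of total
#' variation attributable to the factor, 100 * SS_treatment / SS_total
#' (the eta-squared reading). In the storage trials the factor is the
#' sampling time frame within one treatment cell.
#'
#' @param y numeric response (e.g. concentration in ug/ml).
#' @param group factor (or coercible) with >= 2 levels, each observed at
#'   least twice.
#' @return an `anova_table` with `ss_treatment`, `ss_error`, `ss_total`,
#'   `df_treatment`, `df_error`, `f_stat`, `p_value`, `ttv_percent`.
#' @export
one_way_anova <- function(y, group) {
  group <- factor(group)
  stopifnot(length(y) == length(group))
  if (nlevels(group) < 2) {
    stop("insufficient design: need >= 2 factor levels", call. = FALSE)
  }
  if (any(table(group) < 2)) {
    stop("insufficient design: need >= 2 replicates in every level", call. = FALSE)
  }
  fit <- lm(y ~ group)
  # anova.lm warns on zero-residual (deterministic) cells; that case is
  # legitimate here and handled explicitly below
  tab <- suppressWarnings(anova(fit))
  ss_trt <- tab[["Sum Sq"]][1]
  ss_err <- tab[["Sum Sq"]][2]
  ss_tot <- ss_trt + ss_err
  df_trt <- tab[["Df"]][1]
  df_err <- tab[["Df"]][2]
  # numerically-zero components (deterministic data) are exact zeros
  tiny <- 1e-14 * max(sum(y^2), .Machine$double.xmin)
  if (ss_tot <= tiny) ss_trt <- ss_err <- ss_tot <- 0
  if (ss_err <= 1e-14 * max(ss_tot, .Machine$double.xmin)) ss_err <- 0
  if (ss_err == 0) {
    # deterministic replicates: all variation (if any) is treatment variation
    f <- if (ss_trt > 0) Inf else NaN
    p <- if (ss_trt > 0) 0 else NA_real_
  } else {
    f <- (ss_trt / df_trt) / (ss_err / df_err)
    p <- pf(f, df_trt, df_err, lower.tail = FALSE)
  }
  structure(list(ss_treatment = ss_trt, ss_error = ss_err, ss_total = ss_tot,
                 df_treatment = df_trt, df_error = df_err,
                 f_stat = f, p_value = p,
                 ttv_percent = if (ss_tot > 0) 100 * ss_trt / ss_tot else 0),
            class = "anova_table")
}

#' Label a p-value at a significance level
#'
#' The boundary is inclusive: p equal to `alpha` counts as significant,
#' matching the "p <= alpha" reporting convention.
#'
#' @param p_value p-value in `[0, 1]` (NA allowed, labelled
#'   `"not testable"`).
#' @param alpha significance level (default 0.05).
#' @return `"significant"` or `"not significant"`.
#' @export
significance_label <- function(p_value, alpha = 0.05) {
  if (is.na(p_value)) return("not testable")
  stopifnot(p_value >= 0, p_value <= 1)
  if (p_value <= alpha) "significant" else "not significant"
}

#' Format an ANOVA p-value the way stability reports print it
#'
#' @param p_value p-value.
#' @param digits significant digits.
#' @return a string like `"p <= 0.0021"`.
#' @export
format_p <- function(p_value, digits = 2) {
  if (is.na(p_value)) return("p not testable")
  paste0("p <= ", signif(p_value, digits))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf(
    "<anova_table> SS(trt) = %.4g (df %d), SS(err) = %.4g (df %d)\n",
    x$ss_treatment, x$df_treatment, x$ss_error, x$df_error))
  cat(sprintf("  F = %.4g, %s (%s), TTV = %.1f%%\n",
              x$f_stat, format_p(x$p_value),
              significance_label(x$p_value), x$ttv_percent))
  invisible(x)
}
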