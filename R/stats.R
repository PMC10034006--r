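#' Paired sample t-test
#'
#' Classical paired t on before/after differences, with the degenerate
#' convention t = 0, p = 1 when all differences are zero (no evidence of
#' change, rather than an error).
#'
#' @param before,after Equal-length numeric vectors (n >= 2).
#' @return A tibble with columns `t`, `df`, `p`, `mean_diff`, `n`.
#' @examples
#' paired_ttest(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_ttest <- function(before, after) {
  if (length(before) != length(after)) {
    abort("`before` and `after` must have equal length.",
          class = "tgflsci_contract_error")
  }
  if (length(before) < 2L) {
    abort("Need at least 2 pairs.", class = "tgflsci_contract_error")
  }
  d <- after - before
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    }
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                  mean_diff = mean(d), n = n))
  }
  tt <- t.test(after, before, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = unname(tt$estimate), n = n)
}

#' Compare a TGF metric between periods with a linear mixed-effects model
#'
#' Fits `metric ~ period + (1 | animal_id)` by REML: the period fixed effect
#' (drug minus control) is the quantity of interest, and the per-animal
#' random intercept adjusts for between-subject variability in repeated
#' vessel measurements. The F statistic and p-value use Satterthwaite
#' denominator degrees of freedom. With a single animal the model is
#' unidentifiable and the comparison falls back to a paired t-test across
#' vessels (with a warning).
#'
#' @param metrics Metrics tibble from [compute_metrics()] (columns
#'   `animal_id`, `vessel_id`, `period`, and the metric).
#' @param metric Name of the metric column: `"bfi_mean"`, `"sigma"`, or
#'   `"auc"`.
#' @param alpha Significance threshold (default 0.001).
#' @return A `tgf_comparison` object; see [tidy.tgf_comparison()].
#' @export
compare_periods_lme <- function(metrics, metric = c("bfi_mean", "sigma",
                                                    "auc"),
                                alpha = 0.001) {
  metric <- match.arg(metric)
  stopifnot(all(c("animal_id", "vessel_id", "period", metric) %in%
                  names(metrics)))
  d <- metrics |>
    dplyr::transmute(
      animal_id = factor(.data$animal_id),
      vessel_id = .data$vessel_id,
      period = factor(.data$period, levels = c("control", "drug")),
      value = .data[[metric]])
  if (anyNA(d$period)) {
    abort("`period` must contain only \"control\" and \"drug\".",
          class = "tgflsci_contract_error")
  }
  n_animals <- length(unique(d$animal_id))
  n_vessels <- length(unique(d$vessel_id))
  if (n_animals < 2L) {
    warn("Single animal: falling back to a paired t-test across vessels.")
    wide <- tidyr::pivot_wider(d, id_cols = "vessel_id",
                               names_from = "period",
                               values_from = "value")
    tt <- paired_ttest(wide$control, wide$drug)
    res <- list(metric = metric, estimate = tt$mean_diff,
                f_statistic = tt$t^2, p_value = tt$p, df = tt$df,
                n_vessels = n_vessels, n_animals = n_animals,
                significant = tt$p < alpha, alpha = alpha,
                method = "paired t-test (single animal)", model = NULL)
    return(structure(res, class = "tgf_comparison"))
  }
  fit <- suppressMessages(
    lmerTest::lmer(value ~ period + (1 | animal_id), data = d, REML = TRUE))
  an <- anova(fit)   # Satterthwaite F test for the period effect
  est <- unname(lme4::fixef(fit)["perioddrug"])
  res <- list(metric = metric, estimate = est,
              f_statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
              df = an[["DenDF"]][1], n_vessels = n_vessels,
              n_animals = n_animals,
              significant = an[["Pr(>F)"]][1] < alpha, alpha = alpha,
              method = "linear mixed-effects (Satterthwaite F)", model = fit)
  structure(res, class = "tgf_comparison")
}

#' @export
print.tgf_comparison <- function(x, ...) {
  cat(sprintf(
    "<tgf_comparison> %s: period effect %.4g (F = %.4g, p = %.3g)%s\n",
    x$metric, x$estimate, x$f_statistic, x$p_value,
    if (x$significant) sprintf(" *significant at p < %g*", x$alpha) else ""))
  cat(sprintf("  %d vessels, %d animals; %s\n",
              x$n_vessels, x$n_animals, x$method))
  invisible(x)
}

#' Tidy a period comparison
#'
#' @param x A `tgf_comparison` from [compare_periods_lme()].
#' @param ... Unused.
#' @return One-row tibble: `metric`, `estimate`, `f_statistic`, `p_value`,
#'   `df`, `significant`.
#' @method tidy tgf_comparison
#' @export
tidy.tgf_comparison <- function(x, ...) {
  tibble(metric = x$metric, estimate = x$estimate,
         f_statistic = x$f_statistic, p_value = x$p_value, df = x$df,
         significant = x$significant)
}

#' @describeIn tidy.tgf_comparison Model-level summary (sample sizes,
#'   method, threshold).
#' @method glance tgf_comparison
#' @export
glance.tgf_comparison <- function(x, ...) {
  tibble(n_vessels = x$n_vessels, n_animals = x$n_animals,
         alpha = x$alpha, method = x$method)
}

#' Box-plot summary statistics per period
#'
#' Median and 25th/75th percentiles (linear-interpolation convention,
#' `quantile(type = 7)`) of each metric per period — the numbers a box plot
#' displays.
#'
#' @param metrics Metrics tibble (long or from [compute_metrics()]).
#' @param metric Metric column(s) to summarize; default all three.
#' @return Tibble with `metric`, `period`, `q25`, `median`, `q75`, `n`.
#' @export
summarize_boxstats <- function(metrics,
                               metric = intersect(c("bfi_mean", "sigma",
                                                    "auc"),
                                                  names(metrics))) {
  stopifnot(length(metric) >= 1, "period" %in% names(metrics))
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(metric), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric, .data$period) |>
    dplyr::summarise(
      q25 = unname(quantile(.data$value, 0.25, type = 7)),
      median = unname(quantile(.data$value, 0.5, type = 7)),
      q75 = unname(quantile(.data$value, 0.75, type = 7)),
      n = dplyr::n(), .groups = "drop")
}
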