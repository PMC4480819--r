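#' Pooled objective response rate
#'
#' Objective response = complete plus partial response. Pools responder and
#' evaluable counts over groups and returns the percentage.
#'
#' @param table Data frame with columns `responders` and `evaluable` (one row
#'   per group; extra columns such as a group label are ignored).
#' @return List with `rate_pct` (100 x pooled responders / evaluable),
#'   `responders`, `evaluable`.
#' @examples
#' tab <- data.frame(responders = c(9, 2, 8, 5, 6),
#'                   evaluable = c(15, 11, 14, 19, 15))
#' pooled_response_rate(tab)$rate_pct  # 40.5 -> prints as 41 %
#' @export
pooled_response_rate <- function(table) {
  if (!all(c("responders", "evaluable") %in% names(table)))
    stop("`table` needs `responders` and `evaluable` columns")
  r <- sum(table$responders)
  e <- sum(table$evaluable)
  if (e <= 0) stop("no evaluable patients")
  if (any(table$responders > table$evaluable) || any(table$responders < 0))
    stop("responders must lie in [0, evaluable] in every group")
  list(rate_pct = 100 * r / e, responders = r, evaluable = e)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with complementary log-log confidence bands.
#' The median is the smallest time at which the survivor function drops to
#' 0.5 or below; `NA` means the median was not reached.
#'
#' @param times Follow-up times (months), non-negative.
#' @param events Logical/0-1 event indicators (TRUE = death observed).
#' @param conf_level Confidence level for the bands (default 0.95).
#' @return List of class `km_curve`: `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`, `median`, `median_ci`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_curve <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0L) stop("empty input")
  if (length(times) != length(events)) stop("`times` and `events` lengths differ")
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  structure(list(time = fit$time, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = unname(tab["median"]),
                 median_ci = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.1f months", x$median)
  cat(sprintf("<km_curve> n=%d events=%d  median survival: %s\n",
              x$fit$n, sum(x$n_event), med))
  invisible(x)
}

#' Log-rank test, optionally stratified
#'
#' Standard log-rank chi-squared comparison of survival between groups, with
#' k - 1 degrees of freedom. With `strata` (e.g. tumour cell type), the
#' observed-minus-expected and variance contributions are pooled over the
#' strata (Mantel-Haenszel) before the statistic is formed.
#'
#' @param groups List of >= 2 elements, each a list/data frame with `times`
#'   and `events`.
#' @param strata Optional list parallel to `groups` giving a stratum label
#'   per subject.
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank <- function(groups, strata = NULL) {
  if (length(groups) < 2L) stop("need at least two groups")
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0L)) stop("every group must contain at least one subject")
  time <- unlist(lapply(groups, `[[`, "times"))
  event <- as.integer(unlist(lapply(groups, `[[`, "events")))
  group <- factor(rep(seq_along(groups), sizes))
  if (is.null(strata)) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  } else {
    st <- factor(unlist(strata))
    if (length(st) != length(time)) stop("`strata` must label every subject")
    fit <- survival::survdiff(survival::Surv(time, event) ~ group +
                                survival::strata(st))
  }
  df <- length(groups) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Pearson chi-squared test for an r x c table
#'
#' Without continuity correction (the convention under which the packaged
#' outcome tables reproduce their printed between-group p-values).
#'
#' @param table Numeric count matrix, at least 2 x 2, non-negative, with
#'   positive row and column sums.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared_rxc <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2 x 2")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate margins: every row and column needs a positive sum")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Rank-based group comparison
#'
#' Two groups: two-sided Mann-Whitney U (exact enumeration when the combined
#' sample size is at most 10 and there are no ties, normal approximation with
#' tie correction otherwise). More than two groups: Kruskal-Wallis one-way
#' ANOVA with tie correction.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `method`, `statistic`, `p`.
#' @export
rank_compare <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (length(groups) == 2L) {
    x <- groups[[1]]
    y <- groups[[2]]
    exact <- (length(x) + length(y)) <= 10 && !any(duplicated(c(x, y)))
    res <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    list(method = "mann-whitney", statistic = unname(res$statistic), p = res$p.value)
  } else {
    val <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
    res <- stats::kruskal.test(val, g)
    list(method = "kruskal-wallis", statistic = unname(res$statistic), p = res$p.value)
  }
}

#' Maximum toxicity grade change
#'
#' Maximum over the laboratory panel of the increase from baseline to the
#' worst follow-up grade, with per-lab decreases floored at zero before the
#' maximum (NCI-CTCAE grades 0-4).
#'
#' @param baseline,followup Integer grade vectors (same labs, same order).
#' @return Single non-negative integer grade increase.
#' @examples
#' toxicity_grade_change(c(0, 2), c(1, 2))  # 1
#' @export
toxicity_grade_change <- function(baseline, followup) {
  if (length(baseline) != length(followup)) stop("lab panels do not match")
  g <- c(baseline, followup)
  if (anyNA(g) || any(g < 0) || any(g > 4) || any(g != round(g)))
    stop("grades must be integers in 0..4")
  max(pmax(followup - baseline, 0))
}

#' REILD incidence by cumulative functional-liver dose band
#'
#' Bands cumulative dose (`d_fl_tot + prior_liver_dose`) into `<30`, `30-60`
#' and `>60` Gy (30 and 60 Gy fall in the middle band) and reports the
#' radioembolization-induced liver disease incidence per band. Empty bands
#' report a missing incidence, not zero.
#'
#' @param records Data frame with columns `d_fl_tot`, `prior_liver_dose`
#'   (optional, taken as 0 when absent) and logical `reild`.
#' @return Data frame with one row per band: `band`, `n`, `reild_events`,
#'   `incidence_pct`.
#' @export
reild_band_summary <- function(records) {
  if (!all(c("d_fl_tot", "reild") %in% names(records)))
    stop("`records` needs `d_fl_tot` and `reild` columns")
  prior <- if ("prior_liver_dose" %in% names(records))
    records$prior_liver_dose else 0
  cum <- records$d_fl_tot + prior
  band <- factor(fl_dose_band(cum), levels = c("<30", "30-60", ">60"))
  n <- as.integer(table(band))
  ev <- as.integer(tapply(as.logical(records$reild), band, sum, default = 0L))
  data.frame(band = levels(band), n = n, reild_events = ev,
             incidence_pct = ifelse(n > 0, 100 * ev / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Packaged cohort outcome fixture
#'
#' Per-cell-type outcome counts of a heterogeneous 122-patient
#' radioembolization cohort: objective responders and evaluable patients at
#' 3 and 6 months, grade 3/4 toxicity counts, and REILD cases. Shipped as a
#' plain CSV under `inst/extdata`.
#'
#' @return Data frame with columns `cell_type`, `responders_3m`,
#'   `evaluable_3m`, `responders_6m`, `evaluable_6m`, `grade34`,
#'   `toxicity_evaluable`, `reild`.
#' @export
load_outcome_fixture <- function() {
  path <- system.file("extdata", "cohort_outcomes_by_cell_type.csv",
                      package = "dualspect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
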