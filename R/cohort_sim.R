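CELL_TYPES <- c("HCC", "CCA", "NET", "CRC", "other")

#' Synthetic dose-response cohort specification
#'
#' Generative model for a synthetic radioembolization cohort with known
#' dose-response structure, used to validate the statistics layer. Defaults
#' emulate a heterogeneous 122-patient cohort: per-cell-type log-normal
#' tumour and functional-liver dose distributions centred on the observed
#' medians, a logistic response model in log tumour dose, an ordinal
#' toxicity-grade-change model monotone in functional-liver dose, REILD risk
#' by cumulative functional-liver dose band, and exponential survival with
#' per-cell-type medians contrasted by responder status.
#'
#' @param n_patients Number of patients (>= 1).
#' @param cell_type_mix Named probability vector over
#'   `c("HCC","CCA","NET","CRC","other")`; normalised internally.
#' @param dose_distributions Data frame with columns `cell_type`,
#'   `median_dt`, `sdlog_dt`, `median_dfl`, `sdlog_dfl` (log-normal medians in
#'   Gy and log-sd dispersions).
#' @param response_model List `(intercept, slope)` of the logistic model
#'   `P(responder) = plogis(intercept + slope * log(D_T))`. The default puts
#'   50 % response probability at 45 Gy.
#' @param toxicity_model List `(intercept, slope, noise_scale)` of the latent
#'   ordinal grade-change model in `log(D_FL_TOT)`.
#' @param reild_model List with `band_risk`, risks in `[0,1]` for cumulative
#'   functional-liver dose bands `<30`, `30-60`, `>60` Gy.
#' @param survival_model List with `cell_type_median` (months; exponential
#'   medians per cell type) and `responder_scale` / `nonresponder_scale`
#'   multipliers.
#' @param prior_exposure List `(prob, median, sdlog)`: fraction of patients
#'   with prior liver radiation and the log-normal prior mean liver dose (Gy).
#' @param censoring_rate Expected fraction of censored survival times.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 122,
                        cell_type_mix = c(HCC = 26, CCA = 18, NET = 20,
                                          CRC = 29, other = 29) / 122,
                        dose_distributions = data.frame(
                          cell_type = CELL_TYPES,
                          median_dt = c(109.7, 35, 24.2, 33.3, 33.6),
                          sdlog_dt = 0.7,
                          median_dfl = c(55.1, 24.9, 23.7, 27.8, 29.8),
                          sdlog_dfl = 0.6),
                        response_model = list(intercept = -1.4 * log(45), slope = 1.4),
                        toxicity_model = list(intercept = -2.6, slope = 0.75,
                                              noise_scale = 0.55),
                        reild_model = list(band_risk = c(`<30` = 0, `30-60` = 0,
                                                         `>60` = 0.385)),
                        survival_model = list(
                          cell_type_median = c(HCC = 8, CCA = 5.7, NET = 60,
                                               CRC = 10.8, other = 8.3),
                          responder_scale = 36.0 / 10.1,
                          nonresponder_scale = 8.7 / 10.1),
                        prior_exposure = list(prob = 0.12, median = 20, sdlog = 0.5),
                        censoring_rate = 0.28,
                        seed = 1L) {
  if (n_patients < 1) stop("`n_patients` must be at least 1")
  if (is.null(names(cell_type_mix)) || !setequal(names(cell_type_mix), CELL_TYPES))
    stop("`cell_type_mix` must be named over ", paste(CELL_TYPES, collapse = ", "))
  if (any(cell_type_mix < 0) || sum(cell_type_mix) <= 0)
    stop("`cell_type_mix` must be non-negative with positive sum")
  cell_type_mix <- cell_type_mix[CELL_TYPES] / sum(cell_type_mix)
  if (any(dose_distributions$median_dt <= 0) || any(dose_distributions$median_dfl <= 0))
    stop("dose medians must be positive")
  br <- reild_model$band_risk
  if (length(br) != 3L || any(br < 0) || any(br > 1))
    stop("REILD band risks must be three values in [0, 1]")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("`censoring_rate` must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 cell_type_mix = cell_type_mix,
                 dose_distributions = dose_distributions,
                 response_model = response_model,
                 toxicity_model = toxicity_model,
                 reild_model = reild_model,
                 survival_model = survival_model,
                 prior_exposure = prior_exposure,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws patient records from a [cohort_spec()]. Reproducible per seed;
#' per-cell-type sample dose medians converge to the specified medians as the
#' cohort grows, responder status follows the logistic model in log tumour
#' dose, REILD follows the cumulative-dose band risks, and survival is
#' exponential with responder/nonresponder contrast.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per patient; columns: `id`, `cell_type`,
#'   `d_t`, `d_fl_tot`, `prior_liver_dose` (Gy), `responder`, `response_3m`,
#'   `response_6m` (CR/PR/SD/PD/not_evaluable), per-lab baseline and maximum
#'   follow-up toxicity grades (`baseline_`/`followup_` `bilirubin`, `ast`,
#'   `alt`; 0-4), `reild` (logical), `survival_months`, `event` (TRUE =
#'   death observed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  dd <- spec$dose_distributions
  with_seed(spec$seed, {
    cell_type <- sample(CELL_TYPES, n, replace = TRUE, prob = spec$cell_type_mix)
    i <- match(cell_type, dd$cell_type)
    d_t <- stats::rlnorm(n, log(dd$median_dt[i]), dd$sdlog_dt[i])
    d_fl <- stats::rlnorm(n, log(dd$median_dfl[i]), dd$sdlog_dfl[i])
    prior <- ifelse(stats::runif(n) < spec$prior_exposure$prob,
                    stats::rlnorm(n, log(spec$prior_exposure$median),
                                  spec$prior_exposure$sdlog), 0)

    p_resp <- stats::plogis(spec$response_model$intercept +
                              spec$response_model$slope * log(d_t))
    responder <- stats::rbinom(n, 1L, p_resp) == 1L

    sm <- spec$survival_model
    med <- sm$cell_type_median[cell_type] *
      ifelse(responder, sm$responder_scale, sm$nonresponder_scale)
    t_surv <- stats::rexp(n, rate = log(2) / med)
    censored <- stats::runif(n) < spec$censoring_rate
    survival_months <- ifelse(censored, stats::runif(n) * t_surv, t_surv)
    event <- !censored

    response_3m <- response_label(responder, survival_months, 3)
    resp6 <- (responder & stats::runif(n) < 0.9) |
      (!responder & stats::runif(n) < 0.08)
    response_6m <- response_label(resp6, survival_months, 6)

    tm <- spec$toxicity_model
    latent <- tm$intercept + tm$slope * log(d_fl)
    grades <- lapply(c("bilirubin", "ast", "alt"), function(lab) {
      base <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
      change <- pmax(0, round(latent + stats::rlogis(n, 0, tm$noise_scale)))
      list(baseline = base, followup = pmin(4L, base + as.integer(change)))
    })
    names(grades) <- c("bilirubin", "ast", "alt")

    band <- fl_dose_band(d_fl + prior)
    risk <- spec$reild_model$band_risk[band]
    reild <- stats::rbinom(n, 1L, risk) == 1L

    data.frame(
      id = seq_len(n), cell_type = cell_type,
      d_t = d_t, d_fl_tot = d_fl, prior_liver_dose = prior,
      responder = responder,
      response_3m = response_3m, response_6m = response_6m,
      baseline_bilirubin = grades$bilirubin$baseline,
      baseline_ast = grades$ast$baseline,
      baseline_alt = grades$alt$baseline,
      followup_bilirubin = grades$bilirubin$followup,
      followup_ast = grades$ast$followup,
      followup_alt = grades$alt$followup,
      reild = reild,
      survival_months = survival_months, event = event,
      stringsAsFactors = FALSE)
  })
}

# (m)RECIST-style label from responder status; patients not surviving to the
# timepoint are not evaluable.
response_label <- function(responder, survival_months, timepoint) {
  n <- length(responder)
  lab <- character(n)
  cr <- stats::runif(n) < 0.2
  pd <- stats::runif(n) < 0.5
  lab[responder] <- ifelse(cr[responder], "CR", "PR")
  lab[!responder] <- ifelse(pd[!responder], "PD", "SD")
  lab[survival_months < timepoint] <- "not_evaluable"
  lab
}

#' Read / write cohort tables
#'
#' Plain-CSV round trip for the patient-record table produced by
#' [generate_cohort()] (column dictionary in that help page).
#'
#' @param records Cohort data frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("responder", "reild", "event"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
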