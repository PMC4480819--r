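# MIRD constants for Y-90 in liver: 50 Gy per GBq/kg, tissue density 1.029 kg/L.
Y90_GY_PER_GBQ_KG <- 50
HEPATIC_DENSITY_KG_L <- 1.029

# Planning thresholds (Gy): tumour efficacy floor and cumulative
# functional-liver REILD risk bands.
D_T_EFFICACY_FLOOR_GY <- 32.7
D_FL_SAFE_BAND_GY <- 30
D_FL_HIGH_RISK_BAND_GY <- 60

#' MIRD compartment absorbed dose
#'
#' Mean absorbed dose to a compartment from its share of the hepatic TcMAA
#' activity:
#' \deqn{D = \frac{C_c}{C_{tot}} \times A \times \frac{1}{1.029} \times
#'   \frac{1}{V} \times 50}
#' with `C_c` the compartment TcMAA counts, `C_tot` the total hepatic TcMAA
#' counts, `A` the administered activity (GBq), 1.029 kg/L the hepatic tissue
#' density, `V` the compartment volume (L), and 50 the Y-90 conversion factor
#' from GBq/kg to Gy.
#'
#' @param compartment_counts TcMAA counts in the compartment.
#' @param total_counts Total hepatic TcMAA counts (> 0).
#' @param administered_gbq Administered Y-90 activity in GBq.
#' @param volume_l Compartment volume in litres (> 0).
#' @return Absorbed dose in Gy.
#' @examples
#' compartment_absorbed_dose(100, 100, 1, 1)  # 48.59 Gy: one GBq in one litre
#' @export
compartment_absorbed_dose <- function(compartment_counts, total_counts,
                                      administered_gbq, volume_l) {
  if (total_counts <= 0) stop("`total_counts` must be positive")
  if (volume_l <= 0) stop("`volume_l` must be positive")
  if (compartment_counts < 0 || compartment_counts > total_counts)
    stop("`compartment_counts` must lie in [0, total_counts]")
  if (administered_gbq < 0) stop("`administered_gbq` must be non-negative")
  (compartment_counts / total_counts) * administered_gbq *
    (1 / HEPATIC_DENSITY_KG_L) * (1 / volume_l) * Y90_GY_PER_GBQ_KG
}

#' Compartment dose report
#'
#' Applies the MIRD formula to each compartment of a segmented volume pair.
#' Counts are summed from the ORIGINAL TcMAA volume over each label region;
#' the normalisation denominator is the total TcMAA activity over all hepatic
#' labels (tumour + FL-IR + FL-UN + null), so thresholding affects numerators
#' only. By convention the dose to sub-threshold unirradiated functional
#' liver is zero (`D_FL_UN = 0`), and the total functional liver dose spreads
#' the FL-IR activity over the whole functional liver volume:
#' `D_FL_TOT = D_FL_IR x V_FL_IR / V_FL_TOT`.
#'
#' @param labels A [compartment_labels()] volume.
#' @param maa The original TcMAA [spect_volume()], co-registered with `labels`.
#' @param administered_gbq Administered Y-90 activity (GBq).
#' @return An object of class `dose_report`: list with
#'   `administered_activity_gbq`, doses `D_T`, `D_FL_IR`, `D_FL_TOT`,
#'   `D_FL_UN` (Gy), `ratio_T_FL` (`D_T / D_FL_TOT`, `NA` when undefined),
#'   `volumes` (a `volume_report`), and `activity_fractions` (per-compartment
#'   fraction of hepatic TcMAA counts).
#' @export
dose_report <- function(labels, maa, administered_gbq) {
  stopifnot(inherits(labels, "compartment_labels"), inherits(maa, "spect_volume"))
  if (!identical(dim(labels), dim(maa$counts)))
    stop("labels and MAA volume are not co-registered: grid shapes differ")
  if (administered_gbq < 0) stop("`administered_gbq` must be non-negative")
  lab <- as.integer(labels)
  cnt <- as.numeric(maa$counts)
  hepatic <- lab != COMPARTMENT_CODES[["BACKGROUND"]]
  if (!any(hepatic)) stop("no hepatic voxels: segmentation produced an empty liver")
  total <- sum(cnt[hepatic])
  if (total <= 0) stop("no TcMAA counts inside the hepatic region")
  counts_of <- function(code) sum(cnt[lab == COMPARTMENT_CODES[[code]]])
  c_t <- counts_of("TUMOUR")
  c_ir <- counts_of("FL_IR")
  c_un <- counts_of("FL_UN")
  c_null <- counts_of("NULLC")
  vols <- compartment_volumes(labels)

  dose_in <- function(counts, v_ml) {
    if (v_ml <= 0) return(0)
    compartment_absorbed_dose(counts, total, administered_gbq, v_ml / 1000)
  }
  d_t <- dose_in(c_t, vols$V_T)
  d_ir <- dose_in(c_ir, vols$V_FL_IR)
  d_tot <- dose_in(c_ir, vols$V_FL_TOT)  # FL-IR activity over the whole FL volume
  ratio <- if (d_tot > 0) d_t / d_tot else NA_real_

  structure(list(
    administered_activity_gbq = administered_gbq,
    D_T = d_t, D_FL_IR = d_ir, D_FL_TOT = d_tot, D_FL_UN = 0,
    ratio_T_FL = ratio,
    volumes = vols,
    activity_fractions = c(T = c_t, FL_IR = c_ir, FL_UN = c_un, NULLC = c_null) / total
  ), class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> A=%.3g GBq\n", x$administered_activity_gbq))
  cat(sprintf("  D_T=%.1f Gy  D_FL-IR=%.1f Gy  D_FL-TOT=%.1f Gy  D_FL-UN=%.1f Gy  D_T/D_FL-TOT=%s\n",
              x$D_T, x$D_FL_IR, x$D_FL_TOT, x$D_FL_UN,
              if (is.na(x$ratio_T_FL)) "NA" else sprintf("%.2f", x$ratio_T_FL)))
  print(x$volumes)
  invisible(x)
}

#' Cumulative functional-liver dose
#'
#' Adds the mean liver dose from previous radiation exposure (prior
#' radioembolization or external beam radiotherapy, obtained from
#' dose-volume-histogram analysis of the earlier plan) to the current
#' functional-liver dose.
#'
#' @param d_fl_tot Current `D_FL_TOT` in Gy.
#' @param prior_liver_dose Prior mean liver dose in Gy (0 if none).
#' @return Cumulative dose in Gy.
#' @export
cumulative_fl_dose <- function(d_fl_tot, prior_liver_dose) {
  if (d_fl_tot < 0 || prior_liver_dose < 0) stop("doses must be non-negative")
  d_fl_tot + prior_liver_dose
}

#' BSA activity prescription (resin microspheres)
#'
#' `activity (GBq) = BSA (m^2) - 0.2 + LI`, floored at zero, with `LI` the
#' estimated fractional tumour involvement of the liver.
#'
#' @param bsa Body surface area in m^2 (> 0).
#' @param liver_involvement Tumour liver involvement fraction in `[0, 1]`.
#' @return Prescribed activity in GBq.
#' @examples
#' prescribe_activity_bsa(1.8, 0.25)  # 1.85 GBq
#' @export
prescribe_activity_bsa <- function(bsa, liver_involvement) {
  if (bsa <= 0) stop("`bsa` must be positive")
  if (liver_involvement < 0 || liver_involvement > 1)
    stop("`liver_involvement` must be a fraction in [0, 1]")
  max(bsa - 0.2 + liver_involvement, 0)
}

#' MIRD activity prescription (glass microspheres)
#'
#' Inverts the Y-90 dose conversion to deliver a desired mean absorbed dose
#' (conventionally 90-120 Gy) to a target territory of known mass:
#' `activity (GBq) = target_dose (Gy) x target_mass (kg) / 50`.
#'
#' @param target_dose Desired territory dose in Gy (> 0).
#' @param target_mass Target territory mass in kg (> 0).
#' @return Prescribed activity in GBq.
#' @examples
#' prescribe_activity_glass(120, 1)  # 2.4 GBq
#' @export
prescribe_activity_glass <- function(target_dose, target_mass) {
  if (target_dose <= 0 || target_mass <= 0)
    stop("`target_dose` and `target_mass` must be positive")
  target_dose * target_mass / Y90_GY_PER_GBQ_KG
}

#' Dose-threshold planning recommendation
#'
#' Classifies a dose report against the empirical planning thresholds: the
#' tumour dose should exceed 32.7 Gy (the level above which a 50 % objective
#' response rate was seen, irrespective of cell type) while the cumulative
#' functional-liver dose stays below 30 Gy; 30-60 Gy appeared well tolerated,
#' and above 60 Gy the observed REILD risk was 38.5 %. Boundary handling:
#' strict `>` for the efficacy floor, strict `<` 30 for the safe band, strict
#' `>` 60 for the high-risk band (30 and 60 Gy fall in the middle band).
#'
#' @param report A [dose_report()].
#' @param prior_liver_dose Prior mean liver dose in Gy (default 0).
#' @return List with `action` (one of `"increase_activity"`, `"acceptable"`,
#'   `"reduce_activity"`), `efficacy_met`, `cumulative_fl_dose_gy`,
#'   `reild_band` (`"<30"`, `"30-60"`, `">60"`), `high_reild_risk`.
#' @export
planning_recommendation <- function(report, prior_liver_dose = 0) {
  stopifnot(inherits(report, "dose_report"))
  cum <- cumulative_fl_dose(report$D_FL_TOT, prior_liver_dose)
  band <- fl_dose_band(cum)
  efficacy_met <- report$D_T > D_T_EFFICACY_FLOOR_GY
  high_risk <- band == ">60"
  action <- if (high_risk) {
    "reduce_activity"
  } else if (!efficacy_met && band == "<30") {
    "increase_activity"
  } else {
    "acceptable"
  }
  list(action = action, efficacy_met = efficacy_met,
       cumulative_fl_dose_gy = cum, reild_band = band,
       high_reild_risk = high_risk)
}

# Band a cumulative functional-liver dose; 30 and 60 Gy belong to the middle
# band ("30 - 60 Gy appeared to be well tolerated").
fl_dose_band <- function(cum_dose) {
  ifelse(cum_dose < D_FL_SAFE_BAND_GY, "<30",
         ifelse(cum_dose > D_FL_HIGH_RISK_BAND_GY, ">60", "30-60"))
}
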