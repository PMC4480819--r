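#' Fractional threshold mask
#'
#' Binary mask of all voxels with at least `fraction` of the maximum count of
#' the volume (inclusive boundary). The published segmentation uses a 10 %
#' threshold for both the tumour map (on the TcMAA volume) and the functional
#' liver map (on the corrected TcSC volume); 10 % was the working point chosen
#' from a 5-30 % comparison.
#'
#' @param volume A [spect_volume()] with at least one positive voxel.
#' @param fraction Fraction of the maximum, in (0, 1). Default 0.10.
#' @param envelope Optional logical array (or `binary_mask`) restricting where
#'   the maximum is taken, e.g. a liver envelope when the background is hot.
#'   The mask itself is still evaluated over the full grid.
#' @return An object of class `binary_mask`: list with `mask` (logical array),
#'   `source_tracer`, `threshold_fraction`, `spacing`.
#' @examples
#' v <- spect_volume(array(c(0, 5, 10, 100, 0, 0, 0, 0), c(2, 2, 2)),
#'                   c(1, 1, 1), "TcMAA")
#' sum(fractional_threshold_mask(v, 0.10)$mask)  # 2: voxels at 10 and 100
#' @export
fractional_threshold_mask <- function(volume, fraction = 0.10, envelope = NULL) {
  stopifnot(inherits(volume, "spect_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be a single number in (0, 1)")
  env <- envelope_array(envelope, dim(volume$counts))
  mx <- if (is.null(env)) max(volume$counts) else suppressWarnings(max(volume$counts[env]))
  if (!is.finite(mx) || mx <= 0)
    stop("thresholding is undefined: no positive voxel in the volume (or envelope)")
  binary_mask(volume$counts >= fraction * mx, volume$tracer, fraction, volume$spacing)
}

binary_mask <- function(mask, source_tracer, threshold_fraction, spacing) {
  structure(list(mask = mask, source_tracer = source_tracer,
                 threshold_fraction = threshold_fraction, spacing = spacing),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> source=%s  threshold=%.3g of max  positive voxels=%d\n",
              x$source_tracer, x$threshold_fraction, sum(x$mask)))
  invisible(x)
}

# Accept a binary_mask, a logical array, or NULL; return a logical array.
envelope_array <- function(envelope, dims) {
  if (is.null(envelope)) return(NULL)
  m <- if (inherits(envelope, "binary_mask")) envelope$mask else envelope
  if (!is.logical(m)) m <- m != 0
  if (!identical(dim(m), dims)) stop("envelope grid does not match the volume grid")
  m
}

#' Corrected TcSC volume
#'
#' The second SPECT acquisition images sulphur colloid on top of the
#' still-present MAA activity, so the functional-liver signal is recovered by
#' voxelwise subtraction of the TcMAA image from the TcSC image. Negative
#' differences are clipped to zero.
#'
#' @param sc TcSC [spect_volume()].
#' @param maa TcMAA [spect_volume()], co-registered with `sc`.
#' @param maa_scale Non-negative scale applied to the MAA image before
#'   subtraction. Default 1 (plain subtraction).
#' @return A [spect_volume()] tagged `TcSC_corrected`.
#' @export
corrected_tcsc <- function(sc, maa, maa_scale = 1) {
  stopifnot(inherits(sc, "spect_volume"), inherits(maa, "spect_volume"))
  check_coregistered(sc, maa)
  if (!is.numeric(maa_scale) || length(maa_scale) != 1L || maa_scale < 0)
    stop("`maa_scale` must be a single non-negative number")
  spect_volume(pmax(sc$counts - maa_scale * maa$counts, 0),
               sc$spacing, tracer = "TcSC_corrected")
}

#' Four-compartment partition
#'
#' Fuses the MAA-positive and SC-positive maps into the physiological
#' partition: tumour (MAA+/SC-), irradiated functional liver FL-IR
#' (MAA+/SC+), unirradiated functional liver FL-UN (MAA-/SC+), and the null
#' compartment (MAA-/SC- inside the hepatic envelope; outside it, background).
#' When no envelope is supplied, the hepatic extent is taken as the
#' morphological closure (3x3x3 box) of the union of the two maps, so that
#' cold interior structures (necrosis, vessels, cysts) become null rather
#' than background.
#'
#' @param maa_mask MAA-positive [fractional_threshold_mask()].
#' @param sc_mask SC-positive mask from the corrected TcSC volume.
#' @param liver_envelope Optional logical array / `binary_mask` marking the
#'   hepatic extent.
#' @return A [compartment_labels()] volume.
#' @export
partition_compartments <- function(maa_mask, sc_mask, liver_envelope = NULL) {
  stopifnot(inherits(maa_mask, "binary_mask"), inherits(sc_mask, "binary_mask"))
  if (!identical(dim(maa_mask$mask), dim(sc_mask$mask)))
    stop("masks are not co-registered: grid shapes differ")
  m <- maa_mask$mask
  s <- sc_mask$mask
  env <- envelope_array(liver_envelope, dim(m))
  if (is.null(env)) env <- box_close(m | s)
  lab <- array(COMPARTMENT_CODES[["BACKGROUND"]], dim = dim(m))
  lab[m & !s] <- COMPARTMENT_CODES[["TUMOUR"]]
  lab[m & s]  <- COMPARTMENT_CODES[["FL_IR"]]
  lab[!m & s] <- COMPARTMENT_CODES[["FL_UN"]]
  lab[!m & !s & env] <- COMPARTMENT_CODES[["NULLC"]]
  compartment_labels(lab, maa_mask$spacing)
}

# 3-D morphological closing with a 3x3x3 box structuring element.
# A box dilation is separable into 1-D max filters along each axis.
box_close <- function(mask, r = 1L) {
  box_erode(box_dilate(mask, r), r)
}

box_dilate <- function(mask, r = 1L) {
  out <- mask
  for (ax in 1:3) out <- max_filter_1d(out, ax, r, pad = FALSE)
  out
}

box_erode <- function(mask, r = 1L) {
  out <- mask
  for (ax in 1:3) out <- !max_filter_1d(!out, ax, r, pad = TRUE)
  out
}

# Running OR of shifted copies along one axis; `pad` is the out-of-grid value.
max_filter_1d <- function(mask, axis, r, pad) {
  out <- mask
  for (k in seq_len(r)) {
    out <- out | shift3(mask, axis, k, pad) | shift3(mask, axis, -k, pad)
  }
  out
}

shift3 <- function(a, axis, by, pad) {
  d <- dim(a)
  n <- d[axis]
  out <- array(pad, dim = d)
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  idx_src <- idx_dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  out
}

#' Compartment volumes
#'
#' Converts voxel counts per label into volumes in mL (voxel volume =
#' product of the spacings / 1000). The total functional liver volume is
#' `V_FL_TOT = V_FL_IR + V_FL_UN` and the total liver volume is
#' `V_TOTAL_LIVER = V_T + V_FL_TOT`; the null compartment (necrosis,
#' vessels, cysts) is reported but not counted as liver tissue.
#'
#' @param labels A [compartment_labels()] volume.
#' @param voxel_spacing Optional override of the spacing attribute (mm).
#' @return An object of class `volume_report`: list with `V_T`, `V_FL_IR`,
#'   `V_FL_UN`, `V_FL_TOT`, `V_NULL`, `V_TOTAL_LIVER` (mL) and
#'   `fractional_volumes` (each compartment over `V_TOTAL_LIVER`).
#' @export
compartment_volumes <- function(labels, voxel_spacing = NULL) {
  stopifnot(inherits(labels, "compartment_labels"))
  spacing <- if (is.null(voxel_spacing)) attr(labels, "spacing") else as.numeric(voxel_spacing)
  vox_ml <- prod(spacing) / 1000
  n <- tabulate(as.integer(labels) + 1L, nbins = 5L)  # codes 0..4
  v <- n * vox_ml
  V_T <- v[COMPARTMENT_CODES[["TUMOUR"]] + 1L]
  V_FL_IR <- v[COMPARTMENT_CODES[["FL_IR"]] + 1L]
  V_FL_UN <- v[COMPARTMENT_CODES[["FL_UN"]] + 1L]
  V_NULL <- v[COMPARTMENT_CODES[["NULLC"]] + 1L]
  V_FL_TOT <- V_FL_IR + V_FL_UN
  V_TOTAL <- V_T + V_FL_TOT
  frac <- if (V_TOTAL > 0) {
    c(T = V_T, FL_IR = V_FL_IR, FL_UN = V_FL_UN, NULLC = V_NULL) / V_TOTAL
  } else {
    c(T = NA_real_, FL_IR = NA_real_, FL_UN = NA_real_, NULLC = NA_real_)
  }
  structure(list(V_T = V_T, V_FL_IR = V_FL_IR, V_FL_UN = V_FL_UN,
                 V_FL_TOT = V_FL_TOT, V_NULL = V_NULL, V_TOTAL_LIVER = V_TOTAL,
                 fractional_volumes = frac, voxel_volume_ml = vox_ml),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("<volume_report> (mL)\n")
  cat(sprintf("  V_T=%.1f  V_FL-IR=%.1f  V_FL-UN=%.1f  V_FL-TOT=%.1f  V_NULL=%.1f  V_TOTAL_LIVER=%.1f\n",
              x$V_T, x$V_FL_IR, x$V_FL_UN, x$V_FL_TOT, x$V_NULL, x$V_TOTAL_LIVER))
  invisible(x)
}

#' One-call dual-tracer segmentation
#'
#' Runs the full published segmentation chain on a co-registered pair:
#' tumour map by fractional thresholding of the original TcMAA volume,
#' MAA subtraction from the TcSC volume, functional-liver map by fractional
#' thresholding of the corrected TcSC volume, then the four-way fusion.
#'
#' @inheritParams corrected_tcsc
#' @param threshold_maa,threshold_sc Threshold fractions, default 0.10 each.
#' @param liver_envelope Optional hepatic envelope (see
#'   [partition_compartments()]).
#' @return List with `labels` ([compartment_labels()]), `volumes`
#'   ([compartment_volumes()] report), `maa_mask`, `sc_mask`, `sc_corrected`.
#' @export
segment_dual_tracer <- function(maa, sc, threshold_maa = 0.10, threshold_sc = 0.10,
                                maa_scale = 1, liver_envelope = NULL) {
  stopifnot(inherits(maa, "spect_volume"), inherits(sc, "spect_volume"))
  check_coregistered(maa, sc)
  maa_mask <- fractional_threshold_mask(maa, threshold_maa, envelope = liver_envelope)
  scc <- corrected_tcsc(sc, maa, maa_scale = maa_scale)
  sc_mask <- fractional_threshold_mask(scc, threshold_sc, envelope = liver_envelope)
  labels <- partition_compartments(maa_mask, sc_mask, liver_envelope = liver_envelope)
  list(labels = labels, volumes = compartment_volumes(labels),
       maa_mask = maa_mask, sc_mask = sc_mask, sc_corrected = scc)
}
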