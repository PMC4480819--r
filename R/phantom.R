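#' Tumour description for the digital hepatic phantom
#'
#' A spherical MAA-avid tumour, optionally with a hypervascular rim (MAA- and
#' SC-positive, the marginal zone classified as irradiated functional liver)
#' and a cold necrotic core (null compartment).
#'
#' @param centre Tumour centre in mm (length 3), in the same coordinate frame
#'   as the liver ellipsoid (voxel-centre coordinates starting at spacing/2).
#' @param radius Tumour radius in mm (> 0).
#' @param maa_intensity Relative MAA emission density of the tumour.
#' @param rim_width Width in mm of the rim shell outside `radius`; 0 disables.
#' @param rim_maa_intensity Relative MAA density in the rim.
#' @param necrotic_core_radius Radius in mm of the cold core (< `radius`).
#' @return A list of class `phantom_tumour`.
#' @export
phantom_tumour <- function(centre, radius, maa_intensity = 1,
                           rim_width = 0, rim_maa_intensity = 0.3,
                           necrotic_core_radius = 0) {
  centre <- as.numeric(centre)
  if (length(centre) != 3L) stop("tumour `centre` must be length 3 (mm)")
  if (radius <= 0) stop("tumour `radius` must be positive")
  if (necrotic_core_radius < 0 || necrotic_core_radius >= radius)
    stop("`necrotic_core_radius` must be in [0, radius)")
  if (rim_width < 0) stop("`rim_width` must be non-negative")
  if (maa_intensity < 0 || rim_maa_intensity < 0) stop("intensities must be non-negative")
  structure(list(centre = centre, radius = radius, maa_intensity = maa_intensity,
                 rim_width = rim_width, rim_maa_intensity = rim_maa_intensity,
                 necrotic_core_radius = necrotic_core_radius),
            class = "phantom_tumour")
}

#' Digital dual-tracer hepatic phantom specification
#'
#' Generative parameters for a desk-scale phantom that exercises every
#' compartment of the dual-tracer partition: an ellipsoidal liver of uniform
#' sulphur-colloid-avid parenchyma, spherical MAA-avid tumours with optional
#' hypervascular rims and necrotic cores, isotropic Gaussian resolution blur,
#' and Poisson counting noise. Geometry is analytic so ground truth is exact.
#'
#' @param grid_shape Integer length-3 grid dimensions (voxels).
#' @param voxel_spacing Voxel spacing in mm, length 3. Default 4.42 mm
#'   isotropic on a 64-cube (about a 283 mm field of view).
#' @param liver_centre Liver ellipsoid centre in mm; default grid centre.
#' @param liver_semi_axes Ellipsoid semi-axes in mm (default 80, 60, 50,
#'   about a 1.0 L liver).
#' @param tumours List of [phantom_tumour()] objects (may be empty).
#' @param parenchyma_sc_intensity Relative SC emission density of functional
#'   parenchyma.
#' @param parenchyma_maa_intensity Relative MAA emission density of normal
#'   parenchyma (default 0.02, i.e. sub-threshold: nontarget microsphere
#'   deposition that contributes to the hepatic activity denominator but not
#'   to the MAA-positive map). Must stay below the threshold fraction of the
#'   tumour intensity for exact ground-truth recovery.
#' @param background_intensity Relative density outside the liver for both
#'   tracers (default 0).
#' @param total_maa_counts Expected total MAA counts in the first scan.
#' @param total_sc_counts Expected total counts contributed by the SC tracer
#'   itself. The second scan images SC on top of the still-present MAA, so
#'   its total is `total_sc_counts + total_maa_counts`; the default 5:1 excess
#'   mirrors the injected-activity ratio (185 vs 37 MBq).
#' @param psf_sigma Isotropic Gaussian blur sigma in mm applied before noise;
#'   0 disables.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(4.42, 4.42, 4.42),
                         liver_centre = NULL,
                         liver_semi_axes = c(80, 60, 50),
                         tumours = list(),
                         parenchyma_sc_intensity = 1,
                         parenchyma_maa_intensity = 0.02,
                         background_intensity = 0,
                         total_maa_counts = 2e6,
                         total_sc_counts = 1e7,
                         psf_sigma = 0,
                         noise = c("none", "poisson"),
                         seed = 1L) {
  noise <- match.arg(noise)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be three positive integers")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be three positive mm values")
  if (is.null(liver_centre)) liver_centre <- grid_shape * voxel_spacing / 2
  liver_centre <- as.numeric(liver_centre)
  liver_semi_axes <- as.numeric(liver_semi_axes)
  if (length(liver_semi_axes) != 3L || any(liver_semi_axes <= 0))
    stop("`liver_semi_axes` must be three positive mm values")
  if (parenchyma_sc_intensity < 0 || parenchyma_maa_intensity < 0 ||
      background_intensity < 0)
    stop("intensities must be non-negative")
  if (total_maa_counts < 0 || total_sc_counts < 0)
    stop("total counts must be non-negative")
  if (psf_sigma < 0) stop("`psf_sigma` must be non-negative")
  tumours <- lapply(tumours, function(t) {
    if (!inherits(t, "phantom_tumour")) t <- do.call(phantom_tumour, t)
    # conservative containment test: the distance from the tumour centre to
    # the ellipsoid surface is at least (1 - s) * min(semi-axes), where s is
    # the ellipsoidal norm of the centre offset
    s <- sqrt(sum(((t$centre - liver_centre) / liver_semi_axes)^2))
    if (t$radius > (1 - s) * min(liver_semi_axes) + 1e-9)
      stop("tumour at (", paste(signif(t$centre, 4), collapse = ", "),
           ") mm does not lie inside the liver ellipsoid")
    t
  })
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 liver_centre = liver_centre, liver_semi_axes = liver_semi_axes,
                 tumours = tumours,
                 parenchyma_sc_intensity = parenchyma_sc_intensity,
                 parenchyma_maa_intensity = parenchyma_maa_intensity,
                 background_intensity = background_intensity,
                 total_maa_counts = total_maa_counts,
                 total_sc_counts = total_sc_counts,
                 psf_sigma = psf_sigma, noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Noise-free generative maps: relative emission densities per voxel for each
# tracer plus the geometric ground-truth labels. Labels are defined here,
# pre-blur and pre-noise.
phantom_maps <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  outer3 <- function(a, b, c) outer(outer(a, b, "+"), c, "+")
  liver <- outer3(((x - spec$liver_centre[1]) / spec$liver_semi_axes[1])^2,
                  ((y - spec$liver_centre[2]) / spec$liver_semi_axes[2])^2,
                  ((z - spec$liver_centre[3]) / spec$liver_semi_axes[3])^2) <= 1

  lab <- array(COMPARTMENT_CODES[["BACKGROUND"]], dim = d)
  lab[liver] <- COMPARTMENT_CODES[["FL_UN"]]
  maa_w <- array(0, dim = d)
  sc_w <- array(0, dim = d)
  sc_w[liver] <- spec$parenchyma_sc_intensity
  maa_w[liver] <- spec$parenchyma_maa_intensity

  for (t in spec$tumours) {
    r2 <- outer3((x - t$centre[1])^2, (y - t$centre[2])^2, (z - t$centre[3])^2)
    if (t$rim_width > 0) {
      rim <- liver & r2 <= (t$radius + t$rim_width)^2 & r2 > t$radius^2
      lab[rim] <- COMPARTMENT_CODES[["FL_IR"]]
      maa_w[rim] <- t$rim_maa_intensity
      # sc_w stays at parenchyma level in the rim
    }
    core_r2 <- t$necrotic_core_radius^2
    body <- r2 <= t$radius^2 & r2 > core_r2
    lab[body] <- COMPARTMENT_CODES[["TUMOUR"]]
    maa_w[body] <- t$maa_intensity
    sc_w[body] <- 0
    if (t$necrotic_core_radius > 0) {
      core <- r2 <= core_r2
      lab[core] <- COMPARTMENT_CODES[["NULLC"]]
      maa_w[core] <- 0
      sc_w[core] <- 0
    }
  }
  if (spec$background_intensity > 0) {
    maa_w[!liver] <- spec$background_intensity
    sc_w[!liver] <- spec$background_intensity
  }
  list(maa_w = maa_w, sc_w = sc_w,
       labels = compartment_labels(lab, sp), liver = liver)
}

# Scale a relative density map to an expected total count.
scale_to_counts <- function(w, total) {
  s <- sum(w)
  if (s <= 0 || total <= 0) return(array(0, dim = dim(w)))
  w * (total / s)
}

#' Generate a dual-tracer phantom
#'
#' Produces a co-registered TcMAA / TcSC volume pair and the exact ground
#' truth implied by the generative geometry. The simulated TcSC acquisition
#' contains the still-present MAA activity in addition to the sulphur
#' colloid (the second scan images both tracers), which is what the
#' MAA-subtraction step of the segmentation removes. With `noise = "none"`
#' and `psf_sigma = 0`, [segment_dual_tracer()] with default thresholds
#' recovers the ground-truth labels exactly (given the default generative
#' intensities, which all sit above the 10 % thresholds).
#'
#' @param spec A [phantom_spec()].
#' @return List with `maa` and `sc` ([spect_volume()] pair) and `truth`, a
#'   `ground_truth` object carrying `label_volume`, `true_volumes` (mL),
#'   `maa_fractions` (per-compartment fraction of hepatic MAA activity) and
#'   the noise-free per-voxel MAA counts.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  maps <- phantom_maps(spec)
  maa <- scale_to_counts(maps$maa_w, spec$total_maa_counts)
  sc_tracer <- scale_to_counts(maps$sc_w, spec$total_sc_counts)
  sc <- sc_tracer + maa  # second acquisition: SC superimposed on residual MAA

  truth <- ground_truth(maps, maa, spec)

  if (spec$psf_sigma > 0) {
    sig_vox <- spec$psf_sigma / spec$voxel_spacing
    maa <- gaussian_blur3(maa, sig_vox)
    sc <- gaussian_blur3(sc, sig_vox)
  }
  if (spec$noise == "poisson") {
    with_seed(spec$seed, {
      maa <- array(stats::rpois(length(maa), maa), dim = dim(maa))
      sc <- array(stats::rpois(length(sc), sc), dim = dim(sc))
    })
  }
  list(maa = spect_volume(maa, spec$voxel_spacing, "TcMAA"),
       sc = spect_volume(sc, spec$voxel_spacing, "TcSC"),
       truth = truth)
}

ground_truth <- function(maps, maa_counts, spec) {
  vols <- compartment_volumes(maps$labels)
  lab <- as.integer(maps$labels)
  hep <- lab != COMPARTMENT_CODES[["BACKGROUND"]]
  total <- sum(maa_counts[hep])
  frac_of <- function(code) {
    if (total <= 0) return(0)
    sum(maa_counts[lab == COMPARTMENT_CODES[[code]]]) / total
  }
  structure(list(
    label_volume = maps$labels,
    true_volumes = c(V_T = vols$V_T, V_FL_IR = vols$V_FL_IR,
                     V_FL_UN = vols$V_FL_UN, V_NULL = vols$V_NULL,
                     V_FL_TOT = vols$V_FL_TOT, V_TOTAL_LIVER = vols$V_TOTAL_LIVER),
    volume_report = vols,
    maa_fractions = c(T = frac_of("TUMOUR"), FL_IR = frac_of("FL_IR"),
                      FL_UN = frac_of("FL_UN"), NULLC = frac_of("NULLC")),
    noise_free_maa = maa_counts
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n  volumes (mL): ")
  cat(paste(names(x$true_volumes), sprintf("%.1f", x$true_volumes),
            sep = "=", collapse = "  "), "\n")
  cat("  hepatic MAA fractions: ")
  cat(paste(names(x$maa_fractions), sprintf("%.3f", x$maa_fractions),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Analytic dose report for a phantom
#'
#' Closed-form MIRD dose report from the generative (noise-free, unblurred)
#' activity fractions and the exact voxelized compartment volumes. Serves as
#' the independent oracle for the full segment-then-dose pipeline: on a
#' noiseless, unblurred phantom the pipeline must reproduce it.
#'
#' @param spec A [phantom_spec()].
#' @param administered_gbq Administered Y-90 activity in GBq.
#' @return A `dose_report` (see [dose_report()]).
#' @export
analytic_dose <- function(spec, administered_gbq) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (administered_gbq < 0) stop("`administered_gbq` must be non-negative")
  maps <- phantom_maps(spec)
  maa <- scale_to_counts(maps$maa_w, spec$total_maa_counts)
  truth <- ground_truth(maps, maa, spec)
  v <- truth$volume_report
  f <- truth$maa_fractions
  k <- administered_gbq * Y90_GY_PER_GBQ_KG / HEPATIC_DENSITY_KG_L  # Gy * L
  dose <- function(frac, v_ml) if (v_ml > 0) frac * k / (v_ml / 1000) else 0
  d_t <- dose(f[["T"]], v$V_T)
  d_ir <- dose(f[["FL_IR"]], v$V_FL_IR)
  d_tot <- dose(f[["FL_IR"]], v$V_FL_TOT)
  structure(list(
    administered_activity_gbq = administered_gbq,
    D_T = d_t, D_FL_IR = d_ir, D_FL_TOT = d_tot, D_FL_UN = 0,
    ratio_T_FL = if (d_tot > 0) d_t / d_tot else NA_real_,
    volumes = v,
    activity_fractions = f
  ), class = "dose_report")
}

# Separable 3-D Gaussian blur; sigma given per axis in voxels.
gaussian_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) if (sigma_vox[ax] > 0) a <- blur_axis(a, ax, sigma_vox[ax])
  a
}

blur_axis <- function(a, axis, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  n <- d[1]
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[off + r + 1]
  }
  out <- array(K %*% m, dim = d)
  aperm(out, order(perm))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
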