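vol1d <- function(counts, spacing = c(1, 1, 1), tracer = "TcMAA") {
  spect_volume(array(counts, c(length(counts), 1, 1)), spacing, tracer)
}

test_that("fractional threshold includes the boundary and respects the fraction", {
  v <- vol1d(c(0, 5, 10, 100))
  expect_equal(as.vector(fractional_threshold_mask(v, 0.10)$mask),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.vector(fractional_threshold_mask(v, 0.30)$mask),
               c(FALSE, FALSE, FALSE, TRUE))
  # uniform positive volume: every voxel equals the maximum
  u <- vol1d(rep(7, 8))
  expect_true(all(fractional_threshold_mask(u, 0.9)$mask))
  expect_error(fractional_threshold_mask(vol1d(rep(0, 4))), "positive")
  expect_error(fractional_threshold_mask(v, 0), "fraction")
  expect_error(fractional_threshold_mask(v, 1), "fraction")
})

test_that("threshold masks shrink monotonically and are scale invariant", {
  set.seed(42)
  for (rep in 1:5) {
    v <- spect_volume(array(rexp(6 * 5 * 4), c(6, 5, 4)), c(2, 2, 2), "TcMAA")
    fracs <- sort(runif(4, 0.05, 0.95))
    masks <- lapply(fracs, function(f) fractional_threshold_mask(v, f)$mask)
    for (i in seq_len(length(masks) - 1)) {
      expect_true(all(masks[[i + 1]] <= masks[[i]]))  # raising fraction never grows
    }
    scaled <- spect_volume(v$counts * 537.2, v$spacing, "TcMAA")
    expect_identical(fractional_threshold_mask(scaled, fracs[1])$mask, masks[[1]])
  }
})

test_that("MAA subtraction clips at zero and honours the scale", {
  sc <- vol1d(c(5, 5), tracer = "TcSC")
  maa <- vol1d(c(3, 10))
  out <- corrected_tcsc(sc, maa, maa_scale = 1)
  expect_equal(as.vector(out$counts), c(2, 0))
  expect_identical(out$tracer, "TcSC_corrected")
  expect_equal(corrected_tcsc(sc, maa, maa_scale = 0)$counts, sc$counts)
  expect_true(all(corrected_tcsc(maa, maa, 1)$counts == 0))
  bad <- spect_volume(array(1, c(3, 1, 1)), c(1, 1, 1), "TcMAA")
  expect_error(corrected_tcsc(sc, bad), "co-registered")
  expect_error(corrected_tcsc(vol1d(c(5, 5), spacing = c(2, 2, 2), tracer = "TcSC"), maa),
               "co-registered")
})

test_that("fusion follows the four-way truth table", {
  mk_mask <- function(bits) {
    structure(list(mask = array(as.logical(bits), c(4, 1, 1)),
                   source_tracer = "TcMAA", threshold_fraction = 0.1,
                   spacing = c(1, 1, 1)), class = "binary_mask")
  }
  env <- array(TRUE, c(4, 1, 1))
  lab <- partition_compartments(mk_mask(c(1, 1, 0, 0)), mk_mask(c(0, 1, 1, 0)),
                                liver_envelope = env)
  expect_equal(as.integer(lab), c(1L, 2L, 3L, 4L))  # T, FL-IR, FL-UN, null
  # MAA-negative everywhere: no tumour, no FL-IR
  lab2 <- partition_compartments(mk_mask(c(0, 0, 0, 0)), mk_mask(c(0, 1, 1, 0)),
                                 liver_envelope = env)
  expect_false(any(as.integer(lab2) %in% c(1L, 2L)))
  # identical masks: only FL-IR and null
  lab3 <- partition_compartments(mk_mask(c(1, 1, 0, 0)), mk_mask(c(1, 1, 0, 0)),
                                 liver_envelope = env)
  expect_setequal(unique(as.integer(lab3)), c(2L, 4L))
  expect_error(partition_compartments(mk_mask(c(1, 0, 0, 0)),
                                      structure(list(mask = array(TRUE, c(2, 1, 1)),
                                                     spacing = c(1, 1, 1)),
                                                class = "binary_mask")),
               "co-registered")
})

test_that("labels match an exhaustive per-voxel reference on random grids", {
  set.seed(7)
  for (rep in 1:8) {
    d <- sample(2:8, 3, replace = TRUE)
    maa <- array(runif(prod(d)) < 0.4, d)
    sc <- array(runif(prod(d)) < 0.4, d)
    env <- array(runif(prod(d)) < 0.7, d)
    mk <- function(m) structure(list(mask = m, source_tracer = "TcMAA",
                                     threshold_fraction = 0.1, spacing = c(1, 1, 1)),
                                class = "binary_mask")
    lab <- partition_compartments(mk(maa), mk(sc), liver_envelope = env)
    expect_equal(array(as.integer(lab), d), ref_partition(maa, sc, env))
    # every voxel carries exactly one label, and labels re-derive the masks
    expect_true(all(as.integer(lab) %in% 0:4))
    expect_identical(array(as.integer(lab), d) %in% c(1L, 2L), as.vector(maa))
    expect_identical(array(as.integer(lab), d) %in% c(2L, 3L), as.vector(sc))
  }
})

test_that("null compartment without an envelope stays inside the closed tracer union", {
  maa <- array(FALSE, c(7, 7, 7))
  sc <- array(FALSE, c(7, 7, 7))
  sc[2:6, 2:6, 2:6] <- TRUE
  sc[4, 4, 4] <- FALSE  # interior cold voxel: necrosis
  mk <- function(m, tr) structure(list(mask = m, source_tracer = tr,
                                       threshold_fraction = 0.1, spacing = c(1, 1, 1)),
                                  class = "binary_mask")
  lab <- partition_compartments(mk(maa, "TcMAA"), mk(sc, "TcSC_corrected"))
  expect_identical(as.integer(lab[4, 4, 4]), 4L)       # enclosed voxel is null
  expect_identical(as.integer(lab[1, 1, 1]), 0L)       # far corner is background
})

test_that("volumes are voxel counts times voxel volume with consistent sums", {
  lab <- array(0L, c(3, 2, 2))
  lab[1:3, 1, 1] <- 1L  # 3 tumour voxels
  labels <- compartment_labels(lab, spacing = c(10, 10, 10))
  v <- compartment_volumes(labels)
  expect_equal(v$V_T, 3.0)  # 3 x 1 mL
  expect_equal(v$V_TOTAL_LIVER, v$V_T + v$V_FL_TOT)
  expect_equal(v$V_FL_TOT, v$V_FL_IR + v$V_FL_UN)
  # empty tumour label
  lab2 <- array(0L, c(2, 2, 2)); lab2[1, 1, ] <- 3L
  v2 <- compartment_volumes(compartment_labels(lab2, c(5, 5, 5)))
  expect_equal(v2$V_T, 0)
  expect_equal(v2$V_TOTAL_LIVER, v2$V_FL_TOT)
})
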