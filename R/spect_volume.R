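#' SPECT count volume
#'
#' A reconstructed 3-D SPECT count grid with its voxel spacing and tracer
#' identity. This is the raw input of the dual-tracer partition method:
#' one volume acquired after intraarterial Tc-99m MAA (a surrogate for the
#' subsequent Y-90 microsphere distribution) and one acquired after
#' intravenous Tc-99m sulphur colloid (taken up by functional liver
#' parenchyma).
#'
#' @param counts 3-D numeric array of non-negative reconstructed counts.
#' @param spacing Numeric length-3 voxel spacing in mm (x, y, z).
#' @param tracer One of `"TcMAA"`, `"TcSC"`, `"TcSC_corrected"`.
#' @return An object of class `spect_volume`: a list with elements
#'   `counts`, `spacing` and `tracer`.
#' @examples
#' v <- spect_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4), tracer = "TcMAA")
#' total_counts(v)
#' @export
spect_volume <- function(counts, spacing, tracer = c("TcMAA", "TcSC", "TcSC_corrected")) {
  tracer <- match.arg(tracer)
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-D array")
  if (anyNA(counts) || any(counts < 0))
    stop("`counts` must be non-negative and free of NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel dimensions in mm")
  structure(list(counts = counts, spacing = spacing, tracer = tracer),
            class = "spect_volume")
}

#' @rdname spect_volume
#' @param x A `spect_volume`.
#' @export
total_counts <- function(x) {
  stopifnot(inherits(x, "spect_volume"))
  sum(x$counts)
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<spect_volume> tracer=%s  grid=%dx%dx%d  spacing=%.3gx%.3gx%.3g mm  total=%.4g counts\n",
              x$tracer, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$counts)))
  invisible(x)
}

# Fail early when a pair is not co-registered: same grid, same spacing.
check_coregistered <- function(a, b) {
  if (!identical(dim(a$counts), dim(b$counts)))
    stop("volumes are not co-registered: grid shapes differ")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("volumes are not co-registered: voxel spacings differ")
  invisible(TRUE)
}

#' Read / write SPECT volumes as NIfTI
#'
#' Voxel spacing is carried in the NIfTI `pixdim` header field. Integer label
#' volumes round-trip through the same functions.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tracer Tracer tag to attach on read.
#' @return `read_spect_nifti()` returns a [spect_volume()];
#'   `write_spect_nifti()` returns `path` invisibly.
#' @export
read_spect_nifti <- function(path, tracer = c("TcMAA", "TcSC", "TcSC_corrected")) {
  tracer <- match.arg(tracer)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  spect_volume(arr, spacing = RNifti::pixdim(img)[1:3], tracer = tracer)
}

#' @rdname read_spect_nifti
#' @param volume A [spect_volume()].
#' @export
write_spect_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "spect_volume"))
  img <- RNifti::asNifti(volume$counts)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Integer codes used in every label volume written or read by the package.
COMPARTMENT_CODES <- c(BACKGROUND = 0L, TUMOUR = 1L, FL_IR = 2L, FL_UN = 3L, NULLC = 4L)

#' Compartment label volume
#'
#' Voxelwise assignment to the four hepatic compartments of the dual-tracer
#' partition plus extra-hepatic background. Integer codes: 0 background,
#' 1 tumour (MAA+/SC-), 2 irradiated functional liver FL-IR (MAA+/SC+),
#' 3 unirradiated functional liver FL-UN (MAA-/SC+), 4 null compartment
#' (MAA-/SC- inside the liver: necrosis, vessels, cysts).
#'
#' @param labels 3-D integer array with values in 0..4.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `compartment_labels` (an integer array with a
#'   `spacing` attribute).
#' @export
compartment_labels <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  lab <- as.integer(labels)
  if (anyNA(lab) || any(!(lab %in% 0:4)))
    stop("labels must be integers in 0..4")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel dimensions in mm")
  out <- array(lab, dim = dim(labels))
  attr(out, "spacing") <- spacing
  class(out) <- c("compartment_labels", class(out))
  out
}

#' @export
print.compartment_labels <- function(x, ...) {
  d <- dim(x)
  tab <- tabulate(as.integer(x) + 1L, nbins = 5L)
  cat(sprintf("<compartment_labels> grid=%dx%dx%d  spacing=%.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3],
              attr(x, "spacing")[1], attr(x, "spacing")[2], attr(x, "spacing")[3]))
  cat(sprintf("  voxels: background=%d tumour=%d FL-IR=%d FL-UN=%d null=%d\n",
              tab[1], tab[2], tab[3], tab[4], tab[5]))
  invisible(x)
}

#' @rdname read_spect_nifti
#' @param labels A [compartment_labels()] volume.
#' @export
write_labels_nifti <- function(labels, path) {
  stopifnot(inherits(labels, "compartment_labels"))
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)))
  RNifti::pixdim(img) <- attr(labels, "spacing")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname read_spect_nifti
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  compartment_labels(array(as.integer(img), dim = dim(img)),
                     spacing = RNifti::pixdim(img)[1:3])
}
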