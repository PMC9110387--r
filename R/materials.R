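# Attenuation-to-density calibration and material quantification.
#
# Micro-CT attenuation contrast of light organic materials is
# approximately proportional to physical density, so a linear map fitted
# through reference materials of known density (e.g. print polymer at
# 1.19 g/cm^3, honey at 1.4 g/cm^3) converts normalized voxel values to
# g/cm^3. Density bands then isolate wax (fresh beeswax 0.958-0.970,
# comb typically 0.90-0.96), propolis (1.16), honey, and support
# structures, and band volumes quantify material budgets.

#' Calibrate normalized attenuation to physical density
#'
#' Least-squares line through reference points `(normalized value,
#' known density)`. With exactly two references the line interpolates
#' them. References must be monotone: higher attenuation must mean
#' higher density.
#'
#' @param references a data frame with columns `value`, `density`, and
#'   optionally `label`, or a list of `c(value, density)` pairs.
#' @return A `density_calibration` with `slope`, `intercept` (g/cm^3 per
#'   unit normalized value), and the reference table.
#' @export
calibrate <- function(references) {
  if (!is.data.frame(references))
    references <- do.call(rbind, lapply(references, function(r)
      data.frame(value = r[[1]], density = r[[2]],
                 label = if (length(r) >= 3) r[[3]] else NA)))
  if (is.null(references$label)) references$label <- NA
  if (nrow(references) < 2) stopf("need at least 2 reference points")
  if (anyDuplicated(references$value))
    stopf("reference values must be distinct")
  o <- order(references$value)
  if (any(diff(references$density[o]) <= 0))
    stopf("references are not monotone: higher value must mean higher density")
  v <- references$value; d <- references$density
  slope <- sum((v - mean(v)) * (d - mean(d))) / sum((v - mean(v))^2)
  intercept <- mean(d) - slope * mean(v)
  if (slope <= 0) stopf("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 references = references),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf(
    "<density_calibration> density = %.4g * value + %.4g g/cm^3 (%d refs)\n",
    x$slope, x$intercept, nrow(x$references)))
  invisible(x)
}

#' Apply a calibration to normalized values
#' @param cal a `density_calibration`.
#' @param values normalized attenuation values.
#' @return Densities in g/cm^3.
#' @export
calibrated_density <- function(cal, values) {
  cal$slope * values + cal$intercept
}

#' Material density band
#'
#' A half-open density interval `(lo, hi]` in g/cm^3; adjacent bands
#' sharing an edge partition cleanly, with ties going to the upper band.
#'
#' @param label band name.
#' @param lo,hi band limits, `lo < hi`.
#' @param color display color hint.
#' @return A `material_band`.
#' @export
material_band <- function(label, lo, hi, color = NA) {
  if (!(lo < hi)) stopf("band '%s': lo must be < hi", label)
  structure(list(label = label, lo = lo, hi = hi, color = color),
            class = "material_band")
}

check_bands <- function(bands) {
  if (inherits(bands, "material_band")) bands <- list(bands)
  lo <- vapply(bands, `[[`, numeric(1), "lo")
  hi <- vapply(bands, `[[`, numeric(1), "hi")
  o <- order(lo)
  if (any(hi[o][-length(o)] > lo[o][-1] + 1e-12))
    stopf("material bands overlap")
  bands
}

#' Segment a volume into material density bands
#'
#' Assigns every voxel to the band containing its calibrated density
#' (half-open `(lo, hi]`), leaving voxels outside all bands as
#' background, and reports per-band volumes.
#'
#' @param vol a [density_volume].
#' @param cal a `density_calibration`.
#' @param bands a list of [material_band]s (non-overlapping).
#' @return A list: `labels` (integer array, 0 = background, i = band i)
#'   and `table` (label, voxels, mm3, ml).
#' @export
segment_bands <- function(vol, cal, bands) {
  stopifnot(is_density_volume(vol))
  bands <- check_bands(bands)
  dens <- calibrated_density(cal, vol$values)
  labels <- array(0L, dim = vol$dims)
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    labels[dens > b$lo & dens <= b$hi] <- i
  }
  voxvol <- prod(vol$spacing_mm)
  counts <- tabulate(labels[labels > 0], nbins = length(bands))
  tab <- data.frame(label = vapply(bands, `[[`, character(1), "label"),
                    voxels = counts,
                    mm3 = counts * voxvol,
                    ml = counts * voxvol / 1000)
  list(labels = labels, table = tab)
}

#' Honey volume in a comb scan
#'
#' Volume of the honey density band, optionally restricted to extracted
#' cell interiors.
#'
#' @param vol a [density_volume].
#' @param cal a `density_calibration`.
#' @param honey_band a [material_band] covering honey (about 1.4
#'   g/cm^3).
#' @param restrict_to_cells optional `cell_set`; only honey voxels inside
#'   labeled cells are counted.
#' @return Honey volume in ml.
#' @export
honey_volume <- function(vol, cal, honey_band, restrict_to_cells = NULL) {
  stopifnot(is_density_volume(vol))
  dens <- calibrated_density(cal, vol$values)
  m <- dens > honey_band$lo & dens <= honey_band$hi
  if (!is.null(restrict_to_cells)) {
    if (!all(dim(restrict_to_cells$labels) == vol$dims))
      stopf("cell label grid does not match the volume")
    m <- m & restrict_to_cells$labels > 0
  }
  sum(m) * prod(vol$spacing_mm) / 1000
}

#' Calibrated density histogram of a region
#'
#' @param vol a [density_volume].
#' @param cal a `density_calibration`.
#' @param region voxel set (logical array or n x 3 index matrix).
#' @param bins number of histogram bins.
#' @return A list: `histogram` (data frame bin_lo, bin_hi, count),
#'   `median`, `iqr` (g/cm^3), `n_voxels`.
#' @export
density_profile <- function(vol, cal, region, bins = 50) {
  stopifnot(is_density_volume(vol))
  mask <- as_voxel_mask(region, vol$dims)
  if (!any(mask)) stopf("empty region")
  dens <- calibrated_density(cal, vol$values[mask])
  rng <- range(dens)
  if (diff(rng) == 0) rng <- rng + c(-0.005, 0.005)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(dens, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > bins] <- bins
  list(histogram = data.frame(bin_lo = edges[-length(edges)],
                              bin_hi = edges[-1],
                              count = tabulate(idx, nbins = bins)),
       median = median(dens),
       iqr = unname(diff(quantile(dens, c(0.25, 0.75)))),
       n_voxels = length(dens))
}
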