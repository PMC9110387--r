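#' Density volume
#'
#' A regular 3-D grid of normalized attenuation (density) values in
#' \[0, 1\] with millimetre voxel spacing. This is the primary container
#' for scanned comb data: voxel `(i, j, k)` (0-based) has its center at
#' `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param values numeric 3-D array with all values in \[0, 1\].
#' @param spacing_mm positive voxel spacing, length 1 (isotropic) or 3.
#' @param origin_mm world position (mm) of the center of voxel (0,0,0).
#' @return An object of class `density_volume` with fields `dims`,
#'   `spacing_mm`, `origin_mm`, `values`.
#' @export
density_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stopf("`values` must be a 3-D array")
  dim(values) <- unname(dim(values))
  dims <- dim(values)
  if (any(dims < 2)) stopf("all dims must be >= 2 (got %s)",
                           paste(dims, collapse = "x"))
  spacing_mm <- unname(rep_len(as.numeric(spacing_mm), 3))
  if (any(spacing_mm <= 0)) stopf("spacing must be strictly positive")
  rng <- range(values, finite = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stopf("density values must lie in [0, 1] (got range %.4g..%.4g)",
          rng[1], rng[2])
  structure(list(dims = dims, spacing_mm = spacing_mm,
                 origin_mm = unname(as.numeric(origin_mm)),
                 values = values),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> %s voxels, spacing %s mm, values %.3g..%.3g\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Signed distance volume
#'
#' Per-voxel signed Euclidean distance (mm) to the boundary of a
#' binarized solid: negative strictly inside, positive strictly outside.
#'
#' @param distances numeric 3-D array of signed distances in mm.
#' @param spacing_mm,origin_mm grid geometry as in [density_volume()].
#' @param iso_threshold the density threshold in (0, 1) that defined the
#'   solid (recorded for provenance).
#' @return An object of class `signed_distance_volume`.
#' @export
signed_distance_volume <- function(distances, spacing_mm,
                                   origin_mm = c(0, 0, 0),
                                   iso_threshold = 0.5) {
  if (!is.array(distances) || length(dim(distances)) != 3)
    stopf("`distances` must be a 3-D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  if (any(spacing_mm <= 0)) stopf("spacing must be strictly positive")
  structure(list(dims = dim(distances), spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), distances = distances,
                 iso_threshold = iso_threshold),
            class = "signed_distance_volume")
}

#' @export
print.signed_distance_volume <- function(x, ...) {
  inside <- sum(x$distances < 0)
  cat(sprintf(
    "<signed_distance_volume> %s voxels, spacing %s mm, %d inside (%.1f mm^3)\n",
    paste(x$dims, collapse = "x"),
    paste(signif(x$spacing_mm, 4), collapse = "x"),
    inside, inside * prod(x$spacing_mm)))
  invisible(x)
}

is_sdf <- function(x) inherits(x, "signed_distance_volume")
is_density_volume <- function(x) inherits(x, "density_volume")

# distance (mm) from every voxel to the nearest TRUE voxel; Inf where the
# mask cannot be reached (empty mask)
edt_mm <- function(mask, dims, spacing) {
  sq <- edt_sq_cpp(as.logical(mask), as.integer(dims), as.numeric(spacing))
  d <- sqrt(sq)
  d[d > 1e14] <- Inf
  array(d, dim = dims)
}

#' Convert a density volume to a signed distance field
#'
#' Binarizes the volume at `iso_threshold` (solid = voxels with value
#' `>= iso_threshold`) and computes the exact signed Euclidean distance
#' transform: negative inside the solid, positive outside, both measured
#' between voxel centers.
#'
#' @param vol a [density_volume].
#' @param iso_threshold density threshold in (0, 1).
#' @return A [signed_distance_volume] on the same grid.
#' @export
to_sdf <- function(vol, iso_threshold = 0.5) {
  stopifnot(is_density_volume(vol))
  if (iso_threshold <= 0 || iso_threshold >= 1)
    stopf("iso_threshold must be in (0, 1)")
  inside <- vol$values >= iso_threshold
  if (!any(inside)) stopf("empty solid: no voxel reaches iso_threshold %.3g",
                          iso_threshold)
  sdf_from_mask(inside, vol$spacing_mm, vol$origin_mm, iso_threshold)
}

# signed EDT from a logical inside-mask
sdf_from_mask <- function(inside, spacing, origin, iso_threshold = 0.5) {
  dims <- dim(inside)
  d_out <- edt_mm(inside, dims, spacing)      # 0 on inside voxels
  diag_mm <- grid_diagonal(dims, spacing)
  if (all(inside)) {
    d_in <- array(diag_mm, dim = dims)
  } else {
    d_in <- edt_mm(!inside, dims, spacing)
    d_in[is.infinite(d_in)] <- diag_mm
  }
  d_in[d_in > diag_mm] <- diag_mm
  d_out[d_out > diag_mm] <- diag_mm
  signed_distance_volume(d_out - d_in, spacing, origin, iso_threshold)
}

#' Downsample a density volume by block-mean pooling
#'
#' Averages `factor^3` blocks of voxels; the voxel spacing is multiplied
#' by `factor` and the origin moves to the center of the first block.
#' Trailing voxels that do not fill a complete block are dropped.
#'
#' @param vol a [density_volume].
#' @param factor positive integer pooling factor.
#' @return A [density_volume] at the coarser resolution.
#' @export
downsample <- function(vol, factor) {
  stopifnot(is_density_volume(vol))
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor == 1L) return(vol)
  if (any(factor > vol$dims))
    stopf("factor %d exceeds a volume dimension (%s)", factor,
          paste(vol$dims, collapse = "x"))
  nd <- vol$dims %/% factor
  v <- vol$values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  pool_axis <- function(a) {
    # average consecutive groups of `factor` along the first dimension
    d <- dim(a)
    m <- matrix(a, nrow = factor)
    pooled <- colMeans(m)
    array(pooled, dim = c(d[1] %/% factor, d[2], d[3]))
  }
  v <- pool_axis(v)
  v <- aperm(pool_axis(aperm(v, c(2, 1, 3))), c(2, 1, 3))
  v <- aperm(pool_axis(aperm(v, c(3, 2, 1))), c(3, 2, 1))
  density_volume(pmin(pmax(v, 0), 1), vol$spacing_mm * factor,
                 vol$origin_mm + (factor - 1) / 2 * vol$spacing_mm)
}

#' Load a volumetric image into a density volume
#'
#' Reads a TIFF slice stack (a directory of single-slice files in
#' lexicographic z order, or one multi-page file), an NRRD volume, or a
#' NIfTI volume. With `normalize = TRUE` values are min-max rescaled to
#' \[0, 1\] per volume.
#'
#' @param path file or directory path.
#' @param format one of `"tiff_stack"`, `"nrrd"`, `"nifti"`.
#' @param normalize rescale values to \[0, 1\] by the volume's min/max.
#' @param spacing_mm voxel spacing in mm (required for TIFF stacks, which
#'   carry no spacing metadata; overrides file metadata otherwise).
#' @param origin_mm world position of the first voxel center.
#' @return A [density_volume].
#' @export
load_volume <- function(path, format = c("tiff_stack", "nrrd", "nifti"),
                        normalize = FALSE, spacing_mm = NULL,
                        origin_mm = NULL) {
  format <- match.arg(format)
  if (format == "tiff_stack") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF stacks requires the 'tiff' package")
    if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                               ignore.case = TRUE))
      if (length(files) == 0) stopf("no TIFF slices found in %s", path)
      slices <- lapply(files, tiff::readTIFF)
    } else {
      if (!file.exists(path)) stopf("no such file: %s", path)
      slices <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(slices)) slices <- list(slices)
    }
    shapes <- vapply(slices, function(s) paste(dim(s)[1:2], collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1)
      stopf("format error: mixed slice shapes (%s)",
            paste(unique(shapes), collapse = ", "))
    if (any(vapply(slices, function(s) length(dim(s)) > 2 && dim(s)[3] > 1,
                   logical(1))))
      stopf("format error: multi-channel slices are not supported")
    d2 <- dim(slices[[1]])[1:2]
    vals <- array(0, dim = c(d2[2], d2[1], length(slices)))
    for (k in seq_along(slices)) {
      s <- slices[[k]]
      if (length(dim(s)) == 3) s <- s[, , 1]
      vals[, , k] <- t(s)  # row = image y; store x fastest
    }
    if (is.null(spacing_mm))
      stopf("spacing_mm must be given for TIFF stacks")
    vol <- list(values = vals, spacing = rep_len(spacing_mm, 3),
                origin = origin_mm %||% c(0, 0, 0))
  } else if (format == "nrrd") {
    vol <- read_nrrd_raw(path)
    if (!is.null(spacing_mm)) vol$spacing <- rep_len(spacing_mm, 3)
    if (!is.null(origin_mm)) vol$origin <- origin_mm
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stopf("reading NIfTI requires the 'RNifti' package")
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) != 3) stopf("format error: expected a 3-D NIfTI")
    sp <- RNifti::pixdim(img)[1:3]
    vol <- list(values = vals,
                spacing = if (is.null(spacing_mm)) sp else rep_len(spacing_mm, 3),
                origin = origin_mm %||% c(0, 0, 0))
  }
  v <- vol$values
  if (normalize) {
    rng <- range(v, finite = TRUE)
    if (diff(rng) == 0)
      stopf("degenerate range: constant-valued volume cannot be normalized")
    v <- (v - rng[1]) / diff(rng)
  }
  density_volume(v, vol$spacing, vol$origin %||% c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a density volume to a world-coordinate box
#'
#' @param vol a [density_volume].
#' @param lo_mm,hi_mm box corners in mm (clamped to the grid).
#' @return A [density_volume] over the intersection of the box with the
#'   grid.
#' @export
crop_volume <- function(vol, lo_mm, hi_mm) {
  stopifnot(is_density_volume(vol))
  lo <- pmax(floor((lo_mm - vol$origin_mm) / vol$spacing_mm) + 1, 1)
  hi <- pmin(ceiling((hi_mm - vol$origin_mm) / vol$spacing_mm) + 1,
             vol$dims)
  if (any(hi - lo < 1)) stopf("crop box does not intersect the volume")
  density_volume(vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                            drop = FALSE],
                 vol$spacing_mm,
                 vol$origin_mm + (lo - 1) * vol$spacing_mm)
}

#' Rigidly rotate a density volume
#'
#' Resamples the volume onto the axis-aligned bounding grid of its
#' rotated footprint (trilinear interpolation, same spacing). Used to
#' test rotation equivariance of downstream analyses.
#'
#' @param vol a [density_volume].
#' @param R a 3 x 3 rotation matrix.
#' @param center_mm rotation center (default: volume center).
#' @return A [density_volume] containing the rotated scene.
#' @export
rotate_volume <- function(vol, R, center_mm = NULL) {
  stopifnot(is_density_volume(vol))
  h <- vol$spacing_mm
  ext <- (vol$dims - 1) * h
  if (is.null(center_mm)) center_mm <- vol$origin_mm + ext / 2
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]),
                                   c(0, ext[3])))
  corners <- sweep(corners, 2, vol$origin_mm, `+`)
  rc <- sweep(sweep(corners, 2, center_mm) %*% t(R), 2, center_mm, `+`)
  lo <- apply(rc, 2, min)
  hi <- apply(rc, 2, max)
  dims <- pmax(ceiling((hi - lo) / h) + 1L, 2L)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * h[1]
  ys <- lo[2] + (seq_len(dims[2]) - 1) * h[2]
  zs <- lo[3] + (seq_len(dims[3]) - 1) * h[3]
  W <- cbind(rep(xs, times = dims[2] * dims[3]),
             rep(rep(ys, each = dims[1]), times = dims[3]),
             rep(zs, each = dims[1] * dims[2]))
  # pull back: sample the source at R^-1 (p - c) + c
  src <- sweep(sweep(W, 2, center_mm) %*% R, 2, center_mm, `+`)
  vals <- trilinear(vol$values, vol$dims, vol$spacing_mm, vol$origin_mm,
                    src)
  vals[is.na(vals)] <- 0
  density_volume(array(pmin(pmax(vals, 0), 1), dim = dims), h, lo)
}

#' Total solid volume of a signed distance field
#'
#' @param sdf a [signed_distance_volume].
#' @return Volume in mm^3 (inside-voxel count times voxel volume).
#' @export
sdf_volume <- function(sdf) {
  stopifnot(is_sdf(sdf))
  sum(sdf$distances < 0) * prod(sdf$spacing_mm)
}
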