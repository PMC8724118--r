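#' Binary cancellous-bone volume
#'
#' The unit of analysis: a 3-D logical grid (indexed z, y, x — z is the slice
#' axis, anatomically the superior-inferior direction after end-plate
#' alignment) together with its isotropic voxel size in micrometres and
#' optional anatomic tags.
#'
#' @param grid 3-D logical array, dimensions `(nz, ny, nx)`, every axis at
#'   least 2 voxels.
#' @param voxel_size_um voxel edge length in micrometres (> 0).
#' @param label optional sample identifier.
#' @param region optional anatomic region tag, one of `"ac"`, `"pc"`, `"pl"`,
#'   `"pr"` (anterior/posterior-central/-left/-right).
#' @param level optional vertebral level tag, `"L1"` .. `"L5"`.
#' @return An object of class `binary_volume`.
#' @examples
#' v <- binary_volume(array(c(TRUE, FALSE), c(4, 4, 4)), voxel_size_um = 80)
#' bone_volume_fraction(v)
#' @export
binary_volume <- function(grid, voxel_size_um, label = NULL, region = NULL,
                          level = NULL) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array")
  if (!is.logical(grid)) {
    if (is.numeric(grid)) grid <- array(grid != 0, dim(grid))
    else stop("`grid` must be logical (or numeric 0/1)")
  }
  if (any(dim(grid) < 2L))
    stop("every axis must be at least 2 voxels, got ",
         paste(dim(grid), collapse = "x"))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (!is.null(region)) region <- match.arg(region, c("ac", "pc", "pl", "pr"))
  if (!is.null(level)) level <- match.arg(level, paste0("L", 1:5))
  structure(
    list(grid = grid, voxel_size_um = as.numeric(voxel_size_um),
         label = label, region = region, level = level),
    class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat("<binary_volume> ", paste(d, collapse = " x "),
      sprintf(" voxels @ %g um", x$voxel_size_um), "\n", sep = "")
  cat(sprintf("  BV/TV = %.4f", mean(x$grid)))
  if (!is.null(x$label)) cat("  label:", x$label)
  if (!is.null(x$level)) cat("  level:", x$level)
  if (!is.null(x$region)) cat("  region:", x$region)
  cat("\n")
  invisible(x)
}

#' Grayscale image volume
#'
#' @param grid 3-D numeric array (z, y, x), integer-valued intensities.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(grid, voxel_size_um) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array")
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  structure(list(grid = grid, voxel_size_um = as.numeric(voxel_size_um)),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat("<gray_volume> ", paste(dim(x$grid), collapse = " x "),
      sprintf(" voxels @ %g um, range [%g, %g]\n", x$voxel_size_um,
              min(x$grid), max(x$grid)), sep = "")
  invisible(x)
}

natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(x))))
  ord <- order(is.na(num), num, basename(x))
  x[ord]
}

read_slice <- function(path) {
  sl <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(sl)) == 3L) {
    if (dim(sl)[3] > 1 && var(as.numeric(sl)) > 0 &&
        !all(sl[, , 1] == sl[, , dim(sl)[3]]))
      stop("multi-channel TIFF slices are not supported: ", path)
    sl <- sl[, , 1]
  }
  sl
}

#' Read an image stack
#'
#' Reads either a directory of equally-sized single-page TIFF slices (stacked
#' in natural filename order) or one multi-page TIFF.  Integer intensities
#' are preserved.
#'
#' @param path file or directory path.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return A [gray_volume()].
#' @export
read_stack <- function(path, voxel_size_um) {
  if (dir.exists(path)) {
    files <- natural_sort(list.files(path, pattern = "\\.tiff?$",
                                     ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    slices <- lapply(files, read_slice)
    ref <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), ref))
        stop("slice has inconsistent shape: ", files[i], " (",
             paste(dim(slices[[i]]), collapse = "x"), " vs ",
             paste(ref, collapse = "x"), ")")
  } else if (file.exists(path)) {
    raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    slices <- lapply(seq_along(raw), function(i) {
      sl <- raw[[i]]
      if (length(dim(sl)) == 3L) sl <- sl[, , 1]
      sl
    })
    ref <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), ref))
        stop("slice has inconsistent shape: page ", i)
  } else stop("path does not exist: ", path)
  nz <- length(slices)
  arr <- array(0, c(nz, ref[1], ref[2]))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]
  gray_volume(arr, voxel_size_um)
}

#' Write a volume as a multi-page TIFF
#'
#' Binary volumes are written as 8-bit (0 = marrow, 255 = bone); a JSON
#' sidecar (`<path>.json`) records the voxel size and tags.
#'
#' @param vol a [binary_volume()] or [gray_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  if (inherits(vol, "binary_volume")) {
    slices <- lapply(seq_len(dim(vol$grid)[1]),
                     function(z) matrix(as.numeric(vol$grid[z, , ]),
                                        dim(vol$grid)[2], dim(vol$grid)[3]))
    tiff::writeTIFF(slices, path, bits.per.sample = 8)
    side <- list(voxel_size_um = vol$voxel_size_um, binary = TRUE,
                 label = vol$label, region = vol$region, level = vol$level)
  } else if (inherits(vol, "gray_volume")) {
    mx <- max(vol$grid, 1)
    slices <- lapply(seq_len(dim(vol$grid)[1]),
                     function(z) matrix(vol$grid[z, , ] / mx,
                                        dim(vol$grid)[2], dim(vol$grid)[3]))
    tiff::writeTIFF(slices, path, bits.per.sample = 16)
    side <- list(voxel_size_um = vol$voxel_size_um, binary = FALSE, scale = mx)
  } else stop("`vol` must be a binary_volume or gray_volume")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a binary volume written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar is consulted for the
#'   voxel size when `voxel_size_um` is missing).
#' @param voxel_size_um optional override for the voxel size.
#' @return A [binary_volume()].
#' @export
read_binary_volume <- function(path, voxel_size_um = NULL) {
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  vs <- voxel_size_um %||% side$voxel_size_um
  if (is.null(vs)) stop("voxel size not given and no sidecar found")
  g <- read_stack(path, vs)
  binary_volume(g$grid > max(g$grid) / 2, vs,
                label = side$label %||% NULL,
                region = side$region %||% NULL,
                level = side$level %||% NULL)
}

#' Isodata (Ridler-Calvard) binarization
#'
#' Iterative intensity thresholding on the integer histogram: the threshold
#' converges to the midpoint of the two class means,
#' `T = (mean(values <= T) + mean(values > T)) / 2`, iterated until it moves
#' by less than half a gray level.  Foreground (bone) is `value > T`.
#'
#' @param gray a [gray_volume()].
#' @param ... passed to [binary_volume()] (label, region, level).
#' @return A [binary_volume()] with attribute `"threshold"`.
#' @export
isodata_binarize <- function(gray, ...) {
  stopifnot(inherits(gray, "gray_volume"))
  v <- as.numeric(gray$grid)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant image: no isodata threshold exists")
  vals <- sort(unique(round(v)))
  h <- tabulate(match(round(v), vals))
  cs_n <- cumsum(h)
  cs_s <- cumsum(h * vals)
  n <- sum(h); s <- sum(h * vals)
  thr <- mean(rng)
  for (it in 1:256) {
    k <- findInterval(thr, vals)   # values[1..k] <= thr
    if (k < 1) k <- 1
    if (k >= length(vals)) k <- length(vals) - 1
    m_lo <- cs_s[k] / cs_n[k]
    m_hi <- (s - cs_s[k]) / (n - cs_n[k])
    new_thr <- (m_lo + m_hi) / 2
    if (abs(new_thr - thr) < 0.5) { thr <- new_thr; break }
    thr <- new_thr
  }
  out <- binary_volume(array(gray$grid > thr, dim(gray$grid)),
                       gray$voxel_size_um, ...)
  attr(out, "threshold") <- thr
  out
}

#' Extract an axis-aligned cubic volume of interest
#'
#' @param vol a [binary_volume()].
#' @param origin integer triple `(z, y, x)`, 1-based corner of the cube.
#' @param side_voxels cube edge length in voxels.
#' @return A [binary_volume()] of dimensions `side_voxels^3`.
#' @export
crop_cube <- function(vol, origin, side_voxels) {
  stopifnot(inherits(vol, "binary_volume"))
  origin <- as.integer(origin)
  side_voxels <- as.integer(side_voxels)
  if (length(origin) != 3L || any(origin < 1L))
    stop("`origin` must be three 1-based indices (z, y, x)")
  d <- dim(vol$grid)
  end <- origin + side_voxels - 1L
  for (a in 1:3)
    if (end[a] > d[a])
      stop(sprintf("cube exceeds volume on axis %s: %d + %d - 1 > %d",
                   c("z", "y", "x")[a], origin[a], side_voxels, d[a]))
  binary_volume(vol$grid[origin[1]:end[1], origin[2]:end[2],
                         origin[3]:end[3], drop = FALSE],
                vol$voxel_size_um, label = vol$label, region = vol$region,
                level = vol$level)
}

#' Degrade voxel size by integer block aggregation
#'
#' Aggregates `factor^3` blocks by their mean occupancy; blocks with mean
#' occupancy >= 0.5 become foreground (ties to foreground), which preserves
#' volume fraction in expectation.  Axes not divisible by `factor` are
#' trimmed at the trailing end (never padded).  The voxel size is multiplied
#' by `factor`.
#'
#' @param vol a [binary_volume()].
#' @param factor integer >= 1; `factor = 1` returns the volume unchanged.
#' @return A [binary_volume()] at the coarser resolution.
#' @export
degrade_voxel_size <- function(vol, factor) {
  stopifnot(inherits(vol, "binary_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(vol)
  d <- dim(vol$grid)
  m <- d %/% factor
  if (any(m < 1L)) stop("`factor` larger than volume extent")
  g <- vol$grid[seq_len(m[1] * factor), seq_len(m[2] * factor),
                seq_len(m[3] * factor), drop = FALSE]
  a <- array(as.numeric(g), c(factor, m[1], factor, m[2], factor, m[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(m))
  means <- colMeans(a)
  binary_volume(array(means >= 0.5, m), vol$voxel_size_um * factor,
                label = vol$label, region = vol$region, level = vol$level)
}
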