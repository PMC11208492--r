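#' Sliding-window background subtraction
#'
#' Estimates a smooth background surface from a local statistic (median by
#' default, minimum optionally) computed in a sliding square window on a
#' stride-quarter-window grid, bilinearly interpolated to full resolution,
#' then subtracts it and clamps at zero. Structures much smaller than the
#' window survive essentially unattenuated; structures larger than the
#' window are removed.
#'
#' @param image numeric matrix, finite values.
#' @param window_diameter window edge length in px (default 50, >= 3).
#' @param estimator `"median"` (default) or `"minimum"`.
#' @return background-subtracted image (same shape, >= 0) with the
#'   estimated surface attached as attribute `"background"`.
#' @export
subtract_background <- function(image, window_diameter = 50,
                                estimator = c("median", "minimum")) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (window_diameter < 3) stop("window_diameter must be >= 3")
  nr <- nrow(image); nc <- ncol(image)
  w <- as.integer(round(window_diameter))
  if (w > nr && w > nc) {
    warning("window larger than both image dimensions; ",
            "falling back to a global scalar background")
    stat <- if (estimator == "median") median(image) else min(image)
    bg <- matrix(stat, nr, nc)
    out <- pmax(image - bg, 0)
    attr(out, "background") <- bg
    return(out)
  }
  half <- w / 2
  stride <- max(1L, w %/% 4L)
  grid_r <- unique(c(seq(1, nr, by = stride), nr))
  grid_c <- unique(c(seq(1, nc, by = stride), nc))
  statfun <- if (estimator == "median") median else min
  nodes <- matrix(0, length(grid_r), length(grid_c))
  for (i in seq_along(grid_r)) {
    r0 <- max(1L, as.integer(ceiling(grid_r[i] - half)))
    r1 <- min(nr, as.integer(floor(grid_r[i] + half)))
    strip <- image[r0:r1, , drop = FALSE]
    for (j in seq_along(grid_c)) {
      c0 <- max(1L, as.integer(ceiling(grid_c[j] - half)))
      c1 <- min(nc, as.integer(floor(grid_c[j] + half)))
      nodes[i, j] <- statfun(strip[, c0:c1])
    }
  }
  # bilinear interpolation of the node grid to full resolution
  along_rows <- apply(nodes, 2, function(v)
    if (length(grid_r) == 1) rep(v, nr)
    else approx(grid_r, v, xout = seq_len(nr), rule = 2)$y)
  along_rows <- matrix(along_rows, nrow = nr)
  bg <- t(apply(along_rows, 1, function(v)
    if (length(grid_c) == 1) rep(v, nc)
    else approx(grid_c, v, xout = seq_len(nc), rule = 2)$y))
  bg <- matrix(bg, nr, nc)
  bg <- pmax(bg, 0)
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Collapse a raw SIM pattern stack to a widefield image
#'
#' Structured-illumination acquisition records 15 differently patterned raw
#' frames per plane; their overlay is an ordinary widefield image usable for
#' intensiometric readouts. The overlay is the pixel-wise mean by default so
#' intensities stay on the single-frame scale; `mode = "sum"` gives the
#' additive variant.
#'
#' @param stack list of same-shape numeric matrices (or a 3D array with
#'   frames along the third dimension).
#' @param mode `"mean"` (default) or `"sum"`.
#' @param expected_count required number of pattern frames (default 15).
#' @param allow_any_count skip the frame-count guard.
#' @return single widefield image matrix.
#' @export
sim_overlay <- function(stack, mode = c("mean", "sum"),
                        expected_count = 15L, allow_any_count = FALSE) {
  mode <- match.arg(mode)
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  stopifnot(is.list(stack), length(stack) >= 1)
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1) stop("pattern frames differ in shape")
  if (!allow_any_count && length(stack) != expected_count)
    stop("expected ", expected_count, " pattern images, got ", length(stack))
  acc <- Reduce(`+`, stack)
  if (mode == "mean") acc / length(stack) else acc
}

#' Ratio image of two channels
#'
#' Element-wise `numerator / max(denominator, floor)`. Pixels where both
#' channels fall below the floor are undefined and set to 0. The default
#' floor is 1% of the denominator's foreground (Otsu-positive) median,
#' which keeps the mitochondrial "halo" region finite.
#'
#' @param numerator,denominator same-shape numeric matrices.
#' @param floor positive clipping value for the denominator; `NULL` for the
#'   default.
#' @return ratio image with attribute `"floor"`.
#' @export
ratio_image <- function(numerator, denominator, floor = NULL) {
  stopifnot(is.matrix(numerator), identical(dim(numerator), dim(denominator)))
  if (is.null(floor)) {
    thr <- tryCatch(otsu_threshold(denominator), error = function(e) NULL)
    fg <- if (is.null(thr)) denominator else denominator[denominator > thr]
    floor <- 0.01 * median(fg)
    if (!is.finite(floor) || floor <= 0) floor <- 0.01 * max(denominator, 1)
  }
  if (floor <= 0) stop("floor must be positive")
  out <- numerator / pmax(denominator, floor)
  out[numerator < floor & denominator < floor] <- 0
  attr(out, "floor") <- floor
  out
}

#' Scale an image so its foreground median hits a target
#'
#' Mirrors matching acquisition intensities between conditions: a single
#' multiplicative factor brings the median of the Otsu-positive foreground
#' to `target_median`.
#'
#' @param image numeric matrix with nonempty Otsu foreground.
#' @param target_median desired foreground median (> 0).
#' @return scaled image with the factor attached as attribute `"factor"`.
#' @export
match_intensity <- function(image, target_median) {
  stopifnot(is.matrix(image), target_median > 0)
  thr <- otsu_threshold(image)
  fg <- image[image > thr]
  if (length(fg) == 0) stop("empty foreground, cannot match intensity")
  f <- target_median / median(fg)
  out <- image * f
  attr(out, "factor") <- f
  out
}

#' Dye concentration from absorbance (Beer-Lambert)
#'
#' Converts an absorbance reading of a TMRM stock at 550 nm to molar
#' concentration, `c = A / (epsilon * l)`, used to track stock degradation.
#'
#' @param A absorbance (dimensionless, >= 0).
#' @param epsilon molar extinction coefficient at 550 nm (M^-1 cm^-1, > 0);
#'   instrument/solvent specific, supplied by the user.
#' @param l optical path length (cm, > 0).
#' @return list with `molar` (M) and `nM` concentrations.
#' @export
tmrm_concentration <- function(A, epsilon, l) {
  if (!is.numeric(epsilon) || any(epsilon <= 0)) stop("epsilon must be > 0")
  if (!is.numeric(l) || any(l <= 0)) stop("path length l must be > 0")
  if (!is.numeric(A) || any(A < 0)) stop("absorbance A must be >= 0")
  c_molar <- A / (epsilon * l)
  list(molar = c_molar, nM = c_molar * 1e9)
}
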