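#' Otsu binarization
#'
#' @param image background-subtracted image with nonzero variance.
#' @param hist_bins Otsu histogram bins (default 256).
#' @return logical foreground mask with the threshold attached as attribute
#'   `"threshold"`.
#' @export
binarize <- function(image, hist_bins = 256L) {
  thr <- otsu_threshold(image, bins = hist_bins)
  out <- image > thr
  attr(out, "threshold") <- thr
  out
}

#' Label particles in a binary mask
#'
#' Connected-component labeling with configurable connectivity; components
#' smaller than `min_area_px` are discarded and the survivors relabeled
#' 1..c.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default; corner-touching pixels connect) or 4.
#' @param min_area_px smallest component kept (default 4).
#' @return integer label matrix with attribute `"count"` = c.
#' @export
label_particles <- function(mask, connectivity = 8L, min_area_px = 4L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) > 0 && min_area_px > 1) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0
    lab[pos] <- remap[lab[pos]]
  }
  attr(lab, "count") <- max(lab)
  lab
}

# Corner-corrected chain-code perimeter (Vossepoel-Smeulders weights) of an
# oriented boundary contour given as pixel-center coordinates. Near-unbiased
# on digitized smooth shapes; underestimates right-angle polygons by up to
# ~8% (documented bias band of the estimator).
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(2 * sqrt(pi))  # single pixel: circle-equivalent perimeter
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  step <- nxt - contour
  is_diag <- step[, 1] != 0 & step[, 2] != 0
  ne <- sum(!is_diag); no <- sum(is_diag)
  dirs <- atan2(step[, 2], step[, 1])
  nc <- sum(dirs != c(dirs[-1], dirs[1]))
  0.980 * ne + 1.406 * no - 0.091 * nc
}

#' Measure labeled particles
#'
#' Per-object particle measurements in the ImageJ particle-analyzer
#' convention: area as pixel count, perimeter from a corner-corrected
#' boundary chain walk, minor/major axes from the second-central-moment
#' ellipse scaled to match the pixel area ("Fit Ellipse"), aspect ratio
#' AR = major/minor and form factor FF = p^2 / (4 pi a). All lengths are
#' reported in pixels and physical units.
#'
#' @param labels integer label matrix from [label_particles()].
#' @param pixel_size nm per pixel (default 32).
#' @return data.frame with one row per object: `object_id`, `area_px`,
#'   `area_um2`, `perimeter_px`, `perimeter_um`, `minor_px`, `major_px`,
#'   `minor_um`, `major_um`, `ar`, `ff`, `centroid_row`, `centroid_col`.
#' @export
measure_particles <- function(labels, pixel_size = 32) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("no labeled particles to measure")
  contours <- EBImage::ocontour(EBImage::Image(labels))
  um <- pixel_size / 1000
  rows <- lapply(ids, function(id) {
    px <- which(labels == id)
    rr <- ((px - 1) %% nrow(labels)) + 1
    cc <- ((px - 1) %/% nrow(labels)) + 1
    a <- length(px)
    p <- chain_perimeter(contours[[id]])
    ell <- moment_ellipse(rr, cc)
    x <- min(ell$minor, ell$major); y <- max(ell$minor, ell$major)
    data.frame(object_id = id,
               area_px = a, area_um2 = a * um^2,
               perimeter_px = p, perimeter_um = p * um,
               minor_px = x, major_px = y,
               minor_um = x * um, major_um = y * um,
               ar = aspect_ratio(x, y), ff = form_factor(p, a),
               centroid_row = ell$centroid["row"],
               centroid_col = ell$centroid["col"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aspect ratio of fitted-ellipse axes
#'
#' `AR = y / x` with the axes ordered so `y >= x`.
#'
#' @param x,y minor and major axis lengths (any common unit, `x > 0`).
#' @return dimensionless aspect ratio, >= 1.
#' @export
aspect_ratio <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) stop("axes must be positive")
  pmax(x, y) / pmin(x, y)
}

#' Form factor
#'
#' `FF = p^2 / (4 pi a)`: 1 for an ideal circle, larger for elongated or
#' irregular outlines.
#'
#' @param p perimeter (> 0).
#' @param a area (> 0, same length unit squared).
#' @return dimensionless form factor.
#' @export
form_factor <- function(p, a) {
  if (any(p <= 0)) stop("perimeter must be positive")
  if (any(a <= 0)) stop("area must be positive")
  p^2 / (4 * pi * a)
}

#' Per-frame morphometric summary
#'
#' Count and unweighted per-object means, the per-frame reduction used for
#' morphology traces.
#'
#' @param records a [measure_particles()] data.frame.
#' @return one-row data.frame: `c` (count), `mean_area_um2`, `mean_ar`,
#'   `mean_ff`.
#' @export
morph_summary <- function(records) {
  data.frame(c = nrow(records),
             mean_area_um2 = mean(records$area_um2),
             mean_ar = mean(records$ar),
             mean_ff = mean(records$ff))
}
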