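#' Reference-channel mitochondrial masks
#'
#' Builds the three masks behind the IBM association index from a
#' background-subtracted reference image: `whole` is the Otsu-positive
#' foreground; `core` (cristae-region proxy) is `whole` after a number of
#' binary erosions; `rim` (inner-boundary-membrane proxy) is `whole` after
#' a number of dilations, minus `core` — a hollow band following each
#' mitochondrion's periphery. The structuring element is the 3x3 square
#' (8-connected), the ImageJ binary erode/dilate default.
#'
#' @param reference background-subtracted reference image with nonempty
#'   Otsu foreground.
#' @param erode_iters erosions forming the core (default 1).
#' @param dilate_iters dilations forming the outer rim boundary (default 2).
#' @param hist_bins Otsu histogram bins (default 256).
#' @return object of class `mito_masks`: logical matrices `whole`, `core`,
#'   `rim`, plus the parameters and the Otsu threshold used.
#' @export
reference_masks <- function(reference, erode_iters = 1L, dilate_iters = 2L,
                            hist_bins = 256L) {
  stopifnot(is.matrix(reference))
  if (erode_iters < 0 || dilate_iters < 0)
    stop("iteration counts must be non-negative")
  thr <- otsu_threshold(reference, bins = hist_bins)
  whole <- reference > thr
  if (!any(whole)) stop("no reference foreground above the Otsu threshold")
  # pad with background so pixels beyond the image count as background in
  # both operations (EBImage's erode would otherwise keep border pixels)
  morph <- function(mask, iters, op) {
    if (iters == 0) return(mask > 0)
    kern <- EBImage::makeBrush(3L, shape = "box")
    p <- as.integer(iters) + 1L
    nr <- nrow(mask); nc <- ncol(mask)
    big <- matrix(0, nr + 2 * p, nc + 2 * p)
    big[p + seq_len(nr), p + seq_len(nc)] <- mask
    for (i in seq_len(iters)) big <- op(big, kern)
    matrix(big > 0, nr + 2 * p, nc + 2 * p)[p + seq_len(nr), p + seq_len(nc)]
  }
  core <- morph(whole * 1, erode_iters, EBImage::erode)
  dil <- morph(whole * 1, dilate_iters, EBImage::dilate)
  if (!any(core)) {
    labs <- label_components(whole, 8L)
    stop("core mask empty after ", erode_iters, " erosion(s); objects ",
         paste(sort(unique(labs[labs > 0])), collapse = ", "),
         " are thinner than the erosion")
  }
  rim <- dil & !core
  structure(list(whole = whole, core = core, rim = rim,
                 erode_iters = as.integer(erode_iters),
                 dilate_iters = as.integer(dilate_iters),
                 structuring_element = "3x3 box",
                 threshold = thr),
            class = "mito_masks")
}

#' @export
print.mito_masks <- function(x, ...) {
  cat(sprintf(paste0("<mito_masks> whole %d px, core %d px, rim %d px ",
                     "(erode %d, dilate %d, otsu %.4g)\n"),
              sum(x$whole), sum(x$core), sum(x$rim),
              x$erode_iters, x$dilate_iters, x$threshold))
  invisible(x)
}

#' IBM association index
#'
#' Ratio of the object channel's mean intensity over the rim mask (IBM
#' proxy) to its mean over the core mask (cristae proxy). Values above the
#' baseline indicate a shift of the potential-sensitive dye towards the
#' inner boundary membrane; the lower the index, the more the dye is
#' concentrated in the cristae region.
#'
#' @param object_image object-channel image, same shape as the masks.
#' @param masks a [reference_masks()] result.
#' @param per_object compute one index per connected component of the
#'   dilated footprint instead of one pooled index (default FALSE, matching
#'   whole-field analysis).
#' @return for the pooled case, a list of class `ibm_index_result` with
#'   `index`, `mean_rim`, `mean_core`, `n_rim_px`, `n_core_px`; for
#'   `per_object = TRUE`, a data.frame with one row per object.
#' @export
ibm_association_index <- function(object_image, masks, per_object = FALSE) {
  stopifnot(inherits(masks, "mito_masks"),
            identical(dim(object_image), dim(masks$whole)))
  one <- function(rim, core) {
    n_core <- sum(core); n_rim <- sum(rim)
    if (n_core == 0) stop("empty core mask: index undefined")
    mean_core <- mean(object_image[core])
    mean_rim <- if (n_rim > 0) mean(object_image[rim]) else NA_real_
    if (!is.finite(mean_core) || mean_core <= 0)
      stop("core mean intensity is zero: index undefined")
    list(index = mean_rim / mean_core, mean_rim = mean_rim,
         mean_core = mean_core, n_rim_px = n_rim, n_core_px = n_core)
  }
  if (!per_object) {
    res <- one(masks$rim, masks$core)
    class(res) <- "ibm_index_result"
    return(res)
  }
  foot <- masks$rim | masks$core
  labs <- label_components(foot, 8L)
  ids <- sort(unique(labs[labs > 0]))
  rows <- lapply(ids, function(id) {
    inobj <- labs == id
    r <- tryCatch(one(masks$rim & inobj, masks$core & inobj),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(object_id = id, index = r$index, mean_rim = r$mean_rim,
               mean_core = r$mean_core, n_rim_px = r$n_rim_px,
               n_core_px = r$n_core_px)
  })
  do.call(rbind, rows)
}

#' @export
print.ibm_index_result <- function(x, ...) {
  cat(sprintf("<ibm_index_result> index = %.4f (rim %.4g / core %.4g; %d/%d px)\n",
              x$index, x$mean_rim, x$mean_core, x$n_rim_px, x$n_core_px))
  invisible(x)
}

#' Width-averaged cross-section profile
#'
#' Samples both channels along the segment between two endpoints at a fixed
#' spacing; at each position the reported intensity is the mean of bilinear
#' samples taken along the perpendicular over +/- width/2 (1 px steps).
#' Both channels are sampled at identical coordinates, so reference and
#' object widths are directly comparable.
#'
#' @param frame a [two_channel_frame], or a single matrix (reference only).
#' @param endpoints 2x2 numeric matrix, rows = the two endpoints as
#'   (row, col) pixel coordinates.
#' @param width averaging width in px (default 50, i.e. 1.6 um at
#'   32 nm/px).
#' @param spacing sample spacing along the section, px (default 0.5).
#' @return object of class `line_profile`: `positions_px`, `positions_nm`,
#'   `values_ref`, `values_obj` (NULL for single-channel input), `width`,
#'   `endpoints`, `pixel_size`.
#' @export
cross_profile <- function(frame, endpoints, width = 50, spacing = 0.5) {
  if (is.matrix(frame) && is.numeric(frame))
    frame <- list(reference = frame, object = NULL, pixel_size = NA_real_)
  endpoints <- as.matrix(endpoints)
  stopifnot(identical(dim(endpoints), c(2L, 2L)))
  if (width < 1) stop("width must be >= 1 px")
  img <- frame$reference
  if (any(endpoints[, 1] < 1 | endpoints[, 1] > nrow(img) |
          endpoints[, 2] < 1 | endpoints[, 2] > ncol(img)))
    stop("profile endpoints outside the image")
  d <- endpoints[2, ] - endpoints[1, ]
  len <- sqrt(sum(d^2))
  if (len < 4) stop("profile segment shorter than 4 px")
  u <- d / len                       # along-section unit vector (row, col)
  v <- c(-u[2], u[1])                # perpendicular unit vector
  s <- seq(0, len, by = spacing)
  offs <- seq(-width / 2, width / 2, by = 1)
  # sample grid: positions along section x offsets across it
  rows <- outer(endpoints[1, 1] + s * u[1], offs * v[1], `+`)
  cols <- outer(endpoints[1, 2] + s * u[2], offs * v[2], `+`)
  avg <- function(im) {
    vals <- matrix(bilinear_sample(im, as.vector(rows), as.vector(cols)),
                   nrow = length(s))
    rowMeans(vals)
  }
  px <- frame$pixel_size %||% NA_real_
  structure(list(positions_px = s,
                 positions_nm = s * px,
                 values_ref = avg(img),
                 values_obj = if (!is.null(frame$object)) avg(frame$object),
                 width = width, endpoints = endpoints, pixel_size = px),
            class = "line_profile")
}

#' Subpixel full width at half maximum
#'
#' Half-max is `baseline + (max - baseline)/2`; the two crossings are
#' located by linear interpolation between the bracketing samples on each
#' side of the (unique) peak, giving subpixel resolution. The default
#' baseline of 0 assumes background-subtracted input; pass
#' `baseline = "min"` to use the profile minimum instead.
#'
#' @param positions strictly increasing sample positions (px).
#' @param values profile intensities, finite, with a unique interior
#'   maximum.
#' @param baseline numeric baseline or `"min"`.
#' @return list of class `fwhm_estimate`: `fwhm` (px), `crossings`
#'   (left, right positions), `half_max`.
#' @export
fwhm_subpixel <- function(positions, values, baseline = 0) {
  stopifnot(length(positions) == length(values), length(values) >= 3,
            all(is.finite(positions)), all(is.finite(values)))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (identical(baseline, "min")) baseline <- min(values)
  vmax <- max(values)
  peaks <- which(values == vmax)
  if (any(peaks %in% c(1L, length(values))))
    stop("profile not resolved: maximum at profile end")
  if (length(peaks) > 1 && any(diff(peaks) > 1))
    stop("degenerate profile: multiple separated maxima")
  ipk_l <- peaks[1]; ipk_r <- peaks[length(peaks)]
  half <- baseline + (vmax - baseline) / 2
  cross_one <- function(idx_range, rising) {
    vv <- values[idx_range]; pp <- positions[idx_range]
    if (rising) {
      below <- which(vv < half)
      if (length(below) == 0) {
        at <- which(vv == half)
        if (length(at) > 0) {  # plateau exactly at half-max
          warning("plateau at half-max; using plateau midpoint")
          return(mean(pp[at]))
        }
        stop("profile not resolved: half-max not reached on the left")
      }
      i <- max(below)
      if (i == length(vv)) stop("profile not resolved on the left")
      x0 <- pp[i]; x1 <- pp[i + 1]; y0 <- vv[i]; y1 <- vv[i + 1]
    } else {
      below <- which(vv < half)
      if (length(below) == 0) {
        at <- which(vv == half)
        if (length(at) > 0) {
          warning("plateau at half-max; using plateau midpoint")
          return(mean(pp[at]))
        }
        stop("profile not resolved: half-max not reached on the right")
      }
      i <- min(below)
      if (i == 1) stop("profile not resolved on the right")
      x0 <- pp[i - 1]; x1 <- pp[i]; y0 <- vv[i - 1]; y1 <- vv[i]
    }
    if (y1 == y0) return((x0 + x1) / 2)
    x0 + (half - y0) * (x1 - x0) / (y1 - y0)
  }
  left <- cross_one(seq_len(ipk_l), rising = TRUE)
  right <- cross_one(ipk_r:length(values), rising = FALSE)
  structure(list(fwhm = right - left, crossings = c(left = left, right = right),
                 half_max = half),
            class = "fwhm_estimate")
}

#' @export
print.fwhm_estimate <- function(x, ...) {
  cat(sprintf("<fwhm_estimate> FWHM = %.4f px (crossings %.4f .. %.4f)\n",
              x$fwhm, x$crossings[1], x$crossings[2]))
  invisible(x)
}

#' Delta-FWHM of a two-channel cross-section
#'
#' Measures the subpixel FWHM of the reference and object channels of one
#' profile and reports their difference. With the default sign convention
#' `delta = FWHM_obj - FWHM_ref` (TMRM minus MTG): a negative delta means
#' the potential-sensitive dye runs narrower than the reference, i.e. is
#' concentrated in the cristae; delta rises as dye shifts to the inner
#' boundary membrane.
#'
#' @param profile a two-channel [cross_profile()] result.
#' @param sign `"tmrm_minus_mtg"` (default) or `"mtg_minus_tmrm"`.
#' @param baseline passed to [fwhm_subpixel()].
#' @return object of class `fwhm_result`: `fwhm_ref`, `fwhm_obj`, `delta`
#'   (px), the nm equivalents when the pixel size is known, and the four
#'   half-max crossings.
#' @export
delta_fwhm <- function(profile, sign = c("tmrm_minus_mtg", "mtg_minus_tmrm"),
                       baseline = 0) {
  sign <- match.arg(sign)
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(profile$values_obj))
    stop("profile has no object channel")
  fr <- tryCatch(fwhm_subpixel(profile$positions_px, profile$values_ref,
                               baseline = baseline),
                 error = function(e) stop("reference channel: ",
                                          conditionMessage(e), call. = FALSE))
  fo <- tryCatch(fwhm_subpixel(profile$positions_px, profile$values_obj,
                               baseline = baseline),
                 error = function(e) stop("object channel: ",
                                          conditionMessage(e), call. = FALSE))
  delta <- if (sign == "tmrm_minus_mtg") fo$fwhm - fr$fwhm else fo$fwhm * -1 + fr$fwhm
  px <- profile$pixel_size
  structure(list(fwhm_ref = fr$fwhm, fwhm_obj = fo$fwhm, delta = delta,
                 fwhm_ref_nm = fr$fwhm * px, fwhm_obj_nm = fo$fwhm * px,
                 delta_nm = delta * px, sign = sign,
                 crossings = list(reference = fr$crossings,
                                  object = fo$crossings)),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> ref %.4f px, obj %.4f px, delta = %+.4f px (%s)\n",
              x$fwhm_ref, x$fwhm_obj, x$delta, x$sign))
  invisible(x)
}

#' Automatic cross-section placement
#'
#' Places one cross-section per sufficiently large object: through the
#' object's intensity-weighted centroid, perpendicular to its moment-ellipse
#' major axis, extending a little beyond the dilated footprint on both
#' sides. Complements manually chosen endpoints with a reproducible default.
#'
#' @param frame a [two_channel_frame].
#' @param masks a [reference_masks()] result for the frame.
#' @param min_area_px smallest object profiled (default 30 px).
#' @param margin_px extension beyond the object half-thickness on each side
#'   (default 4 px).
#' @return list of 2x2 endpoint matrices (row, col), one per object.
#' @export
auto_profiles <- function(frame, masks, min_area_px = 30, margin_px = 4) {
  stopifnot(inherits(masks, "mito_masks"))
  labs <- label_components(masks$whole, 8L)
  ids <- sort(unique(labs[labs > 0]))
  img <- frame$reference
  out <- list()
  for (id in ids) {
    px <- which(labs == id)
    if (length(px) < min_area_px) next
    rr <- ((px - 1) %% nrow(labs)) + 1
    cc <- ((px - 1) %/% nrow(labs)) + 1
    wts <- img[px]
    ctr_r <- sum(rr * wts) / sum(wts)
    ctr_c <- sum(cc * wts) / sum(wts)
    ell <- moment_ellipse(rr, cc)
    # theta is the major-axis angle in (col, row) space; the section runs
    # perpendicular to it
    perp <- c(cos(ell$theta), -sin(ell$theta))  # (row, col) step
    half <- ell$minor / 2 + margin_px
    e1 <- c(ctr_r, ctr_c) - half * perp
    e2 <- c(ctr_r, ctr_c) + half * perp
    clamp <- function(p) c(min(max(p[1], 1), nrow(img)),
                           min(max(p[2], 1), ncol(img)))
    out[[length(out) + 1]] <- rbind(clamp(e1), clamp(e2))
  }
  out
}
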