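`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinear interpolation of image intensities
#'
#' Samples an image at arbitrary (row, col) positions using bilinear
#' interpolation. Pixel centers sit at integer coordinates (row-major,
#' origin top-left); positions outside the grid are clamped to the border.
#'
#' @param image numeric matrix.
#' @param rows,cols numeric vectors of equal length, sample positions.
#' @return numeric vector of sampled intensities.
#' @export
bilinear_sample <- function(image, rows, cols) {
  stopifnot(is.matrix(image), length(rows) == length(cols))
  nr <- nrow(image); nc <- ncol(image)
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- image[cbind(r0, c0)]
  i10 <- image[cbind(r0 + 1, c0)]
  i01 <- image[cbind(r0, c0 + 1)]
  i11 <- image[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

#' Otsu threshold on a binned histogram
#'
#' Computes the Otsu threshold of an image on a fixed-bin histogram spanning
#' the image's intensity range (the ImageJ convention).
#'
#' @param image numeric matrix with nonzero variance.
#' @param bins number of histogram bins (default 256).
#' @return threshold value on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, bins = 256L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (diff(rng) <= 0)
    stop("otsu_threshold: constant image, no threshold exists")
  EBImage::otsu(EBImage::Image(image), range = rng, levels = bins)
}

# Connected-component labeling with selectable connectivity. EBImage's
# bwlabel is 4-connected; 8-connectivity needs diagonal adjacency, built
# here as a pixel-adjacency graph.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  m <- mask != 0
  idx <- which(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(m)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(m)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- m[j]
    from <- c(from, idx[ok][hit]); to <- c(to, j[hit])
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(from, idx), match(to, idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel 1..k in first-pixel order for determinism
  first <- tapply(seq_along(idx), comp, min)
  ord <- rank(first)
  lab[idx] <- as.integer(ord[as.character(comp)])
  lab
}

# Moment-ellipse axes of a pixel set, ImageJ "Fit Ellipse" convention:
# axes from the second central moments of a uniform ellipse, then scaled so
# the ellipse area equals the pixel area. A 1/12 per-pixel variance term
# keeps single-pixel-wide objects non-degenerate.
moment_ellipse <- function(rr, cc) {
  n <- length(rr)
  mr <- mean(rr); mc <- mean(cc)
  mu20 <- sum((cc - mc)^2) / n + 1 / 12
  mu02 <- sum((rr - mr)^2) / n + 1 / 12
  mu11 <- sum((cc - mc) * (rr - mr)) / n
  tr <- mu20 + mu02
  det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
  a0 <- 2 * sqrt(pmax(l1, 1e-12)); b0 <- 2 * sqrt(pmax(l2, 1e-12))
  s <- sqrt(n / (pi * a0 * b0))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(major = 2 * a0 * s, minor = 2 * b0 * s,
       theta = theta, centroid = c(row = mr, col = mc))
}
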