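#' Per-frame metric traces from a time lapse
#'
#' Runs the full pipeline on every frame: background subtraction (unless
#' disabled in the config), reference masks, IBM association index,
#' automated delta-FWHM, particle morphometrics and channel totals. A
#' metric that fails on a single frame is recorded as `NA` with a reason in
#' the `notes` attribute; the other frames are unaffected. If every frame
#' fails a metric, that is an error naming the metric.
#'
#' @param timelapse a [time_lapse].
#' @param config parameter list from [mg_defaults()] / [load_config()].
#' @param atp optional ATP-proxy trace: data.frame with columns
#'   `t_seconds`, `value` (possibly on a different clock), linearly
#'   interpolated onto the imaging timebase; or a numeric vector with one
#'   value per frame.
#' @return data.frame with one row per frame: `t`, `ibm_index`,
#'   `delta_fwhm_px`, `total_ref`, `total_obj`, `c`, `mean_area_um2`,
#'   `mean_ar`, `mean_ff`, and `atp_proxy` when supplied; attribute
#'   `notes` lists per-frame failures.
#' @export
compute_traces <- function(timelapse, config = mg_defaults(), atp = NULL) {
  stopifnot(inherits(timelapse, "time_lapse"))
  n <- length(timelapse$frames)
  notes <- character(0)
  locked_masks <- NULL
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    fr <- timelapse$frames[[k]]
    ref <- fr$reference; obj <- fr$object
    if (isTRUE(config$background_subtract)) {
      ref <- subtract_background(ref, config$window_diameter,
                                 config$background_estimator)
      obj <- subtract_background(obj, config$window_diameter,
                                 config$background_estimator)
    }
    prep <- two_channel_frame(ref, obj, pixel_size = fr$pixel_size,
                              time = fr$time)
    masks <- tryCatch({
      if (isTRUE(config$lock_masks) && !is.null(locked_masks)) locked_masks
      else reference_masks(ref, config$erode_iters, config$dilate_iters,
                           config$hist_bins)
    }, error = function(e) {
      notes <<- c(notes, sprintf("frame %d masks: %s", k,
                                 conditionMessage(e)))
      NULL
    })
    if (isTRUE(config$lock_masks) && is.null(locked_masks))
      locked_masks <- masks
    idx <- NA_real_
    if (!is.null(masks)) {
      idx <- tryCatch(ibm_association_index(obj, masks)$index,
                      error = function(e) {
                        notes <<- c(notes, sprintf("frame %d ibm_index: %s",
                                                   k, conditionMessage(e)))
                        NA_real_
                      })
    }
    dfw <- NA_real_
    if (!is.null(masks)) {
      dfw <- tryCatch({
        eps <- auto_profiles(prep, masks)
        if (length(eps) == 0) stop("no object large enough to profile")
        deltas <- vapply(eps, function(e) {
          tryCatch(delta_fwhm(cross_profile(prep, e,
                                            width = config$profile_width,
                                            spacing = config$profile_spacing),
                              sign = config$delta_sign)$delta,
                   error = function(err) NA_real_)
        }, numeric(1))
        if (all(is.na(deltas))) stop("no resolvable profile in frame")
        mean(deltas, na.rm = TRUE)
      }, error = function(e) {
        notes <<- c(notes, sprintf("frame %d delta_fwhm: %s", k,
                                   conditionMessage(e)))
        NA_real_
      })
    }
    morph <- tryCatch({
      labs <- label_particles(binarize(ref, config$hist_bins),
                              config$connectivity, config$min_area_px)
      morph_summary(measure_particles(labs, fr$pixel_size))
    }, error = function(e) {
      notes <<- c(notes, sprintf("frame %d morphometrics: %s", k,
                                 conditionMessage(e)))
      data.frame(c = NA_integer_, mean_area_um2 = NA_real_,
                 mean_ar = NA_real_, mean_ff = NA_real_)
    })
    rows[[k]] <- cbind(data.frame(t = fr$time, ibm_index = idx,
                                  delta_fwhm_px = dfw,
                                  total_ref = sum(ref),
                                  total_obj = sum(obj)),
                       morph)
  }
  out <- do.call(rbind, rows)
  for (metric in c("ibm_index", "delta_fwhm_px", "c"))
    if (all(is.na(out[[metric]])))
      stop("metric '", metric, "' failed on every frame")
  if (!is.null(atp)) {
    out$atp_proxy <- if (is.data.frame(atp)) {
      approx(atp$t_seconds, atp$value, xout = out$t, rule = 2)$y
    } else {
      if (length(atp) != n) stop("atp vector length does not match frames")
      as.numeric(atp)
    }
  }
  attr(out, "notes") <- notes
  attr(out, "stimulus_time") <- timelapse$stimulus_time
  out
}

#' Baseline-normalize a trace
#'
#' Subtracts (additive mode) or divides by (fractional mode) the mean over
#' a pre-stimulus baseline window.
#'
#' @param values numeric trace.
#' @param baseline indices (or logical mask) of baseline frames; at least
#'   2 frames.
#' @param mode `"additive"` (default): `x - mean(baseline)`;
#'   `"fractional"`: `(x - mean) / mean`.
#' @return normalized trace with attributes `baseline_mean` and
#'   `baseline_sd`.
#' @export
normalize_delta <- function(values, baseline, mode = c("additive", "fractional")) {
  mode <- match.arg(mode)
  base <- values[baseline]
  if (length(base) < 2) stop("baseline window must contain at least 2 frames")
  m <- mean(base, na.rm = TRUE)
  out <- if (mode == "additive") values - m else (values - m) / m
  attr(out, "baseline_mean") <- m
  attr(out, "baseline_sd") <- stats::sd(base, na.rm = TRUE)
  out
}

#' Ordinary least-squares fit of one trace against another
#'
#' Simple linear regression `y ~ x` with `r_squared = 1 - SS_res/SS_tot`
#' and a two-sided p-value for zero slope from the classical t statistic
#' on n - 2 degrees of freedom. Optionally a percentile bootstrap CI for
#' the slope (resampling pairs).
#'
#' @param x,y paired numeric traces; pairs with missing values are dropped,
#'   at least 3 must remain.
#' @param n_boot bootstrap replicates for the slope CI (0 = none).
#' @param conf CI level (default 0.95).
#' @return object of class `correlation_result`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n`, and `slope_ci` when bootstrapped.
#' @export
linear_fit <- function(x, y, n_boot = 0L, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite points")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  if (stats::var(y) == 0) stop("zero variance in y: r_squared undefined")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(sse / (n - 2) / sum((x - mean(x))^2))
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  res <- list(slope = slope,
              intercept = unname(coef(fit)[1]),
              r_squared = 1 - sse / sst,
              p_slope = 2 * pt(-abs(tval), df = n - 2),
              n = n)
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0) return(NA_real_)
      xc <- x[i] - mean(x[i])
      sum(xc * y[i]) / sum(xc^2)
    }, numeric(1))
    a <- (1 - conf) / 2
    res$slope_ci <- unname(quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  structure(res, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_slope, x$n))
  if (!is.null(x$slope_ci))
    cat(sprintf("  slope CI [%.4g, %.4g]\n", x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Detect fission events between consecutive frames
#'
#' A fission event is a labeled object in frame k whose footprint overlaps
#' at least two labels in frame k+1, each overlap covering at least
#' `overlap_frac` of the child's area. For each event the fractional
#' object-channel intensity change in a small window at the split site
#' over the preceding `lookback` frames is recorded (the local dye-loss
#' signature preceding a split).
#'
#' @param labels_list list of integer label matrices, one per frame.
#' @param object_images list of object-channel images, same length.
#' @param overlap_frac minimum child overlap fraction (default 0.25).
#' @param window split-site window edge, px (default 5).
#' @param lookback frames before the split for the dimming baseline
#'   (default 2).
#' @return data.frame of events: `frame` (the post-split frame), `parent`,
#'   `children` (comma-joined labels), `row`, `col` (split site),
#'   `local_drop` (fractional, NA when no lookback frame exists).
#' @export
detect_fission <- function(labels_list, object_images,
                           overlap_frac = 0.25, window = 5L, lookback = 2L) {
  stopifnot(length(labels_list) == length(object_images),
            length(labels_list) >= 2)
  events <- list()
  half <- window %/% 2
  for (k in seq_len(length(labels_list) - 1)) {
    lab0 <- labels_list[[k]]; lab1 <- labels_list[[k + 1]]
    for (p in sort(unique(lab0[lab0 > 0]))) {
      foot <- lab0 == p
      kids <- integer(0)
      for (ch in sort(unique(lab1[lab1 > 0]))) {
        child <- lab1 == ch
        if (sum(child & foot) >= overlap_frac * sum(child))
          kids <- c(kids, ch)
      }
      if (length(kids) < 2) next
      # split site: between the facing ends of the closest child pair --
      # for each child, the pixel nearest the sibling's centroid marks its
      # end at the gap; the site is the midpoint of those two end pixels
      coords <- lapply(kids, function(ch) {
        px <- which(lab1 == ch)
        cbind(((px - 1) %% nrow(lab1)) + 1, ((px - 1) %/% nrow(lab1)) + 1)
      })
      ctr <- t(vapply(coords, colMeans, numeric(2)))
      best <- c(1, 2); bd <- Inf
      for (i in seq_len(nrow(ctr) - 1)) for (j in (i + 1):nrow(ctr)) {
        d <- sum((ctr[i, ] - ctr[j, ])^2)
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
      end_px <- function(a, b) {  # pixel of child a closest to centroid of b
        xy <- coords[[a]]
        xy[which.min((xy[, 1] - ctr[b, 1])^2 + (xy[, 2] - ctr[b, 2])^2), ]
      }
      site <- round((end_px(best[1], best[2]) + end_px(best[2], best[1])) / 2)
      drop <- NA_real_
      kb <- k - lookback
      if (kb >= 1) {
        win <- function(img) {
          r <- pmin(pmax((site[1] - half):(site[1] + half), 1), nrow(img))
          c <- pmin(pmax((site[2] - half):(site[2] + half), 1), ncol(img))
          mean(img[r, c])
        }
        before <- win(object_images[[kb]])
        at <- win(object_images[[k]])
        if (is.finite(before) && before > 0) drop <- 1 - at / before
      }
      events[[length(events) + 1]] <-
        data.frame(frame = k + 1L, parent = p,
                   children = paste(kids, collapse = ","),
                   row = site[1], col = site[2], local_drop = drop)
    }
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(frame = integer(0), parent = integer(0),
                  children = character(0), row = numeric(0),
                  col = numeric(0), local_drop = numeric(0))
}
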