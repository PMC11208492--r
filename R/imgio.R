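#' Two-channel frame
#'
#' Bundles a registered reference-channel image (geometry marker, e.g. MTG)
#' and an object-channel image (potential-sensitive dye, e.g. TMRM) with the
#' pixel size and acquisition time. Pixel centers sit at integer (row, col)
#' coordinates, origin top-left; all lengths can be reported both in pixels
#' and in physical units through `pixel_size`.
#'
#' @param reference,object numeric matrices of identical shape, finite and
#'   non-negative.
#' @param pixel_size pixel edge length in nm (default 32, i.e. 1.6 um per
#'   50 px).
#' @param time acquisition time in seconds.
#' @param labels channel names, reference first.
#' @return an object of class `two_channel_frame`.
#' @export
two_channel_frame <- function(reference, object, pixel_size = 32,
                              time = 0, labels = c("MTG", "TMRM")) {
  stopifnot(is.matrix(reference), is.matrix(object))
  if (!identical(dim(reference), dim(object)))
    stop("reference and object channels differ in shape")
  if (!all(is.finite(reference)) || !all(is.finite(object)))
    stop("non-finite intensities in input images")
  if (min(reference) < 0 || min(object) < 0)
    stop("negative intensities in input images")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (nm)")
  structure(list(reference = reference, object = object,
                 pixel_size = pixel_size, time = time,
                 labels = labels),
            class = "two_channel_frame")
}

#' @export
print.two_channel_frame <- function(x, ...) {
  cat(sprintf("<two_channel_frame> %d x %d px (%.0f nm/px), t = %g s, channels: %s\n",
              nrow(x$reference), ncol(x$reference), x$pixel_size, x$time,
              paste(x$labels, collapse = " / ")))
  invisible(x)
}

#' Time lapse of two-channel frames
#'
#' @param frames list of [two_channel_frame] objects with strictly
#'   increasing times and a constant pixel size.
#' @param stimulus_time stimulus time in seconds, or `NULL`.
#' @return an object of class `time_lapse`.
#' @export
time_lapse <- function(frames, stimulus_time = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  ok <- vapply(frames, inherits, logical(1), "two_channel_frame")
  if (!all(ok)) stop("all frames must be two_channel_frame objects")
  tt <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(tt) <= 0)) stop("frame times must be strictly increasing")
  px <- vapply(frames, `[[`, numeric(1), "pixel_size")
  if (length(unique(px)) != 1) stop("pixel_size must be constant across frames")
  structure(list(frames = frames, stimulus_time = stimulus_time),
            class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  tt <- vapply(x$frames, `[[`, numeric(1), "time")
  cat(sprintf("<time_lapse> %d frames, t = %g..%g s%s\n", length(x$frames),
              min(tt), max(tt),
              if (is.null(x$stimulus_time)) "" else
                sprintf(", stimulus at %g s", x$stimulus_time)))
  invisible(x)
}

#' @export
length.time_lapse <- function(x) length(x$frames)

#' Load a two-channel stack from TIFF
#'
#' Reads either a single multi-page TIFF with interleaved channels
#' (reference page, object page, reference page, ...) or a pair of
#' single-channel multi-page TIFFs. Integer pixel data are promoted to
#' double without rescaling (a 16-bit value of 65535 loads as 65535.0).
#'
#' @param path one path (interleaved) or two paths (reference, object).
#' @param channel_order for interleaved stacks, which channel comes first:
#'   `c("reference", "object")` (default) or reversed.
#' @param pixel_size nm per pixel; TIFF carries no calibrated pixel size
#'   here, so it must be supplied (default 32).
#' @param times frame times in seconds; defaults to
#'   `(0:(n-1)) * frame_interval`.
#' @param frame_interval seconds between frames when `times` is absent.
#' @param stimulus_time optional stimulus time (s).
#' @return a [time_lapse].
#' @export
load_stack <- function(path, channel_order = c("reference", "object"),
                       pixel_size = 32, times = NULL, frame_interval = 1,
                       stimulus_time = NULL) {
  channel_order <- match.arg(channel_order[1], c("reference", "object"))
  read_pages <- function(p) {
    if (!file.exists(p)) stop("input file not found: ", p)
    probe <- tiff::readTIFF(p, all = TRUE, info = TRUE)
    bps <- vapply(probe, function(m)
      attr(m, "bits.per.sample") %||% 16L, integer(1))
    if (all(bps <= 16)) {
      # integer data: read raw counts, promote to double unscaled
      pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
      lapply(pg, function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "double"
        m
      })
    } else {
      # 32-bit float pages: stored on the [0, 1] = [0, 65535] convention
      # used by write_stack (the TIFF writer cannot keep values above 1)
      lapply(probe, function(m) {
        m <- as.matrix(m) * 65535
        attributes(m) <- list(dim = dim(m))
        m
      })
    }
  }
  if (length(path) == 1) {
    pages <- read_pages(path)
    if (length(pages) %% 2 != 0)
      stop("channel pairing impossible: odd page count (", length(pages),
           ") in interleaved stack ", path)
    first <- pages[seq(1, length(pages), by = 2)]
    second <- pages[seq(2, length(pages), by = 2)]
    if (channel_order == "reference") {
      refs <- first; objs <- second
    } else {
      refs <- second; objs <- first
    }
  } else if (length(path) == 2) {
    refs <- read_pages(path[1])
    objs <- read_pages(path[2])
    if (length(refs) != length(objs))
      stop("channel pairing impossible: page counts differ between files")
  } else stop("path must name one interleaved or two single-channel TIFFs")
  n <- length(refs)
  if (is.null(times)) times <- (seq_len(n) - 1) * frame_interval
  if (length(times) != n) stop("times length does not match frame count")
  frames <- lapply(seq_len(n), function(i)
    two_channel_frame(refs[[i]], objs[[i]], pixel_size = pixel_size,
                      time = times[i]))
  time_lapse(frames, stimulus_time = stimulus_time)
}

#' Write a time lapse to an interleaved multi-page TIFF
#'
#' Integer-valued data are written as 16-bit (lossless for values in
#' 0..65535); fractional data are written as 32-bit float pages holding
#' `value / 65535`, which [load_stack] undoes. Values above 65535 are an
#' error (rescale first).
#'
#' @param timelapse a [time_lapse].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(timelapse, path) {
  stopifnot(inherits(timelapse, "time_lapse"))
  pages <- list()
  for (fr in timelapse$frames)
    pages <- c(pages, list(fr$reference, fr$object))
  vals <- unlist(lapply(pages, range))
  if (max(vals) > 65535)
    stop("intensities above 65535 cannot be stored; rescale first")
  integral <- all(vapply(pages, function(m) all(m == round(m)), logical(1)))
  if (integral) {
    tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                    bits.per.sample = 16)
  } else {
    # fractional data: 32-bit float pages on the [0, 65535] convention
    tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                    bits.per.sample = 32)
  }
  invisible(path)
}

#' Write a results table as CSV with a unit header
#'
#' The first line is a comment of the form `# units: col=unit,...`; the
#' rest is a standard CSV readable by [read_traces]. Numeric values
#' round-trip at full double precision.
#'
#' @param table data.frame, non-empty.
#' @param path output file.
#' @param units named character vector mapping column names to unit strings;
#'   unnamed columns default to `"dimensionless"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(table, path, units = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("refusing to write an empty table")
  u <- setNames(rep("dimensionless", ncol(table)), names(table))
  if (!is.null(units)) u[names(units)] <- units
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(names(u), u, sep = "=", collapse = ",")), con)
  utils::write.csv(format(table, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a traces CSV written by [write_traces]
#'
#' @param path CSV file with a `# units:` header line.
#' @return data.frame with a `units` attribute.
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  units <- NULL
  if (startsWith(first, "# units:")) {
    spec <- strsplit(sub("^# units: *", "", first), ",")[[1]]
    kv <- strsplit(spec, "=")
    units <- setNames(vapply(kv, `[`, character(1), 2),
                      vapply(kv, `[`, character(1), 1))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  attr(df, "units") <- units
  df
}
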