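#' Default analysis parameters
#'
#' Central defaults used across the pipeline. Lengths are in pixels unless
#' suffixed `_nm`; the default pixel size of 32 nm makes 50 px equal 1.6 um.
#'
#' @return named list of parameters:
#' \describe{
#'   \item{window_diameter}{background-subtraction sliding-window diameter,
#'     px (50).}
#'   \item{background_estimator}{`"median"` or `"minimum"` local statistic.}
#'   \item{background_subtract}{run background subtraction before metrics
#'     (TRUE).}
#'   \item{erode_iters, dilate_iters}{binary erosions (1) / dilations (2)
#'     building the core and rim masks.}
#'   \item{profile_width}{cross-section averaging width, px (50).}
#'   \item{profile_spacing}{sample spacing along the section, px (0.5).}
#'   \item{pixel_size}{nm per pixel (32).}
#'   \item{overlay_count}{raw pattern frames per widefield overlay (15).}
#'   \item{overlay_mode}{`"mean"` or `"sum"`.}
#'   \item{connectivity}{particle connectivity, 4 or 8 (8).}
#'   \item{min_area_px}{smallest particle kept, px (4).}
#'   \item{hist_bins}{Otsu histogram bins (256).}
#'   \item{delta_sign}{`"tmrm_minus_mtg"` (default) or `"mtg_minus_tmrm"`.}
#'   \item{lock_masks}{reuse first-frame masks across a time lapse (FALSE).}
#' }
#' @export
mg_defaults <- function() {
  list(
    window_diameter = 50L,
    background_estimator = "median",
    background_subtract = TRUE,
    erode_iters = 1L,
    dilate_iters = 2L,
    profile_width = 50L,
    profile_spacing = 0.5,
    pixel_size = 32,
    overlay_count = 15L,
    overlay_mode = "mean",
    connectivity = 8L,
    min_area_px = 4L,
    hist_bins = 256L,
    delta_sign = "tmrm_minus_mtg",
    lock_masks = FALSE
  )
}

validate_config <- function(cfg) {
  pos <- c("window_diameter", "profile_width", "profile_spacing",
           "pixel_size", "overlay_count", "hist_bins")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config: ", k, " must be a positive number")
  nonneg <- c("erode_iters", "dilate_iters", "min_area_px")
  for (k in nonneg)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] != round(cfg[[k]]))
      stop("config: ", k, " must be a non-negative integer")
  if (cfg$window_diameter < 3) stop("config: window_diameter must be >= 3")
  if (!cfg$connectivity %in% c(4, 8)) stop("config: connectivity must be 4 or 8")
  if (!cfg$background_estimator %in% c("median", "minimum"))
    stop("config: background_estimator must be 'median' or 'minimum'")
  if (!cfg$overlay_mode %in% c("mean", "sum"))
    stop("config: overlay_mode must be 'mean' or 'sum'")
  if (!cfg$delta_sign %in% c("tmrm_minus_mtg", "mtg_minus_tmrm"))
    stop("config: delta_sign must be 'tmrm_minus_mtg' or 'mtg_minus_tmrm'")
  cfg
}

#' Load analysis parameters from a YAML config file
#'
#' Missing keys fall back to [mg_defaults()]; in strict mode (default)
#' unknown keys are rejected rather than silently ignored. Nested sections
#' are flattened with `.`-joined names and matched against the flat default
#' names, so `masks: {erode_iters: 2}` and `erode_iters: 2` are equivalent.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param strict reject unknown keys (default TRUE).
#' @return validated parameter list.
#' @export
load_config <- function(path = NULL, strict = TRUE) {
  cfg <- mg_defaults()
  if (is.null(path)) return(validate_config(cfg))
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(validate_config(cfg))
  flat <- list()
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(x[[nm]])) flatten(x[[nm]], key)
      else flat[[key]] <<- x[[nm]]
    }
  }
  flatten(raw)
  for (key in names(flat)) {
    leaf <- sub(".*\\.", "", key)
    if (leaf %in% names(cfg)) {
      cfg[[leaf]] <- flat[[key]]
    } else if (strict) {
      stop("config: unknown key '", key, "'")
    }
  }
  validate_config(cfg)
}
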