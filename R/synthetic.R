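#' Partition dye between cristae and inner boundary membrane
#'
#' Minimal two-compartment model of a cationic potential probe: Nernstian
#' weights `w_i = exp(-z F psi_i / (R T))` (z = +1, psi in mV, negative
#' inside) allocate the total load between the cristae membrane (CM) and
#' the inner boundary membrane (IBM) in proportion to `w_i * area_i`; the
#' CM allocation is then passed through a saturable Langmuir cap of
#' capacity `k_sat` and the overflow is reassigned to the IBM. At low load
#' the dye prefers the more negative cristae; as the cristae saturate the
#' rim fraction grows.
#'
#' @param dye_total total dye load (a.u., > 0).
#' @param psi_c,psi_ibm membrane potentials in mV (<= 0); the CM is
#'   typically more negative.
#' @param k_sat CM binding capacity in the same a.u. as `dye_total` (> 0).
#' @param temperature absolute temperature, K (default 310).
#' @param area_cm,area_ibm relative membrane areas of the two compartments
#'   (defaults 2 and 1: cristae fold more membrane than the boundary).
#' @return list: `cm_amount`, `ibm_amount` (a.u.), `cm_density`,
#'   `ibm_density` (a.u. per unit membrane area), and the rim fraction
#'   `f = ibm / (cm + ibm)`.
#' @export
partition_dye <- function(dye_total, psi_c, psi_ibm, k_sat,
                          temperature = 310, area_cm = 2, area_ibm = 1) {
  if (dye_total <= 0) stop("dye_total must be positive")
  if (k_sat <= 0) stop("k_sat must be positive")
  if (psi_c > 0 || psi_ibm > 0) stop("membrane potentials must be <= 0 mV")
  if (area_cm <= 0 || area_ibm <= 0) stop("membrane areas must be positive")
  rt_f <- 1000 * 8.31446 * temperature / 96485.33  # thermal voltage, mV
  w_c <- exp(-psi_c / rt_f)
  w_i <- exp(-psi_ibm / rt_f)
  share_cm <- (w_c * area_cm) / (w_c * area_cm + w_i * area_ibm)
  cm_alloc <- share_cm * dye_total
  ibm_alloc <- dye_total - cm_alloc
  cm_bound <- k_sat * cm_alloc / (k_sat + cm_alloc)
  overflow <- cm_alloc - cm_bound
  ibm_amount <- ibm_alloc + overflow
  list(cm_amount = cm_bound, ibm_amount = ibm_amount,
       cm_density = cm_bound / area_cm,
       ibm_density = ibm_amount / area_ibm,
       f = ibm_amount / dye_total)
}

default_mitochondria <- function(dims) {
  # three well-separated capsules at mixed orientations, away from borders
  nr <- dims[1]; nc <- dims[2]
  list(
    list(center = c(0.30 * nr, 0.50 * nc), angle = 0.15,
         length_nm = 1800, radius_nm = 125),
    list(center = c(0.62 * nr, 0.30 * nc), angle = 1.25,
         length_nm = 1200, radius_nm = 125),
    list(center = c(0.72 * nr, 0.70 * nc), angle = -0.55,
         length_nm = 1500, radius_nm = 125)
  )
}

#' Synthetic two-channel mitochondria scene
#'
#' Generative parameters for the image simulator: barrel-shaped
#' mitochondria (capsules of ~250 nm diameter), unresolved transverse
#' cristae slabs, a membrane-potential-driven dye partition with saturable
#' cristae binding, a Gaussian PSF at SIM scale, and shot plus read noise.
#' The reference channel is rendered with uniform density over the whole
#' inner membrane (a loaded, potential-insensitive marker); the object
#' channel follows [partition_dye()].
#'
#' @param dims image size, c(rows, cols) in px (default 96 x 96).
#' @param mitochondria list of capsules, each
#'   `list(center = c(row, col) px, angle rad, length_nm, radius_nm)`;
#'   default: three capsules of 125 nm radius.
#' @param psi_c,psi_ibm CM and IBM potentials, mV (defaults -150, -120).
#' @param dye_total object-dye load, a.u. (default 13.5; the concentration
#'   series spans 1.35-81, a 60-fold range).
#' @param k_sat CM capacity (default 40 a.u., placing the 1.35-81 load
#'   series on both sides of saturation).
#' @param rim_fraction if set, overrides the partition model with an exact
#'   rim fraction f (used for identifiability sweeps).
#' @param psf_fwhm_nm PSF full width at half maximum (default 120 nm,
#'   SIM-scale).
#' @param pixel_size_nm nm per pixel (default 32).
#' @param crista_spacing_nm,crista_width_nm transverse slab period and
#'   thickness (defaults 70 and 30 nm, below the PSF).
#' @param crista_margin_nm gap between slab ends and the envelope
#'   (default 50 nm), making the cristae region narrower than the rim.
#' @param membrane_nm envelope (IBM) shell thickness (default 25 nm).
#' @param area_cm,area_ibm relative CM and IBM membrane areas (defaults 2
#'   and 1), used both by the dye partition and to mix the
#'   uniform-per-membrane-area reference channel.
#' @param ref_total reference-channel total signal (a.u., default 500).
#' @param gain photons per a.u. of total signal (default 2e4, giving
#'   hundreds to thousands of photons per foreground pixel).
#' @param read_sigma read-noise s.d. in photons (default 2).
#' @param noise logical, apply shot + read noise (default TRUE).
#' @param seed integer RNG seed for the noise pipeline.
#' @return object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(dims = c(96L, 96L),
                            mitochondria = NULL,
                            psi_c = -150, psi_ibm = -120,
                            dye_total = 13.5, k_sat = 40,
                            rim_fraction = NULL,
                            psf_fwhm_nm = 120, pixel_size_nm = 32,
                            crista_spacing_nm = 70, crista_width_nm = 30,
                            crista_margin_nm = 50, membrane_nm = 25,
                            area_cm = 2, area_ibm = 1,
                            ref_total = 500, gain = 2e4, read_sigma = 2,
                            noise = TRUE, seed = 1L) {
  if (is.null(mitochondria)) mitochondria <- default_mitochondria(dims)
  stopifnot(psf_fwhm_nm > 0, pixel_size_nm > 0, dye_total > 0)
  for (m in mitochondria)
    if (m$radius_nm <= 0) stop("mitochondrion radius must be positive")
  if (!is.null(rim_fraction) &&
      (rim_fraction < 0 || rim_fraction > 1))
    stop("rim_fraction must be in [0, 1]")
  structure(list(dims = as.integer(dims), mitochondria = mitochondria,
                 psi_c = psi_c, psi_ibm = psi_ibm,
                 dye_total = dye_total, k_sat = k_sat,
                 rim_fraction = rim_fraction,
                 psf_fwhm_nm = psf_fwhm_nm, pixel_size_nm = pixel_size_nm,
                 crista_spacing_nm = crista_spacing_nm,
                 crista_width_nm = crista_width_nm,
                 crista_margin_nm = crista_margin_nm,
                 membrane_nm = membrane_nm,
                 area_cm = area_cm, area_ibm = area_ibm,
                 ref_total = ref_total, gain = gain,
                 read_sigma = read_sigma, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Rasterize CM and IBM projected-density maps on a supersampled grid
# (factor ss). The mitochondrion is a 3D barrel whose optical section
# integrates the full depth, so the in-plane density is the 2D projection
# of the 3D structure: an infinitely thin cylindrical envelope (IBM)
# projects to 1/sqrt(R^2 - d^2) and a transverse crista disc of radius
# R_c projects to a sqrt(R_c^2 - d^2) dome. Each mitochondrion may carry
# a `dim_site` entry list(s_frac, width_nm, factor) that multiplies the
# local object density (local membrane-potential loss before fission).
rasterize_regions <- function(scene, ss = 2L) {
  nr <- scene$dims[1] * ss; nc <- scene$dims[2] * ss
  px <- scene$pixel_size_nm / ss
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  # subpixel centers in nm, aligned so full-res pixel centers average out
  y <- (rr - 0.5) * px
  x <- (cc - 0.5) * px
  cm <- matrix(0, nr, nc); ibm <- matrix(0, nr, nc)
  cm_obj <- cm; ibm_obj <- ibm
  for (m in scene$mitochondria) {
    cy <- m$center[1] * scene$pixel_size_nm
    cx <- m$center[2] * scene$pixel_size_nm
    u <- c(sin(m$angle), cos(m$angle))   # axis direction (row, col)
    hl <- m$length_nm / 2
    dy <- y - cy; dx <- x - cx
    s <- dy * u[1] + dx * u[2]           # along-axis coordinate, nm
    t <- -dy * u[2] + dx * u[1]          # across-axis coordinate, nm
    sc <- pmin(pmax(s, -hl), hl)
    d <- sqrt((s - sc)^2 + t^2)          # distance to the centerline segment
    R <- m$radius_nm
    # shell projection, clipped half a subpixel short of the edge where
    # the 1/sqrt divergence would be unresolvable anyway
    dedge <- pmin(d, R - px / 2)
    w_ibm <- ifelse(d <= R, 1 / sqrt(pmax(R^2 - dedge^2, 1e-9)), 0)
    Rc <- max(R - scene$crista_margin_nm, px)
    slab <- ((s + hl) %% scene$crista_spacing_nm) < scene$crista_width_nm
    w_cm <- ifelse(d <= Rc & abs(s) <= hl & slab,
                   sqrt(pmax(Rc^2 - d^2, 0)), 0)
    dimf <- matrix(1, nr, nc)
    if (!is.null(m$dim_site)) {
      s0 <- (m$dim_site$s_frac - 0.5) * m$length_nm
      w <- m$dim_site$width_nm
      local <- abs(s - s0) <= w / 2 & d <= R
      dimf[local] <- m$dim_site$factor
    }
    cm <- cm + w_cm
    ibm <- ibm + w_ibm
    cm_obj <- cm_obj + w_cm * dimf
    ibm_obj <- ibm_obj + w_ibm * dimf
  }
  list(cm = cm, ibm = ibm, cm_obj = cm_obj, ibm_obj = ibm_obj)
}

downsample <- function(img, ss) {
  if (ss == 1L) return(img)
  nr <- nrow(img) / ss; nc <- ncol(img) / ss
  m <- matrix(0, nr, nc)
  for (i in seq_len(ss)) for (j in seq_len(ss))
    m <- m + img[seq(i, by = ss, length.out = nr),
                 seq(j, by = ss, length.out = nc)]
  m / ss^2
}

gaussian_kernel <- function(sigma_px) {
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  k / sum(k)
}

#' Render one synthetic two-channel frame
#'
#' Rasterizes the scene on a 2x supersampled grid, convolves with the
#' Gaussian PSF, downsamples to the target pixel size and (optionally)
#' applies Poisson shot noise and Gaussian read noise. Channel totals are
#' normalized region masks scaled by the partitioned dye amounts, so the
#' pre-noise object-channel integral equals `dye_total * gain` exactly
#' (up to local dimming events, which remove dye).
#'
#' @param scene a [synthetic_scene()].
#' @param t frame time, seconds.
#' @param seed RNG seed for this frame's noise; defaults to the scene seed.
#' @return list with `frame` (a [two_channel_frame]) and `truth` (list:
#'   rim fraction `f`, `psi_c`, `psi_ibm`, `dye_total`, per-object
#'   pre-optics geometry measures).
#' @export
render_frame <- function(scene, t = 0, seed = scene$seed) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ss <- 2L
  reg <- rasterize_regions(scene, ss)
  if (sum(reg$cm) == 0 || sum(reg$ibm) == 0)
    stop("mitochondrion outside the field of view or degenerate geometry")
  if (is.null(scene$rim_fraction)) {
    part <- partition_dye(scene$dye_total, scene$psi_c, scene$psi_ibm,
                          scene$k_sat, area_cm = scene$area_cm,
                          area_ibm = scene$area_ibm)
    f <- part$f
  } else {
    f <- scene$rim_fraction
  }
  cm_amt <- (1 - f) * scene$dye_total
  ibm_amt <- f * scene$dye_total
  # normalized maps guarantee dye conservation before noise
  obj <- cm_amt * (reg$cm_obj / sum(reg$cm)) +
    ibm_amt * (reg$ibm_obj / sum(reg$ibm))
  # reference: uniform density per unit membrane area across the IMM
  atot <- scene$area_cm + scene$area_ibm
  ref <- scene$ref_total * (scene$area_cm / atot * reg$cm / sum(reg$cm) +
                              scene$area_ibm / atot * reg$ibm / sum(reg$ibm))
  sigma_px <- scene$psf_fwhm_nm / scene$pixel_size_nm /
    (2 * sqrt(2 * log(2))) * ss
  if (sigma_px > 0) {
    k <- gaussian_kernel(sigma_px)
    obj <- EBImage::filter2(obj, k)   # circular boundary: totals preserved
    ref <- EBImage::filter2(ref, k)
  }
  # FFT convolution can leave ~1e-16 negative ripple; clamp at zero
  obj <- pmax(downsample(matrix(as.numeric(obj), nrow(reg$cm)), ss), 0) *
    ss^2 * scene$gain
  ref <- pmax(downsample(matrix(as.numeric(ref), nrow(reg$cm)), ss), 0) *
    ss^2 * scene$gain
  if (scene$noise) {
    set.seed(seed)
    obj <- rpois(length(obj), pmax(obj, 0)) +
      rnorm(length(obj), 0, scene$read_sigma)
    ref <- rpois(length(ref), pmax(ref, 0)) +
      rnorm(length(ref), 0, scene$read_sigma)
    obj <- matrix(pmax(obj, 0), scene$dims[1], scene$dims[2])
    ref <- matrix(pmax(ref, 0), scene$dims[1], scene$dims[2])
  }
  geom <- lapply(scene$mitochondria, function(m) {
    R <- m$radius_nm; L <- m$length_nm
    a <- 2 * R * L + pi * R^2
    p <- 2 * L + 2 * pi * R
    list(length_nm = L, radius_nm = R,
         ar = (L + 2 * R) / (2 * R), ff = form_factor(p, a))
  })
  list(frame = two_channel_frame(ref, obj,
                                 pixel_size = scene$pixel_size_nm, time = t),
       truth = list(f = f, psi_c = scene$psi_c, psi_ibm = scene$psi_ibm,
                    dye_total = scene$dye_total, objects = geom))
}

#' Stimulation protocols for the simulator
#'
#' `protocol_null` holds every parameter constant. `protocol_histamine`
#' steps the cristae potential more negative after the stimulus
#' (exponential approach, time constant `tau`), so the rim fraction f
#' drops; an ATP-proxy trace rises with a lag (logistic by default, or a
#' linear coupling `atp = alpha * (1 - f) + noise`), and optional fission
#' events split a mitochondrion after two frames of local dimming.
#' `protocol_oligomycin` ramps the cristae potential more negative from
#' the stimulus, then a crista-junction opening event at `t_cj` pulls the
#' IBM potential down to meet it (f rises, a drop-then-rise index shape)
#' while mitochondria progressively shorten and thicken (aspect ratio
#' falls).
#'
#' @param n_frames number of frames.
#' @param dt frame interval, seconds.
#' @param t_stim stimulus time, seconds (histamine default 20 s, oligomycin
#'   default 120 s).
#' @param dpsi_c potential step on the cristae membrane, mV (negative =
#'   hyperpolarization).
#' @param tau approach time constant, seconds.
#' @param atp ATP-proxy settings: `list(model = "logistic", base, amp, lag,
#'   rate)` or `list(model = "linear", alpha, noise_sd)`.
#' @param fissions list of events, each `list(t, mito, s_frac, dim_frac)`:
#'   event time, index of the mitochondrion to split, split position as a
#'   fraction of its length, and the fractional local dye loss programmed
#'   for the two preceding frames.
#' @param ramp_rate oligomycin: cristae hyperpolarization rate, mV/s.
#' @param t_cj oligomycin: crista-junction opening time, seconds.
#' @param cj_tau oligomycin: potential-equalization time constant, seconds.
#' @param shorten_rate oligomycin: fractional length loss per second after
#'   `t_cj`.
#' @return a `sim_protocol` list consumed by [simulate_timelapse()].
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_null <- function(n_frames = 10L, dt = 10) {
  structure(list(kind = "null", n_frames = as.integer(n_frames), dt = dt,
                 t_stim = NULL, fissions = list()),
            class = "sim_protocol")
}

#' @rdname protocols
#' @export
protocol_histamine <- function(n_frames = 12L, dt = 10, t_stim = 20,
                               dpsi_c = -30, tau = 15,
                               atp = list(model = "logistic", base = 1,
                                          amp = 0.2, lag = 20, rate = 0.1),
                               fissions = list()) {
  structure(list(kind = "histamine", n_frames = as.integer(n_frames),
                 dt = dt, t_stim = t_stim, dpsi_c = dpsi_c, tau = tau,
                 atp = atp, fissions = fissions),
            class = "sim_protocol")
}

#' @rdname protocols
#' @export
protocol_oligomycin <- function(n_frames = 24L, dt = 10, t_stim = 120,
                                ramp_rate = -0.25, t_cj = 240, cj_tau = 40,
                                shorten_rate = 0.004, fissions = list()) {
  structure(list(kind = "oligomycin", n_frames = as.integer(n_frames),
                 dt = dt, t_stim = t_stim, ramp_rate = ramp_rate,
                 t_cj = t_cj, cj_tau = cj_tau, shorten_rate = shorten_rate,
                 fissions = fissions),
            class = "sim_protocol")
}

split_capsule <- function(m, s_frac, gap_nm = 200) {
  # Replace one capsule by two shorter ones with a visible gap at s_frac.
  # Capsule end caps extend one radius beyond the centerline segment, so
  # the children's centerlines retract by gap/2 + R on their split side.
  u <- c(sin(m$angle), cos(m$angle))
  hl <- m$length_nm / 2
  R <- m$radius_nm
  s0 <- (s_frac - 0.5) * m$length_nm
  px <- attr(m, "pixel_size_nm")
  end1 <- s0 - gap_nm / 2 - R   # right end of child 1's centerline
  end2 <- s0 + gap_nm / 2 + R   # left end of child 2's centerline
  mk <- function(sa, sb) {
    ctr <- m$center + u * ((sa + sb) / 2) / px
    list(center = ctr, angle = m$angle, length_nm = max(sb - sa, 100),
         radius_nm = R)
  }
  list(mk(-hl, end1), mk(end2, hl))
}

#' Simulate a two-channel time lapse with ground truth
#'
#' Runs a [synthetic_scene()] through a stimulation protocol, rendering one
#' frame per time point and recording exact per-frame truth (rim fraction,
#' potentials, ATP proxy, object count) plus an event log for programmed
#' fissions. Frame noise is seeded deterministically from the scene seed
#' and the frame index.
#'
#' @param scene a [synthetic_scene()].
#' @param protocol a protocol from [protocol_null()],
#'   [protocol_histamine()] or [protocol_oligomycin()].
#' @return list: `timelapse` (a [time_lapse]), `truth` (per-frame
#'   data.frame: t, f, psi_c, psi_ibm, atp, n_objects), `events`
#'   (data.frame of programmed fissions: t, frame, mito, row, col,
#'   dim_frac).
#' @export
simulate_timelapse <- function(scene, protocol) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(protocol, "sim_protocol"))
  tt <- (seq_len(protocol$n_frames) - 1) * protocol$dt
  for (fe in protocol$fissions)
    if (fe$t < min(tt) || fe$t > max(tt))
      stop("fission event at t = ", fe$t, " s outside the simulated interval")
  frames <- list(); truth <- list(); events <- list()
  mitos0 <- scene$mitochondria
  set.seed(scene$seed + 1013L)  # protocol-level noise (ATP), frame noise below
  atp_noise <- rnorm(protocol$n_frames, 0,
                     if (identical(protocol$atp$model, "linear"))
                       protocol$atp$noise_sd %||% 0 else 0)
  for (k in seq_len(protocol$n_frames)) {
    t <- tt[k]
    psi_c <- scene$psi_c; psi_ibm <- scene$psi_ibm
    mitos <- mitos0
    if (protocol$kind == "histamine" && t >= protocol$t_stim) {
      psi_c <- scene$psi_c +
        protocol$dpsi_c * (1 - exp(-(t - protocol$t_stim) / protocol$tau))
    }
    if (protocol$kind == "oligomycin") {
      if (t >= protocol$t_stim)
        psi_c <- scene$psi_c + protocol$ramp_rate *
          (min(t, protocol$t_cj) - protocol$t_stim)
      if (t >= protocol$t_cj) {
        mix <- 1 - exp(-(t - protocol$t_cj) / protocol$cj_tau)
        psi_ibm <- scene$psi_ibm + mix * (psi_c - scene$psi_ibm)
        shrink <- max(1 - protocol$shorten_rate * (t - protocol$t_cj), 0.4)
        mitos <- lapply(mitos, function(m) {
          m$length_nm <- m$length_nm * shrink
          m$radius_nm <- m$radius_nm / sqrt(shrink)  # roughly area-conserving
          m
        })
      }
    }
    # fission events: dim for the 2 frames preceding the split, then split.
    # Event `mito` indices refer to the original scene list; splits are
    # collected first and applied in one pass so indices stay valid.
    split_idx <- integer(0); kids_all <- list()
    for (ei in seq_along(protocol$fissions)) {
      fe <- protocol$fissions[[ei]]
      if (t >= fe$t) {
        m <- mitos[[fe$mito]]
        attr(m, "pixel_size_nm") <- scene$pixel_size_nm
        kids_all <- c(kids_all, split_capsule(m, fe$s_frac))
        split_idx <- c(split_idx, fe$mito)
        if (ei > length(events) || is.null(events[[ei]])) {
          u <- c(sin(m$angle), cos(m$angle))
          site <- m$center + u * (fe$s_frac - 0.5) * m$length_nm /
            scene$pixel_size_nm
          events[[ei]] <- data.frame(t = fe$t, frame = k, mito = fe$mito,
                                     row = site[1], col = site[2],
                                     dim_frac = fe$dim_frac %||% 0.4)
        }
      } else if (t >= fe$t - 2 * protocol$dt) {
        mitos[[fe$mito]]$dim_site <-
          list(s_frac = fe$s_frac, width_nm = 400,
               factor = 1 - (fe$dim_frac %||% 0.4))
      }
    }
    if (length(split_idx)) mitos <- c(mitos[-split_idx], kids_all)
    sc <- scene
    sc$mitochondria <- mitos
    sc$psi_c <- psi_c; sc$psi_ibm <- psi_ibm
    fr <- render_frame(sc, t = t, seed = scene$seed + 7L * k)
    atp <- NA_real_
    if (protocol$kind == "histamine") {
      a <- protocol$atp
      atp <- if (identical(a$model, "linear")) {
        a$alpha * (1 - fr$truth$f) + atp_noise[k]
      } else {
        a$base + a$amp / (1 + exp(-a$rate * (t - protocol$t_stim - a$lag)))
      }
    }
    frames[[k]] <- fr$frame
    truth[[k]] <- data.frame(t = t, f = fr$truth$f, psi_c = psi_c,
                             psi_ibm = psi_ibm, atp = atp,
                             n_objects = length(mitos))
  }
  list(timelapse = time_lapse(frames, stimulus_time = protocol$t_stim),
       truth = do.call(rbind, truth),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(t = numeric(0), frame = integer(0), mito = integer(0),
                    row = numeric(0), col = numeric(0),
                    dim_frac = numeric(0)))
}
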