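# Independent oracles and fixture builders used across the suite.

# --- brute-force binary morphology by set translation ---------------------
# erosion: a pixel survives iff every 3x3 neighbour (8-connected structuring
# element) is foreground; pixels beyond the image count as background.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr); tr <- sr + dr
  sc <- max(1, 1 - dc):min(nc, nc - dc); tc <- sc + dc
  out[tr, tc] <- m[sr, sc]
  out
}

brute_erode <- function(m, iters = 1) {
  m <- m != 0
  for (k in seq_len(iters)) {
    out <- matrix(TRUE, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) out <- out & shift_mask(m, dr, dc)
    m <- out
  }
  m
}

brute_dilate <- function(m, iters = 1) {
  m <- m != 0
  for (k in seq_len(iters)) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) out <- out | shift_mask(m, dr, dc)
    m <- out
  }
  m
}

# --- brute-force connected components (BFS flood fill) --------------------
brute_label <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1) %% nr) + 1; pc <- ((p - 1) %/% nr) + 1
      for (i in seq_len(nrow(nb))) {
        r <- pr + nb$dr[i]; c <- pc + nb$dc[i]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          q <- (c - 1) * nr + r
          if (m[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# --- simple geometric fixtures -------------------------------------------
disk_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- matrix(0, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- 1
  m
}

# sampled 1D Gaussian on integer-ish grid
gaussian_profile <- function(sigma, center = 10, spacing = 1, half = 10) {
  x <- seq(center - half, center + half, by = spacing)
  list(x = x, y = exp(-(x - center)^2 / (2 * sigma^2)))
}

# drop-then-rise shape: change-point sign test on a trace after a stimulus.
# Splits post-stimulus samples at the trace minimum; requires a strict
# majority of negative steps before the minimum and positive steps after.
has_drop_then_rise <- function(t, values, t_stim) {
  post <- which(t >= t_stim)
  v <- values[post]
  k <- which.min(v)
  if (k <= 1 || k >= length(v)) return(FALSE)
  before <- diff(v[1:k]); after <- diff(v[k:length(v)])
  mean(before < 0) > 0.5 && mean(after > 0) > 0.5
}

# fission truth matching: detected events vs programmed events
match_events <- function(detected, truth, max_dist = 6) {
  if (nrow(truth) == 0) return(list(tp = 0, fp = nrow(detected), fn = 0))
  used <- rep(FALSE, nrow(detected))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    hit <- which(!used & detected$frame == truth$frame[i] &
                   sqrt((detected$row - truth$row[i])^2 +
                          (detected$col - truth$col[i])^2) <= max_dist)
    if (length(hit)) { used[hit[1]] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}
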