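# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# FWHM by crossing search on a 1 MHz-oversampled copy of a sampled trace
# (linear interpolation onto the fine grid, then a plain scan).
oracle_fwhm_sampled <- function(time, force, baseline) {
  tf <- seq(time[1], time[length(time)], by = 1e-6)
  ff <- approx(time, force, xout = tf)$y
  half <- baseline + 0.5 * (max(ff) - baseline)
  above <- ff >= half
  up <- which(!above[-length(above)] & above[-1])[1]
  dn_cand <- which(above[-length(above)] & !above[-1])
  dn <- dn_cand[dn_cand > up][1]
  1000 * (tf[dn] - tf[up])
}

# FWHM of an analytic two-exponential twitch, crossing scan at 1 MHz.
oracle_fwhm_twoexp <- function(tau1_ms, tau2_ms) {
  t <- seq(0, 12 * tau2_ms, by = 1e-3)   # ms grid at 1 MHz
  f <- exp(-t / tau2_ms) - exp(-t / tau1_ms)
  half <- max(f) / 2
  above <- f >= half
  up <- which(!above[-length(above)] & above[-1])[1]
  dn_cand <- which(above[-length(above)] & !above[-1])
  dn <- dn_cand[dn_cand > up][1]
  t[dn] - t[up]
}

# The 30/40 ms duration rules applied by explicit index scanning, written
# independently of the rle-based implementation.
oracle_duration_rules <- function(sound, hop, min_sound = 0.030,
                                  min_silence = 0.040) {
  n <- length(sound)
  runs <- function(x) {
    out <- list(); i <- 1
    while (i <= n) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      out[[length(out) + 1]] <- c(start = i, end = j, val = x[i])
      i <- j + 1
    }
    out
  }
  x <- sound
  for (r in runs(x))
    if (r["val"] == 1 && (r["end"] - r["start"] + 1) * hop < min_sound)
      x[r["start"]:r["end"]] <- FALSE
  rs <- runs(x)
  if (length(rs) > 2) {
    for (k in 2:(length(rs) - 1)) {
      r <- rs[[k]]
      if (r["val"] == 0 && (r["end"] - r["start"] + 1) * hop < min_silence)
        x[r["start"]:r["end"]] <- TRUE
    }
  }
  x
}

# chi-square (df = 1) upper tail through the normal distribution:
# P(X > x) = 2 * (1 - pnorm(sqrt(x))).
oracle_chisq1_tail <- function(x) 2 * (1 - pnorm(sqrt(x)))

# Convex-hull area by point-in-polygon counting on a 4x subgrid (mgcv::in.out),
# for checking solidity denominators.
oracle_hull_area <- function(r, c) {
  px <- cbind(rep(r, each = 4) + c(-0.5, -0.5, 0.5, 0.5),
              rep(c, each = 4) + c(-0.5, 0.5, -0.5, 0.5))
  h <- grDevices::chull(px)
  poly <- px[c(h, h[1]), ]
  step <- 0.25
  gr <- seq(min(px[, 1]) - 0.5, max(px[, 1]) + 0.5, by = step)
  gc <- seq(min(px[, 2]) - 0.5, max(px[, 2]) + 0.5, by = step)
  pts <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
  inside <- mgcv::in.out(poly, pts)
  sum(inside) * step^2
}

# Mean IoU of ground-truth fibres against a detected label map, plus the
# detected count (truth labels matched greedily by maximal overlap).
match_iou <- function(truth, detected) {
  ids <- sort(unique(truth[truth > 0]))
  iou <- vapply(ids, function(i) {
    px <- which(truth == i)
    cand <- detected[px]; cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    b <- as.integer(names(which.max(table(cand))))
    inter <- sum(detected[px] == b)
    inter / (length(px) + sum(detected == b) - inter)
  }, 0)
  list(mean_iou = mean(iou), iou = iou, n_detected = max(detected))
}
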