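#' Construct a two-channel muscle section image
#'
#' Holds a laminin channel (cell borders), a MY-32 channel (fast myosin
#' immunoreactivity) and a binary region mask for one hemisyrinx, together
#' with the pixel scale. Channels are numeric matrices of equal shape;
#' intensities are assumed to lie in `intensity_range` (8-bit by default so
#' that the MY-32 classification cutoff of 50 is meaningful).
#'
#' @param laminin numeric matrix, laminin channel.
#' @param my32 numeric matrix, MY-32 channel, same shape.
#' @param mask logical/0-1 matrix marking the hemisyrinx region; defaults to
#'   the whole frame.
#' @param microns_per_pixel pixel size (um/px), positive.
#' @param intensity_range declared intensity range, default `c(0, 255)`.
#' @return An object of class `section_image`.
#' @export
section_image <- function(laminin, my32, mask = NULL, microns_per_pixel,
                          intensity_range = c(0, 255)) {
  laminin <- as.matrix(laminin); my32 <- as.matrix(my32)
  if (!identical(dim(laminin), dim(my32)))
    stop("laminin and my32 must have the same shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(laminin), ncol(laminin))
  mask <- matrix(as.logical(mask), nrow(laminin), ncol(laminin))
  if (!identical(dim(mask), dim(laminin)))
    stop("mask shape must match the channels")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  structure(list(laminin = laminin, my32 = my32, mask = mask,
                 microns_per_pixel = microns_per_pixel,
                 intensity_range = intensity_range),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image: %d x %d px, %.3g um/px, mask %.1f%%>\n",
              nrow(x$laminin), ncol(x$laminin), x$microns_per_pixel,
              100 * mean(x$mask)))
  invisible(x)
}

#' Segmentation parameters for myofibre detection
#'
#' Tunables of the border-based watershed segmentation. The Otsu threshold on
#' the contrast-equalized laminin channel is reduced by `threshold_reduction`
#' (10--20% is sensible; default 15%) so that faint borders are still caught.
#' `hmin_depth` is the H-minima suppression depth applied to the distance
#' map before the watershed; larger values merge shallow basins and prevent
#' over-segmentation.
#'
#' @param target_height optional output height (px) to rescale image and mask
#'   to before processing (bilinear for channels, nearest-neighbour for the
#'   mask); `NULL` preserves the input size.
#' @param clahe_tiles number of CLAHE tiles per side (default 8).
#' @param threshold_reduction fractional reduction of the Otsu threshold,
#'   default 0.15.
#' @param noise_area_px connected components (and holes) smaller than this
#'   many pixels are removed (filled), default 30.
#' @param smooth_radius radius of the diamond structuring element used to
#'   close fibre interiors, default 1.
#' @param hmin_depth H-minima depth on the distance map (distance units),
#'   default 2.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(target_height = NULL, clahe_tiles = 8,
                                threshold_reduction = 0.15,
                                noise_area_px = 30, smooth_radius = 1,
                                hmin_depth = 2) {
  structure(list(target_height = target_height, clahe_tiles = clahe_tiles,
                 threshold_reduction = threshold_reduction,
                 noise_area_px = noise_area_px, smooth_radius = smooth_radius,
                 hmin_depth = hmin_depth),
            class = "segmentation_params")
}

.diamond <- function(radius) EBImage::makeBrush(2L * radius + 1L, "diamond")

# Relabel a label matrix to consecutive integers 1..k preserving scan order.
.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0L) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Watershed segmentation of myofibres from the laminin channel
#'
#' Detects individual muscle fibres as the dark interiors enclosed by
#' laminin-stained borders. The chain is: optional rescale; CLAHE contrast
#' equalization of the laminin channel; masking; Otsu global threshold
#' reduced by a configurable fraction to binarize borders; removal of small
#' components and filling of small holes; diamond closing of the interiors;
#' Euclidean distance transform; H-minima suppression and watershed, which
#' splits touching interiors at their necks.
#'
#' @param image a [section_image].
#' @param params a [segmentation_params].
#' @return integer label matrix, same shape as the (possibly rescaled)
#'   channels: 0 = background, 1..k = fibre interiors, all inside the mask.
#'   The attribute `"image"` carries the (possibly rescaled) section so that
#'   feature extraction sees matching pixels.
#' @export
segment_fibres <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "section_image"))
  lam <- image$laminin; mask <- image$mask; my32 <- image$my32
  if (!is.null(params$target_height) &&
      params$target_height != nrow(lam)) {
    h <- as.integer(params$target_height)
    w <- as.integer(round(ncol(lam) * h / nrow(lam)))
    lam  <- as.matrix(EBImage::resize(EBImage::Image(lam),  w = h, h = w))
    my32 <- as.matrix(EBImage::resize(EBImage::Image(my32), w = h, h = w))
    mask <- as.matrix(EBImage::resize(EBImage::Image(mask * 1), w = h, h = w,
                                      filter = "none")) > 0.5
    image <- section_image(lam, my32, mask,
                           image$microns_per_pixel * nrow(image$laminin) / h,
                           image$intensity_range)
  }
  if (!any(mask)) {
    out <- matrix(0L, nrow(lam), ncol(lam))
    attr(out, "image") <- image
    return(out)
  }
  rng <- image$intensity_range
  lam01 <- (lam - rng[1]) / (rng[2] - rng[1])
  lam01[lam01 < 0] <- 0; lam01[lam01 > 1] <- 1
  # clahe needs dimensions divisible by the tile counts: pad by edge
  # replication, equalize, crop back
  nt <- params$clahe_tiles
  pr <- (nt - nrow(lam01) %% nt) %% nt
  pc <- (nt - ncol(lam01) %% nt) %% nt
  padded <- lam01[c(seq_len(nrow(lam01)), rep(nrow(lam01), pr)),
                  c(seq_len(ncol(lam01)), rep(ncol(lam01), pc)), drop = FALSE]
  eq <- as.matrix(EBImage::clahe(EBImage::Image(padded), nx = nt, ny = nt))
  eq <- eq[seq_len(nrow(lam01)), seq_len(ncol(lam01)), drop = FALSE]
  vals <- eq[mask]
  if (diff(range(vals)) < 1e-8) stop("no borders detected")
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)))
  thr <- thr * (1 - params$threshold_reduction)
  borders <- eq > thr & mask
  interior <- mask & !borders

  lab <- EBImage::bwlabel(EBImage::Image(interior * 1))
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  small <- which(sizes < params$noise_area_px)
  interior[as.matrix(lab) %in% small] <- FALSE
  # fill holes smaller than the noise area
  holes <- EBImage::bwlabel(EBImage::Image((!interior & mask) * 1))
  hm <- as.matrix(holes)
  hsizes <- tabulate(hm[hm > 0])
  fill <- which(hsizes < params$noise_area_px)
  interior[hm %in% fill] <- TRUE

  if (params$smooth_radius > 0) {
    k <- .diamond(params$smooth_radius)
    interior <- as.matrix(EBImage::closing(EBImage::Image(interior * 1), k)) > 0.5
    interior <- interior & mask
  }
  dm <- EBImage::distmap(EBImage::Image(interior * 1))
  ws <- EBImage::watershed(dm, tolerance = params$hmin_depth, ext = 1)
  out <- matrix(as.integer(as.matrix(ws)), nrow(lam), ncol(lam))
  out[!mask] <- 0L
  # regions touching the image border or the mask boundary are open field,
  # not laminin-enclosed fibres
  edge <- matrix(FALSE, nrow(out), ncol(out))
  edge[c(1L, nrow(out)), ] <- TRUE
  edge[, c(1L, ncol(out))] <- TRUE
  if (!all(mask)) {
    nm <- as.matrix(EBImage::dilate(EBImage::Image((!mask) * 1),
                                    .diamond(1L))) > 0.5
    edge <- edge | (nm & mask)
  }
  touching <- unique(out[edge & out > 0])
  if (length(touching)) out[out %in% touching] <- 0L
  out <- .relabel(out)
  storage.mode(out) <- "integer"
  attr(out, "image") <- image
  out
}

#' Feature constraints for false-detection removal
#'
#' Detected regions violating any constraint are dropped (and reported via a
#' message). Defaults: area in \[50, 2500\] um^2, solidity >= 0.80,
#' circularity >= 0.30.
#'
#' @param min_area,max_area area bounds (um^2).
#' @param min_solidity minimum solidity.
#' @param min_circularity minimum circularity `4*pi*area/perimeter^2`.
#' @return list of class `feature_constraints`.
#' @export
feature_constraints <- function(min_area = 50, max_area = 2500,
                                min_solidity = 0.80, min_circularity = 0.30) {
  structure(list(min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity,
                 min_circularity = min_circularity),
            class = "feature_constraints")
}

# Convex-hull area of the union of unit pixel squares centred on (r, c):
# hull of the 4 corners of every pixel, shoelace formula.
.hull_area <- function(r, c) {
  px <- cbind(rep(r, each = 4L) + c(-0.5, -0.5, 0.5, 0.5),
              rep(c, each = 4L) + c(-0.5, 0.5, -0.5, 0.5))
  h <- grDevices::chull(px)
  xy <- px[h, , drop = FALSE]
  n <- nrow(xy)
  if (n < 3L) return(length(r))
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Measure per-fibre geometry and MY-32 intensity
#'
#' For every label of a segmentation, measures area, perimeter, eccentricity,
#' solidity, ellipse major/minor axis lengths and their ratio, circularity
#' (`4*pi*area/perimeter^2`), and the mean MY-32 intensity over the label's
#' pixels. Linear measures are converted with `microns_per_pixel`, areas with
#' its square. Labels violating the [feature_constraints] are dropped and
#' reported.
#'
#' @param label_map integer label matrix from [segment_fibres()].
#' @param image the matching [section_image]; defaults to the one attached to
#'   the label map.
#' @param constraints a [feature_constraints].
#' @return data.frame of class `fibre_records`, one row per retained fibre:
#'   `fibre_id, area, perimeter, eccentricity, solidity, major_axis,
#'   minor_axis, axis_ratio, circularity, mean_my32`. Dropped labels are in
#'   `attr(, "dropped")`.
#' @export
extract_fibre_features <- function(label_map, image = attr(label_map, "image"),
                                   constraints = feature_constraints()) {
  stopifnot(inherits(image, "section_image"))
  lab <- matrix(as.integer(label_map), nrow(image$laminin), ncol(image$laminin))
  mpp <- image$microns_per_pixel
  empty <- data.frame(fibre_id = integer(), area = numeric(),
                      perimeter = numeric(), eccentricity = numeric(),
                      solidity = numeric(), major_axis = numeric(),
                      minor_axis = numeric(), axis_ratio = numeric(),
                      circularity = numeric(), mean_my32 = numeric())
  class(empty) <- c("fibre_records", "data.frame")
  if (!any(lab > 0)) return(empty)
  img <- EBImage::Image(lab)
  sh <- EBImage::computeFeatures.shape(img)
  mo <- EBImage::computeFeatures.moment(img)
  ids <- as.integer(rownames(sh))
  area_px <- sh[, "s.area"]
  per_px <- sh[, "s.perimeter"]
  ecc <- mo[ids_match <- match(ids, as.integer(rownames(mo))), "m.eccentricity"]
  major_px <- mo[ids_match, "m.majoraxis"]
  minor_px <- major_px * sqrt(pmax(0, 1 - ecc^2))
  # solidity needs pixel coordinates per label
  pos <- which(lab > 0)
  rr <- (pos - 1L) %% nrow(lab) + 1L
  cc <- (pos - 1L) %/% nrow(lab) + 1L
  lv <- lab[pos]
  ord <- order(lv)
  rr <- rr[ord]; cc <- cc[ord]; lv <- lv[ord]
  brk <- c(which(diff(lv) != 0), length(lv))
  st <- c(1L, head(brk, -1L) + 1L)
  sol <- numeric(length(ids))
  mmy <- numeric(length(ids))
  my <- image$my32
  for (k in seq_along(ids)) {
    i <- st[k]:brk[k]
    sol[k] <- length(i) / .hull_area(rr[i], cc[i])
    mmy[k] <- mean(my[cbind(rr[i], cc[i])])
  }
  sol[sol > 1] <- 1
  df <- data.frame(fibre_id = ids,
                   area = area_px * mpp^2,
                   perimeter = per_px * mpp,
                   eccentricity = ecc,
                   solidity = sol,
                   major_axis = major_px * mpp,
                   minor_axis = minor_px * mpp,
                   axis_ratio = major_px / pmax(minor_px, 1e-9),
                   circularity = pmin(1, 4 * pi * area_px / pmax(per_px, 1e-9)^2),
                   mean_my32 = mmy)
  keep <- df$area >= constraints$min_area & df$area <= constraints$max_area &
    df$solidity >= constraints$min_solidity &
    df$circularity >= constraints$min_circularity
  dropped <- df[!keep, , drop = FALSE]
  if (nrow(dropped) > 0)
    message(sprintf("dropped %d label(s) violating feature constraints",
                    nrow(dropped)))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("fibre_records", "data.frame")
  out
}

#' Classify fibres as superfast or fast from MY-32 intensity
#'
#' Fast fibres have mean MY-32 intensity strictly greater than the cutoff
#' (default 50 on a 0--255 scale); superfast fibres are at or below it.
#' Intensities recorded on another bit depth can be declared via
#' `intensity_range` and are rescaled to 0--255 before applying the cutoff.
#'
#' @param records a `fibre_records` data.frame with `mean_my32`.
#' @param cutoff classification cutoff, default 50.
#' @param intensity_range the range `mean_my32` was measured on; default
#'   `c(0, 255)` (no rescaling).
#' @return `records` with a `fibre_type` factor column
#'   (`"superfast"`/`"fast"`).
#' @export
classify_fibres <- function(records, cutoff = 50, intensity_range = c(0, 255)) {
  stopifnot("mean_my32" %in% names(records))
  v <- records$mean_my32
  if (!identical(as.numeric(intensity_range), c(0, 255)))
    v <- (v - intensity_range[1]) / diff(intensity_range) * 255
  records$fibre_type <- factor(ifelse(v > cutoff, "fast", "superfast"),
                               levels = c("superfast", "fast"))
  records
}

.pdf_hist <- function(x, binwidth) {
  if (length(x) == 0L)
    return(data.frame(mid = numeric(), density = numeric()))
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  h <- graphics::hist(x, breaks = seq(lo, hi, by = binwidth), plot = FALSE)
  data.frame(mid = h$mids, density = h$density)
}

#' Summarize fibre typing for one hemisyrinx
#'
#' Counts and medians per fibre type, the superfast fraction, probability
#' density estimates of fibre area and MY-32 intensity (fixed bin widths,
#' normalized so that density times bin width sums to 1), and the total
#' muscle cross-sectional area of the hemisyrinx. Because the watershed
#' leaves out the inter-fibre space, the hemisyrinx CSA is measured as the
#' area of the union of all fibre labels after dilation with a diamond
#' structuring element (radius 10 px).
#'
#' @param records classified `fibre_records` (see [classify_fibres()]).
#' @param label_map the label matrix the records came from.
#' @param image the matching [section_image]; defaults to the one attached to
#'   `label_map`.
#' @param area_binwidth fibre-area bin width (um^2), default 50.
#' @param my32_binwidth MY-32 intensity bin width, default 5.
#' @param dilation_radius diamond radius (px) for the CSA dilation, default 10.
#' @return list of class `fibre_typing_summary`.
#' @export
summarize_hemisyrinx <- function(records, label_map,
                                 image = attr(label_map, "image"),
                                 area_binwidth = 50, my32_binwidth = 5,
                                 dilation_radius = 10) {
  stopifnot("fibre_type" %in% names(records))
  n_sf <- sum(records$fibre_type == "superfast")
  n_f <- sum(records$fibre_type == "fast")
  mpp <- image$microns_per_pixel
  keep <- matrix(as.integer(label_map) %in% records$fibre_id,
                 nrow(label_map), ncol(label_map))
  dil <- as.matrix(EBImage::dilate(EBImage::Image(keep * 1),
                                   .diamond(dilation_radius))) > 0.5
  structure(list(
    n_fibres = nrow(records), n_superfast = n_sf, n_fast = n_f,
    superfast_fraction = if (nrow(records) > 0) n_sf / nrow(records) else NA_real_,
    median_area = stats::median(records$area),
    median_my32 = stats::median(records$mean_my32),
    hemisyrinx_csa = sum(dil) * mpp^2,
    area_pdf = .pdf_hist(records$area, area_binwidth),
    my32_pdf = .pdf_hist(records$mean_my32, my32_binwidth),
    area_binwidth = area_binwidth, my32_binwidth = my32_binwidth),
    class = "fibre_typing_summary")
}

#' @export
print.fibre_typing_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<fibre_typing_summary: %d fibres (%d superfast / %d fast, %.1f%% superfast)\n",
    "  median area %.1f um^2, median MY-32 %.1f, hemisyrinx CSA %.3g um^2>\n"),
    x$n_fibres, x$n_superfast, x$n_fast, 100 * x$superfast_fraction,
    x$median_area, x$median_my32, x$hemisyrinx_csa))
  invisible(x)
}
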