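## Seeded retinal-section phantom: a layered immunofluorescence section
## (IS / ONL / OPL bands plus INL nuclei) with curvilinear bipolar-dendrite
## sprouts of known length rising from the OPL into the ONL, a TUNEL channel
## with a known number of positive nuclei, and exact ground-truth masks.

#' Specification of a retinal-section phantom
#'
#' Geometry follows a radial cross-section with row 1 at the scleral (inner
#' segment) side. `layer_boundaries` are four increasing pixel rows
#' `c(is_top, is_onl, onl_opl, opl_bottom)`: the IS band occupies rows
#' `[is_top, is_onl)`, the ONL `[is_onl, onl_opl)` and the OPL
#' `[onl_opl, opl_bottom)`.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param layer_boundaries four increasing row coordinates (see above).
#' @param nucleus_density nuclei per 100 um^2 of ONL.
#' @param nucleus_diameter_um nominal nucleus diameter (um).
#' @param sprouts list of polylines; each a matrix with columns `x_um`
#'   (lateral) and `y_um` (depth, 0 at the scleral edge). Every polyline must
#'   start inside the OPL band and rise into the ONL.
#' @param channel_levels named list of `c(fg=, bg=)` intensity pairs on the
#'   `[0, 1]` scale for channels `nuclei`, `bipolar`, `opl_marker`,
#'   `is_marker`, `tunel`.
#' @param psf_sigma_um Gaussian blur sigma emulating the point-spread
#'   function (um).
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param tunel_positive_count number of TUNEL-positive nuclei to plant in
#'   the ONL.
#' @param sprout_width_px stroke width of rasterised sprouts (pixels).
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return an object of class `retina_phantom_spec`.
#' @export
retina_phantom_spec <- function(image_height_px = 360L,
                                image_width_px = 256L,
                                pixel_size_um = 0.5,
                                layer_boundaries = c(20L, 60L, 180L, 220L),
                                nucleus_density = 2.5,
                                nucleus_diameter_um = 5,
                                sprouts = list(),
                                channel_levels = NULL,
                                psf_sigma_um = 0.5,
                                noise_sigma = 0.04,
                                tunel_positive_count = 0L,
                                sprout_width_px = 2,
                                seed = 1L) {
  assert_num1(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  assert_num1(nucleus_density, "nucleus_density", 0, strict = TRUE)
  assert_num1(nucleus_diameter_um, "nucleus_diameter_um", 0, strict = TRUE)
  assert_num1(noise_sigma, "noise_sigma", 0)
  assert_num1(psf_sigma_um, "psf_sigma_um", 0)
  assert_num1(tunel_positive_count, "tunel_positive_count", 0)
  if (length(layer_boundaries) != 4L || any(diff(layer_boundaries) <= 0)) {
    stop("'layer_boundaries' must be four strictly increasing rows",
         call. = FALSE)
  }
  if (layer_boundaries[4] > image_height_px || layer_boundaries[1] < 1) {
    stop("'layer_boundaries' must lie within the image", call. = FALSE)
  }
  default_levels <- list(
    nuclei = c(fg = 0.85, bg = 0.05),
    bipolar = c(fg = 0.90, bg = 0.05),
    opl_marker = c(fg = 0.85, bg = 0.05),
    is_marker = c(fg = 0.85, bg = 0.05),
    tunel = c(fg = 0.90, bg = 0.02)
  )
  channel_levels <- utils::modifyList(default_levels,
                                      channel_levels %||% list())
  if (any(unlist(channel_levels) < 0)) {
    stop("channel intensities must be >= 0", call. = FALSE)
  }
  spec <- structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_size_um = pixel_size_um,
         layer_boundaries = as.integer(layer_boundaries),
         nucleus_density = nucleus_density,
         nucleus_diameter_um = nucleus_diameter_um,
         sprouts = sprouts,
         channel_levels = channel_levels,
         psf_sigma_um = psf_sigma_um,
         noise_sigma = noise_sigma,
         tunel_positive_count = as.integer(tunel_positive_count),
         sprout_width_px = sprout_width_px,
         seed = as.integer(seed)),
    class = "retina_phantom_spec"
  )
  validate_sprouts(spec)
  spec
}

## a polyline's OPL-start invariant and image bounds, with the sprout index
## named in the error
validate_sprouts <- function(spec) {
  psz <- spec$pixel_size_um
  b <- spec$layer_boundaries
  h_um <- spec$image_height_px * psz
  w_um <- spec$image_width_px * psz
  opl_top_um <- (b[3] - 1) * psz
  opl_bot_um <- (b[4] - 1) * psz
  for (i in seq_along(spec$sprouts)) {
    p <- spec$sprouts[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L) {
      stop(sprintf("sprout %d: polyline must be a matrix with >= 2 rows and columns (x_um, y_um)", i),
           call. = FALSE)
    }
    if (any(p[, 1] < 0 | p[, 1] > w_um | p[, 2] < 0 | p[, 2] > h_um)) {
      stop(sprintf("sprout %d has a vertex outside the image", i),
           call. = FALSE)
    }
    y0 <- p[1, 2]
    if (y0 < opl_top_um || y0 >= opl_bot_um) {
      stop(sprintf("sprout %d does not start inside the OPL band", i),
           call. = FALSE)
    }
  }
  invisible(spec)
}

polyline_length_um <- function(p) {
  sum(sqrt(rowSums(diff(p)^2)))
}

## rasterise a polyline with anti-aliasing off: pixel centres within
## width/2 of a densely sampled path point are set
draw_polyline <- function(mask, poly_um, pixel_size_um, width_px = 2) {
  h <- nrow(mask); w <- ncol(mask)
  r_px <- width_px / 2
  step_um <- 0.3 * pixel_size_um
  for (k in seq_len(nrow(poly_um) - 1L)) {
    a <- poly_um[k, ]; b <- poly_um[k + 1L, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / step_um) + 1L))
    xs <- (a[1] + ts * (b[1] - a[1])) / pixel_size_um  # column axis, px
    ys <- (a[2] + ts * (b[2] - a[2])) / pixel_size_um  # row axis, px
    off <- expand.grid(dr = -2:2, dc = -2:2)
    base_r <- floor(ys) + 1L
    base_c <- floor(xs) + 1L
    for (o in seq_len(nrow(off))) {
      rr <- base_r + off$dr[o]
      cc <- base_c + off$dc[o]
      keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      if (!any(keep)) next
      cy <- rr[keep] - 0.5; cx <- cc[keep] - 0.5
      hit <- (cx - xs[keep])^2 + (cy - ys[keep])^2 <= r_px^2
      if (any(hit)) mask[cbind(rr[keep][hit], cc[keep][hit])] <- TRUE
    }
  }
  mask
}

## pixel-centre-inside disk
draw_disk <- function(mask, cx_px, cy_px, r_px) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(cy_px - r_px)); r1 <- min(h, ceiling(cy_px + r_px) + 1L)
  c0 <- max(1L, floor(cx_px - r_px)); c1 <- min(w, ceiling(cx_px + r_px) + 1L)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 0.5) - cy_px
  dx <- (cols - 0.5) - cx_px
  hit <- outer(dy^2, dx^2, "+") <= r_px^2
  mask[rows, cols] <- mask[rows, cols] | hit
  mask
}

#' Generate a retinal-section phantom with exact ground truth
#'
#' Rasterises five channels (nuclei/DAPI-like, bipolar marker with sprouts,
#' OPL marker, IS marker, TUNEL), applies Gaussian blur and additive noise,
#' and returns the exact truth: per-sprout polyline lengths, ground-truth
#' layer masks, the sprouted area fraction of the ONL and the planted TUNEL
#' count. Identical spec + seed gives bit-identical output.
#'
#' @param spec a [retina_phantom_spec()].
#' @return list with elements `channels` (named list of matrices on
#'   `[0, 1]`), `truth` (see Details) and `spec`.
#' @export
make_retina_phantom <- function(spec) {
  stopifnot(inherits(spec, "retina_phantom_spec"))
  validate_sprouts(spec)
  withr::with_seed(spec$seed, make_retina_phantom_impl(spec))
}

make_retina_phantom_impl <- function(spec) {
  h <- spec$image_height_px; w <- spec$image_width_px
  psz <- spec$pixel_size_um
  b <- spec$layer_boundaries
  is_rows <- b[1]:(b[2] - 1L)
  onl_rows <- b[2]:(b[3] - 1L)
  opl_rows <- b[3]:(b[4] - 1L)

  masks <- layer_masks(band_mask(h, w, onl_rows), band_mask(h, w, opl_rows),
                       band_mask(h, w, is_rows), psz,
                       source = list(kind = "phantom-truth"))

  r_px <- spec$nucleus_diameter_um / 2 / psz
  nuc <- matrix(FALSE, h, w)
  nuc <- place_nuclei(nuc, onl_rows, spec, r_px)
  ## INL nuclei on the vitreal side of the OPL (realistic DAPI content; the
  ## segmenter must pick the scleral band)
  inl_rows_end <- min(h, b[4] + round(40 / psz))
  if (inl_rows_end > b[4] + 2 * r_px) {
    nuc <- place_nuclei(nuc, (b[4] + 1L):inl_rows_end, spec, r_px)
  }

  sprout_mask <- matrix(FALSE, h, w)
  for (p in spec$sprouts) {
    sprout_mask <- draw_polyline(sprout_mask, p, psz, spec$sprout_width_px)
  }

  tunel_mask <- matrix(FALSE, h, w)
  k <- spec$tunel_positive_count
  if (k > 0) {
    pos <- place_separated(onl_rows, w, k, min_sep_px = 1.6 * 2 * r_px,
                           margin_px = r_px)
    for (i in seq_len(nrow(pos))) {
      tunel_mask <- draw_disk(tunel_mask, pos[i, 2], pos[i, 1], r_px)
    }
  }

  lv <- spec$channel_levels
  render <- function(mask, level) {
    img <- matrix(level[["bg"]], h, w)
    img[mask] <- level[["fg"]]
    img <- gaussian_blur(img, spec$psf_sigma_um / psz)
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    pmin(pmax(img, 0), 1)
  }
  channels <- list(
    nuclei = render(nuc, lv$nuclei),
    bipolar = render(sprout_mask | masks$opl_mask, lv$bipolar),
    opl_marker = render(masks$opl_mask, lv$opl_marker),
    is_marker = render(masks$is_mask, lv$is_marker),
    tunel = render(tunel_mask, lv$tunel)
  )

  per_len <- vapply(spec$sprouts, polyline_length_um, numeric(1))
  onl_area <- sum(masks$onl_mask)
  truth <- list(
    total_sprout_length_um = sum(per_len),
    per_sprout_length_um = per_len,
    sprouted_area_fraction_pct =
      100 * sum(sprout_mask & masks$onl_mask) / onl_area,
    layer_masks = masks,
    tunel_count = k,
    sprout_mask = sprout_mask,
    tunel_mask = tunel_mask,
    nuclei_mask = nuc
  )
  list(channels = channels, truth = truth, spec = spec)
}

## jittered square grid of nuclei filling a row band; edge rows are clamped
## so disks stay inside the band (and the top disks touch its first row)
place_nuclei <- function(mask, rows, spec, r_px) {
  psz <- spec$pixel_size_um
  s_px <- sqrt(100 / spec$nucleus_density) / psz
  top <- min(rows); bot <- max(rows)
  if (bot - top < 2 * r_px) return(mask)
  cy <- seq(top - 1 + r_px, bot - r_px, by = s_px) + 0.5
  cx <- seq(r_px, ncol(mask) - r_px, by = s_px) + 0.5
  jit <- 0.15 * s_px
  for (y in cy) for (x in cx) {
    yy <- min(max(y + stats::runif(1, -jit, jit), top - 1 + r_px), bot - r_px)
    xx <- min(max(x + stats::runif(1, -jit, jit), r_px),
              ncol(mask) - r_px)
    mask <- draw_disk(mask, xx, yy, r_px)
  }
  mask
}

## rejection-sample k well-separated (row, col) centres inside a row band
place_separated <- function(rows, w, k, min_sep_px, margin_px,
                            max_tries = 20000L) {
  top <- min(rows) + margin_px; bot <- max(rows) - margin_px
  pos <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pos) < k && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, top, bot), stats::runif(1, margin_px, w - margin_px))
    if (nrow(pos) == 0 ||
        all(sqrt(rowSums(sweep(pos, 2, cand)^2)) >= min_sep_px)) {
      pos <- rbind(pos, cand)
    }
  }
  if (nrow(pos) < k) {
    stop("could not place ", k, " separated nuclei; reduce the count or separation",
         call. = FALSE)
  }
  pos
}

#' Random sprout polylines for a phantom spec
#'
#' Draws `n` gently curved polylines that start just inside the OPL band and
#' rise into the ONL with small lateral wobble, emulating bipolar-cell
#' dendrites sprouting past their normal OPL territory.
#'
#' @param n number of sprouts.
#' @param spec a [retina_phantom_spec()] providing the geometry.
#' @param length_range_um range of total sprout lengths (um).
#' @param seed integer seed.
#' @return list of polyline matrices suitable for `spec$sprouts`.
#' @export
random_sprouts <- function(n, spec, length_range_um = c(25, 50), seed = 1L) {
  psz <- spec$pixel_size_um
  b <- spec$layer_boundaries
  opl_top_um <- (b[3] - 1) * psz
  w_um <- spec$image_width_px * psz
  withr::with_seed(seed, {
    ## distinct dendrites: evenly spaced jittered bases so separate sprouts
    ## do not coincide in the raster (their truth lengths are additive)
    span <- c(0.08 * w_um, 0.92 * w_um)
    spacing <- diff(span) / n
    xs <- sample(span[1] + (seq_len(n) - 0.5) * spacing +
                   stats::runif(n, -0.2, 0.2) * spacing)
    lens <- stats::runif(n, length_range_um[1], length_range_um[2])
    lapply(seq_len(n), function(i) {
      start_y <- opl_top_um + 0.25         # just inside the OPL
      n_seg <- 6L
      seg <- lens[i] / n_seg
      x <- xs[i]; y <- start_y
      pts <- matrix(c(x, y), 1, 2)
      for (s in seq_len(n_seg)) {
        ang <- stats::runif(1, -0.12, 0.12)  # radians off vertical
        x <- min(max(x + seg * sin(ang), 1), w_um - 1)
        y <- y - seg * cos(ang)
        pts <- rbind(pts, c(x, y))
      }
      colnames(pts) <- c("x_um", "y_um")
      pts
    })
  })
}
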