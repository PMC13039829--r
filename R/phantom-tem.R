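## Electron-micrograph-like phantom: photoreceptor terminals (rod spherules,
## cone pedicles) as polygons containing elliptical mitochondria with
## analytic areas, rasterised to a grayscale image plus label masks.

#' Specification of a TEM terminal/mitochondria phantom
#'
#' @param terminals list; each element a list with `type` ("rod" or "cone")
#'   and `polygon`, a matrix of vertices with columns `x_um`, `y_um`.
#' @param mitochondria list parallel to `terminals`; each element a list of
#'   ellipses, each a list/vector with `cx`, `cy` (centre, um), `a`, `b`
#'   (semi-axes, um) and `theta` (orientation, radians).
#' @param pixel_size_um micrometres per pixel (TEM scale, e.g. 0.005).
#' @param noise_sigma additive Gaussian noise s.d. on the grayscale render.
#' @param seed integer seed.
#' @return object of class `tem_phantom_spec`.
#' @export
tem_phantom_spec <- function(terminals, mitochondria, pixel_size_um = 0.005,
                             noise_sigma = 0.02, seed = 1L) {
  assert_num1(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  assert_num1(noise_sigma, "noise_sigma", 0)
  if (length(terminals) != length(mitochondria)) {
    stop("'mitochondria' must have one entry (possibly empty) per terminal",
         call. = FALSE)
  }
  for (i in seq_along(terminals)) {
    t <- terminals[[i]]
    if (!t$type %in% c("rod", "cone")) {
      stop(sprintf("terminal %d: type must be 'rod' or 'cone'", i),
           call. = FALSE)
    }
    for (j in seq_along(mitochondria[[i]])) {
      e <- mitochondria[[i]][[j]]
      if (!ellipse_inside_polygon(e, t$polygon)) {
        stop(sprintf("mitochondrion %d of terminal %d escapes its terminal polygon",
                     j, i), call. = FALSE)
      }
    }
  }
  structure(list(terminals = terminals, mitochondria = mitochondria,
                 pixel_size_um = pixel_size_um, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "tem_phantom_spec")
}

## vectorised even-odd ray casting
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area_um2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

ellipse_boundary <- function(e, n = 90L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  x0 <- e$a * cos(t); y0 <- e$b * sin(t)
  cbind(e$cx + x0 * cos(e$theta) - y0 * sin(e$theta),
        e$cy + x0 * sin(e$theta) + y0 * cos(e$theta))
}

ellipse_inside_polygon <- function(e, poly) {
  bd <- ellipse_boundary(e)
  all(point_in_polygon(bd[, 1], bd[, 2], poly))
}

in_ellipse <- function(px, py, e) {
  dx <- px - e$cx; dy <- py - e$cy
  u <- dx * cos(e$theta) + dy * sin(e$theta)
  v <- -dx * sin(e$theta) + dy * cos(e$theta)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' Generate a TEM terminal phantom
#'
#' Rasterises terminals and mitochondria by the pixel-centre-inside rule and
#' reports analytic truth areas: the shoelace polygon area per terminal and
#' `pi * a * b` per mitochondrion ellipse.
#'
#' @param spec a [tem_phantom_spec()].
#' @return list with `image` (grayscale matrix), `terminal_labels` (integer
#'   label matrix), `mito_mask` (logical), `truth` (list of data frames
#'   `terminals` and `mitochondria`) and `spec`.
#' @export
make_tem_phantom <- function(spec) {
  stopifnot(inherits(spec, "tem_phantom_spec"))
  psz <- spec$pixel_size_um
  allx <- unlist(lapply(spec$terminals, function(t) t$polygon[, 1]))
  ally <- unlist(lapply(spec$terminals, function(t) t$polygon[, 2]))
  pad <- 0.3
  w <- ceiling((max(allx) + pad) / psz)
  h <- ceiling((max(ally) + pad) / psz)

  ## evaluate hit tests only inside each shape's pixel bounding box
  bbox_grid <- function(x0, x1, y0, y1) {
    cols <- max(1L, floor(x0 / psz)):min(w, ceiling(x1 / psz))
    rows <- max(1L, floor(y0 / psz)):min(h, ceiling(y1 / psz))
    list(rows = rows, cols = cols,
         cx = rep((cols - 0.5) * psz, each = length(rows)),
         cy = rep((rows - 0.5) * psz, times = length(cols)))
  }

  labels <- matrix(0L, h, w)
  mito <- matrix(FALSE, h, w)
  tt <- list(); mm <- list()
  for (i in seq_along(spec$terminals)) {
    term <- spec$terminals[[i]]
    g <- bbox_grid(min(term$polygon[, 1]), max(term$polygon[, 1]),
                   min(term$polygon[, 2]), max(term$polygon[, 2]))
    inside <- matrix(point_in_polygon(g$cx, g$cy, term$polygon),
                     length(g$rows), length(g$cols))
    if (any(labels[g$rows, g$cols] > 0L & inside)) {
      stop("terminal polygons overlap; phantom terminals must be disjoint",
           call. = FALSE)
    }
    sub <- labels[g$rows, g$cols]
    sub[inside] <- i
    labels[g$rows, g$cols] <- sub
    tt[[i]] <- data.frame(terminal_id = i, terminal_type = term$type,
                          area_um2 = polygon_area_um2(term$polygon))
    for (j in seq_along(spec$mitochondria[[i]])) {
      e <- spec$mitochondria[[i]][[j]]
      r <- max(e$a, e$b)
      ge <- bbox_grid(e$cx - r, e$cx + r, e$cy - r, e$cy + r)
      hit <- matrix(in_ellipse(ge$cx, ge$cy, e),
                    length(ge$rows), length(ge$cols))
      mito[ge$rows, ge$cols] <- mito[ge$rows, ge$cols] | hit
      mm[[length(mm) + 1L]] <- data.frame(
        terminal_id = i, mito_id = j, area_um2 = pi * e$a * e$b)
    }
  }
  truth_term <- do.call(rbind, tt)
  truth_mito <- if (length(mm)) do.call(rbind, mm) else
    data.frame(terminal_id = integer(), mito_id = integer(),
               area_um2 = numeric())
  if (nrow(truth_mito)) {
    agg <- stats::aggregate(area_um2 ~ terminal_id, truth_mito, sum)
    truth_term$mito_area_um2 <-
      agg$area_um2[match(truth_term$terminal_id, agg$terminal_id)]
    truth_term$mito_area_um2[is.na(truth_term$mito_area_um2)] <- 0
  } else {
    truth_term$mito_area_um2 <- 0
  }
  truth_term$occupancy <- truth_term$mito_area_um2 / truth_term$area_um2

  img <- matrix(0.15, h, w)
  img[labels > 0L] <- 0.45
  img[mito] <- 0.8
  img <- withr::with_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    } else img
  })
  img <- pmin(pmax(img, 0), 1)

  list(image = img, terminal_labels = labels, mito_mask = mito,
       truth = list(terminals = truth_term, mitochondria = truth_mito),
       spec = spec)
}

## regular n-gon polygon helper (um)
regular_polygon <- function(cx, cy, r, n = 24L, phase = 0) {
  t <- phase + seq(0, 2 * pi, length.out = n + 1L)[-1L]
  cbind(x_um = cx + r * cos(t), y_um = cy + r * sin(t))
}

#' Random TEM phantom spec of rod spherules and cone pedicles
#'
#' Rod terminals are small near-circular profiles carrying exactly one large
#' mitochondrion; cone pedicles are larger profiles carrying several smaller
#' mitochondria.
#'
#' @param n_rod,n_cone number of rod and cone terminals.
#' @param seed integer seed.
#' @param pixel_size_um passed to [tem_phantom_spec()].
#' @export
random_tem_spec <- function(n_rod = 4L, n_cone = 2L, seed = 1L,
                            pixel_size_um = 0.005) {
  withr::with_seed(seed, {
    n <- n_rod + n_cone
    terminals <- list(); mitos <- list()
    ## terminals on a grid with spacing large enough never to overlap
    spacing <- 5
    for (i in seq_len(n)) {
      gx <- ((i - 1) %% 3) * spacing + 2.5
      gy <- ((i - 1) %/% 3) * spacing + 2.5
      if (i <= n_rod) {
        r <- stats::runif(1, 0.9, 1.2)
        terminals[[i]] <- list(type = "rod",
                               polygon = regular_polygon(gx, gy, r))
        mitos[[i]] <- list(list(cx = gx + stats::runif(1, -0.1, 0.1),
                                cy = gy + stats::runif(1, -0.1, 0.1),
                                a = stats::runif(1, 0.45, 0.6),
                                b = stats::runif(1, 0.3, 0.42),
                                theta = stats::runif(1, 0, pi)))
      } else {
        r <- stats::runif(1, 1.8, 2.2)
        terminals[[i]] <- list(type = "cone",
                               polygon = regular_polygon(gx, gy, r))
        k <- sample(3:6, 1)
        ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = k + 1L)[-1L]
        rad <- 0.55 * r
        mitos[[i]] <- lapply(ang, function(a0) {
          list(cx = gx + rad * cos(a0), cy = gy + rad * sin(a0),
               a = stats::runif(1, 0.25, 0.35),
               b = stats::runif(1, 0.15, 0.25),
               theta = stats::runif(1, 0, pi))
        })
      }
    }
    tem_phantom_spec(terminals, mitos, pixel_size_um = pixel_size_um,
                     seed = seed)
  })
}
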