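## Binary-image primitives shared by the image-quantification modules.
##
## EBImage's bwlabel() uses 4-connectivity; closed organelles and thin
## neurites are traced with 8-connectivity, so labels that touch only
## diagonally are merged with a small union-find pass.

#' Label connected components with 8-connectivity
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background), labelled
#'   compactly from 1.
#' @export
label8 <- function(mask) {
  mask <- mask > 0
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax < 2L) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbour pairs: SE and SW
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0L & b > 0L & a != b)
  if (length(idx)) mapply(union2, a[idx], b[idx])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  idx <- which(a > 0L & b > 0L & a != b)
  if (length(idx)) mapply(union2, a[idx], b[idx])
  roots <- vapply(seq_len(nmax), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

## dilate a logical mask by `px` pixels (square structuring element)
dilate_px <- function(mask, px = 1L) {
  m <- mask > 0
  for (i in seq_len(px)) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -nc]
    out[, -nc] <- out[, -nc] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    m <- out
  }
  m
}

## morphological closing (dilate then erode) with a box element; erosion is
## the complement of dilating the complement
close_px <- function(mask, px = 1L) {
  if (px < 1L) return(mask > 0)
  !dilate_px(!dilate_px(mask, px), px)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of identical dimension.
#' @return IoU in [0, 1]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Do two masks agree up to a boundary band?
#'
#' TRUE when every pixel of each mask lies within `tol_px` pixels of the
#' other mask, i.e. the symmetric difference is confined to a boundary ring.
#'
#' @param a,b logical matrices.
#' @param tol_px boundary tolerance in pixels.
#' @export
masks_agree <- function(a, b, tol_px = 1L) {
  a <- a > 0; b <- b > 0
  !any(a & !dilate_px(b, tol_px)) && !any(b & !dilate_px(a, tol_px))
}

## Zhang-Suen thinning of a binary matrix, vectorised over neighbour shifts.
skeletonize <- function(mask) {
  m <- (mask > 0) * 1L
  if (!any(m == 1L)) return(m > 0)
  pad <- function(x) {
    out <- matrix(0L, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      core <- 2:(nr + 1L)
      corc <- 2:(nc + 1L)
      ## neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
      ## rows index the vertical axis so "N" is row - 1
      p2 <- p[core - 1L, corc];      p3 <- p[core - 1L, corc + 1L]
      p4 <- p[core, corc + 1L];      p5 <- p[core + 1L, corc + 1L]
      p6 <- p[core + 1L, corc];      p7 <- p[core + 1L, corc - 1L]
      p8 <- p[core, corc - 1L];      p9 <- p[core - 1L, corc - 1L]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- (p2 * p4 * p6) == 0L
        c2 <- (p4 * p6 * p8) == 0L
      } else {
        c1 <- (p2 * p4 * p8) == 0L
        c2 <- (p2 * p6 * p8) == 0L
      }
      del <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

## Calibrated length of a thin 8-connected skeleton: orthogonal neighbour
## pairs count 1, diagonal pairs sqrt(2); a diagonal pair is skipped when
## either of its two orthogonal common neighbours is present (corner triples
## would otherwise be double-counted).
skeleton_length_px <- function(skel) {
  m <- skel > 0
  if (!any(m)) return(0)
  nr <- nrow(m); nc <- ncol(m)
  orth <- sum(m[, -nc] & m[, -1]) + sum(m[-nr, ] & m[-1, ])
  ## SE pair (i,j)-(i+1,j+1); common neighbours (i,j+1) and (i+1,j)
  se <- m[-nr, -nc] & m[-1, -1] & !m[-nr, -1] & !m[-1, -nc]
  ## SW pair (i,j+1)-(i+1,j); common neighbours (i,j) and (i+1,j+1)
  sw <- m[-nr, -1] & m[-1, -nc] & !m[-nr, -nc] & !m[-1, -1]
  orth + sqrt(2) * (sum(se) + sum(sw))
}
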