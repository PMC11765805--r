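# Regions of interest. Coordinates are 0-based pixel indices (x right,
# y down); a pixel belongs to a region if its center does.

#' Region-of-interest constructors
#'
#' `roi_ellipse()` is the usual shape for the nucleus (region A) and for
#' foci-free regions (B); `roi_rect()` (half-open window) suits the
#' extracellular background region (C); `roi_polygon()` takes explicit
#' vertices. `roi_annulus()` is used for local focus background.
#'
#' @param center `c(x, y)` center, pixels.
#' @param semiaxes `c(rx, ry)` semi-axes, pixels.
#' @param xmin,ymin,xmax,ymax half-open rectangle bounds in pixels
#'   (`xmin <= x < xmax`).
#' @param vertices `n x 2` matrix of polygon vertices (x, y).
#' @param r_inner,r_outer annulus radii, pixels.
#' @return an object of class `roi`.
#' @name roi
#' @export
roi_ellipse <- function(center, semiaxes) {
  stopifnot(length(center) == 2L, length(semiaxes) == 2L, all(semiaxes > 0))
  structure(list(type = "ellipse", center = center, semiaxes = semiaxes),
            class = "roi")
}

#' @rdname roi
#' @export
roi_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(type = "rect", xmin = xmin, ymin = ymin,
                 xmax = xmax, ymax = ymax), class = "roi")
}

#' @rdname roi
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(type = "polygon", vertices = unname(vertices)),
            class = "roi")
}

#' @rdname roi
#' @export
roi_annulus <- function(center, r_inner, r_outer) {
  stopifnot(length(center) == 2L, r_outer > r_inner, r_inner >= 0)
  structure(list(type = "annulus", center = center,
                 r_inner = r_inner, r_outer = r_outer), class = "roi")
}

#' Rasterize an ROI to a logical mask
#'
#' @param roi an object from the [roi] constructors.
#' @param dim image size `c(ny, nx)`.
#' @return logical `ny x nx` matrix.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi"), length(dim) == 2L)
  xs <- seq_len(dim[2]) - 1
  ys <- seq_len(dim[1]) - 1
  switch(roi$type,
    ellipse = outer(((ys - roi$center[2]) / roi$semiaxes[2])^2,
                    ((xs - roi$center[1]) / roi$semiaxes[1])^2, `+`) <= 1,
    rect = outer(ys >= roi$ymin & ys < roi$ymax,
                 xs >= roi$xmin & xs < roi$xmax, `&`),
    annulus = {
      d2 <- outer((ys - roi$center[2])^2, (xs - roi$center[1])^2, `+`)
      d2 >= roi$r_inner^2 & d2 <= roi$r_outer^2
    },
    polygon = {
      m <- matrix(FALSE, dim[1], dim[2])
      vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
      n <- length(vx)
      for (yi in seq_along(ys)) {
        y <- ys[yi]
        # even-odd rule scanline crossings
        xcross <- numeric(0)
        j <- n
        for (i in seq_len(n)) {
          if ((vy[i] > y) != (vy[j] > y)) {
            xcross <- c(xcross,
              vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i]))
          }
          j <- i
        }
        if (length(xcross)) {
          xcross <- sort(xcross)
          for (k in seq(1, length(xcross) - 1, by = 2)) {
            m[yi, xs >= xcross[k] & xs < xcross[k + 1]] <- TRUE
          }
        }
      }
      m
    },
    stopf("unknown roi type '%s'", roi$type))
}

#' ROI scheme for diffuse-pool photometry
#'
#' Bundles the nucleus region A, one to three foci-free regions B inside
#' the nucleus, and an extracellular background region C. Validity (B
#' inside A, C disjoint from A, every region at least 25 px) is checked
#' against the image size at measurement time.
#'
#' @param A nucleus [roi].
#' @param B list of 1-3 foci-free [roi]s inside A.
#' @param C background [roi] outside all nuclei.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(A, B, C) {
  if (inherits(B, "roi")) B <- list(B)
  stopifnot(inherits(A, "roi"), inherits(C, "roi"),
            is.list(B), length(B) >= 1L,
            all(vapply(B, inherits, logical(1), "roi")))
  structure(list(A = A, B = B, C = C), class = "roi_set")
}

validate_roi_set <- function(rois, dim) {
  mA <- roi_mask(rois$A, dim)
  mC <- roi_mask(rois$C, dim)
  mBs <- lapply(rois$B, roi_mask, dim = dim)
  for (m in c(list(A = mA, C = mC), mBs)) {
    if (sum(m) < 25) stopf("every ROI must cover at least 25 pixels")
  }
  for (i in seq_along(mBs)) {
    if (any(mBs[[i]] & !mA))
      stopf("foci-free region B[%d] extends outside the nucleus region A", i)
  }
  if (any(mC & mA))
    stopf("background region C overlaps the nucleus region A")
  list(A = mA, B = mBs, C = mC)
}

#' Foci-free B regions and a background region from known scene geometry
#'
#' Convenience for simulated data: selects `n` small elliptical regions
#' inside the nucleus at least `clearance` pixels away from every focus
#' (mimicking the manual choice of foci-free regions), plus a background
#' rectangle outside the nucleus. This reads the geometry, never the
#' pixels, so it is configuration, not image segmentation.
#'
#' @param geometry a [scene_geometry()].
#' @param n number of B regions (default 3).
#' @param b_semiaxes semi-axes of each B ellipse, pixels.
#' @param clearance minimum distance from any focus center, pixels
#'   (default 4 PSF sigmas plus the region radius).
#' @return an [roi_set()].
#' @export
roi_set_from_geometry <- function(geometry, n = 3L,
                                  b_semiaxes = c(5, 5),
                                  clearance = 4 * geometry$focus_sigma +
                                    max(b_semiaxes)) {
  stopifnot(inherits(geometry, "scene_geometry"))
  A <- roi_ellipse(geometry$center, geometry$semiaxes)
  # deterministic grid search: candidate centers on a lattice inside the
  # shrunken nucleus, ranked by distance to the nearest focus
  ax <- geometry$semiaxes - max(b_semiaxes) - 1
  gx <- seq(geometry$center[1] - ax[1], geometry$center[1] + ax[1], by = 2)
  gy <- seq(geometry$center[2] - ax[2], geometry$center[2] + ax[2], by = 2)
  cand <- expand.grid(x = gx, y = gy)
  inside <- ((cand$x - geometry$center[1]) / ax[1])^2 +
            ((cand$y - geometry$center[2]) / ax[2])^2 <= 1
  cand <- cand[inside, ]
  if (geometry$n_foci > 0) {
    dmin <- apply(cand, 1, function(p)
      min(sqrt((geometry$foci[, 1] - p[1])^2 +
               (geometry$foci[, 2] - p[2])^2)))
  } else dmin <- rep(Inf, nrow(cand))
  cand <- cand[order(-dmin), ]
  dmin <- sort(dmin, decreasing = TRUE)
  picked <- list()
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (length(picked) >= n) break
    if (dmin[i] < clearance) break
    p <- as.numeric(cand[i, ])
    if (nrow(centers) > 0 &&
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) <
          2.2 * max(b_semiaxes)) next
    picked[[length(picked) + 1L]] <- roi_ellipse(p, b_semiaxes)
    centers <- rbind(centers, p)
  }
  if (length(picked) < n)
    stopf("could not place %d foci-free regions with clearance %.1f px",
          n, clearance)
  # background: a corner rectangle clear of the nucleus
  bx <- geometry$center[1] - geometry$semiaxes[1]
  by <- geometry$center[2] - geometry$semiaxes[2]
  side <- max(6, floor(min(bx, by) - 2))
  if (side < 5)
    stopf("no room outside the nucleus for a background region")
  C <- roi_rect(0, 0, side, side)
  roi_set(A, picked, C)
}
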