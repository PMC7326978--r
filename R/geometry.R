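# Raster and polygon primitives shared by every other module.
#
# Conventions (fixed throughout the package):
#   * image frame: x rightward, y downward, 0-based pixel indices;
#   * a mask is a logical height x width matrix, mask[y + 1, x + 1];
#   * the pixel with integer coordinates (x, y) has its center at
#     (x + 0.5, y + 0.5) and occupies the unit square [x, x+1] x [y, y+1].

#' Construct a polygon outline
#'
#' A polygon outline is an ordered set of (x, y) vertices in the image frame
#' (x rightward, y downward, 0-based, closed implicitly). At least three
#' distinct vertices are required.
#'
#' @param x,y Numeric vectors of equal length with the vertex coordinates.
#' @return A numeric matrix with columns `x` and `y` and class
#'   `"polygon_outline"`.
#' @export
polygon_outline <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (anyNA(v)) stop("polygon vertices must be finite")
  if (nrow(unique(v)) < 3L) stop("degenerate polygon: fewer than 3 distinct vertices")
  structure(v, class = c("polygon_outline", class(v)))
}

#' Signed area of a polygon outline (shoelace; positive or negative)
#' @keywords internal
polygon_signed_area <- function(outline) {
  x <- outline[, 1]; y <- outline[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Rasterize a polygon onto a pixel frame
#'
#' A pixel is a member of the mask iff its center lies inside the polygon
#' (even-odd rule, half-open scanlines so results are deterministic and
#' adjacent polygons tile without double coverage). Vertices outside the
#' frame are allowed; the filled region is clipped to the frame. If nothing
#' survives clipping the empty mask is returned with attribute
#' `clipped_empty = TRUE`.
#'
#' @param outline A [polygon_outline()] (or a 2-column x,y matrix).
#' @param height,width Frame dimensions in pixels.
#' @return A logical `height x width` matrix (`mask[y + 1, x + 1]`).
#' @export
rasterize <- function(outline, height, width) {
  outline <- as_outline(outline)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("frame dimensions must be positive")
  mask <- matrix(FALSE, nrow = height, ncol = width)
  x <- outline[, 1]; y <- outline[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  keep <- y != y2                       # horizontal edges never cross a scanline
  if (any(keep)) {
    ex1 <- x[keep]; ey1 <- y[keep]; ex2 <- x2[keep]; ey2 <- y2[keep]
    ylo <- pmin(ey1, ey2); yhi <- pmax(ey1, ey2)
    j0 <- max(0L, floor(min(ylo) - 0.5))
    j1 <- min(height - 1L, ceiling(max(yhi)))
    if (j0 <= j1) {
      for (j in j0:j1) {
        yc <- j + 0.5
        hit <- ylo <= yc & yc < yhi     # half-open: vertex-on-scanline counted once
        if (!any(hit)) next
        xs <- ex1[hit] + (yc - ey1[hit]) * (ex2[hit] - ex1[hit]) / (ey2[hit] - ey1[hit])
        xs <- sort(xs)
        # fill between successive crossing pairs
        for (k in seq(1L, length(xs) - 1L, by = 2L)) {
          i0 <- max(0L, ceiling(xs[k] - 0.5))
          i1 <- min(width - 1L, ceiling(xs[k + 1L] - 0.5) - 1L)
          if (i0 <= i1) mask[j + 1L, (i0:i1) + 1L] <- TRUE
        }
      }
    }
  }
  if (!any(mask)) attr(mask, "clipped_empty") <- TRUE
  mask
}

as_outline <- function(p) {
  if (inherits(p, "polygon_outline")) return(p)
  if (is.matrix(p) && ncol(p) == 2L) return(polygon_outline(p[, 1], p[, 2]))
  stop("expected a polygon_outline or a 2-column (x, y) matrix")
}

check_same_frame <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks are on different frames: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

#' Mask intersection-over-union
#'
#' The area ratio between the intersection and the union of two binary
#' masks on a common frame. Two empty masks have no defined IoU.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return A ratio in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  check_same_frame(a, b)
  u <- sum(a | b)
  if (u == 0L) stop("IoU of two empty masks is undefined")
  sum(a & b) / u
}

#' Pixel count of the union of masks
#'
#' Overlapping pixels are counted once: this is the area `A` entering the
#' compactness ratio, where predicted masks of touching berries may overlap.
#'
#' @param masks A non-empty list of logical matrices on a common frame.
#' @return Integer pixel count.
#' @export
union_area <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) stop("need at least one mask")
  u <- masks[[1]]
  if (length(masks) > 1L) for (m in masks[-1]) {
    check_same_frame(u, m)
    u <- u | m
  }
  sum(u)
}

#' Corner points of all member pixels of a mask
#'
#' Each member pixel contributes its four unit-square corners, so that an
#' enclosing rectangle of the returned points contains the full rasterized
#' area (not just pixel centers).
#'
#' @param mask Logical matrix.
#' @return A 2-column (x, y) matrix of corner coordinates.
#' @export
mask_corner_points <- function(mask) {
  if (!any(mask)) stop("empty mask has no corner points")
  # corners of the row-extreme (leftmost/rightmost per row) member pixels:
  # at every horizontal level the x-extremes of the full corner set come
  # from these pixels, so their corners have the same convex hull as the
  # corners of all member pixels
  rows <- which(rowSums(mask) > 0L)
  xmin <- xmax <- integer(length(rows))
  for (k in seq_along(rows)) {
    cc <- which(mask[rows[k], ])
    xmin[k] <- cc[1L]; xmax[k] <- cc[length(cc)]
  }
  x <- c(xmin, xmax) - 1L; y <- rep(rows, 2L) - 1L   # 0-based pixel coords
  unique(cbind(x = c(x, x + 1L, x, x + 1L),
               y = c(y, y, y + 1L, y + 1L)))
}

#' Minimum-area enclosing rotated rectangle
#'
#' The smallest-area rectangle, over all orientations, enclosing a point
#' set; found by the rotating-calipers property that the optimum is flush
#' with an edge of the convex hull. The result is invariant (in area) to
#' rotation of the input.
#'
#' The rectangle is reported canonically with `w >= h` and `angle` the
#' orientation of the rectangle's axis pair in degrees, reduced to
#' `[0, 90)`; an axis-aligned rectangle reports angle 0.
#'
#' @param points A 2-column (x, y) matrix with at least 3 non-collinear
#'   points, e.g. from [mask_corner_points()].
#' @return A list of class `"rotated_rect"` with elements `center`
#'   (length-2), `w`, `h` (`w >= h`), `angle` (degrees in `[0, 90)`),
#'   `long_axis` (exact direction of the `w` side in `[0, 180)`, used for
#'   corner reconstruction) and `area`.
#' @export
min_area_rect <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L) stop("points must be a 2-column matrix")
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(unique(points)) < 3L) stop("need at least 3 distinct points")
  h <- grDevices::chull(points)
  hull <- points[h, , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate (collinear) point set")
  nh <- nrow(hull)
  e1 <- hull
  e2 <- hull[c(2:nh, 1L), , drop = FALSE]
  dx <- e2[, 1] - e1[, 1]; dy <- e2[, 2] - e1[, 2]
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  ct <- dx[ok] / len[ok]; st <- dy[ok] / len[ok]
  # coordinates of every hull vertex in each edge-aligned frame
  px <- hull[, 1]; py <- hull[, 2]
  u <- outer(ct, px) + outer(st, py)        # edges x vertices
  v <- outer(-st, px) + outer(ct, py)
  w_all <- apply(u, 1L, max) - apply(u, 1L, min)
  h_all <- apply(v, 1L, max) - apply(v, 1L, min)
  areas <- w_all * h_all
  k <- which.min(areas)
  umin <- min(u[k, ]); umax <- max(u[k, ])
  vmin <- min(v[k, ]); vmax <- max(v[k, ])
  ctk <- ct[k]; stk <- st[k]
  cu <- (umin + umax) / 2; cv <- (vmin + vmax) / 2
  center <- c(x = ctk * cu - stk * cv, y = stk * cu + ctk * cv)
  we <- umax - umin; he <- vmax - vmin       # extent along edge / perpendicular
  ang <- atan2(stk, ctk) * 180 / pi          # edge direction
  if (we < he) { tmp <- we; we <- he; he <- tmp; ang <- ang + 90 }
  long_axis <- ang %% 180                    # exact direction of the w side
  structure(list(center = center, w = we, h = he,
                 angle = long_axis %% 90,    # canonical axis-pair orientation
                 long_axis = long_axis, area = we * he),
            class = "rotated_rect")
}

#' @export
print.rotated_rect <- function(x, ...) {
  cat(sprintf("rotated_rect: center (%.2f, %.2f), %.2f x %.2f, angle %.2f deg, area %.2f\n",
              x$center[1], x$center[2], x$w, x$h, x$angle, x$area))
  invisible(x)
}

#' Corner coordinates of a rotated rectangle
#' @param rect A `"rotated_rect"`.
#' @return A 4 x 2 (x, y) matrix.
#' @export
rect_corners <- function(rect) {
  a <- rect$long_axis * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  half <- rbind(c(-rect$w, -rect$h), c(rect$w, -rect$h),
                c(rect$w, rect$h), c(-rect$w, rect$h)) / 2
  sweep(half %*% t(R), 2L, rect$center, "+")
}

#' Erode a binary mask with a Euclidean disk
#'
#' Morphological erosion with a disk structuring element of the given
#' radius, computed via the Euclidean distance transform: a pixel survives
#' iff its distance to the nearest background pixel exceeds the radius.
#' Pixels outside the frame count as background. If erosion would empty the
#' mask entirely the original mask is returned with attribute
#' `eroded = FALSE`, so that small objects still receive a color decision.
#'
#' @param mask Logical matrix.
#' @param radius Erosion radius in pixels, `>= 0`.
#' @return A logical matrix with attribute `eroded` (`TRUE` if erosion was
#'   applied, `FALSE` if the vanishing fallback triggered).
#' @export
erode_mask <- function(mask, radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 0) stop("radius must be >= 0")
  if (radius == 0 || !any(mask)) {
    attr(mask, "eroded") <- TRUE
    return(mask)
  }
  # crop to bounding box (+1 px background collar) before the distance
  # transform; keeps per-berry erosion cheap on large frames
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 1L); r1 <- min(nrow(mask), max(idx[, 1]) + 1L)
  c0 <- max(1L, min(idx[, 2]) - 1L); c1 <- min(ncol(mask), max(idx[, 2]) + 1L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  # explicit background collar: pixels beyond the frame are background
  pad <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  dm <- EBImage::distmap(EBImage::Image(pad * 1), metric = "euclidean")
  er <- EBImage::imageData(dm)[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L), drop = FALSE] > radius
  if (!any(er)) {
    attr(mask, "eroded") <- FALSE
    return(mask)
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[r0:r1, c0:c1] <- er
  attr(out, "eroded") <- TRUE
  out
}
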