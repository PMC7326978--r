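# Synthetic berry-cluster scenes with exact ground truth.
#
# Branches carry 5-25 partially occluding berries in a few clusters,
# imaged against an artificial background; occlusion comes from z-order:
# the visible mask of a berry is its disk minus the union of the disks in
# front of it. Berries are rendered as colored disks — the generator
# exercises the geometry and color logic of the pipeline, not
# photorealism. Mature berries take Hues in the red-purple ranges
# (0, 30) u (150, 180) on the 0-180 scale; immature berries sit in the
# green band (35, 100).

#' Scene generator parameters
#'
#' Defaults emulate the study conditions: branches of 5-25 berries in 1-4
#' clusters, five views per branch, partial occlusion, mature/immature
#' colors separable by Hue.
#'
#' @param width,height Image size in pixels.
#' @param n_berries Berry count, or a length-2 range sampled uniformly.
#' @param radius_mean,radius_sd Berry radius distribution (pixels; normal,
#'   truncated at `radius_min`).
#' @param radius_min Smallest allowed radius.
#' @param n_clusters Cluster count, or a length-2 range.
#' @param cluster_spread Within-cluster placement spread (pixels, normal sd).
#' @param overlap Occlusion intensity in `[0, 1]`: 0 forces disjoint
#'   berries; larger values allow centers as close as
#'   `(1 - overlap) * (r_i + r_j)`.
#' @param p_mature Probability a berry is mature.
#' @param hue_mature Two `(lo, hi)` Hue bands (length-4 vector) for mature
#'   berries on the 0-180 scale, sampled uniformly over their union.
#' @param hue_immature `(lo, hi)` Hue band for immature berries.
#' @param sat_range,val_range HSV saturation/value ranges for berry colors.
#' @param background RGB triple in `[0, 1]` for the artificial background.
#' @param color_noise Per-pixel Gaussian RGB noise sd (0 = clean colors).
#' @param outline_vertices Vertex count of the polygonal full outlines.
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(width = 320, height = 320,
                         n_berries = c(5, 25),
                         radius_mean = 22, radius_sd = 3, radius_min = 8,
                         n_clusters = c(1, 4), cluster_spread = 40,
                         overlap = 0.3,
                         p_mature = 0.5,
                         hue_mature = c(2, 28, 152, 178),
                         hue_immature = c(40, 95),
                         sat_range = c(0.55, 0.9), val_range = c(0.45, 0.9),
                         background = c(0.85, 0.84, 0.80),
                         color_noise = 0.02,
                         outline_vertices = 40) {
  stopifnot(width >= 32, height >= 32, overlap >= 0, overlap <= 1,
            p_mature >= 0, p_mature <= 1, radius_min > 0,
            length(hue_mature) == 4L, length(hue_immature) == 2L)
  # class Hue supports must be disjoint
  if (hue_immature[1] < hue_mature[2] && hue_mature[1] < hue_immature[2] ||
      hue_immature[1] < hue_mature[4] && hue_mature[3] < hue_immature[2])
    stop("mature and immature Hue supports overlap")
  structure(as.list(environment()), class = "scene_params")
}

# Restore the caller's RNG state afterwards; all generator randomness goes
# through this so scenes are bit-reproducible from (params, seed).
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

sample_range <- function(x) {
  if (length(x) == 1L) return(as.integer(x))
  sample(seq.int(x[1], x[2]), 1L)
}

disk_mask <- function(cx, cy, r, height, width) {
  m <- matrix(FALSE, height, width)
  x0 <- max(0L, floor(cx - r)); x1 <- min(width - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(height - 1L, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1 + 0.5; ys <- y0:y1 + 0.5
  sub <- outer(ys - cy, xs - cx, function(dy, dx) dy^2 + dx^2) <= r^2
  m[(y0:y1) + 1L, (x0:x1) + 1L] <- sub
  m
}

circle_outline <- function(cx, cy, r, k) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  polygon_outline(cx + r * cos(th), cy + r * sin(th))
}

# sample one berry set (shared across the views of a branch sample)
draw_berry_set <- function(params) {
  n <- sample_range(params$n_berries)
  n_c <- min(sample_range(params$n_clusters), n)
  radii <- pmax(params$radius_min,
                stats::rnorm(n, params$radius_mean, params$radius_sd))
  labels <- ifelse(stats::runif(n) < params$p_mature, "mature", "immature")
  hues <- vapply(labels, function(l) {
    if (l == "mature") {
      b <- params$hue_mature
      w1 <- b[2] - b[1]; w2 <- b[4] - b[3]
      if (stats::runif(1) < w1 / (w1 + w2)) stats::runif(1, b[1], b[2])
      else stats::runif(1, b[3], b[4])
    } else stats::runif(1, params$hue_immature[1], params$hue_immature[2])
  }, numeric(1))
  sat <- stats::runif(n, params$sat_range[1], params$sat_range[2])
  val <- stats::runif(n, params$val_range[1], params$val_range[2])
  cluster <- sample.int(n_c, n, replace = TRUE)
  # every cluster keeps at least one berry
  for (c_ in seq_len(n_c)) if (!any(cluster == c_)) cluster[sample.int(n, 1L)] <- c_
  list(n = n, n_clusters = n_c, radii = radii, labels = labels,
       hue = hues, sat = sat, val = val, cluster = cluster)
}

place_berries <- function(set, params, max_tries = 400L) {
  w <- params$width; h <- params$height
  margin <- max(set$radii) + 1
  lo <- margin + params$cluster_spread
  ccx <- stats::runif(set$n_clusters, lo, max(lo + 1, w - lo))
  ccy <- stats::runif(set$n_clusters, lo, max(lo + 1, h - lo))
  px <- numeric(set$n); py <- numeric(set$n)
  min_gap <- (1 - params$overlap)
  for (i in seq_len(set$n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      # widen the cluster gradually when the neighborhood is saturated
      spread <- params$cluster_spread * (1 + (try - 1) / 50)
      x <- ccx[set$cluster[i]] + stats::rnorm(1, 0, spread)
      y <- ccy[set$cluster[i]] + stats::rnorm(1, 0, spread)
      x <- min(max(x, margin), w - margin)
      y <- min(max(y, margin), h - margin)
      if (i == 1L) { ok <- TRUE } else {
        d <- sqrt((px[1:(i - 1L)] - x)^2 + (py[1:(i - 1L)] - y)^2)
        need <- min_gap * (set$radii[1:(i - 1L)] + set$radii[i])
        ok <- all(d >= need)
      }
      if (ok) { px[i] <- x; py[i] <- y; break }
    }
    if (!ok) stop("could not place berry ", i, " within the frame; ",
                  "reduce berry count/radius or raise overlap")
  }
  list(x = px, y = py)
}

#' Generate one synthetic berry-cluster scene
#'
#' Berries are placed around cluster centers, given a random z-order, and
#' rendered back to front; the visible mask of each berry is its disk
#' minus the union of the disks in front of it (so a partially occluded
#' berry may have a disconnected visible mask, kept as one instance).
#' Fully occluded berries stay in the ground truth flagged invisible.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed; the scene is bit-reproducible from
#'   `(params, seed)`.
#' @param berry_set,placement Internal overrides used by
#'   [generate_branch_sample()] to share one berry set across views.
#' @return A list of class `"synthetic_scene"`: `image` (H x W x 3 array),
#'   `berries` (per-berry records: center, radius, label, hue, z_rank,
#'   `full_outline`, `visible_mask`, `visible`), `N_t`, `N_m`, `params`,
#'   `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L,
                           berry_set = NULL, placement = NULL) {
  with_seed(seed, {
    set <- if (is.null(berry_set)) draw_berry_set(params) else berry_set
    pos <- if (is.null(placement)) place_berries(set, params) else placement
    n <- set$n
    h <- params$height; w <- params$width
    z <- sample.int(n)                       # higher rank = closer to camera
    disks <- lapply(seq_len(n), function(i)
      disk_mask(pos$x[i], pos$y[i], set$radii[i], h, w))
    front_union <- matrix(FALSE, h, w)
    visible <- vector("list", n)
    for (i in order(z, decreasing = TRUE)) { # frontmost first
      visible[[i]] <- disks[[i]] & !front_union
      front_union <- front_union | disks[[i]]
    }
    chan <- lapply(params$background, function(b) rep(b, h * w))
    rgbcol <- grDevices::col2rgb(grDevices::hsv(set$hue / 180, set$sat, set$val)) / 255
    for (i in order(z)) {                    # paint back to front
      sel <- which(disks[[i]])
      if (!length(sel)) next
      for (ch in 1:3) {
        v <- rgbcol[ch, i]
        if (params$color_noise > 0)
          v <- pmin(1, pmax(0, v + stats::rnorm(length(sel), 0, params$color_noise)))
        chan[[ch]][sel] <- v
      }
    }
    img <- array(c(chan[[1]], chan[[2]], chan[[3]]), dim = c(h, w, 3))
    berries <- lapply(seq_len(n), function(i) {
      list(id = i, x = pos$x[i], y = pos$y[i], radius = set$radii[i],
           label = set$labels[i], hue = set$hue[i], z_rank = z[i],
           full_outline = circle_outline(pos$x[i], pos$y[i], set$radii[i],
                                         params$outline_vertices),
           visible_mask = visible[[i]],
           visible = any(visible[[i]]))
    })
    structure(list(image = img, berries = berries,
                   N_t = n, N_m = sum(set$labels == "mature"),
                   n_clusters = set$n_clusters,
                   params = params, seed = seed),
              class = "synthetic_scene")
  })
}

#' Ground-truth detection instances of a scene
#'
#' @param scene A `"synthetic_scene"`.
#' @param image_id Image identifier for the instances.
#' @param visible_only Drop fully occluded berries (the default; a 2D
#'   detector cannot see them).
#' @param as_polygon Use the full circular outlines instead of the visible
#'   raster masks (amodal ground truth, e.g. for VIA export).
#' @return A list of [detection_instance()]s without scores.
#' @export
scene_gt_instances <- function(scene, image_id = "scene.png",
                               visible_only = TRUE, as_polygon = FALSE) {
  keep <- if (visible_only) Filter(function(b) b$visible, scene$berries)
          else scene$berries
  lapply(keep, function(b)
    detection_instance(image_id,
                       if (as_polygon) b$full_outline else b$visible_mask,
                       b$label))
}

#' Generate a branch sample: several views of one berry set
#'
#' The five views of a branch share the same berries (count, radii,
#' labels, colors, cluster count) but are re-projected independently:
#' placements and z-orders are re-sampled per view, so per-view visibility
#' varies while the sample ground truth `N_t`, `N_c` is fixed.
#'
#' @param params A [scene_params()].
#' @param n_views Number of views (default 5, covering the branch).
#' @param seed Integer seed.
#' @return A list of class `"branch_sample"`: `views` (list of scenes),
#'   `N_t`, `N_m`, `N_c`, `seed`.
#' @export
generate_branch_sample <- function(params = scene_params(), n_views = 5L,
                                   seed = 1L) {
  set <- with_seed(seed, draw_berry_set(params))
  views <- lapply(seq_len(n_views), function(v)
    generate_scene(params, seed = (seed * 131L + v) %% .Machine$integer.max,
                   berry_set = set))
  structure(list(views = views, N_t = set$n,
                 N_m = sum(set$labels == "mature"),
                 N_c = set$n_clusters, seed = seed),
            class = "branch_sample")
}

#' Perturb a scene's ground truth into imperfect detections
#'
#' Reproduces the four detection-error modes, plus label noise, at
#' controlled rates. Each visible berry independently suffers at most one
#' event:
#'
#' * `drop` — no detection emitted (missed detection);
#' * `split` — the visible mask is cut into two pieces separated by a gap
#'   strip (one berry detected as two);
#' * `merge` — the berry and its nearest visible neighbor are replaced by
#'   a single blob, the convex hull of their visible masks (two berries
#'   detected as one);
#' * `jitter` — the visible mask is translated by `jitter_px` pixels in a
#'   random direction (partial detection when the shift is large);
#' * `relabel` — the maturity label is flipped.
#'
#' Unperturbed detections receive scores in `[0.9, 1]`, perturbed ones in
#' `[0.5, 0.9)`.
#'
#' @param scene A `"synthetic_scene"`.
#' @param rates Named numeric: `drop`, `split`, `merge`, `jitter`,
#'   `relabel`; each in `[0, 1]` and summing to at most 1.
#' @param jitter_px Translation magnitude in pixels for `jitter` events.
#' @param seed Integer seed.
#' @param image_id Image identifier for the detections.
#' @return A list of scored [detection_instance()]s.
#' @export
perturb_to_detections <- function(scene,
                                  rates = c(drop = 0, split = 0, merge = 0,
                                            jitter = 0, relabel = 0),
                                  jitter_px = 0, seed = 1L,
                                  image_id = "scene.png") {
  full <- c(drop = 0, split = 0, merge = 0, jitter = 0, relabel = 0)
  full[names(rates)] <- rates
  rates <- full
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  if (sum(rates) > 1) stop("per-instance event rates sum to more than 1")
  if (jitter_px < 0) stop("jitter_px must be >= 0")
  vis <- Filter(function(b) b$visible, scene$berries)
  h <- scene$params$height; w <- scene$params$width
  with_seed(seed, {
    n <- length(vis)
    events <- vapply(seq_len(n), function(i) {
      u <- stats::runif(1)
      cum <- cumsum(rates)
      if (u < cum[1]) "drop"
      else if (u < cum[2]) "split"
      else if (u < cum[3]) "merge"
      else if (u < cum[4]) "jitter"
      else if (u < cum[5]) "relabel"
      else "none"
    }, character(1))
    consumed <- rep(FALSE, n)
    out <- list()
    emit <- function(mask, label, perturbed) {
      score <- if (perturbed) stats::runif(1, 0.5, 0.9) else stats::runif(1, 0.9, 1.0)
      out[[length(out) + 1L]] <<- detection_instance(image_id, mask, label, score)
    }
    for (i in seq_len(n)) {
      if (consumed[i]) next
      b <- vis[[i]]
      ev <- events[i]
      if (ev == "merge") {
        # nearest unconsumed visible neighbor; degenerate to none if alone
        others <- setdiff(which(!consumed), i)
        if (length(others) == 0L) ev <- "none"
      }
      consumed[i] <- TRUE
      switch(ev,
        drop = NULL,
        split = {
          pieces <- split_mask(b$visible_mask,
                               gap = max(3L, round(b$radius / 4)))
          if (length(pieces) == 2L) {
            emit(pieces[[1]], b$label, TRUE)
            emit(pieces[[2]], b$label, TRUE)
          } else emit(b$visible_mask, b$label, FALSE)
        },
        merge = {
          others <- setdiff(which(!consumed), i)
          d <- vapply(others, function(j)
            (vis[[j]]$x - b$x)^2 + (vis[[j]]$y - b$y)^2, numeric(1))
          j <- others[which.min(d)]
          consumed[j] <- TRUE
          blob <- hull_mask(b$visible_mask | vis[[j]]$visible_mask)
          emit(blob, b$label, TRUE)
        },
        jitter = {
          th <- stats::runif(1, 0, 2 * pi)
          m <- translate_mask(b$visible_mask,
                              round(jitter_px * cos(th)),
                              round(jitter_px * sin(th)))
          if (any(m)) emit(m, b$label, TRUE)
        },
        relabel = emit(b$visible_mask,
                       if (b$label == "mature") "immature" else "mature", TRUE),
        none = emit(b$visible_mask, b$label, FALSE))
    }
    out
  })
}

# cut a mask in two along a random line through its centroid, removing a
# gap strip so neither piece reaches IoU 0.5 with the original
split_mask <- function(mask, gap = 3L) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  th <- stats::runif(1, 0, pi)
  # signed distance of each member pixel to the cut line
  d <- (idx[, 2] - cx) * cos(th) + (idx[, 1] - cy) * sin(th)
  a <- mask; a[] <- FALSE; b <- a
  a[idx[d <= -gap / 2, , drop = FALSE]] <- TRUE
  b[idx[d >= gap / 2, , drop = FALSE]] <- TRUE
  pieces <- Filter(any, list(a, b))
  pieces
}

# convex hull of a mask's member pixels, rasterized back to the frame
hull_mask <- function(mask) {
  pts <- mask_corner_points(mask)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  rasterize(polygon_outline(hull[, 1], hull[, 2]), nrow(mask), ncol(mask))
}

translate_mask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h; ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

#' Write a scene's image as PNG
#' @param scene A `"synthetic_scene"`.
#' @param path Output path.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image, path)
  invisible(path)
}
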