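# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form and
# never call the implementation paths they check.

# brute-force rasterizer: even-odd crossing test at every pixel center
brute_rasterize <- function(xs, ys, height, width) {
  m <- matrix(FALSE, height, width)
  n <- length(xs)
  for (j in 0:(height - 1L)) for (i in 0:(width - 1L)) {
    px <- i + 0.5; py <- j + 0.5
    inside <- FALSE
    k2 <- n
    for (k in 1:n) {
      if ((ys[k] > py) != (ys[k2] > py)) {
        xint <- xs[k] + (py - ys[k]) * (xs[k2] - xs[k]) / (ys[k2] - ys[k])
        if (px < xint) inside <- !inside
      }
      k2 <- k
    }
    m[j + 1L, i + 1L] <- inside
  }
  m
}

# minimum-area rectangle by dense angle sweep (step in degrees)
sweep_min_rect_area <- function(points, step = 0.01) {
  th <- seq(0, 90 - step, by = step) * pi / 180
  A <- cbind(cos(th), sin(th))
  B <- cbind(-sin(th), cos(th))
  u <- A %*% t(points)                      # angles x points
  v <- B %*% t(points)
  du <- do.call(pmax, as.data.frame(u)) - do.call(pmin, as.data.frame(u))
  dv <- do.call(pmax, as.data.frame(v)) - do.call(pmin, as.data.frame(v))
  min(du * dv)
}

rotate_points <- function(points, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  points %*% t(R)
}

# axis-aligned square instance helpers on a shared frame
square_mask <- function(x0, y0, side_x, side_y = side_x, height = 64, width = 64) {
  m <- matrix(FALSE, height, width)
  m[(y0 + 1):(y0 + side_y), (x0 + 1):(x0 + side_x)] <- TRUE
  m
}

square_inst <- function(x0, y0, side_x, side_y = side_x, label = "mature",
                        score = NA_real_, image = "img", height = 64, width = 64) {
  detection_instance(image, square_mask(x0, y0, side_x, side_y, height, width),
                     label, score)
}

disk_inst <- function(cx, cy, r, label = "mature", score = NA_real_,
                      image = "img", height = 128, width = 128) {
  d <- outer(seq_len(height) - 0.5 - cy, seq_len(width) - 0.5 - cx,
             function(dy, dx) dx^2 + dy^2) <= r^2
  detection_instance(image, d, label, score)
}

# exhaustive prefix-enumeration AP oracle: greedy same-class matching by
# descending score, every prefix of the sorted list becomes a PR point,
# AP integrates max precision at equal-or-higher recall
oracle_ap <- function(preds, gts, class, iou_threshold, height, width) {
  keep_p <- vapply(preds, function(p) p$label == class, logical(1))
  keep_g <- vapply(gts, function(g) g$label == class, logical(1))
  p <- preds[keep_p]; g <- gts[keep_g]
  n_gt <- length(g)
  stopifnot(n_gt > 0L)
  if (length(p) == 0L) return(0)
  s <- vapply(p, function(x) x$score, numeric(1))
  p <- p[order(-s)]
  pim <- vapply(p, function(x) x$image, character(1))
  gim <- vapply(g, function(x) x$image, character(1))
  gm <- lapply(g, function(x) instance_mask(x, height, width))
  taken <- rep(FALSE, n_gt)
  is_tp <- logical(length(p))
  for (i in seq_along(p)) {
    m <- instance_mask(p[[i]], height, width)
    best <- 0; bj <- 0L
    for (j in seq_len(n_gt)) {
      if (taken[j] || gim[j] != pim[i]) next
      if (!any(m | gm[[j]])) next
      v <- sum(m & gm[[j]]) / sum(m | gm[[j]])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0L && best >= iou_threshold) { is_tp[i] <- TRUE; taken[bj] <- TRUE }
  }
  prec <- rec <- numeric(length(p))
  for (k in seq_along(p)) {                  # every prefix
    tp <- sum(is_tp[1:k])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  ap <- 0; prev_r <- 0
  for (k in seq_along(p)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * max(prec[k:length(p)])
      prev_r <- rec[k]
    }
  }
  ap
}

# exact (float, unquantized) HSV -> RGB for boundary-accurate Hue fixtures;
# h on the 0-180 half-degree scale
hsv_rgb_exact <- function(h180, s, v) {
  hp <- (h180 * 2) / 60
  c_ <- v * s
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  rgb1 <- if (hp < 1) c(c_, x, 0) else if (hp < 2) c(x, c_, 0) else
          if (hp < 3) c(0, c_, x) else if (hp < 4) c(0, x, c_) else
          if (hp < 5) c(x, 0, c_) else c(c_, 0, x)
  rgb1 + m
}

# taxonomy fixture: isolates one perturbation mode on equal, disjoint berries
taxonomy_params <- function() {
  scene_params(radius_sd = 0, overlap = 0, color_noise = 0,
               n_berries = c(5, 12))
}
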