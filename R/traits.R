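# Per-view fruit traits and their aggregation across the five views of a
# branch sample:
#
#   N_b          number of detected berries in the view
#   N_m          number of those labeled mature
#   maturity     N_m / N_b
#   A            pixel area of the union of all berry masks
#   A_b          area of the minimum-area rotated rectangle enclosing them
#   compactness  A / A_b, in (0, 1] — a proxy for cluster tightness
#
# plus the objective per-berry maturity call from HSV Hue.

#' Count detected berries in a view
#' @param view A list of [detection_instance()]s from one image.
#' @return Integer count `N_b`.
#' @export
count_berries <- function(view) length(view)

#' Mature fraction of the detected berries in a view
#'
#' The ratio of mature-labeled instances (`N_m`) over all detected
#' instances (`N_b`). Undefined on an empty view.
#'
#' @param view A non-empty list of [detection_instance()]s.
#' @return Ratio in `[0, 1]`.
#' @export
maturity_ratio <- function(view) {
  if (length(view) == 0L) stop("maturity is undefined for a view with no detections")
  sum(vapply(view, function(d) d$label == "mature", logical(1))) / length(view)
}

#' Objective per-berry maturity from Hue
#'
#' Classifies one berry from image color rather than its annotation label.
#' The mask boundary is first eroded (default 10 px) to remove background
#' and neighboring-berry pixels near the edge; Hue is computed from RGB on
#' the 0-180 half-degree scale, ignoring saturation and illumination. The
#' berry is called mature iff more than half of the eroded-mask pixels
#' have Hue strictly inside (0, 30) or (150, 180) — the red-to-purple
#' range of ripe fruit; green immature fruit falls near (35, 100).
#'
#' If erosion would erase the mask completely the original mask is used,
#' so small berries still receive a decision.
#'
#' @param image RGB array `height x width x 3`, values in `[0, 1]`.
#' @param instance A [detection_instance()] whose mask lies in the frame.
#' @param erosion_radius Boundary erosion in pixels.
#' @param mature_hue Length-4 numeric `(lo1, hi1, lo2, hi2)`: Hue is
#'   mature-colored when in `(lo1, hi1)` or `(lo2, hi2)` (strict).
#' @return `"mature"` or `"immature"`.
#' @export
hue_maturity <- function(image, instance, erosion_radius = 10,
                         mature_hue = c(0, 30, 150, 180)) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be an RGB array")
  h <- dim(image)[1]; w <- dim(image)[2]
  mask <- instance_mask(instance, h, w)
  if (!any(mask)) stop("instance mask lies entirely outside the image")
  mask <- erode_mask(mask, erosion_radius)
  rgb <- rbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  hue <- grDevices::rgb2hsv(rgb, maxColorValue = 1)[1, ] * 180
  inside <- (hue > mature_hue[1] & hue < mature_hue[2]) |
            (hue > mature_hue[3] & hue < mature_hue[4])
  if (mean(inside) > 0.5) "mature" else "immature"
}

#' Cluster compactness of a view
#'
#' `A` is the union area of all instance masks (overlap counted once);
#' `A_b` is the area of the minimum-area rotated rectangle enclosing every
#' member pixel (pixel squares, not centers, so the masks are geometrically
#' contained); compactness is `A / A_b`.
#'
#' @param view A non-empty list of [detection_instance()]s.
#' @param height,width Frame dimensions in pixels.
#' @return A list with `A`, `A_b`, `compactness` and the enclosing `rect`.
#' @export
compactness <- function(view, height, width) {
  if (length(view) == 0L) stop("compactness is undefined for an empty view")
  masks <- lapply(view, instance_mask, height = height, width = width)
  if (any(!vapply(masks, any, logical(1)))) stop("compactness requires nonempty masks")
  u <- masks[[1]]
  if (length(masks) > 1L) for (m in masks[-1]) u <- u | m
  A <- sum(u)
  rect <- min_area_rect(mask_corner_points(u))
  list(A = A, A_b = rect$area, compactness = A / rect$area, rect = rect)
}

#' Per-view trait record
#'
#' Computes all traits of one view in one pass.
#'
#' @inheritParams compactness
#' @param sample_id,cultivar,view_id Identification columns for the output
#'   row.
#' @return A one-row data.frame with columns `sample_id`, `cultivar`,
#'   `view`, `N_b`, `N_m`, `maturity`, `A`, `A_b`, `compactness`.
#' @export
view_traits <- function(view, height, width, sample_id = NA_character_,
                        cultivar = NA_character_, view_id = NA_integer_) {
  n_b <- count_berries(view)
  if (n_b == 0L)
    return(data.frame(sample_id = sample_id, cultivar = cultivar,
                      view = as.character(view_id), N_b = 0L, N_m = 0L,
                      maturity = NA_real_, A = NA_real_, A_b = NA_real_,
                      compactness = NA_real_))
  n_m <- sum(vapply(view, function(d) d$label == "mature", logical(1)))
  cp <- compactness(view, height, width)
  data.frame(sample_id = sample_id, cultivar = cultivar,
             view = as.character(view_id), N_b = n_b, N_m = as.integer(n_m),
             maturity = n_m / n_b, A = cp$A, A_b = cp$A_b,
             compactness = cp$compactness)
}

#' Aggregate per-view traits to the branch sample
#'
#' Sample traits are the unweighted arithmetic means of the per-view
#' berry count, maturity and compactness (views cover the branch over
#' 360 degrees; no view is privileged). The per-view rows are retained and
#' one `view = "mean"` row is appended per sample.
#'
#' @param records A data.frame of [view_traits()] rows (>= 1 view per
#'   sample).
#' @return A data.frame with the input rows plus one aggregated row per
#'   sample.
#' @export
aggregate_sample <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("need at least one per-view trait record")
  agg <- do.call(rbind, lapply(split(records, records$sample_id), function(g) {
    data.frame(sample_id = g$sample_id[1], cultivar = g$cultivar[1],
               view = "mean",
               N_b = mean(g$N_b), N_m = mean(g$N_m),
               maturity = mean(g$maturity), A = mean(g$A), A_b = mean(g$A_b),
               compactness = mean(g$compactness))
  }))
  out <- rbind(records, agg)
  rownames(out) <- NULL
  out
}

#' Write the traits table as CSV
#' @param traits A data.frame from [aggregate_sample()] (or [view_traits()]).
#' @param path Output CSV path.
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
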