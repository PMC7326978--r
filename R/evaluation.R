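# Segmentation-quality evaluation: greedy score-ordered matching of
# predictions to ground truth by mask IoU, per-class average precision
# over a grid of IoU thresholds (0.50 to 0.95, step 0.05), mean IoU of the
# matched pairs, and the four-way detection-error taxonomy
# (one-as-two, missed, two-as-one, partial).
#
# Rasters are only needed to compute the per-image IoU matrices and error
# tallies; everything downstream (matching, AP, mAP, mIOU) works on those
# summaries, so datasets of hundreds of images never hold all masks at
# once.

#' Pairwise IoU matrix between two instance sets on one frame
#' @keywords internal
iou_matrix <- function(preds, gts, height, width) {
  pm <- lapply(preds, instance_mask, height = height, width = width)
  gm <- lapply(gts, instance_mask, height = height, width = width)
  iou_matrix_masks(pm, gm)
}

iou_matrix_masks <- function(pm, gm) {
  M <- matrix(0, length(pm), length(gm))
  if (length(pm) && length(gm)) {
    pidx <- lapply(pm, which)
    gidx <- lapply(gm, which)
    pa <- lengths(pidx); ga <- lengths(gidx)
    for (i in seq_along(pm)) for (j in seq_along(gm)) {
      inter <- length(intersect(pidx[[i]], gidx[[j]]))
      if (inter > 0L) M[i, j] <- inter / (pa[i] + ga[j] - inter)
    }
  }
  M
}

#' Match predictions to ground truth at one IoU threshold
#'
#' Predictions are processed in descending confidence order (ties broken
#' by the larger available IoU, then by stable input order); each is
#' assigned to the unmatched ground truth with the highest IoU — of the
#' same class when `class_aware` — provided that IoU reaches the
#' threshold. Unassigned predictions are false positives; unassigned
#' ground truths are false negatives.
#'
#' @param preds Predictions (scored [detection_instance()]s) on one image.
#' @param gts Ground-truth instances on the same image.
#' @param iou_threshold Matching threshold in `(0, 1]`.
#' @param class_aware Restrict matches to equal labels (default `TRUE`).
#' @param height,width Frame dimensions.
#' @param iou Optional precomputed IoU matrix (`length(preds)` x
#'   `length(gts)`).
#' @return A list of class `"match_result"`: data.frame `pairs`
#'   (`pred`, `gt`, `iou` indices), integer vectors `fp` (unmatched
#'   prediction indices) and `fn` (unmatched ground-truth indices), and
#'   the threshold.
#' @export
match_instances <- function(preds, gts, iou_threshold, class_aware = TRUE,
                            height = NULL, width = NULL, iou = NULL) {
  if (iou_threshold <= 0 || iou_threshold > 1) stop("iou_threshold must be in (0, 1]")
  scores <- vapply(preds, function(p) p$score, numeric(1))
  if (length(preds) && anyNA(scores)) stop("predictions must carry confidence scores")
  if (is.null(iou)) {
    if (is.null(height) || is.null(width)) stop("supply frame dimensions or an IoU matrix")
    iou <- iou_matrix(preds, gts, height, width)
  }
  plab <- vapply(preds, function(p) p$label, character(1))
  glab <- vapply(gts, function(g) g$label, character(1))
  best_iou <- if (length(gts)) apply(iou, 1L, max) else rep(0, length(preds))
  ord <- order(-scores, -best_iou, seq_along(preds))
  gt_free <- rep(TRUE, length(gts))
  pairs <- list()
  fp <- integer(0)
  for (i in ord) {
    cand <- which(gt_free & iou[i, ] >= iou_threshold &
                    (!class_aware | glab == plab[i]))
    if (length(cand) == 0L) {
      fp <- c(fp, i)
      next
    }
    j <- cand[which.max(iou[i, cand])]
    gt_free[j] <- FALSE
    pairs[[length(pairs) + 1L]] <- data.frame(pred = i, gt = j, iou = iou[i, j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  structure(list(pairs = pairs, fp = sort(fp), fn = which(gt_free),
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' Mean IoU of matched (true-positive) pairs
#'
#' Measures mask shape accuracy independent of detection accuracy:
#' the arithmetic mean IoU over true-positive pairs only.
#'
#' @param match A `"match_result"`, or a list of them (pairs pooled).
#' @return Ratio in `[0, 1]`.
#' @export
mean_iou <- function(match) {
  if (inherits(match, "match_result")) match <- list(match)
  ious <- unlist(lapply(match, function(m) m$pairs$iou))
  if (length(ious) == 0L) stop("mean IoU is undefined with no true-positive pairs")
  mean(ious)
}

# ---- per-image summaries ----------------------------------------------------

# Everything AP/mAP/mIOU needs from one image: label/score stubs, the IoU
# matrix, and the error tally. Masks are dropped after this.
summarize_image <- function(img, preds, gts, height, width,
                            primary_threshold = 0.5, floor_threshold = 0.1) {
  pm <- lapply(preds, instance_mask, height = height, width = width)
  gm <- lapply(gts, instance_mask, height = height, width = width)
  iou <- iou_matrix_masks(pm, gm)
  tally <- classify_errors_impl(pm, gm, iou, primary_threshold, floor_threshold,
                                vapply(preds, function(p) p$score, numeric(1)))
  stub <- function(x) list(image = x$image, label = x$label, score = x$score)
  list(image = img, preds = lapply(preds, stub), gts = lapply(gts, stub),
       iou = iou, tally = tally)
}

# group decoded instances (or encoded records) by image and summarize
prepare_dataset <- function(preds, gts, height, width,
                            primary_threshold = 0.5, floor_threshold = 0.1,
                            encoded = FALSE) {
  pim <- vapply(preds, function(p) p$image, character(1))
  gim <- vapply(gts, function(g) g$image, character(1))
  imgs <- sort(unique(c(pim, gim)))
  lapply(imgs, function(img) {
    p <- preds[pim == img]
    g <- gts[gim == img]
    if (encoded) {
      p <- lapply(p, record_to_instance)
      g <- lapply(g, record_to_instance)
    }
    summarize_image(img, p, g, height, width, primary_threshold, floor_threshold)
  })
}

#' Average precision for one class at one IoU threshold
#'
#' Detections of the class are pooled over all images and sorted by
#' descending score; matching runs per image. Precision-recall points are
#' accumulated along the sorted list, precision is monotonized (each point
#' takes the maximum precision at equal-or-higher recall), and AP is the
#' area under the monotonized curve over all recall increments.
#'
#' @param preds,gts Lists of [detection_instance()]s (any images; grouped
#'   by their `image` field).
#' @param class `"mature"` or `"immature"`.
#' @param iou_threshold Matching threshold.
#' @param height,width Frame dimensions (shared by all images).
#' @param dataset Optional prepared per-image summary list (internal reuse).
#' @return A list of class `"ap_result"`: `class`, `iou_threshold`, `ap`,
#'   and data.frame `curve` (`score`, `recall`, `precision`).
#' @export
average_precision <- function(preds, gts, class, iou_threshold,
                              height = NULL, width = NULL, dataset = NULL) {
  if (is.null(dataset)) dataset <- prepare_dataset(preds, gts, height, width)
  tpfp <- list(); scores <- numeric(0)
  n_gt <- 0L
  for (entry in dataset) {
    keep_p <- vapply(entry$preds, function(p) p$label == class, logical(1))
    keep_g <- vapply(entry$gts, function(g) g$label == class, logical(1))
    n_gt <- n_gt + sum(keep_g)
    if (!any(keep_p)) next
    p <- entry$preds[keep_p]
    g <- entry$gts[keep_g]
    m <- match_instances(p, g, iou_threshold, class_aware = FALSE,
                         iou = entry$iou[keep_p, keep_g, drop = FALSE])
    s <- vapply(p, function(x) x$score, numeric(1))
    is_tp <- seq_along(p) %in% m$pairs$pred
    scores <- c(scores, s)
    tpfp <- c(tpfp, list(is_tp))
  }
  if (n_gt == 0L) stop("no ground truth of class '", class, "': AP undefined")
  is_tp <- unlist(tpfp)
  if (length(scores) == 0L)
    return(structure(list(class = class, iou_threshold = iou_threshold, ap = 0,
                          curve = data.frame(score = numeric(0), recall = numeric(0),
                                             precision = numeric(0))),
                     class = "ap_result"))
  ord <- order(-scores)
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  prec_mono <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * prec_mono)
  structure(list(class = class, iou_threshold = iou_threshold, ap = ap,
                 curve = data.frame(score = scores[ord], recall = recall,
                                    precision = precision)),
            class = "ap_result")
}

map_from_dataset <- function(dataset, thresholds, classes) {
  glab <- unlist(lapply(dataset, function(e)
    vapply(e$gts, function(g) g$label, character(1))))
  present <- classes[classes %in% glab]
  if (length(present) < length(classes))
    warning("class(es) absent from ground truth excluded from mAP: ",
            paste(setdiff(classes, present), collapse = ", "))
  if (length(present) == 0L) stop("no ground truth of any evaluated class")
  aps <- list()
  rows <- lapply(thresholds, function(t) {
    ap_t <- lapply(present, function(cl)
      average_precision(NULL, NULL, cl, t, dataset = dataset))
    names(ap_t) <- present
    aps[[as.character(t)]] <<- ap_t
    vals <- vapply(ap_t, function(a) a$ap, numeric(1))
    row <- data.frame(iou_threshold = t, t(vals), mAP = mean(vals))
    names(row)[2:(1 + length(present))] <- paste0("AP_", present)
    row
  })
  structure(list(table = do.call(rbind, rows), ap_results = aps,
                 classes = present),
            class = "map_result")
}

#' Mean average precision over IoU thresholds
#'
#' For each threshold, AP is computed per class over the pooled dataset
#' and averaged across the classes present in the ground truth (a class
#' absent from all ground truth is excluded with a warning).
#'
#' @param preds,gts Lists of [detection_instance()]s.
#' @param thresholds IoU thresholds (default 0.50 to 0.95 by 0.05).
#' @param height,width Frame dimensions.
#' @param classes Class labels to evaluate.
#' @return A list of class `"map_result"`: data.frame `table` with columns
#'   `iou_threshold`, one AP column per class, and `mAP`; plus the list of
#'   per-(class, threshold) `"ap_result"`s.
#' @export
mean_average_precision <- function(preds, gts, thresholds = seq(0.5, 0.95, by = 0.05),
                                   height = NULL, width = NULL,
                                   classes = BERRY_CLASSES) {
  dataset <- prepare_dataset(preds, gts, height, width)
  map_from_dataset(dataset, thresholds, classes)
}

# taxonomy core on precomputed masks + IoU matrix
classify_errors_impl <- function(pm, gm, iou, primary_threshold, floor_threshold,
                                 scores = rep(1, length(pm))) {
  scores[is.na(scores)] <- 1
  preds_stub <- lapply(seq_along(pm), function(i) list(label = "x", score = scores[i]))
  gts_stub <- lapply(seq_along(gm), function(j) list(label = "x"))
  m <- match_instances(preds_stub, gts_stub, primary_threshold,
                       class_aware = FALSE, iou = iou)
  tally <- c(one_as_two = 0L, missed = 0L, two_as_one = 0L, partial = 0L)
  pred_free <- !(seq_along(pm) %in% m$pairs$pred)
  gt_free <- !(seq_along(gm) %in% m$pairs$gt)
  # one-as-two: >= 2 unmatched predictions fragmenting one ground truth
  for (j in seq_along(gm)) {
    frag <- which(pred_free & iou[, j] >= floor_threshold)
    if (length(frag) >= 2L) {
      u <- Reduce(`|`, pm[frag])
      if (mask_iou(u, gm[[j]]) >= primary_threshold) {
        tally["one_as_two"] <- tally["one_as_two"] + 1L
        pred_free[frag] <- FALSE
        gt_free[j] <- FALSE
      }
    }
  }
  # two-as-one: one unmatched prediction blanketing >= 2 ground truths
  for (i in seq_along(pm)) {
    if (!pred_free[i]) next
    cover <- which(gt_free & iou[i, ] >= floor_threshold)
    if (length(cover) >= 2L) {
      tally["two_as_one"] <- tally["two_as_one"] + 1L
      pred_free[i] <- FALSE
      gt_free[cover] <- FALSE
    }
  }
  # partial / missed on the remaining ground truths
  for (j in seq_along(gm)) {
    if (!gt_free[j]) next
    ov <- iou[, j]
    n_floor <- sum(ov >= floor_threshold)
    if (n_floor == 0L) {
      tally["missed"] <- tally["missed"] + 1L
      gt_free[j] <- FALSE
    } else if (n_floor == 1L && max(ov) < primary_threshold) {
      tally["partial"] <- tally["partial"] + 1L
      gt_free[j] <- FALSE
    }
  }
  tally
}

#' Classify detection errors into the four-way taxonomy
#'
#' After matching at the primary threshold (class-agnostic — the taxonomy
#' is geometric), each remaining instance is assigned at most one error
#' event, in priority order:
#'
#' * **one_as_two** — a ground truth overlapped (IoU >= `floor_threshold`)
#'   by two or more unmatched predictions whose union reaches the primary
#'   threshold: one berry detected as two.
#' * **two_as_one** — an unmatched prediction overlapping two or more
#'   ground truths at the floor each: two berries detected as one.
#' * **partial** — an unmatched ground truth with exactly one overlapping
#'   prediction in `[floor, primary)`: partial detection.
#' * **missed** — an unmatched ground truth with no prediction overlap at
#'   the floor: missed detection.
#'
#' @param preds,gts Instances on one image.
#' @param primary_threshold Matching threshold (default 0.5).
#' @param floor_threshold Minimum overlap for an association (default 0.1).
#' @param height,width Frame dimensions.
#' @return A list of class `"error_tally"` with integer counts
#'   `one_as_two`, `missed`, `two_as_one`, `partial`.
#' @export
classify_errors <- function(preds, gts, primary_threshold = 0.5,
                            floor_threshold = 0.1, height = NULL, width = NULL) {
  if (floor_threshold >= primary_threshold)
    stop("floor_threshold must be below primary_threshold")
  pm <- lapply(preds, instance_mask, height = height, width = width)
  gm <- lapply(gts, instance_mask, height = height, width = width)
  iou <- iou_matrix_masks(pm, gm)
  tally <- classify_errors_impl(pm, gm, iou, primary_threshold, floor_threshold,
                                vapply(preds, function(p) p$score, numeric(1)))
  structure(as.list(tally), class = "error_tally")
}

report_from_dataset <- function(dataset, thresholds, primary_threshold,
                                n_predictions, n_ground_truth) {
  mapres <- map_from_dataset(dataset, thresholds, BERRY_CLASSES)
  matches <- lapply(dataset, function(e)
    match_instances(e$preds, e$gts, primary_threshold, class_aware = TRUE,
                    iou = e$iou))
  miou <- tryCatch(mean_iou(matches), error = function(e) NA_real_)
  errs <- Reduce(`+`, lapply(dataset, function(e) e$tally))
  structure(list(map = mapres, miou = miou, errors = as.list(errs),
                 n_images = length(dataset),
                 n_predictions = n_predictions, n_ground_truth = n_ground_truth,
                 primary_threshold = primary_threshold),
            class = "evaluation_report")
}

#' Full evaluation report
#'
#' Bundles the threshold-by-threshold mAP table, per-class APs, mean IoU
#' at the primary threshold, and the summed per-image error tallies into
#' one report; see [write_report()] for the JSON form and
#' [plot_pr_curves()] for the figure.
#'
#' @inheritParams mean_average_precision
#' @param primary_threshold Threshold for mIOU and the error taxonomy.
#' @return A list of class `"evaluation_report"`.
#' @export
evaluate_detections <- function(preds, gts, height, width,
                                thresholds = seq(0.5, 0.95, by = 0.05),
                                primary_threshold = 0.5) {
  dataset <- prepare_dataset(preds, gts, height, width, primary_threshold)
  report_from_dataset(dataset, thresholds, primary_threshold,
                      length(preds), length(gts))
}

#' Write an evaluation report as JSON
#' @param report An `"evaluation_report"`.
#' @param path Output path; if `NULL`, JSON text is returned.
#' @export
write_report <- function(report, path = NULL) {
  curves <- list()
  for (t in names(report$map$ap_results)) {
    for (cl in names(report$map$ap_results[[t]])) {
      a <- report$map$ap_results[[t]][[cl]]
      curves[[length(curves) + 1L]] <-
        list(class = cl, iou_threshold = as.numeric(t), ap = a$ap,
             recall = a$curve$recall, precision = a$curve$precision)
    }
  }
  obj <- list(map_table = report$map$table,
              miou = report$miou,
              errors = report$errors,
              n_images = report$n_images,
              n_predictions = report$n_predictions,
              n_ground_truth = report$n_ground_truth,
              primary_threshold = report$primary_threshold,
              pr_curves = curves)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Structural validation of an evaluation-report JSON
#' @param source Path or JSON string.
#' @return `TRUE` invisibly; stops on the first violation.
#' @export
validate_report <- function(source) {
  txt <- if (length(source) == 1L && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else source
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  stopifnot(is.data.frame(obj$map_table),
            all(c("iou_threshold", "mAP") %in% names(obj$map_table)),
            is.numeric(obj$map_table$mAP),
            all(obj$map_table$mAP >= 0 & obj$map_table$mAP <= 1),
            is.numeric(obj$miou) || is.null(obj$miou),
            all(c("one_as_two", "missed", "two_as_one", "partial") %in%
                  names(obj$errors)),
            all(unlist(obj$errors) >= 0))
  invisible(TRUE)
}

#' Precision-recall curves across IoU thresholds
#'
#' One panel per class, one curve per IoU threshold, mirroring the usual
#' recall-precision layout of segmentation-model evaluations.
#'
#' @param report An `"evaluation_report"`.
#' @param path Optional image path (written via [ggplot2::ggsave()]).
#' @return The ggplot object.
#' @export
plot_pr_curves <- function(report, path = NULL) {
  rows <- list()
  for (t in names(report$map$ap_results)) {
    for (cl in names(report$map$ap_results[[t]])) {
      a <- report$map$ap_results[[t]][[cl]]
      if (nrow(a$curve) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, iou_threshold = t,
                   recall = a$curve$recall, precision = a$curve$precision)
    }
  }
  df <- do.call(rbind, rows)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = recall, y = precision,
                                        color = iou_threshold)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", color = "IoU threshold") +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 150)
  p
}
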