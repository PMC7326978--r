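# Reading/writing VGG Image Annotator (VIA) 2.x polygon projects, the
# detection-JSON interchange format, the per-branch ground-truth CSV, and
# quantification of manual-correction rounds in the iterative annotation
# loop (run model -> export as annotations -> correct by hand -> retrain).

BERRY_CLASSES <- c("mature", "immature")

#' Construct an annotated region
#'
#' @param image Image identifier (filename).
#' @param outline A [polygon_outline()].
#' @param label `"mature"` or `"immature"` (background is the absence of
#'   regions).
#' @return A list of class `"annotated_region"`.
#' @export
annotated_region <- function(image, outline, label) {
  label <- normalize_label(label)
  if (is.na(label)) stop("label must be one of: ", paste(BERRY_CLASSES, collapse = ", "))
  structure(list(image = as.character(image), outline = as_outline(outline),
                 label = label),
            class = "annotated_region")
}

#' Construct a detection instance
#'
#' One detected berry: its mask (as a polygon outline or a raster mask),
#' maturity label, and — for model predictions — a confidence score.
#' Ground-truth instances carry no score.
#'
#' @param image Image identifier.
#' @param mask A [polygon_outline()] or a logical matrix.
#' @param label `"mature"` or `"immature"`.
#' @param score Confidence in `[0, 1]`, or `NA` for ground truth.
#' @return A list of class `"detection_instance"`.
#' @export
detection_instance <- function(image, mask, label, score = NA_real_) {
  label <- normalize_label(label)
  if (is.na(label)) stop("label must be one of: ", paste(BERRY_CLASSES, collapse = ", "))
  if (!is.na(score) && (score < 0 || score > 1)) stop("score must be in [0, 1]")
  if (is.matrix(mask) && is.logical(mask)) {
    if (!any(mask)) stop("detection mask must be nonempty")
  } else {
    mask <- as_outline(mask)
  }
  structure(list(image = as.character(image), mask = mask, label = label,
                 score = as.numeric(score)),
            class = "detection_instance")
}

normalize_label <- function(label) {
  l <- tolower(trimws(as.character(label)))
  if (length(l) != 1L || !(l %in% BERRY_CLASSES)) return(NA_character_)
  l
}

#' Rasterize an instance's mask onto a frame
#' @param inst An `annotated_region` or `detection_instance`.
#' @param height,width Frame dimensions.
#' @return Logical matrix.
#' @export
instance_mask <- function(inst, height, width) {
  m <- if (!is.null(inst$mask)) inst$mask else inst$outline
  if (is.matrix(m) && is.logical(m)) {
    if (nrow(m) != height || ncol(m) != width)
      stop("instance raster mask frame does not match requested frame")
    return(m)
  }
  rasterize(m, height, width)
}

# ---- VIA 2.x project JSON ---------------------------------------------------

#' Read a VIA 2.x polygon project
#'
#' Accepts both the full project dialect (regions under
#' `_via_img_metadata`) and the flat image-metadata dialect. Only polygon
#' regions are kept; other shapes are skipped with a warning. The maturity
#' label is read from a configurable region attribute (default
#' `"maturity"`), normalized case-insensitively; regions with an unknown
#' label value are skipped with a warning.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param label_attribute Region-attribute key carrying the class label.
#' @return A list of [annotated_region()]s.
#' @export
read_via <- function(source, label_attribute = "maturity") {
  txt <- if (length(source) == 1L && !grepl("[{\\[]", substr(source, 1L, 1L)) &&
             file.exists(source)) paste(readLines(source, warn = FALSE), collapse = "\n")
         else source
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  imgs <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  regions <- list()
  for (key in names(imgs)) {
    entry <- imgs[[key]]
    if (!is.list(entry) || is.null(entry$regions)) next
    fname <- if (!is.null(entry$filename)) entry$filename else key
    for (rg in entry$regions) {
      sa <- rg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) {
        warning("skipping non-polygon region in image ", fname, call. = FALSE)
        next
      }
      lab <- normalize_label(rg$region_attributes[[label_attribute]])
      if (is.na(lab)) {
        warning("skipping region with unknown '", label_attribute,
                "' label in image ", fname, call. = FALSE)
        next
      }
      out <- tryCatch(
        polygon_outline(unlist(sa$all_points_x), unlist(sa$all_points_y)),
        error = function(e) {
          warning("skipping degenerate polygon in image ", fname, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(out)) next
      regions[[length(regions) + 1L]] <- annotated_region(fname, out, lab)
    }
  }
  regions
}

#' Write annotated regions as a VIA 2.x project (flat dialect)
#'
#' @param regions A list of [annotated_region()]s.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @param label_attribute Region-attribute key for the class label.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_via <- function(regions, path = NULL, label_attribute = "maturity") {
  by_img <- split(regions, vapply(regions, function(r) r$image, character(1)))
  out <- list()
  for (img in names(by_img)) {
    regs <- lapply(by_img[[img]], function(r) {
      list(shape_attributes = list(
             name = "polygon",
             all_points_x = I(as.numeric(r$outline[, 1])),
             all_points_y = I(as.numeric(r$outline[, 2]))),
           region_attributes = stats::setNames(list(r$label), label_attribute))
    })
    out[[paste0(img, "-1")]] <- list(filename = img, size = -1L,
                                     regions = regs, file_attributes = c())
  }
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "list")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# ---- detection JSON ---------------------------------------------------------

#' Read detection instances from JSON
#'
#' One record per instance, carrying the mask either as a polygon —
#' `{"image": ..., "polygon": [[x, y], ...], "label": ..., "score": ...}`
#' — or as an uncompressed column-major run-length encoding —
#' `{"image": ..., "rle": {"height": h, "width": w, "runs": [start, length,
#' ...]}, ...}` (1-based starts in column-major pixel order). `score` is
#' absent or null for ground truth. The schema ships at
#' `system.file("schemas", "detection.schema.json", package = "berryfield")`.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A list of [detection_instance()]s.
#' @export
read_detections <- function(source) {
  lapply(parse_detection_json(source), record_to_instance)
}

# raw records (masks still encoded) — lets the pipeline commands decode
# per image instead of holding every raster in memory at once
parse_detection_json <- function(source) {
  txt <- if (length(source) == 1L && !grepl("[{\\[]", substr(source, 1L, 1L)) &&
             file.exists(source)) paste(readLines(source, warn = FALSE), collapse = "\n")
         else source
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

record_to_instance <- function(r) {
  mask <- if (!is.null(r$polygon)) {
    poly <- do.call(rbind, lapply(r$polygon, function(p) c(p[[1]], p[[2]])))
    polygon_outline(poly[, 1], poly[, 2])
  } else if (!is.null(r$rle)) {
    rle_decode(r$rle)
  } else stop("detection record has neither 'polygon' nor 'rle'")
  detection_instance(r$image, mask, r$label,
                     score = if (is.null(r$score)) NA_real_ else as.numeric(r$score))
}

#' Write detection instances to JSON
#'
#' Polygon masks are written as vertex lists, raster masks as run-length
#' encodings; both round-trip exactly through [read_detections()].
#'
#' @param detections A list of [detection_instance()]s.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_detections <- function(detections, path = NULL) {
  recs <- lapply(detections, function(d) {
    rec <- list(image = d$image)
    if (is.matrix(d$mask) && is.logical(d$mask)) {
      rec$rle <- rle_encode(d$mask)
    } else {
      rec$polygon <- lapply(seq_len(nrow(d$mask)),
                            function(i) I(as.numeric(d$mask[i, ])))
    }
    rec$label <- d$label
    if (!is.na(d$score)) rec$score <- d$score
    rec
  })
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(height = nrow(mask), width = ncol(mask),
       runs = I(as.vector(rbind(starts[keep], r$lengths[keep]))))
}

rle_decode <- function(rle) {
  h <- as.integer(rle$height); w <- as.integer(rle$width)
  v <- logical(h * w)
  runs <- as.integer(unlist(rle$runs))
  if (length(runs)) {
    starts <- runs[seq(1L, length(runs), by = 2L)]
    lens <- runs[seq(2L, length(runs), by = 2L)]
    v[sequence(lens, from = starts)] <- TRUE
  }
  matrix(v, h, w)
}

#' Light structural validation of detection JSON records
#' @param source Path or JSON string.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_detections <- function(source) {
  dets <- read_detections(source)
  for (d in dets) {
    stopifnot(nchar(d$image) > 0L, d$label %in% BERRY_CLASSES)
    if (is.matrix(d$mask) && is.logical(d$mask)) stopifnot(any(d$mask))
    else stopifnot(nrow(d$mask) >= 3L)
  }
  invisible(TRUE)
}

# ---- ground-truth CSV -------------------------------------------------------

#' Read the per-branch ground-truth table
#'
#' Columns: `sample_id`, `cultivar`, `N_t` (true berry count) and `N_c`
#' (cluster count); extra columns are kept.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "N_t", "N_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ground-truth CSV missing columns: ", paste(miss, collapse = ", "))
  df
}

# ---- correction diff --------------------------------------------------------

#' Quantify a manual-correction round
#'
#' Compares model-generated annotations with their manually corrected
#' version. Regions of the same image are paired greedily by descending
#' mask IoU above `iou_match_threshold`; a pair with the same label and
#' IoU at or above `reshape_tolerance` is *unchanged*, a pair with a label
#' change is *relabeled*, a pair below the reshape tolerance is *reshaped*;
#' unpaired generated regions were *removed* and unpaired corrected regions
#' were *added*.
#'
#' @param generated,corrected Lists of [annotated_region()]s.
#' @param iou_match_threshold Minimum IoU for two regions to be considered
#'   the same berry, in `(0, 1]`.
#' @param reshape_tolerance IoU at or above which a matched outline counts
#'   as unchanged.
#' @param frame Optional `c(height, width)`; inferred from the outlines
#'   when omitted.
#' @return A list of class `"correction_report"` with total counts
#'   (`added`, `removed`, `relabeled`, `reshaped`, `unchanged`) and a
#'   per-image data.frame `by_image`.
#' @export
diff_corrections <- function(generated, corrected, iou_match_threshold = 0.5,
                             reshape_tolerance = 0.95, frame = NULL) {
  if (iou_match_threshold <= 0 || iou_match_threshold > 1)
    stop("iou_match_threshold must be in (0, 1]")
  if (length(generated) + length(corrected) == 0L)
    stop("no regions to compare")
  if (is.null(frame)) {
    all_xy <- do.call(rbind, lapply(c(generated, corrected), function(r) r$outline))
    frame <- c(ceiling(max(all_xy[, 2])) + 1L, ceiling(max(all_xy[, 1])) + 1L)
  }
  imgs <- sort(unique(c(vapply(generated, function(r) r$image, character(1)),
                        vapply(corrected, function(r) r$image, character(1)))))
  tot <- c(added = 0L, removed = 0L, relabeled = 0L, reshaped = 0L, unchanged = 0L)
  rows <- list()
  for (img in imgs) {
    g <- Filter(function(r) r$image == img, generated)
    c_ <- Filter(function(r) r$image == img, corrected)
    gm <- lapply(g, instance_mask, height = frame[1], width = frame[2])
    cm <- lapply(c_, instance_mask, height = frame[1], width = frame[2])
    cnt <- c(added = 0L, removed = 0L, relabeled = 0L, reshaped = 0L, unchanged = 0L)
    if (length(g) && length(c_)) {
      iou <- matrix(0, length(g), length(c_))
      for (i in seq_along(g)) for (j in seq_along(c_)) {
        if (any(gm[[i]] | cm[[j]])) iou[i, j] <- mask_iou(gm[[i]], cm[[j]])
      }
      gi_free <- rep(TRUE, length(g)); cj_free <- rep(TRUE, length(c_))
      repeat {
        iou_f <- iou
        iou_f[!gi_free, ] <- -1; iou_f[, !cj_free] <- -1
        best <- which.max(iou_f)
        if (length(best) == 0L || iou_f[best] < iou_match_threshold) break
        i <- (best - 1L) %% length(g) + 1L
        j <- (best - 1L) %/% length(g) + 1L
        gi_free[i] <- FALSE; cj_free[j] <- FALSE
        if (g[[i]]$label != c_[[j]]$label) cnt["relabeled"] <- cnt["relabeled"] + 1L
        else if (iou[i, j] >= reshape_tolerance) cnt["unchanged"] <- cnt["unchanged"] + 1L
        else cnt["reshaped"] <- cnt["reshaped"] + 1L
      }
      cnt["removed"] <- sum(gi_free)
      cnt["added"] <- sum(cj_free)
    } else {
      cnt["removed"] <- length(g)
      cnt["added"] <- length(c_)
    }
    tot <- tot + cnt
    rows[[img]] <- data.frame(image = img, t(cnt))
  }
  structure(c(as.list(tot),
              list(by_image = do.call(rbind, c(rows, list(make.row.names = FALSE))))),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("correction report: %d added, %d removed, %d relabeled, %d reshaped, %d unchanged\n",
              x$added, x$removed, x$relabeled, x$reshaped, x$unchanged))
  invisible(x)
}
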