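#' Confidence suppression
#'
#' Removes detection candidates whose confidence falls below the threshold,
#' before any decoding. The comparison is `>=` (keep-at-boundary), so
#' threshold 0 keeps every candidate. Record order is preserved.
#'
#' @param detections A detections data.frame.
#' @param threshold Confidence threshold in \[0, 1\].
#' @return The surviving subset of `detections`.
#' @export
confidence_suppress <- function(detections, threshold) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  detections[detections$confidence >= threshold, , drop = FALSE]
}

#' @keywords internal
empty_findings <- function() {
  data.frame(bone = character(), grade = integer(), confidence = numeric(),
             x_min = numeric(), y_min = numeric(), x_max = numeric(),
             y_max = numeric(), stringsAsFactors = FALSE)
}

#' Key Bone Search decoding
#'
#' The KBS decoder: after confidence suppression, every candidate label is
#' split into its key bone and developmental grade, and for each of the 13
#' key bones the single candidate with the maximum confidence across all of
#' that bone's grade classes is kept — its grade, confidence and prediction
#' box become the bone's final output. Bones with no surviving candidate are
#' reported as missing, so the result always covers the 13 bones exactly
#' once between `findings` and `missing`.
#'
#' Ties on confidence are broken deterministically (lower grade first, then
#' larger box area), so the result does not depend on input record order.
#'
#' @param detections Detection candidates for a single image (any
#'   `image_id` column must hold one unique value).
#' @param catalog A `class_catalog`.
#' @param threshold Confidence-suppression threshold; default 0.1, the
#'   operating point at which decoding is fast and no bones go missing.
#' @return An object of class `kbs_result`: list with `image_id`,
#'   `findings` (data.frame bone/grade/confidence/box, one row per found
#'   bone) and `missing` (character vector of bones with no candidate).
#' @examples
#' catalog <- build_class_catalog()
#' det <- data.frame(image_id = "im1",
#'                   class_label = c("radius_1", "radius_2"),
#'                   confidence = c(0.6, 0.8),
#'                   x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' kbs_decode(det, catalog, threshold = 0.1)
#' @export
kbs_decode <- function(detections, catalog = build_class_catalog(),
                       threshold = 0.1) {
  detections <- as.data.frame(detections)
  image_id <- if ("image_id" %in% names(detections) && nrow(detections)) {
    ids <- unique(detections$image_id)
    if (length(ids) > 1L) {
      stop("kbs_decode expects a single image; got ", length(ids),
           " image ids (use kbs_decode_all)", call. = FALSE)
    }
    ids
  } else NA_character_
  bones <- unique(catalog$bone)
  kept <- confidence_suppress(detections, threshold)
  if (nrow(kept) == 0L) {
    res <- list(image_id = image_id, findings = empty_findings(),
                missing = bones)
    class(res) <- "kbs_result"
    return(res)
  }
  dec <- decode_label(kept$class_label, catalog)
  kept$bone <- dec$bone
  kept$grade <- dec$grade
  area <- (kept$x_max - kept$x_min) * (kept$y_max - kept$y_min)
  # argmax confidence per bone; ties -> lower grade, then larger area
  ord <- order(kept$bone, -kept$confidence, kept$grade, -area)
  kept <- kept[ord, , drop = FALSE]
  best <- kept[!duplicated(kept$bone), , drop = FALSE]
  best <- best[match(bones, best$bone), , drop = FALSE]
  best <- best[!is.na(best$bone), , drop = FALSE]
  findings <- best[, c("bone", "grade", "confidence", box_cols())]
  rownames(findings) <- NULL
  res <- list(image_id = image_id, findings = findings,
              missing = setdiff(bones, findings$bone))
  class(res) <- "kbs_result"
  res
}

#' @export
print.kbs_result <- function(x, ...) {
  cat("KBS result for image ", x$image_id, ": ", nrow(x$findings),
      " bones found, ", length(x$missing), " missing\n", sep = "")
  if (nrow(x$findings)) print(x$findings, ...)
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Decode a multi-image detection set with KBS
#'
#' @inheritParams kbs_decode
#' @param detections Detection candidates with an `image_id` column.
#' @return Named list of `kbs_result`, one per image id (in first-appearance
#'   order).
#' @export
kbs_decode_all <- function(detections, catalog = build_class_catalog(),
                           threshold = 0.1) {
  ids <- unique(detections$image_id)
  out <- lapply(ids, function(id) {
    kbs_decode(detections[detections$image_id == id, , drop = FALSE],
               catalog, threshold)
  })
  stats::setNames(out, ids)
}

#' @keywords internal
greedy_nms <- function(det, iou_threshold) {
  keep <- logical(nrow(det))
  ord <- order(-det$confidence)
  alive <- rep(TRUE, nrow(det))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    others <- which(alive & !keep)
    if (length(others)) {
      ov <- iou(det[rep(i, length(others)), box_cols()],
                det[others, box_cols()])
      alive[others[ov > iou_threshold]] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' Per-class non-maximum-suppression baseline
#'
#' The conventional detector decoder KBS is contrasted with: after
#' confidence suppression, greedy NMS is applied within each target class
#' (bone-grade pair), so one key bone can end up with several surviving
#' grades/boxes ("repeat") or with none ("lack"). KBS by construction never
#' repeats.
#'
#' @inheritParams kbs_decode
#' @param conf_threshold Confidence-suppression threshold.
#' @param iou_threshold Overlap threshold above which a lower-confidence
#'   same-class box is suppressed; default 0.5.
#' @return List with `findings` (possibly several rows per bone),
#'   `repeat_count` (bones with >1 surviving detection), `lack_count`
#'   (bones with none) and `missing` (those bones' names).
#' @export
nms_decode <- function(detections, catalog = build_class_catalog(),
                       conf_threshold = 0.1, iou_threshold = 0.5) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1)
  bones <- unique(catalog$bone)
  kept <- confidence_suppress(as.data.frame(detections), conf_threshold)
  if (nrow(kept)) {
    dec <- decode_label(kept$class_label, catalog)
    kept$bone <- dec$bone
    kept$grade <- dec$grade
    kept <- do.call(rbind, lapply(split(kept, kept$class_label),
                                  greedy_nms, iou_threshold = iou_threshold))
    kept <- kept[order(kept$bone, -kept$confidence), , drop = FALSE]
  }
  findings <- if (nrow(kept)) {
    f <- kept[, c("bone", "grade", "confidence", box_cols())]
    rownames(f) <- NULL
    f
  } else empty_findings()
  per_bone <- table(factor(findings$bone, levels = bones))
  list(findings = findings,
       repeat_count = sum(per_bone > 1L),
       lack_count = sum(per_bone == 0L),
       missing = names(per_bone)[per_bone == 0L])
}

#' Sweep decoders over confidence thresholds
#'
#' Runs the chosen decoder on every image at each confidence threshold and
#' totals the error accounting over the image set: `lack_count` (key bones
#' with no output) and, for NMS, `repeat_count` (key bones with duplicated
#' outputs). The default grid is the six thresholds 0.0, 0.1, ..., 0.5.
#'
#' @param detections Multi-image detections data.frame.
#' @param catalog A `class_catalog`.
#' @param thresholds Ascending numeric vector of confidence thresholds.
#' @param method `"kbs"` or `"nms"`.
#' @param iou_threshold NMS overlap threshold (ignored for KBS).
#' @return data.frame with columns `threshold`, `lack_count`,
#'   `repeat_count` (`repeat_count` is NA for KBS, which cannot repeat).
#' @export
threshold_sweep <- function(detections, catalog = build_class_catalog(),
                            thresholds = seq(0, 0.5, by = 0.1),
                            method = c("kbs", "nms"), iou_threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(thresholds))
  ids <- unique(detections$image_id)
  rows <- lapply(thresholds, function(th) {
    lack <- 0L; rep_ <- 0L
    for (id in ids) {
      d <- detections[detections$image_id == id, , drop = FALSE]
      if (method == "kbs") {
        r <- kbs_decode(d, catalog, th)
        lack <- lack + length(r$missing)
      } else {
        r <- nms_decode(d, catalog, th, iou_threshold)
        lack <- lack + r$lack_count
        rep_ <- rep_ + r$repeat_count
      }
    }
    data.frame(threshold = th, lack_count = lack,
               repeat_count = if (method == "nms") rep_ else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Flatten decode results to the interchange detection dialect
#'
#' @param results List of `kbs_result` (or the `findings` of [nms_decode()]
#'   tagged with an image id).
#' @return data.frame with one row per finding plus rows flagged
#'   `missing = TRUE` for absent bones.
#' @export
results_to_frame <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    f <- r$findings
    out <- if (nrow(f)) {
      cbind(data.frame(image_id = r$image_id, stringsAsFactors = FALSE),
            f, missing = FALSE)
    } else NULL
    if (length(r$missing)) {
      miss <- data.frame(image_id = r$image_id, bone = r$missing,
                         grade = NA_integer_, confidence = NA_real_,
                         x_min = NA_real_, y_min = NA_real_,
                         x_max = NA_real_, y_max = NA_real_, missing = TRUE,
                         stringsAsFactors = FALSE)
      out <- rbind(out, miss)
    }
    out
  }))
}
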