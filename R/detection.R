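#' @keywords internal
box_cols <- function() c("x_min", "y_min", "x_max", "y_max")

#' Validate corner-format boxes
#'
#' Boxes are continuous pixel coordinates, origin top-left, corner format
#' (`x_min`, `y_min`, `x_max`, `y_max`); area is `(x_max - x_min) *
#' (y_max - y_min)` with no +1 (the continuous detector convention).
#'
#' @param box A data.frame (or coercible) with the four corner columns.
#' @return The validated data.frame, invisibly.
#' @keywords internal
validate_boxes <- function(box) {
  box <- as.data.frame(box)
  if (!all(box_cols() %in% names(box))) {
    stop("box error: need columns ", paste(box_cols(), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(box[, box_cols()])
  if (any(!is.finite(m))) stop("box error: non-finite coordinate", call. = FALSE)
  if (any(box$x_max <= box$x_min) || any(box$y_max <= box$y_min)) {
    stop("box error: degenerate box (x_max <= x_min or y_max <= y_min)",
         call. = FALSE)
  }
  invisible(box)
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes: either numeric vectors `c(x_min, y_min, x_max, y_max)`
#'   or single-row data.frames with those columns. Vectorised row-wise when
#'   both are data.frames of equal height.
#' @return IoU in \[0, 1\]; 0 when the boxes are disjoint.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  as_box_df <- function(x) {
    if (is.numeric(x) && length(x) == 4L) {
      x <- as.data.frame(as.list(stats::setNames(x, box_cols())))
    }
    validate_boxes(x)
    as.data.frame(x)
  }
  a <- as_box_df(a); b <- as_box_df(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' @keywords internal
validate_detections <- function(det, catalog = NULL, where = "detections") {
  req <- c("image_id", "class_label", "confidence", box_cols())
  missing_cols <- setdiff(req, names(det))
  if (length(missing_cols)) {
    stop("parse error in ", where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(det$confidence) | det$confidence < 0 |
                 det$confidence > 1)
  if (length(bad)) {
    stop("parse error in ", where, ", record ", bad[1],
         ": confidence must be in [0, 1] (got ", det$confidence[bad[1]], ")",
         call. = FALSE)
  }
  if (nrow(det)) validate_boxes(det)
  if (!is.null(catalog)) {
    unknown <- setdiff(det$class_label, catalog$class_label)
    if (length(unknown)) {
      stop("schema error: class label(s) not in catalog: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  det[, req]
}

#' Read and write detection-candidate files
#'
#' The interchange format is one CSV record per raw detector candidate with
#' fields `image_id`, `class_label`, `confidence`, `x_min`, `y_min`,
#' `x_max`, `y_max`. Reading validates the confidence range, box geometry
#' and (when a catalog is given) that every label is decodable.
#'
#' @param path File path.
#' @param catalog Optional `class_catalog` to validate labels against.
#' @param detections A detections data.frame.
#' @return `read_detections` returns a data.frame (possibly 0-row) of
#'   candidates; `write_detections` returns `path` invisibly.
#' @export
read_detections <- function(path, catalog = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_id = "character"))
  if (nrow(x) == 0L) {
    x <- data.frame(image_id = character(), class_label = character(),
                    confidence = numeric(), x_min = numeric(),
                    y_min = numeric(), x_max = numeric(), y_max = numeric(),
                    stringsAsFactors = FALSE)
    return(x)
  }
  validate_detections(x, catalog, where = basename(path))
}

#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  detections <- validate_detections(as.data.frame(detections))
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
validate_annotations <- function(ann, catalog = build_class_catalog(),
                                 where = "annotations") {
  req <- c("image_id", "sex", "chronological_age", "bone", "grade", box_cols())
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols)) {
    stop("parse error in ", where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(ann$sex %in% c("male", "female"))) {
    stop("schema error: sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(ann$chronological_age < 0)) {
    stop("schema error: negative chronological_age", call. = FALSE)
  }
  per_image <- split(ann$bone, ann$image_id)
  bones <- sort(rus_chn_bones())
  ok <- vapply(per_image, function(b) identical(sort(b), bones), logical(1))
  if (!all(ok)) {
    stop("schema error: image(s) without exactly one entry per key bone: ",
         paste(utils::head(names(per_image)[!ok], 5), collapse = ", "),
         call. = FALSE)
  }
  lab <- paste0(ann$bone, "_", ann$grade)
  if (!all(lab %in% catalog$class_label)) {
    stop("schema error: grade out of range in annotations", call. = FALSE)
  }
  validate_boxes(ann)
  ann[, req]
}

#' Read and write ground-truth annotation files
#'
#' Annotations are long-format CSV: 13 rows per image (one per key bone)
#' with per-image `sex` and `chronological_age` (years) repeated, plus the
#' bone's developmental `grade` and box corners.
#'
#' @param path File path.
#' @param annotations An annotations data.frame.
#' @param catalog `class_catalog` used to validate grades.
#' @return `read_annotations` returns the validated data.frame.
#' @export
read_annotations <- function(path, catalog = build_class_catalog()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_id = "character"))
  validate_annotations(x, catalog, where = basename(path))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path,
                              catalog = build_class_catalog()) {
  annotations <- validate_annotations(as.data.frame(annotations), catalog)
  annotations$chronological_age <- round(annotations$chronological_age, 2)
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
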