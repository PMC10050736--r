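#' The 13 RUS-CHN key bones
#'
#' Canonical identifiers of the 13 key bones graded by the RUS-CHN (China-05)
#' skeletal maturity method: radius, ulna, and the metacarpals and phalanges
#' of the first, third and fifth rays. The order is the canonical row order
#' used throughout the package (class ids, grade vectors, score tables).
#'
#' @return Character vector of length 13, lowercase snake_case names.
#' @examples
#' rus_chn_bones()
#' @export
rus_chn_bones <- function() {
  c("radius", "ulna",
    "first_metacarpal", "third_metacarpal", "fifth_metacarpal",
    "first_proximal_phalange", "third_proximal_phalange",
    "fifth_proximal_phalange",
    "third_middle_phalange", "fifth_middle_phalange",
    "first_distal_phalange", "third_distal_phalange",
    "fifth_distal_phalange")
}

#' Display names for the key bones
#'
#' Maps the internal snake_case identifiers to conventional display names
#' ("Radius", "Third Middle Phalange", ...).
#'
#' @param bone Character vector of internal bone names.
#' @return Character vector of display names.
#' @export
bone_display_name <- function(bone) {
  stopifnot(all(bone %in% rus_chn_bones()))
  vapply(strsplit(bone, "_", fixed = TRUE), function(w) {
    paste(toupper(substring(w, 1, 1)), substring(w, 2), sep = "", collapse = " ")
  }, character(1))
}

#' RUS-CHN developmental grade ranges
#'
#' The per-bone developmental grade ranges of the RUS-CHN method. Every bone
#' starts at grade 0 (ossification centre not yet present); the ceiling is
#' bone-specific: radius 14, ulna 12, first metacarpal 11, third and fifth
#' metacarpals 10, all proximal and middle phalanges 12, all distal
#' phalanges 11.
#'
#' @return A data.frame with columns `bone`, `min_grade` (always 0) and
#'   `max_grade`, one row per key bone in canonical order.
#' @examples
#' sum(rus_chn_grade_ranges()$max_grade + 1)  # 163 target classes
#' @export
rus_chn_grade_ranges <- function() {
  bones <- rus_chn_bones()
  max_grade <- c(radius = 14L, ulna = 12L,
                 first_metacarpal = 11L, third_metacarpal = 10L,
                 fifth_metacarpal = 10L,
                 first_proximal_phalange = 12L, third_proximal_phalange = 12L,
                 fifth_proximal_phalange = 12L,
                 third_middle_phalange = 12L, fifth_middle_phalange = 12L,
                 first_distal_phalange = 11L, third_distal_phalange = 11L,
                 fifth_distal_phalange = 11L)
  data.frame(bone = bones, min_grade = 0L,
             max_grade = unname(max_grade[bones]),
             stringsAsFactors = FALSE)
}

#' Build the bone-by-grade target-class catalog
#'
#' Enumerates every (bone, developmental grade) pair as one detector target
#' class, bones in the supplied order and grades ascending within each bone.
#' Class labels follow the `<bone>_<grade>` grammar (`radius_1`, `radius_2`,
#' ...); class ids are contiguous 0-based integers. With the standard
#' RUS-CHN grade ranges this yields exactly 163 classes.
#'
#' @param grade_ranges A data.frame with columns `bone`, `min_grade`,
#'   `max_grade` (one row per bone); defaults to [rus_chn_grade_ranges()].
#' @return A data.frame of class `class_catalog` with columns `class_id`
#'   (0-based), `bone`, `grade`, `class_label`.
#' @examples
#' catalog <- build_class_catalog()
#' nrow(catalog)  # 163
#' @export
build_class_catalog <- function(grade_ranges = rus_chn_grade_ranges()) {
  req <- c("bone", "min_grade", "max_grade")
  if (!is.data.frame(grade_ranges) || !all(req %in% names(grade_ranges)) ||
      nrow(grade_ranges) == 0L) {
    stop("schema error: grade_ranges must be a non-empty data.frame with ",
         "columns bone, min_grade, max_grade", call. = FALSE)
  }
  if (anyDuplicated(grade_ranges$bone)) {
    stop("schema error: duplicate bone in grade ranges: ",
         paste(unique(grade_ranges$bone[duplicated(grade_ranges$bone)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(grade_ranges$max_grade < 0)) {
    stop("schema error: negative max_grade", call. = FALSE)
  }
  if (any(grade_ranges$min_grade != 0)) {
    stop("schema error: min_grade must be 0 for every bone", call. = FALSE)
  }
  entries <- do.call(rbind, lapply(seq_len(nrow(grade_ranges)), function(i) {
    g <- seq.int(0L, grade_ranges$max_grade[i])
    data.frame(bone = grade_ranges$bone[i], grade = g,
               stringsAsFactors = FALSE)
  }))
  entries$class_id <- seq_len(nrow(entries)) - 1L
  entries$class_label <- paste0(entries$bone, "_", entries$grade)
  catalog <- entries[, c("class_id", "bone", "grade", "class_label")]
  rownames(catalog) <- NULL
  class(catalog) <- c("class_catalog", "data.frame")
  catalog
}

#' Encode a (bone, grade) pair as its target-class label
#'
#' @param bone Character vector of bone names present in the catalog.
#' @param grade Integer vector of developmental grades (recycled with
#'   `bone`).
#' @param catalog A `class_catalog`, default the standard RUS-CHN catalog.
#' @return Character vector of class labels, e.g. `"radius_1"`.
#' @examples
#' encode_label("radius", 1)
#' @export
encode_label <- function(bone, grade, catalog = build_class_catalog()) {
  n <- max(length(bone), length(grade))
  bone <- rep_len(bone, n); grade <- rep_len(as.integer(grade), n)
  unknown <- setdiff(bone, catalog$bone)
  if (length(unknown)) {
    stop("schema error: unknown bone(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  label <- paste0(bone, "_", grade)
  bad <- !(label %in% catalog$class_label)
  if (any(bad)) {
    stop("grade error: grade out of range for ",
         paste(unique(paste0(bone[bad], " (grade ", grade[bad], ")")),
               collapse = ", "), call. = FALSE)
  }
  label
}

#' Decode a target-class label into its (bone, grade) pair
#'
#' Exact inverse of [encode_label()]: `radius_1` decodes to the radius at
#' developmental grade 1.
#'
#' @param class_label Character vector of catalog class labels.
#' @param catalog A `class_catalog`.
#' @return A data.frame with columns `bone` and `grade`, one row per label.
#' @examples
#' decode_label("radius_1")
#' @export
decode_label <- function(class_label, catalog = build_class_catalog()) {
  idx <- match(class_label, catalog$class_label)
  if (anyNA(idx)) {
    stop("schema error: unknown class label(s): ",
         paste(unique(class_label[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(bone = catalog$bone[idx], grade = catalog$grade[idx],
             stringsAsFactors = FALSE)
}

#' Read / write a class catalog as a delimited table
#'
#' The on-disk form is a plain CSV with columns `class_id`, `bone`, `grade`,
#' `class_label`, so non-RUS-CHN schemas can be supplied from config.
#'
#' @param path File path.
#' @param catalog A `class_catalog`.
#' @return `read_class_catalog` returns a validated `class_catalog`;
#'   `write_class_catalog` returns `path` invisibly.
#' @export
read_class_catalog <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("class_id", "bone", "grade", "class_label")
  if (!all(req %in% names(x))) {
    stop("schema error: catalog file must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  x <- x[order(x$class_id), req]
  if (!identical(as.integer(x$class_id), seq_len(nrow(x)) - 1L) ||
      anyDuplicated(x$class_label)) {
    stop("schema error: class_id must be contiguous 0-based and labels unique",
         call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("class_catalog", "data.frame")
  x
}

#' @rdname read_class_catalog
#' @export
write_class_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read grade ranges from a config file
#'
#' @param path CSV with columns `bone`, `min_grade`, `max_grade`.
#' @return A data.frame suitable for [build_class_catalog()].
#' @export
read_grade_ranges <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bone", "min_grade", "max_grade")
  if (!all(req %in% names(x))) {
    stop("schema error: grade-range file must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  x[, req]
}

#' Grade ceiling for a bone
#'
#' @param bone Character vector of bone names.
#' @param catalog A `class_catalog`.
#' @return Integer vector of per-bone maximum grades.
#' @export
max_grade <- function(bone, catalog = build_class_catalog()) {
  vapply(bone, function(b) {
    g <- catalog$grade[catalog$bone == b]
    if (!length(g)) stop("schema error: unknown bone: ", b, call. = FALSE)
    max(g)
  }, integer(1), USE.NAMES = FALSE)
}
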