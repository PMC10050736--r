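#' Validate a maturity score table
#'
#' A score table maps every (bone, developmental grade) pair to a sex-
#' specific maturity score. It must be complete over the catalog's domain
#' for both sexes and non-decreasing in grade within each bone (maturation
#' never removes points).
#'
#' @param table data.frame with columns `sex`, `bone`, `grade`, `score`.
#' @param catalog A `class_catalog`.
#' @return The table with class `score_table`, invisibly validated.
#' @export
as_score_table <- function(table, catalog = build_class_catalog()) {
  req <- c("sex", "bone", "grade", "score")
  if (!all(req %in% names(table))) {
    stop("schema error: score table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("schema error: score-table sex must be male/female", call. = FALSE)
  }
  for (s in c("male", "female")) {
    sub <- table[table$sex == s, ]
    key <- paste0(sub$bone, "_", sub$grade)
    if (!setequal(key, catalog$class_label) || anyDuplicated(key)) {
      stop("schema error: score table for sex '", s,
           "' does not cover the catalog domain exactly once", call. = FALSE)
    }
    for (b in unique(sub$bone)) {
      sc <- sub$score[sub$bone == b][order(sub$grade[sub$bone == b])]
      if (is.unsorted(sc)) {
        stop("schema error: scores for ", b, " (", s,
             ") must be non-decreasing in grade", call. = FALSE)
      }
    }
  }
  if (any(table$score < 0)) {
    stop("schema error: negative maturity score", call. = FALSE)
  }
  class(table) <- c("score_table", "data.frame")
  table
}

#' Validate a total-score-to-bone-age standard curve
#'
#' @param curve data.frame with columns `sex`, `total_score`, `age_years`;
#'   per sex, total scores strictly increasing and ages non-decreasing,
#'   with at least two knots.
#' @return The curve with class `maturity_curve`.
#' @export
as_maturity_curve <- function(curve) {
  req <- c("sex", "total_score", "age_years")
  if (!all(req %in% names(curve))) {
    stop("curve error: needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (s in unique(curve$sex)) {
    sub <- curve[curve$sex == s, ]
    sub <- sub[order(sub$total_score), ]
    if (nrow(sub) < 2L) stop("curve error: need >= 2 knots", call. = FALSE)
    if (any(diff(sub$total_score) <= 0)) {
      stop("curve error: total_score knots must be strictly increasing",
           call. = FALSE)
    }
    if (any(diff(sub$age_years) < 0)) {
      stop("curve error: age must be non-decreasing in total score",
           call. = FALSE)
    }
  }
  class(curve) <- c("maturity_curve", "data.frame")
  curve
}

#' Read score tables and standard curves from delimited files
#'
#' @param path CSV path: score table columns (`sex`, `bone`, `grade`,
#'   `score`); curve columns (`sex`, `total_score`, `age_years`).
#' @param catalog Catalog the score table must cover.
#' @return A validated `score_table` / `maturity_curve`.
#' @export
read_score_table <- function(path, catalog = build_class_catalog()) {
  as_score_table(utils::read.csv(path, stringsAsFactors = FALSE), catalog)
}

#' @rdname read_score_table
#' @export
read_maturity_curve <- function(path) {
  as_maturity_curve(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @keywords internal
grades_as_vector <- function(grades) {
  # accept a named vector, a kbs_result, or a findings data.frame
  if (inherits(grades, "kbs_result")) {
    if (length(grades$missing)) {
      stop("incomplete-input error: missing bone(s): ",
           paste(grades$missing, collapse = ", "), call. = FALSE)
    }
    grades <- stats::setNames(grades$findings$grade, grades$findings$bone)
  } else if (is.data.frame(grades)) {
    stopifnot(all(c("bone", "grade") %in% names(grades)))
    grades <- stats::setNames(grades$grade, grades$bone)
  }
  bones <- rus_chn_bones()
  missing <- setdiff(bones, names(grades))
  if (length(missing)) {
    stop("incomplete-input error: missing bone(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grades[bones]
}

#' Total maturity score from 13 developmental grades
#'
#' Scheme 1, first half: each key bone's developmental grade is converted
#' into its maturity score by table lookup for the given sex, and the 13
#' scores are summed into the total maturity score. All 13 bones must be
#' present; missing bones abort rather than impute.
#'
#' @param grades Named integer vector (names = bone identifiers), a
#'   `kbs_result`, or a data.frame with `bone`/`grade` columns.
#' @param sex `"male"` or `"female"`.
#' @param table A `score_table`.
#' @return List with `per_bone` (named score vector in canonical bone
#'   order) and `total`.
#' @export
grades_to_total_score <- function(grades, sex, table) {
  if (!sex %in% c("male", "female")) {
    stop("schema error: sex must be 'male' or 'female'", call. = FALSE)
  }
  g <- grades_as_vector(grades)
  sub <- table[table$sex == sex, ]
  idx <- match(paste0(names(g), "_", g),
               paste0(sub$bone, "_", sub$grade))
  if (anyNA(idx)) {
    bad <- names(g)[is.na(idx)]
    stop("schema error: grade outside score table for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  per_bone <- stats::setNames(sub$score[idx], names(g))
  list(per_bone = per_bone, total = sum(per_bone))
}

#' Bone age from a total maturity score
#'
#' Scheme 1, second half: the total maturity score is looked up on the
#' sex-specific standard curve by piecewise-linear interpolation between
#' the bracketing knots; scores below the first or above the last knot
#' clamp to the end ages.
#'
#' @param total_score Numeric vector of total maturity scores.
#' @param curve A `maturity_curve`.
#' @param sex `"male"` or `"female"`.
#' @return Bone age(s) in years.
#' @export
total_score_to_age <- function(total_score, curve, sex) {
  if (!sex %in% c("male", "female")) {
    stop("schema error: sex must be 'male' or 'female'", call. = FALSE)
  }
  curve <- as_maturity_curve(as.data.frame(curve))
  sub <- curve[curve$sex == sex, ]
  if (nrow(sub) < 2L) stop("curve error: no curve for sex ", sex, call. = FALSE)
  stats::approx(sub$total_score, sub$age_years, xout = total_score,
                rule = 2, ties = "ordered")$y
}

#' Scheme-1 bone-age model (score tables + standard curve)
#'
#' Bundles a score table and a standard curve into a predictor object so
#' the table-lookup pathway and the regression pathway share one
#' [predict_age()] interface.
#'
#' @param table A `score_table`.
#' @param curve A `maturity_curve`.
#' @return Object of class `rus_scheme1`.
#' @export
scheme1_model <- function(table, curve) {
  structure(list(table = as_score_table(as.data.frame(table)),
                 curve = as_maturity_curve(as.data.frame(curve))),
            class = "rus_scheme1")
}

#' Predict bone age from 13 developmental grades
#'
#' Dispatches on the model: a `rus_scheme1` object performs the
#' table-lookup + standard-curve computation; an `age_regressor` (Schemes
#' 2/3) runs the fitted gradient-boosted trees. Both require the complete
#' 13-grade vector.
#'
#' @param model A `rus_scheme1` or `age_regressor`.
#' @param grades Named grade vector / `kbs_result` / bone-grade data.frame,
#'   or a 13-column matrix (canonical bone order) for many cases at once.
#' @param sex `"male"` or `"female"` (scalar, or vector matching the rows
#'   of a grade matrix).
#' @param ... Unused.
#' @return Bone age in years.
#' @export
predict_age <- function(model, grades, sex, ...) UseMethod("predict_age")

#' @export
predict_age.rus_scheme1 <- function(model, grades, sex, ...) {
  if (is.matrix(grades)) {
    stopifnot(ncol(grades) == 13L, length(sex) %in% c(1L, nrow(grades)))
    sex <- rep_len(sex, nrow(grades))
    return(vapply(seq_len(nrow(grades)), function(i) {
      predict_age(model, stats::setNames(grades[i, ], rus_chn_bones()),
                  sex[i])
    }, numeric(1)))
  }
  s <- grades_to_total_score(grades, sex, model$table)
  total_score_to_age(s$total, model$curve, sex)
}
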