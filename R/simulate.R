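#' @keywords internal
max_age_for_sex <- function(sex) ifelse(sex == "male", 18, 17)

#' @keywords internal
#' Per-bone phase offsets (|phase| < 0.5) staggering the ages at which
#' different bones step to their next grade; without them, bones sharing a
#' grade ceiling would all increment at the same ages and the total-score
#' step function would be needlessly coarse.
bone_phases <- function() {
  i <- seq_len(13L) - 1L
  k <- (i * 5L) %% 13L
  stats::setNames(((k + 0.5) / 13 - 0.5) * 0.9, rus_chn_bones())
}

#' Expected developmental grade at a given age
#'
#' The generative grade-vs-age map of the simulator: a linear ramp from
#' grade 0 at age 0 to the bone's ceiling at the sex's maximum age,
#' rounded to the nearest integer after a small fixed per-bone phase
#' offset, and clipped to the grade range. Monotone non-decreasing in age;
#' exactly 0 at age 0 and exactly the ceiling at the maximum age.
#'
#' @param bone Bone name(s).
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"` (sets the maximum age, 18 / 17).
#' @param catalog A `class_catalog`.
#' @return Integer grade(s).
#' @export
expected_grade <- function(bone, age, sex, catalog = build_class_catalog()) {
  n <- max(length(bone), length(age), length(sex))
  bone <- rep_len(bone, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  mg <- max_grade(bone, catalog)
  ph <- bone_phases()[bone]
  g <- round(mg * age / max_age_for_sex(sex) + ph)
  as.integer(pmin(pmax(g, 0L), mg))
}

#' Simulation configuration
#'
#' Parameters of the synthetic ground-truth and detector-output generator.
#' The defaults emulate a held-out evaluation split: 450 images, balanced
#' sexes, ages uniform over each sex's assessable range (under 18 years
#' male / under 17 female), a detector that confuses the grade with a
#' neighbouring one 10% of the time, jitters boxes by a few percent of
#' their size, and emits occasional low-confidence spurious candidates.
#'
#' @param n_images Number of simulated radiographs.
#' @param seed Integer RNG seed; the whole generator is deterministic
#'   given it.
#' @param sex_ratio Probability a case is male.
#' @param truth_grade_jitter Probability an expert truth grade deviates by
#'   one from the expected grade-for-age (biological spread).
#' @param p_confuse Probability the detector's primary candidate carries a
#'   wrong (neighbouring) grade.
#' @param max_grade_offset Largest grade confusion offset.
#' @param box_jitter_sd Box corner jitter, s.d. relative to box size.
#' @param conf_correct,conf_spurious Beta shape pairs for the confidence of
#'   primary (high mode) and spurious (low mode) candidates; their overlap
#'   controls when rising thresholds start losing bones.
#' @param spurious_rate Poisson mean of extra low-confidence candidates per
#'   (image, bone).
#' @param drop_rate Probability the detector misses a bone entirely.
#' @param image_size Canvas side in pixels for the schematic hand layout.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_images = 450, seed = 1, sex_ratio = 0.5,
                       truth_grade_jitter = 0.05,
                       p_confuse = 0.1, max_grade_offset = 1,
                       box_jitter_sd = 0.03,
                       conf_correct = c(8, 2), conf_spurious = c(2, 8),
                       spurious_rate = 0.5, drop_rate = 0,
                       image_size = 640) {
  cfg <- list(n_images = as.integer(n_images), seed = as.integer(seed),
              sex_ratio = sex_ratio, truth_grade_jitter = truth_grade_jitter,
              p_confuse = p_confuse,
              max_grade_offset = as.integer(max_grade_offset),
              box_jitter_sd = box_jitter_sd, conf_correct = conf_correct,
              conf_spurious = conf_spurious, spurious_rate = spurious_rate,
              drop_rate = drop_rate, image_size = image_size)
  probs <- c(sex_ratio = cfg$sex_ratio, truth_grade_jitter =
               cfg$truth_grade_jitter, p_confuse = cfg$p_confuse,
             drop_rate = cfg$drop_rate)
  if (any(probs < 0 | probs > 1) || cfg$n_images < 1 ||
      cfg$spurious_rate < 0 || cfg$box_jitter_sd < 0 ||
      cfg$max_grade_offset < 1) {
    stop("config error: probabilities must lie in [0,1] and rates be >= 0",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
#' Schematic hand template: 13 disjoint axis-aligned boxes on the canvas,
#' rows from distal phalanges at the top down to radius/ulna at the wrist.
hand_template <- function(image_size = 640) {
  u <- image_size / 640
  row_y <- c(20, 140, 260, 380, 510) * u   # distal, middle, prox, MC, wrist
  col_x <- c(40, 230, 420) * u
  w <- 150 * u; h <- 100 * u
  cell <- function(col, row, shrink = 0) {
    c(x_min = col_x[col] + shrink, y_min = row_y[row] + shrink,
      x_max = col_x[col] + w - shrink, y_max = row_y[row] + h - shrink)
  }
  boxes <- rbind(
    radius = cell(1, 5), ulna = cell(2, 5),
    first_metacarpal = cell(1, 4), third_metacarpal = cell(2, 4),
    fifth_metacarpal = cell(3, 4),
    first_proximal_phalange = cell(1, 3),
    third_proximal_phalange = cell(2, 3),
    fifth_proximal_phalange = cell(3, 3),
    third_middle_phalange = cell(2, 2, shrink = 8 * u),
    fifth_middle_phalange = cell(3, 2, shrink = 8 * u),
    first_distal_phalange = cell(1, 1, shrink = 14 * u),
    third_distal_phalange = cell(2, 1, shrink = 14 * u),
    fifth_distal_phalange = cell(3, 1, shrink = 14 * u))
  as.data.frame(boxes)[rus_chn_bones(), ]
}

#' Simulate ground-truth annotated cases
#'
#' Draws `n_images` cases: sex Bernoulli(`sex_ratio`), chronological age
#' uniform over the sex's range, per-bone truth grades from the
#' [expected_grade()] ramp with optional bounded integer jitter, and 13
#' disjoint boxes from a schematic hand template under a per-image affine
#' jitter (common scale and shift). Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @param catalog A `class_catalog`.
#' @return Annotations data.frame (13 rows per image).
#' @export
simulate_cases <- function(config = sim_config(),
                           catalog = build_class_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bones <- rus_chn_bones()
  template <- hand_template(config$image_size)
  rows <- lapply(seq_len(config$n_images), function(i) {
    sex <- if (stats::runif(1) < config$sex_ratio) "male" else "female"
    age <- stats::runif(1, 0, max_age_for_sex(sex))
    g <- expected_grade(bones, age, sex, catalog)
    if (config$truth_grade_jitter > 0) {
      flip <- stats::runif(13) < config$truth_grade_jitter
      g <- g + ifelse(flip, sample(c(-1L, 1L), 13, replace = TRUE), 0L)
      g <- pmin(pmax(g, 0L), max_grade(bones, catalog))
    }
    s <- exp(stats::rnorm(1, 0, 0.02))
    tx <- stats::rnorm(1, 0, 6); ty <- stats::rnorm(1, 0, 6)
    data.frame(image_id = sprintf("img_%04d", i), sex = sex,
               chronological_age = round(age, 2), bone = bones,
               grade = as.integer(g),
               x_min = template$x_min * s + tx,
               y_min = template$y_min * s + ty,
               x_max = template$x_max * s + tx,
               y_max = template$y_max * s + ty,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
jitter_box <- function(box, sd_rel) {
  w <- box["x_max"] - box["x_min"]; h <- box["y_max"] - box["y_min"]
  b <- box + stats::rnorm(4, 0, sd_rel) * c(w, h, w, h)
  # keep the box non-degenerate
  if (b["x_max"] <= b["x_min"]) b[c("x_min", "x_max")] <-
      mean(b[c("x_min", "x_max")]) + c(-1, 1)
  if (b["y_max"] <= b["y_min"]) b[c("y_min", "y_max")] <-
      mean(b[c("y_min", "y_max")]) + c(-1, 1)
  b
}

#' @keywords internal
confused_grade <- function(g, mg, max_offset) {
  d <- sample.int(max_offset, 1)
  cand <- g + sample(c(-1L, 1L), 1) * d
  if (cand < 0L || cand > mg) cand <- g - sign(cand - g) * d
  as.integer(pmin(pmax(cand, 0L), mg))
}

#' Simulate noisy detector output for annotated cases
#'
#' Emulates raw multi-candidate detector inference: per (image, bone),
#' with probability `1 - drop_rate` a primary candidate at the truth grade
#' (probability `1 - p_confuse`) or a neighbouring grade, with a jittered
#' box and a confidence drawn from the high-mode Beta; plus
#' Poisson(`spurious_rate`) extra candidates at random grades with larger
#' box jitter and low-mode confidences. Deterministic given
#' `config$seed`.
#'
#' @param truth Annotations data.frame from [simulate_cases()].
#' @param config A `sim_config`.
#' @param catalog A `class_catalog`.
#' @return Raw detections data.frame.
#' @export
simulate_detector_output <- function(truth, config = sim_config(),
                                     catalog = build_class_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104729L)  # independent stream from simulate_cases
  mg_all <- stats::setNames(max_grade(rus_chn_bones(), catalog),
                            rus_chn_bones())
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    mg <- mg_all[[row$bone]]
    box <- c(x_min = row$x_min, y_min = row$y_min,
             x_max = row$x_max, y_max = row$y_max)
    recs <- list()
    if (stats::runif(1) >= config$drop_rate) {
      g <- if (stats::runif(1) < config$p_confuse) {
        confused_grade(row$grade, mg, config$max_grade_offset)
      } else row$grade
      b <- jitter_box(box, config$box_jitter_sd)
      recs[[1]] <- data.frame(
        image_id = row$image_id, class_label = paste0(row$bone, "_", g),
        confidence = stats::rbeta(1, config$conf_correct[1],
                                  config$conf_correct[2]),
        x_min = b[["x_min"]], y_min = b[["y_min"]],
        x_max = b[["x_max"]], y_max = b[["y_max"]],
        stringsAsFactors = FALSE)
    }
    n_sp <- stats::rpois(1, config$spurious_rate)
    for (k in seq_len(n_sp)) {
      g <- sample.int(mg + 1L, 1) - 1L
      b <- jitter_box(box, 3 * config$box_jitter_sd + 0.02)
      recs[[length(recs) + 1L]] <- data.frame(
        image_id = row$image_id, class_label = paste0(row$bone, "_", g),
        confidence = stats::rbeta(1, config$conf_spurious[1],
                                  config$conf_spurious[2]),
        x_min = b[["x_min"]], y_min = b[["y_min"]],
        x_max = b[["x_max"]], y_max = b[["y_max"]],
        stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  det <- do.call(rbind, out)
  if (is.null(det)) {
    det <- data.frame(image_id = character(), class_label = character(),
                      confidence = numeric(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), stringsAsFactors = FALSE)
  }
  rownames(det) <- NULL
  det
}

#' Synthetic stand-in score tables and standard curves
#'
#' The real China-05 maturity-score tables and total-score-to-age standard
#' curves are not in the public domain, so the package generates clearly
#' synthetic, non-clinical stand-ins with the right structural properties:
#' per-bone scores strictly increasing in grade (grade 0 scores 0, radius
#' and ulna weighted above the short bones), and per-sex strictly
#' increasing curves anchored at age 0 for total score 0 and at the sex's
#' maximum assessable age (18 male / 17 female) for the all-ceiling score.
#' The curve knots invert the simulator's own grade-vs-age ramp, one knot
#' per attainable total score at the mean age attaining it. Deterministic.
#'
#' @param catalog A `class_catalog`.
#' @return List with `score_table` and `curve`, both covering both sexes.
#' @export
make_toy_reference <- function(catalog = build_class_catalog()) {
  bones <- rus_chn_bones()
  weights <- list(
    male = stats::setNames(c(3, 2, rep(1, 11)), bones),
    female = stats::setNames(c(4, 3, rep(1, 11)), bones))
  tabs <- lapply(c(male = "male", female = "female"), function(s) {
    data.frame(sex = s, bone = catalog$bone, grade = catalog$grade,
               score = weights[[s]][catalog$bone] * catalog$grade,
               stringsAsFactors = FALSE)
  })
  table <- as_score_table(do.call(rbind, unname(tabs)), catalog)
  curves <- lapply(c(male = "male", female = "female"), function(s) {
    max_a <- max_age_for_sex(s)
    ages <- seq(0, max_a, by = 0.004)
    total <- rowSums(vapply(bones, function(b) {
      weights[[s]][[b]] * expected_grade(b, ages, s, catalog)
    }, numeric(length(ages))))
    knots <- stats::aggregate(ages, list(total_score = total), mean)
    names(knots)[2] <- "age_years"
    knots <- knots[order(knots$total_score), ]
    knots$age_years[1] <- 0
    knots$age_years[nrow(knots)] <- max_a
    data.frame(sex = s, total_score = knots$total_score,
               age_years = knots$age_years, stringsAsFactors = FALSE)
  })
  curve <- as_maturity_curve(do.call(rbind, unname(curves)))
  rownames(table) <- rownames(curve) <- NULL
  list(score_table = table, curve = curve)
}

#' Write a full synthetic benchmark to a directory
#'
#' Convenience wrapper: simulates cases and detector output and writes
#' annotations, detections, the class catalog, the synthetic score table
#' and the standard curve in the package's interchange formats.
#'
#' @param dir Output directory (created if needed).
#' @param config A `sim_config`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_benchmark <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- build_class_catalog()
  truth <- simulate_cases(config, catalog)
  det <- simulate_detector_output(truth, config, catalog)
  ref <- make_toy_reference(catalog)
  paths <- list(
    annotations = file.path(dir, "annotations.csv"),
    detections = file.path(dir, "detections.csv"),
    catalog = file.path(dir, "class_catalog.csv"),
    score_table = file.path(dir, "synthetic_score_table.csv"),
    curve = file.path(dir, "synthetic_maturity_curve.csv"))
  write_annotations(truth, paths$annotations, catalog)
  write_detections(det, paths$detections)
  write_class_catalog(catalog, paths$catalog)
  utils::write.csv(as.data.frame(ref$score_table), paths$score_table,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(ref$curve), paths$curve,
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
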