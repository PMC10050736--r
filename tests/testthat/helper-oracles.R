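# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the package
# implementations: plain loops over records.

# Brute-force per-bone argmax decode: one pass over the candidates,
# splitting each label on its trailing "_<grade>" itself (independent of
# the package's catalog machinery) and keeping the best candidate per bone
# by (confidence desc, grade asc, area desc).
oracle_kbs <- function(det, catalog, threshold) {
  bones <- unique(catalog$bone)
  findings <- list()
  for (i in seq_len(nrow(det))) {
    if (det$confidence[i] < threshold) next
    lab <- det$class_label[i]
    b <- sub("_[0-9]+$", "", lab)
    cand <- list(grade = as.integer(sub("^.*_", "", lab)),
                 confidence = det$confidence[i],
                 area = (det$x_max[i] - det$x_min[i]) *
                   (det$y_max[i] - det$y_min[i]))
    best <- findings[[b]]
    if (is.null(best) ||
        cand$confidence > best$confidence ||
        (cand$confidence == best$confidence && cand$grade < best$grade) ||
        (cand$confidence == best$confidence && cand$grade == best$grade &&
           cand$area > best$area)) {
      findings[[b]] <- cand
    }
  }
  list(findings = findings, missing = setdiff(bones, names(findings)))
}

# Naive loop-based regression metrics.
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  sa <- 0; ss <- 0; sp <- 0
  for (i in seq_len(n)) {
    sa <- sa + abs(y[i] - yhat[i])
    ss <- ss + (y[i] - yhat[i])^2
    sp <- sp + ((y[i] - yhat[i]) / y[i])^2
  }
  c(mae = sa / n, rmse = sqrt(ss / n), rmspe = sqrt(sp / n))
}

# Naive IoU from explicit corner arithmetic.
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

# Naive accuracy / weighted precision from raw label pairs.
oracle_grade_report <- function(true_g, pred_g) {
  acc <- mean(true_g == pred_g)
  wp <- 0
  for (g in unique(true_g)) {
    support <- sum(true_g == g)
    tp <- sum(true_g == g & pred_g == g)
    fp <- sum(true_g != g & pred_g == g)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    wp <- wp + support * prec
  }
  c(accuracy = acc, weighted_precision = wp / length(true_g))
}

# Naive all-point-interpolated AP for a single class from ranked TP flags.
oracle_ap <- function(tp_flags, n_truth) {
  if (n_truth == 0 || !length(tp_flags)) return(0)
  ap <- 0; tp <- 0; prev_recall <- 0
  for (i in seq_along(tp_flags)) {
    tp <- tp + tp_flags[i]
  }
  n <- length(tp_flags)
  cum_tp <- cumsum(tp_flags)
  prec <- cum_tp / seq_len(n)
  recall <- cum_tp / n_truth
  for (i in seq_len(n)) {
    p_env <- max(prec[i:n])
    ap <- ap + (recall[i] - prev_recall) * p_env
    prev_recall <- recall[i]
  }
  ap
}

# Random detection instance over the full catalog.
random_detections <- function(catalog, n, image_id = "im1",
                              tie_fraction = 0) {
  labs <- sample(catalog$class_label, n, replace = TRUE)
  conf <- stats::runif(n)
  if (tie_fraction > 0 && n > 2) {
    k <- max(2L, floor(n * tie_fraction))
    conf[sample(n, k)] <- round(stats::runif(1), 1)
  }
  x <- stats::runif(n, 0, 600); y <- stats::runif(n, 0, 600)
  data.frame(image_id = image_id, class_label = labs, confidence = conf,
             x_min = x, y_min = y,
             x_max = x + stats::runif(n, 5, 40),
             y_max = y + stats::runif(n, 5, 40),
             stringsAsFactors = FALSE)
}

# Noise-free simulation settings shared by several tests.
noiseless_config <- function(n_images, seed) {
  sim_config(n_images = n_images, seed = seed, truth_grade_jitter = 0,
             p_confuse = 0, box_jitter_sd = 0, spurious_rate = 0,
             drop_rate = 0)
}

# Extract the canonical 13-column grade matrix + sex vector from decoded
# results, using the annotation table for sex.
grades_from_results <- function(results, truth) {
  g <- t(vapply(results, function(r) {
    stats::setNames(r$findings$grade, r$findings$bone)[rus_chn_bones()]
  }, integer(13)))
  colnames(g) <- rus_chn_bones()
  list(grades = g,
       sex = truth$sex[match(names(results), truth$image_id)],
       age = truth$chronological_age[match(names(results), truth$image_id)])
}

# Grade feature set (13 bone columns + sex + bone_age) of noiseless cases
# labelled by a scheme-1 model.
scheme1_feature_set <- function(n, seed, model) {
  truth <- simulate_cases(noiseless_config(n, seed))
  per_image <- split(truth, truth$image_id)
  g <- do.call(rbind, lapply(per_image, function(x) {
    stats::setNames(x$grade, x$bone)[rus_chn_bones()]
  }))
  colnames(g) <- rus_chn_bones()
  sex <- vapply(per_image, function(x) x$sex[1], character(1))
  df <- as.data.frame(g)
  df$sex <- sex
  df$bone_age <- predict_age(model, g, sex)
  df
}
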