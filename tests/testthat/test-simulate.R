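catalog <- build_class_catalog()

test_that("simulation is byte-deterministic given the seed", {
  cfg <- sim_config(n_images = 15, seed = 7)
  a <- simulate_cases(cfg); b <- simulate_cases(cfg)
  expect_identical(a, b)
  da <- simulate_detector_output(a, cfg)
  db <- simulate_detector_output(b, cfg)
  expect_identical(da, db)
  # a different seed changes the draw
  expect_false(identical(a, simulate_cases(sim_config(n_images = 15,
                                                      seed = 8))))
})

test_that("the grade-for-age ramp anchors at 0 and at the ceiling and is monotone", {
  bones <- rus_chn_bones()
  expect_equal(expected_grade(bones, 0, "male"), rep(0L, 13))
  expect_equal(expected_grade(bones, 18, "male"),
               max_grade(bones, catalog))
  expect_equal(expected_grade(bones, 17, "female"),
               max_grade(bones, catalog))
  ages <- seq(0, 18, by = 0.05)
  for (b in c("radius", "third_middle_phalange")) {
    g <- expected_grade(b, ages, "male")
    expect_true(all(diff(g) >= 0))
  }
  # noiseless cases sorted by age have non-decreasing per-bone grades
  truth <- simulate_cases(noiseless_config(300, 13))
  for (b in c("radius", "ulna", "fifth_distal_phalange")) {
    sub <- truth[truth$bone == b & truth$sex == "female", ]
    sub <- sub[order(sub$chronological_age), ]
    expect_true(all(diff(sub$grade) >= 0))
  }
})

test_that("simulated annotations respect the data contract", {
  truth <- simulate_cases(sim_config(n_images = 30, seed = 29))
  expect_equal(nrow(truth), 30 * 13)
  expect_true(all(truth$sex %in% c("male", "female")))
  expect_true(all(truth$chronological_age[truth$sex == "male"] < 18))
  expect_true(all(truth$chronological_age[truth$sex == "female"] < 17))
  # grades inside the catalog ranges, boxes valid and disjoint per image
  expect_true(all(paste0(truth$bone, "_", truth$grade) %in%
                    catalog$class_label))
  img <- truth[truth$image_id == truth$image_id[1], ]
  ov <- outer(seq_len(13), seq_len(13), Vectorize(function(i, j) {
    if (i >= j) return(0)
    iou(as.numeric(img[i, c("x_min", "y_min", "x_max", "y_max")]),
        as.numeric(img[j, c("x_min", "y_min", "x_max", "y_max")]))
  }))
  expect_true(all(ov == 0))
})

test_that("detector-output noise knobs behave as documented", {
  cfg0 <- noiseless_config(10, 37)
  truth <- simulate_cases(cfg0)
  det <- simulate_detector_output(truth, cfg0)
  # noiseless: one candidate per (image, bone), exact grade and box
  expect_equal(nrow(det), 130L)
  res <- kbs_decode_all(det, catalog, 0)
  m <- mean_iou_per_bone(res, truth)
  expect_equal(m$mean_iou, rep(1, 13))
  rep_ <- grade_classification_report(res, truth, catalog)
  expect_equal(rep_$overall_accuracy, 1)
  # drop rate 1: every bone missing at any positive threshold
  cfg_drop <- sim_config(n_images = 5, seed = 37, drop_rate = 1,
                         spurious_rate = 0)
  det_drop <- simulate_detector_output(simulate_cases(cfg_drop), cfg_drop)
  expect_equal(nrow(det_drop), 0L)
  # spurious candidates carry lower confidence on average
  cfg_sp <- sim_config(n_images = 30, seed = 41, spurious_rate = 2)
  t_sp <- simulate_cases(cfg_sp)
  d_sp <- simulate_detector_output(t_sp, cfg_sp)
  expect_gt(nrow(d_sp), 30 * 13)
  expect_error(sim_config(p_confuse = 1.2), "config error")
})

test_that("detector grade confusion hits the configured rate", {
  cfg <- sim_config(n_images = 200, seed = 43, p_confuse = 0.25,
                    truth_grade_jitter = 0, spurious_rate = 0)
  truth <- simulate_cases(cfg)
  det <- simulate_detector_output(truth, cfg)
  res <- kbs_decode_all(det, catalog, 0)
  rep_ <- grade_classification_report(res, truth, catalog)
  # overall accuracy ~ Binomial(200*13, 0.75)
  p <- rep_$overall_accuracy
  se <- sqrt(0.75 * 0.25 / (200 * 13))
  expect_lt(abs(p - 0.75), 4 * se)
})

test_that("synthetic reference tables have the structural properties of score tables", {
  ref <- make_toy_reference(catalog)
  tab <- ref$score_table
  # grade 0 scores 0 for every bone and sex
  expect_true(all(tab$score[tab$grade == 0] == 0))
  # strictly increasing in grade within each (sex, bone)
  for (s in c("male", "female")) {
    for (b in c("radius", "fifth_metacarpal")) {
      sc <- tab$score[tab$sex == s & tab$bone == b]
      expect_true(all(diff(sc) > 0))
    }
  }
  # all-ceiling total score maps to the sex's maximum age
  m1 <- scheme1_model(ref$score_table, ref$curve)
  g_max <- stats::setNames(max_grade(rus_chn_bones(), catalog),
                           rus_chn_bones())
  expect_equal(predict_age(m1, g_max, "male"), 18)
  expect_equal(predict_age(m1, g_max, "female"), 17)
  g0 <- stats::setNames(rep(0L, 13), rus_chn_bones())
  expect_equal(predict_age(m1, g0, "male"), 0)
  # scheme-1 age monotone in case age on a noiseless simulation
  truth <- simulate_cases(noiseless_config(150, 47))
  per <- split(truth, truth$image_id)
  age <- vapply(per, function(x) x$chronological_age[1], numeric(1))
  sex <- vapply(per, function(x) x$sex[1], character(1))
  pred <- vapply(per, function(x) {
    predict_age(m1, stats::setNames(x$grade, x$bone), x$sex[1])
  }, numeric(1))
  for (s in c("male", "female")) {
    o <- order(age[sex == s])
    expect_true(all(diff(pred[sex == s][o]) >= 0))
  }
})

test_that("a full synthetic benchmark round-trips through the interchange files", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_benchmark(dir, sim_config(n_images = 8, seed = 53))
  expect_true(all(file.exists(unlist(paths))))
  truth <- read_annotations(paths$annotations)
  det <- read_detections(paths$detections, read_class_catalog(paths$catalog))
  expect_equal(length(unique(truth$image_id)), 8L)
  tab <- read_score_table(paths$score_table)
  curve <- read_maturity_curve(paths$curve)
  expect_s3_class(tab, "score_table")
  expect_s3_class(curve, "maturity_curve")
})
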