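catalog <- build_class_catalog()

test_that("regression metrics match their closed forms", {
  expect_equal(unname(regression_metrics(c(1, 2, 3), c(1, 2, 3))),
               c(0, 0, 0))
  m <- regression_metrics(c(1, 2), c(2, 4))
  expect_equal(unname(m), c(1.5, sqrt(2.5), 1))
  m1 <- regression_metrics(4, 3)
  expect_equal(unname(m1), c(1, 1, 0.25))
  expect_error(regression_metrics(c(0, 1), c(1, 1)), "undefined-metric")
  expect_equal(unname(regression_metrics(c(0, 1), c(1, 1),
                                         rmspe = FALSE)[1:2]),
               c(0.5, sqrt(0.5)))
})

test_that("metrics equal a brute-force recomputation and MAE never exceeds RMSE", {
  set.seed(53)
  for (i in 1:60) {
    n <- sample(1:40, 1)
    y <- stats::runif(n, 0.5, 18)
    yhat <- y + stats::rnorm(n, 0, 0.7)
    got <- regression_metrics(y, yhat)
    expect_equal(unname(got), unname(oracle_metrics(y, yhat)),
                 tolerance = 1e-12)
    expect_lte(got[["mae"]], got[["rmse"]] + 1e-12)
  }
})

test_that("stratified metrics use half-open yearly bands and pool back exactly", {
  y <- c(0.5, 1.0, 1.7, 5.2, 5.9)
  yhat <- y + c(0.1, -0.2, 0.3, 0, -0.4)
  tab <- stratified_metrics(y, yhat, by = "age_band")
  # age exactly 1.0 falls in band 1-2
  expect_equal(tab$n[tab$age_band == "1-2"], 2L)
  expect_equal(tab$n[tab$age_band == "0-1"], 1L)
  # single stratum reduces to the plain metrics
  one <- stratified_metrics(y, yhat, sex = rep("male", 5), by = "sex")
  expect_equal(c(one$mae, one$rmse, one$rmspe),
               unname(regression_metrics(y, yhat)))
  # pooled MAE is the support-weighted mean of per-stratum MAEs
  pooled <- regression_metrics(y, yhat)[["mae"]]
  expect_equal(sum(tab$mae * tab$n) / sum(tab$n), pooled,
               tolerance = 1e-12)
})

test_that("per-bone mean IoU matches the box oracle and excludes missing bones", {
  truth <- simulate_cases(noiseless_config(6, 71))
  det <- simulate_detector_output(truth, noiseless_config(6, 71))
  results <- kbs_decode_all(det, catalog, 0.1)
  tab <- mean_iou_per_bone(results, truth)
  expect_equal(tab$mean_iou, rep(1, 13))  # noiseless: identical boxes
  expect_true(all(tab$n_missing == 0))
  # knock the radius out of one image: excluded with a count, not zeroed
  results2 <- results
  f <- results2[[1]]$findings
  results2[[1]]$findings <- f[f$bone != "radius", ]
  results2[[1]]$missing <- "radius"
  tab2 <- mean_iou_per_bone(results2, truth)
  expect_equal(tab2$n_missing[tab2$bone == "radius"], 1L)
  expect_equal(tab2$n[tab2$bone == "radius"], 5L)
  expect_equal(tab2$mean_iou[tab2$bone == "radius"], 1)
  expect_error(mean_iou_per_bone(results,
                                 transform(truth, image_id = paste0("x", image_id))),
               "evaluation error")
})

test_that("grade report reproduces the hand confusion-matrix example", {
  # 2-grade toy: truth (0,0,1), predictions (0,1,1)
  tiny_cat <- build_class_catalog(data.frame(bone = "radius", min_grade = 0L,
                                             max_grade = 1L))
  got <- oracle_grade_report(c(0, 0, 1), c(0, 1, 1))
  expect_equal(got[["accuracy"]], 2 / 3)
  expect_equal(got[["weighted_precision"]], 5 / 6)
})

test_that("grade report matches a brute-force recomputation on simulated data", {
  cfg <- sim_config(n_images = 40, seed = 83, p_confuse = 0.3,
                    spurious_rate = 0, truth_grade_jitter = 0)
  truth <- simulate_cases(cfg)
  det <- simulate_detector_output(truth, cfg)
  results <- kbs_decode_all(det, catalog, 0.1)
  rep_ <- grade_classification_report(results, truth, catalog)
  for (b in c("radius", "fifth_distal_phalange")) {
    tg <- truth$grade[truth$bone == b][match(names(results),
                                             truth$image_id[truth$bone == b])]
    pg <- vapply(results, function(r)
      r$findings$grade[r$findings$bone == b], integer(1))
    want <- oracle_grade_report(tg, pg)
    row <- rep_$per_bone[rep_$per_bone$bone == b, ]
    expect_equal(row$accuracy, want[["accuracy"]], tolerance = 1e-12)
    expect_equal(row$weighted_precision, want[["weighted_precision"]],
                 tolerance = 1e-12)
    expect_equal(sum(rep_$confusion[[b]]), length(names(results)))
  }
})

test_that("mAP@0.5 handles the canonical precision-recall cases", {
  truth <- simulate_cases(noiseless_config(4, 91))
  det <- simulate_detector_output(truth, noiseless_config(4, 91))
  # detections identical to truth at full confidence
  perfect <- det; perfect$confidence <- 1
  expect_equal(map_at_iou(perfect, truth)$map, 1)
  # no detections at all
  expect_equal(map_at_iou(det[0, ], truth)$map, 0)
  expect_error(map_at_iou(det, truth[0, ]), "evaluation error")
  # one class, one truth, detections ranked TP then FP -> AP stays 1
  t1 <- truth[truth$image_id == truth$image_id[1] & truth$bone == "radius", ]
  d1 <- data.frame(image_id = t1$image_id,
                   class_label = paste0("radius_", t1$grade),
                   confidence = c(0.9, 0.5),
                   x_min = c(t1$x_min, t1$x_min + 500),
                   y_min = c(t1$y_min, t1$y_min + 500),
                   x_max = c(t1$x_max, t1$x_max + 520),
                   y_max = c(t1$y_max, t1$y_max + 520))
  expect_equal(map_at_iou(d1, t1)$map, 1)
  expect_equal(oracle_ap(c(1, 0), 1), 1)
  # FP ranked first halves the interpolated precision at recall 1
  d2 <- d1; d2$confidence <- c(0.5, 0.9)
  expect_equal(map_at_iou(d2, t1)$map, oracle_ap(c(0, 1), 1))
  expect_equal(map_at_iou(d2, t1)$map, 0.5)
})

test_that("mAP equals the per-class oracle on random jittered sets", {
  set.seed(97)
  for (i in 1:5) {
    cfg <- sim_config(n_images = 10, seed = 100 + i, p_confuse = 0.2,
                      spurious_rate = 1, box_jitter_sd = 0.08)
    truth <- simulate_cases(cfg)
    det <- simulate_detector_output(truth, cfg)
    got <- map_at_iou(det, truth, 0.5)
    # oracle: recompute each class AP with independent greedy matching
    truth$lab <- paste0(truth$bone, "_", truth$grade)
    aps <- vapply(unique(truth$lab), function(cl) {
      t_cl <- truth[truth$lab == cl, ]
      d_cl <- det[det$class_label == cl, ]
      if (!nrow(d_cl)) return(0)
      d_cl <- d_cl[order(-d_cl$confidence), ]
      used <- rep(FALSE, nrow(t_cl))
      tp <- numeric(nrow(d_cl))
      for (j in seq_len(nrow(d_cl))) {
        best <- 0; bi <- 0
        for (k in seq_len(nrow(t_cl))) {
          if (used[k] || t_cl$image_id[k] != d_cl$image_id[j]) next
          ov <- oracle_iou(as.numeric(d_cl[j, c("x_min", "y_min", "x_max", "y_max")]),
                           as.numeric(t_cl[k, c("x_min", "y_min", "x_max", "y_max")]))
          if (ov > best) { best <- ov; bi <- k }
        }
        if (bi > 0 && best >= 0.5) { used[bi] <- TRUE; tp[j] <- 1 }
      }
      oracle_ap(tp, nrow(t_cl))
    }, numeric(1))
    expect_equal(got$map, mean(aps), tolerance = 1e-10)
  }
})
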