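catalog <- build_class_catalog()

toy_table <- function() {
  # score equal to the grade, both sexes
  as_score_table(do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(sex = s, bone = catalog$bone, grade = catalog$grade,
               score = catalog$grade, stringsAsFactors = FALSE)
  })), catalog)
}

toy_curve <- function() {
  as_maturity_curve(do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(sex = s, total_score = c(0, 100), age_years = c(0, 10),
               stringsAsFactors = FALSE)
  })))
}

test_that("total maturity score is the tabled sum over the 13 bones", {
  tab <- toy_table()
  g0 <- stats::setNames(rep(0L, 13), rus_chn_bones())
  expect_equal(grades_to_total_score(g0, "male", tab)$total, 0)
  g1 <- stats::setNames(rep(1L, 13), rus_chn_bones())
  s <- grades_to_total_score(g1, "female", tab)
  expect_equal(s$total, 13)
  expect_equal(unname(s$per_bone), rep(1, 13))
  # order of the input vector is irrelevant
  shuffled <- g1[sample(13)]
  expect_equal(grades_to_total_score(shuffled, "female", tab)$total, 13)
  # missing bone aborts, no silent imputation
  expect_error(grades_to_total_score(g1[-1], "male", tab),
               "incomplete-input")
  expect_error(grades_to_total_score(g1, "other", tab), "schema error")
})

test_that("standard-curve lookup interpolates linearly and clamps at the ends", {
  curve <- toy_curve()
  expect_equal(total_score_to_age(0, curve, "male"), 0)
  expect_equal(total_score_to_age(100, curve, "male"), 10)
  expect_equal(total_score_to_age(50, curve, "male"), 5)
  expect_equal(total_score_to_age(110, curve, "male"), 10)  # clamped
  expect_equal(total_score_to_age(-5, curve, "female"), 0)  # clamped
  bad <- data.frame(sex = "male", total_score = c(0, 0), age_years = c(0, 1))
  expect_error(total_score_to_age(1, bad, "male"), "curve error")
})

test_that("scheme 1 composes table and curve and is monotone in any grade", {
  m1 <- scheme1_model(toy_table(), toy_curve())
  g1 <- stats::setNames(rep(1L, 13), rus_chn_bones())
  expect_equal(predict_age(m1, g1, "male"), 13 / 100 * 10)
  # raising one grade never lowers the age (monotone table and curve)
  ref <- make_toy_reference(catalog)
  m <- scheme1_model(ref$score_table, ref$curve)
  set.seed(41)
  for (i in 1:20) {
    g <- vapply(rus_chn_bones(), function(b)
      sample.int(max_grade(b, catalog) + 1L, 1) - 1L, integer(1))
    base <- predict_age(m, g, "male")
    b <- sample(rus_chn_bones(), 1)
    if (g[[b]] < max_grade(b, catalog)) {
      g2 <- g; g2[[b]] <- g2[[b]] + 1L
      expect_gte(predict_age(m, g2, "male"), base)
    }
  }
  expect_error(predict_age(m1, g1, "unknown"), "schema error")
})

test_that("score tables are validated for completeness and monotonicity", {
  tab <- as.data.frame(toy_table())
  expect_error(as_score_table(tab[-1, ], catalog), "cover the catalog")
  tab2 <- tab
  tab2$score[tab2$bone == "ulna" & tab2$grade == 5 &
               tab2$sex == "male"] <- 0.5
  # grade-5 score now below grade-4: not monotone
  expect_error(as_score_table(tab2, catalog), "non-decreasing")
})

test_that("regressor accepts the standard hyperparameter names and learns a constant", {
  g <- matrix(rep(3L, 13 * 30), ncol = 13,
              dimnames = list(NULL, rus_chn_bones()))
  train <- as.data.frame(g)
  train$sex <- rep(c("male", "female"), length.out = 30)
  train$bone_age <- 7
  expect_setequal(names(default_regressor_params()),
                  c("num_leaves", "max_depth", "learning_rate",
                    "stopping_rounds"))
  reg <- fit_age_regressor(train, params = list(num_leaves = 7), nrounds = 50,
                           seed = 3)
  pred <- predict_age(reg, g[1:4, ], c("male", "female", "male", "female"))
  expect_equal(pred, rep(7, 4), tolerance = 1e-3)
  # feature-count mismatch is a schema error
  expect_error(predict_age(reg, g[1:2, 1:12], "male"))
  expect_error(fit_age_regressor(train[, -1]), "schema error")
})

test_that("a fitted regressor survives a save/load round trip", {
  ref <- make_toy_reference(catalog)
  m1 <- scheme1_model(ref$score_table, ref$curve)
  train <- scheme1_feature_set(120, 61, m1)
  reg <- fit_age_regressor(train, nrounds = 80, seed = 9)
  g <- as.matrix(train[1:10, rus_chn_bones()])
  before <- predict_age(reg, g, train$sex[1:10])
  dir <- withr::local_tempdir()
  save_age_regressor(reg, dir)
  reg2 <- load_age_regressor(dir)
  expect_equal(predict_age(reg2, g, train$sex[1:10]), before,
               tolerance = 1e-7)
  expect_equal(reg2$params$stopping_rounds, reg$params$stopping_rounds)
})
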