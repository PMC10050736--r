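#' @keywords internal
grade_feature_matrix <- function(data) {
  bones <- rus_chn_bones()
  if (!all(bones %in% names(data))) {
    stop("schema error: feature set needs one column per key bone (",
         paste(setdiff(bones, names(data)), collapse = ", "), " missing)",
         call. = FALSE)
  }
  m <- as.matrix(data[, bones, drop = FALSE])
  if (anyNA(m)) stop("incomplete-input error: NA grade in feature set",
                     call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Default regressor hyperparameters
#'
#' The tunable knobs of the gradient-boosted bone-age regressor, named as
#' in the LightGBM-style convention: `num_leaves` (leaf-count ceiling per
#' tree), `max_depth`, `learning_rate` and `stopping_rounds` (early-stop
#' patience on the validation set). Internally they drive xgboost's
#' histogram trees with loss-guided (leaf-wise) growth, the same growth
#' policy that makes `num_leaves` the binding complexity control.
#'
#' @return Named list of defaults.
#' @export
default_regressor_params <- function() {
  list(num_leaves = 31, max_depth = 6, learning_rate = 0.1,
       stopping_rounds = 300)
}

#' Fit the bone-age regression model (Schemes 2 and 3)
#'
#' Fits one gradient-boosted regression per sex on the 13 developmental
#' grades (canonical bone order) with bone age in years as the label.
#' Scheme 2 trains on expert-rated grades, Scheme 3 on decoder-inferred
#' grades; the fit itself is identical — only the provenance of the grade
#' columns differs. Early stopping monitors RMSE on the validation set.
#'
#' @param train data.frame with the 13 bone columns, `sex` and `bone_age`.
#' @param val Optional validation data.frame of the same shape; enables
#'   early stopping.
#' @param params Hyperparameters, see [default_regressor_params()]. A
#'   partial list overrides the defaults. A `hyperparameter_search` hook:
#'   pass a list of candidate `params` lists via `search`; the candidate
#'   with the lowest validation MAE is kept.
#' @param nrounds Boosting-round ceiling (early stopping picks the
#'   effective number).
#' @param seed Integer seed for reproducibility.
#' @param search Optional list of candidate hyperparameter lists.
#' @return An `age_regressor` holding one booster per sex.
#' @export
fit_age_regressor <- function(train, val = NULL,
                              params = default_regressor_params(),
                              nrounds = 600, seed = 0, search = NULL) {
  stopifnot(nrow(train) > 0, all(c("sex", "bone_age") %in% names(train)))
  params <- utils::modifyList(default_regressor_params(), params)
  if (!is.null(search)) {
    stopifnot(!is.null(val))
    cand <- lapply(search, function(p) {
      fit_age_regressor(train, val, params = p, nrounds = nrounds,
                        seed = seed)
    })
    mae <- vapply(cand, function(m) {
      pred <- predict_age(m, grade_feature_matrix(val), val$sex)
      mean(abs(pred - val$bone_age))
    }, numeric(1))
    best <- cand[[which.min(mae)]]
    best$search_mae <- mae
    return(best)
  }
  fit_one <- function(sub, vsub) {
    dtrain <- xgboost::xgb.DMatrix(grade_feature_matrix(sub),
                                   label = sub$bone_age)
    xgb_params <- list(objective = "reg:squarederror",
                       eta = params$learning_rate,
                       max_depth = params$max_depth,
                       max_leaves = params$num_leaves,
                       tree_method = "hist",
                       grow_policy = "lossguide",
                       min_child_weight = 1,
                       seed = seed,
                       nthread = 1)
    evals <- list(train = dtrain)
    esr <- NULL
    if (!is.null(vsub) && nrow(vsub) > 0) {
      evals <- c(evals, list(val = xgboost::xgb.DMatrix(
        grade_feature_matrix(vsub), label = vsub$bone_age)))
      esr <- params$stopping_rounds
    }
    xgboost::xgb.train(params = xgb_params, data = dtrain, nrounds = nrounds,
                       evals = evals, early_stopping_rounds = esr,
                       verbose = 0)
  }
  sexes <- c("male", "female")
  models <- lapply(sexes, function(s) {
    sub <- train[train$sex == s, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    vsub <- if (!is.null(val)) val[val$sex == s, , drop = FALSE]
    fit_one(sub, vsub)
  })
  structure(list(models = stats::setNames(models, sexes),
                 params = params, seed = seed,
                 feature_names = rus_chn_bones()),
            class = "age_regressor")
}

#' @export
predict_age.age_regressor <- function(model, grades, sex, ...) {
  if (!is.matrix(grades)) {
    g <- grades_as_vector(grades)
    grades <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  }
  stopifnot(ncol(grades) == 13L)
  if (!all(sex %in% c("male", "female"))) {
    stop("schema error: sex must be 'male' or 'female'", call. = FALSE)
  }
  sex <- rep_len(sex, nrow(grades))
  out <- numeric(nrow(grades))
  for (s in unique(sex)) {
    m <- model$models[[s]]
    if (is.null(m)) stop("no fitted model for sex ", s, call. = FALSE)
    rows <- sex == s
    out[rows] <- predict(m, xgboost::xgb.DMatrix(
      grades[rows, , drop = FALSE]))
  }
  out
}

#' @export
print.age_regressor <- function(x, ...) {
  fitted <- names(x$models)[!vapply(x$models, is.null, logical(1))]
  cat("Gradient-boosted bone-age regressor; fitted sexes:",
      paste(fitted, collapse = ", "), "\n")
  cat("params:", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a fitted age regressor
#'
#' Boosters are serialised through xgboost's own JSON text format, one
#' file per sex next to a small metadata JSON, so the artifact stays
#' text-only.
#'
#' @param model An `age_regressor`.
#' @param dir Directory to write to / read from.
#' @return `save_age_regressor` returns `dir` invisibly.
#' @export
save_age_regressor <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(model$models)) {
    if (!is.null(model$models[[s]])) {
      xgboost::xgb.save(model$models[[s]],
                        file.path(dir, paste0("booster_", s, ".json")))
    }
  }
  meta <- c(list(feature_names = paste(model$feature_names, collapse = ",")),
            model$params, list(seed = model$seed))
  utils::write.csv(data.frame(key = names(meta),
                              value = vapply(meta, as.character,
                                             character(1))),
                   file.path(dir, "regressor_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_age_regressor
#' @export
load_age_regressor <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "regressor_meta.csv"),
                          stringsAsFactors = FALSE)
  getv <- function(k) meta$value[match(k, meta$key)]
  models <- lapply(stats::setNames(nm = c("male", "female")), function(s) {
    f <- file.path(dir, paste0("booster_", s, ".json"))
    if (file.exists(f)) xgboost::xgb.load(f) else NULL
  })
  structure(list(models = models,
                 params = list(num_leaves = as.numeric(getv("num_leaves")),
                               max_depth = as.numeric(getv("max_depth")),
                               learning_rate = as.numeric(getv("learning_rate")),
                               stopping_rounds = as.numeric(getv("stopping_rounds"))),
                 seed = as.numeric(getv("seed")),
                 feature_names = strsplit(getv("feature_names"), ",")[[1]]),
            class = "age_regressor")
}
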