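#' Bone-age regression metrics
#'
#' Computes the three error metrics used for predicted-vs-true bone age:
#' mean absolute error `MAE = (1/n) * sum |y_i - yhat_i|`, root mean
#' square error `RMSE = sqrt((1/n) * sum (y_i - yhat_i)^2)`, and root mean
#' squared percentage error
#' `RMSPE = sqrt((1/n) * sum ((y_i - yhat_i)/y_i)^2)`. RMSPE is undefined
#' when any true age is 0; that raises an explicit error rather than being
#' skipped silently.
#'
#' @param true_age,pred_age Numeric vectors of equal length (years).
#' @param rmspe Compute RMSPE (requires all `true_age != 0`).
#' @return Named numeric vector `c(mae, rmse, rmspe)` (`rmspe` NA when not
#'   requested).
#' @examples
#' regression_metrics(c(1, 2), c(2, 4))  # MAE 1.5, RMSE sqrt(2.5), RMSPE 1
#' @export
regression_metrics <- function(true_age, pred_age, rmspe = TRUE) {
  stopifnot(length(true_age) == length(pred_age), length(true_age) >= 1)
  err <- true_age - pred_age
  out <- c(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), rmspe = NA_real_)
  if (rmspe) {
    if (any(true_age == 0)) {
      stop("undefined-metric error: RMSPE requires all true ages != 0",
           call. = FALSE)
    }
    out["rmspe"] <- sqrt(mean((err / true_age)^2))
  }
  out
}

#' Metrics stratified by sex and/or integer age band
#'
#' Applies [regression_metrics()] within each stratum. Age bands are the
#' half-open yearly intervals `[k, k+1)` (an age of exactly 1.0 falls in
#' band "1-2"). Strata whose true ages include 0 get `rmspe = NA` with a
#' note rather than an error; empty strata are omitted.
#'
#' @param true_age,pred_age Numeric vectors (years).
#' @param sex Optional character vector (`male`/`female`) to stratify by.
#' @param by `"age_band"`, `"sex"`, or both.
#' @return data.frame with one row per stratum: stratum labels, `n`,
#'   `mae`, `rmse`, `rmspe`.
#' @export
stratified_metrics <- function(true_age, pred_age, sex = NULL,
                               by = c("age_band", "sex")) {
  by <- match.arg(by, several.ok = TRUE)
  keys <- list()
  if ("age_band" %in% by) {
    k <- floor(true_age)
    keys$age_band <- sprintf("%d-%d", k, k + 1L)
  }
  if ("sex" %in% by) {
    stopifnot(!is.null(sex))
    keys$sex <- rep_len(sex, length(true_age))
  }
  strata <- interaction(as.data.frame(keys), drop = TRUE, sep = "|")
  rows <- lapply(levels(strata), function(lv) {
    i <- strata == lv
    m <- if (any(true_age[i] == 0)) {
      c(regression_metrics(true_age[i], pred_age[i], rmspe = FALSE))
    } else regression_metrics(true_age[i], pred_age[i])
    lab <- strsplit(lv, "|", fixed = TRUE)[[1]]
    cbind(stats::setNames(as.data.frame(as.list(lab),
                                        stringsAsFactors = FALSE),
                          names(keys)),
          data.frame(n = sum(i), mae = m["mae"], rmse = m["rmse"],
                     rmspe = m["rmspe"], row.names = NULL))
  })
  out <- do.call(rbind, rows)
  if ("age_band" %in% names(out)) {
    out <- out[order(as.integer(sub("-.*", "", out$age_band))), ]
  }
  rownames(out) <- NULL
  out
}

#' @keywords internal
match_findings_truth <- function(results, truth) {
  ids <- vapply(results, function(r) r$image_id, character(1))
  common <- intersect(ids, unique(truth$image_id))
  if (!length(common)) {
    stop("evaluation error: no overlapping image ids between results and truth",
         call. = FALSE)
  }
  do.call(rbind, lapply(common, function(id) {
    r <- results[[match(id, ids)]]
    t_img <- truth[truth$image_id == id, ]
    f <- r$findings
    idx <- match(t_img$bone, f$bone)
    ok <- !is.na(idx)
    iou_v <- rep(NA_real_, nrow(t_img))
    if (any(ok)) {
      iou_v[ok] <- iou(t_img[ok, box_cols()], f[idx[ok], box_cols()])
    }
    data.frame(image_id = id, bone = t_img$bone,
               true_grade = t_img$grade,
               pred_grade = ifelse(ok, f$grade[idx], NA_integer_),
               iou = iou_v, stringsAsFactors = FALSE)
  }))
}

#' Per-bone mean IoU of decoded boxes against ground truth
#'
#' Findings are matched to truth by bone identity (the KBS decoder
#' guarantees at most one finding per bone). Bones missing from a result
#' are excluded from that bone's mean and counted in `n_missing`; a bone
#' missing everywhere gets mean `NA`, never 0.
#'
#' @param results List of `kbs_result`.
#' @param truth Annotations data.frame.
#' @return data.frame `bone`, `mean_iou`, `n`, `n_missing`, bones in
#'   canonical order.
#' @export
mean_iou_per_bone <- function(results, truth) {
  m <- match_findings_truth(results, truth)
  bones <- rus_chn_bones()
  out <- do.call(rbind, lapply(bones, function(b) {
    v <- m$iou[m$bone == b]
    data.frame(bone = b,
               mean_iou = if (all(is.na(v))) NA_real_ else
                 mean(v, na.rm = TRUE),
               n = sum(!is.na(v)), n_missing = sum(is.na(v)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-bone grade confusion, accuracy and weighted precision
#'
#' Builds one confusion matrix per key bone (true grade in rows, predicted
#' in columns, side `max_grade + 1`), from which per-bone accuracy
#' (`trace / total`) and support-weighted precision
#' (`sum_g support_g * precision_g / sum_g support_g`,
#' `precision_g = TP_g / (TP_g + FP_g)`) are computed. Predicted grades for
#' missing bones are excluded with a count. A predicted grade absent from
#' the truth contributes to weighted precision only through false
#' positives (its own weight is its truth support, 0).
#'
#' @param results List of `kbs_result`.
#' @param truth Annotations data.frame.
#' @param catalog A `class_catalog` (fixes the matrix sides).
#' @return List with `per_bone` (data.frame `bone`, `accuracy`,
#'   `weighted_precision`, `n`, `n_missing`), `confusion` (named list of
#'   matrices) and `overall_accuracy`.
#' @export
grade_classification_report <- function(results, truth,
                                        catalog = build_class_catalog()) {
  m <- match_findings_truth(results, truth)
  bones <- unique(catalog$bone)
  confusion <- list()
  rows <- lapply(bones, function(b) {
    sub <- m[m$bone == b & !is.na(m$pred_grade), ]
    n_missing <- sum(m$bone == b & is.na(m$pred_grade))
    side <- max_grade(b, catalog) + 1L
    lv <- 0:(side - 1L)
    cm <- table(factor(sub$true_grade, levels = lv),
                factor(sub$pred_grade, levels = lv))
    confusion[[b]] <<- unclass(cm)
    total <- sum(cm)
    acc <- if (total) sum(diag(cm)) / total else NA_real_
    support <- rowSums(cm)
    colsum <- colSums(cm)
    prec_g <- ifelse(colsum > 0, diag(cm) / colsum, 0)
    wp <- if (sum(support)) sum(support * prec_g) / sum(support) else NA_real_
    data.frame(bone = b, accuracy = acc, weighted_precision = wp,
               n = total, n_missing = n_missing, stringsAsFactors = FALSE)
  })
  per_bone <- do.call(rbind, rows)
  rownames(per_bone) <- NULL
  ok <- !is.na(m$pred_grade)
  list(per_bone = per_bone, confusion = confusion,
       overall_accuracy = mean(m$true_grade[ok] == m$pred_grade[ok]))
}

#' @keywords internal
average_precision <- function(tp, fp, n_truth) {
  # tp/fp: 0/1 flags in confidence-rank order; all-point interpolation
  if (!length(tp) || n_truth == 0) return(0)
  cum_tp <- cumsum(tp); cum_fp <- cumsum(fp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # envelope: precision at recall r = max precision at recall >= r
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}

#' Mean average precision at an IoU threshold
#'
#' Evaluates raw (pre-decoding) detections against truth boxes labelled
#' with encoded bone-grade classes. Per class, detections are ranked by
#' confidence and greedily matched to unmatched truth boxes of the same
#' image and class at `IoU >= iou_threshold` (each truth box matched at
#' most once); average precision uses all-point interpolation; mAP is the
#' macro average over classes with at least one truth instance.
#'
#' @param detections Raw detections data.frame.
#' @param truth Annotations data.frame (its `bone`+`grade` give the class).
#' @param iou_threshold Match threshold; default 0.5.
#' @param catalog A `class_catalog`.
#' @return List with `map` and `per_class` (data.frame `class_label`,
#'   `ap`, `n_truth`).
#' @export
map_at_iou <- function(detections, truth, iou_threshold = 0.5,
                       catalog = build_class_catalog()) {
  if (nrow(truth) == 0L) {
    stop("evaluation error: no truth instances", call. = FALSE)
  }
  truth$class_label <- paste0(truth$bone, "_", truth$grade)
  classes <- sort(unique(truth$class_label))
  per_class <- lapply(classes, function(cl) {
    t_cl <- truth[truth$class_label == cl, , drop = FALSE]
    d_cl <- detections[detections$class_label == cl, , drop = FALSE]
    n_truth <- nrow(t_cl)
    if (nrow(d_cl) == 0L) {
      return(data.frame(class_label = cl, ap = 0, n_truth = n_truth))
    }
    d_cl <- d_cl[order(-d_cl$confidence), , drop = FALSE]
    matched <- rep(FALSE, n_truth)
    tp <- fp <- numeric(nrow(d_cl))
    for (i in seq_len(nrow(d_cl))) {
      cand <- which(t_cl$image_id == d_cl$image_id[i] & !matched)
      if (length(cand)) {
        ov <- iou(d_cl[rep(i, length(cand)), box_cols()],
                  t_cl[cand, box_cols()])
        j <- which.max(ov)
        if (ov[j] >= iou_threshold) {
          matched[cand[j]] <- TRUE
          tp[i] <- 1
          next
        }
      }
      fp[i] <- 1
    }
    data.frame(class_label = cl, ap = average_precision(tp, fp, n_truth),
               n_truth = n_truth, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, per_class)
  list(map = mean(per_class$ap), per_class = per_class)
}
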