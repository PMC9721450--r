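#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling; equal to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more malignant)
#' @param labels benign/malignant or 0/1 vector
#' @return AUC in [0, 1]
#' @export
auc <- function(scores, labels) {
  y <- label_to_binary(labels)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0)
    stop("AUC requires both classes to be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

# fast DeLong structural components via midranks
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two models scored on the same cases using the
#' structural-components (midrank) algorithm, with a two-sided normal p.
#' Degenerate variance (e.g. a model compared with itself, or two perfect
#' models) reports z = 0, p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b paired score vectors on identical cases
#' @param labels benign/malignant or 0/1 vector
#' @return an object of class `delong_result`: `auc_a`, `auc_b`, `z`, `p`
#'   (two-sided), `var_diff`, `covariance` (2 x 2 matrix of the paired AUC
#'   estimates), `degenerate`
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- label_to_binary(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(y))
  if (!all(c(0, 1) %in% y))
    stop("DeLong test requires both classes to be present", call. = FALSE)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !is.finite(var_diff) || var_diff < 1e-15
  z <- if (degenerate) 0 else (ca$auc - cb$auc) / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p,
                 var_diff = var_diff, covariance = S,
                 degenerate = degenerate),
            class = "delong_result")
}

#' @exportS3Method base::print
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' DeLong 95% confidence interval for one AUC
#'
#' @inheritParams auc
#' @return list with `auc`, `se`, `ci95` (truncated to [0, 1])
#' @export
delong_ci <- function(scores, labels) {
  y <- label_to_binary(labels)
  if (!all(c(0, 1) %in% y))
    stop("AUC CI requires both classes to be present", call. = FALSE)
  comp <- delong_components(scores, y)
  se <- sqrt(stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n)
  lo <- max(0, comp$auc - 1.96 * se)
  hi <- min(1, comp$auc + 1.96 * se)
  list(auc = comp$auc, se = se, ci95 = c(lo, hi))
}

#' Patient-stratified five-fold cross-validation plan
#'
#' Patients (both views move together) are shuffled within label strata and
#' dealt cyclically into k folds, giving fold sizes within 1 overall and per
#' stratum. The k rotations each use 1 fold as test, the next as validation
#' and the remaining k-2 as training (the 3:1:1 pattern at k = 5); every
#' patient is in the test role exactly once.
#'
#' @param patient_ids patient identifier per patient (unique)
#' @param labels label per patient
#' @param k number of folds (default 5)
#' @param seed RNG seed
#' @param max_retry reshuffles allowed when a fold misses a class
#' @return an object of class `cv_plan`: `assignment` (data.frame of
#'   patient_id, label, fold) and `rotations` (list of train/validation/test
#'   fold ids)
#' @export
make_cv_plan <- function(patient_ids, labels, k = 5, seed = 1,
                         max_retry = 20) {
  stopifnot(!anyDuplicated(patient_ids), length(patient_ids) == length(labels))
  if (length(patient_ids) < k)
    stop("need at least k patients", call. = FALSE)
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2)
    stop("both classes are required to build a stratified plan", call. = FALSE)
  with_seed(derive_seed(seed, "cv_plan"), {
    for (attempt in seq_len(max_retry)) {
      ord <- order(y, stats::runif(length(y)))
      fold <- integer(length(y))
      fold[ord] <- (seq_along(ord) - 1L) %% k
      ok <- all(vapply(0:(k - 1), function(f)
        length(unique(y[fold == f])) == 2, logical(1)))
      if (ok) break
    }
    if (!ok)
      stop("could not build folds containing both classes after ",
           max_retry, " attempts", call. = FALSE)
    rotations <- lapply(0:(k - 1), function(r) list(
      test = r,
      validation = (r + 1) %% k,
      train = setdiff(0:(k - 1), c(r, (r + 1) %% k))))
    structure(list(
      assignment = data.frame(patient_id = patient_ids, label = labels,
                              fold = fold, stringsAsFactors = FALSE),
      k = k, rotations = rotations), class = "cv_plan")
  })
}

#' Aggregate ROI scores to patient level
#'
#' @param scores per-ROI scores
#' @param patient_ids patient id per ROI
#' @param rule `"max"` (default; most-suspicious view), `"mean"` or `"min"`
#' @return named vector of per-patient scores
#' @export
patient_level_scores <- function(scores, patient_ids,
                                 rule = c("max", "mean", "min")) {
  rule <- match.arg(rule)
  f <- switch(rule, max = max, mean = mean, min = min)
  v <- tapply(scores, patient_ids, f)
  stats::setNames(as.numeric(v), dimnames(v)[[1]])
}

#' Operating point by Youden's J
#'
#' Scans every observed score as a candidate threshold (prediction positive
#' when score >= threshold, plus the all-negative threshold `Inf`) and
#' returns the one maximizing J = sensitivity + specificity - 1; ties are
#' broken toward the smallest threshold, so fully tied scores give
#' (sensitivity 1, specificity 0) at the common score value.
#'
#' @inheritParams auc
#' @param threshold optional fixed threshold (e.g. chosen on validation data)
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`
#' @export
operating_point <- function(scores, labels, threshold = NULL) {
  y <- label_to_binary(labels)
  if (!all(c(0, 1) %in% y))
    stop("operating point requires both classes", call. = FALSE)
  eval_at <- function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    c(sens, spec)
  }
  if (!is.null(threshold)) {
    ss <- eval_at(threshold)
    return(list(threshold = threshold, sensitivity = ss[1],
                specificity = ss[2], youden = sum(ss) - 1))
  }
  cand <- c(sort(unique(scores)), Inf)
  ss <- vapply(cand, eval_at, numeric(2))
  jj <- ss[1, ] + ss[2, ] - 1
  best <- which.max(jj)  # first max = smallest threshold among ties
  list(threshold = cand[best], sensitivity = ss[1, best],
       specificity = ss[2, best], youden = jj[best])
}

region_model_grid <- function(distances_mm) {
  rbind(data.frame(region = "tumoral", distance_mm = NA_real_),
        data.frame(region = "peritumoral", distance_mm = distances_mm),
        data.frame(region = "combined", distance_mm = distances_mm))
}

model_rows <- function(table, region, distance) {
  if (region == "tumoral") which(table$region == "tumoral")
  else which(table$region == region & table$distance_mm == distance)
}

#' Run the full region-comparison study
#'
#' For every region model (tumoral, peritumoral and combined at each
#' distance) and every rotation of the cross-validation plan: the
#' correlation filter and feature standardization are computed on the
#' training folds only, the lasso penalty is chosen by validation AUC, the
#' operating threshold by validation Youden J, and the test fold is scored.
#' Each case is therefore scored out-of-fold exactly once; reported AUCs are
#' the mean over the five test sets, confidence intervals come from DeLong on
#' the pooled out-of-fold scores, and every non-tumoral model is compared to
#' the tumoral model with a paired DeLong test on those pooled scores, at
#' both ROI (per view) and patient (max over views) level.
#'
#' @param dataset a `phantom_dataset`
#' @param distances_mm ring distances (default 1:5, the 11-model study)
#' @param feature_config a [feature_config()]
#' @param selection_config a [selection_config()]
#' @param penalty_grid lasso penalties searched on the validation folds
#' @param k folds (default 5)
#' @param seed RNG seed for the CV plan
#' @param aggregate patient-level aggregation rule
#' @param feature_table optional precomputed [extract_feature_table()] output
#' @return an object of class `perirad_study`: `roi` and `patient` summary
#'   data.frames, `scores` (pooled out-of-fold scores per model), `plan`,
#'   `feature_table`
#' @export
run_study <- function(dataset, distances_mm = 1:5,
                      feature_config = perirad::feature_config(),
                      selection_config = perirad::selection_config(),
                      penalty_grid = c(0.01, 0.1, 1, 10),
                      k = 5, seed = 1, aggregate = "max",
                      feature_table = NULL) {
  if (is.null(feature_table))
    feature_table <- extract_feature_table(dataset, distances_mm, feature_config)
  fcols <- feature_columns(feature_table)

  patients <- unique(feature_table[, c("patient_id", "label")])
  plan <- make_cv_plan(patients$patient_id, patients$label, k = k, seed = seed)
  fold_of <- stats::setNames(plan$assignment$fold, plan$assignment$patient_id)

  grid <- region_model_grid(distances_mm)
  roi_rows <- patient_rows <- vector("list", nrow(grid))
  scores_out <- list()

  for (g in seq_len(nrow(grid))) {
    rows <- model_rows(feature_table, grid$region[g], grid$distance_mm[g])
    sub <- feature_table[rows, , drop = FALSE]
    x <- as.matrix(sub[, fcols, drop = FALSE])
    y <- sub$label
    pid <- sub$patient_id
    folds <- fold_of[pid]

    pooled <- rep(NA_real_, nrow(sub))
    fold_auc_roi <- fold_auc_pat <- fold_sens <- fold_spec <-
      fold_sens_pat <- fold_spec_pat <- numeric(plan$k)
    for (r in seq_len(plan$k)) {
      rot <- plan$rotations[[r]]
      tr <- folds %in% rot$train
      va <- folds == rot$validation
      te <- folds == rot$test
      sel <- correlation_filter(x[tr, , drop = FALSE], y[tr], selection_config)
      model <- fit_l1_logistic(x[tr, , drop = FALSE], y[tr],
                               selected_names = sel,
                               penalty_grid = penalty_grid,
                               xval = x[va, , drop = FALSE],
                               valid_labels = y[va])
      val_scores <- predict(model, x[va, , drop = FALSE])
      thr <- operating_point(val_scores, y[va])$threshold
      sc <- predict(model, x[te, , drop = FALSE])
      pooled[te] <- sc

      fold_auc_roi[r] <- auc(sc, y[te])
      opr <- operating_point(sc, y[te], threshold = thr)
      fold_sens[r] <- opr$sensitivity
      fold_spec[r] <- opr$specificity
      ps <- patient_level_scores(sc, pid[te], aggregate)
      pl <- patient_level_scores(label_to_binary(y[te]), pid[te], "max")
      fold_auc_pat[r] <- auc(ps, pl)
      opp <- operating_point(ps, pl, threshold = thr)
      fold_sens_pat[r] <- opp$sensitivity
      fold_spec_pat[r] <- opp$specificity
    }

    pooled_pat <- patient_level_scores(pooled, pid, aggregate)
    label_pat <- patient_level_scores(label_to_binary(y), pid, "max")
    ci_roi <- delong_ci(pooled, y)
    ci_pat <- delong_ci(pooled_pat, label_pat)
    key <- if (grid$region[g] == "tumoral") "tumoral"
           else sprintf("%s_%gmm", grid$region[g], grid$distance_mm[g])
    scores_out[[key]] <- list(
      roi = data.frame(patient_id = pid, view = sub$view, label = y,
                       score = pooled, stringsAsFactors = FALSE),
      patient = data.frame(patient_id = names(pooled_pat),
                           label = as.integer(label_pat),
                           score = as.numeric(pooled_pat),
                           stringsAsFactors = FALSE))
    roi_rows[[g]] <- data.frame(
      region = grid$region[g], distance_mm = grid$distance_mm[g],
      auc = mean(fold_auc_roi), ci_lo = ci_roi$ci95[1], ci_hi = ci_roi$ci95[2],
      sensitivity = mean(fold_sens), specificity = mean(fold_spec),
      n_pos = sum(label_to_binary(y) == 1), n_neg = sum(label_to_binary(y) == 0),
      stringsAsFactors = FALSE)
    patient_rows[[g]] <- data.frame(
      region = grid$region[g], distance_mm = grid$distance_mm[g],
      auc = mean(fold_auc_pat), ci_lo = ci_pat$ci95[1], ci_hi = ci_pat$ci95[2],
      sensitivity = mean(fold_sens_pat), specificity = mean(fold_spec_pat),
      n_pos = sum(label_pat == 1), n_neg = sum(label_pat == 0),
      stringsAsFactors = FALSE)
  }

  roi <- do.call(rbind, roi_rows)
  patient <- do.call(rbind, patient_rows)

  # paired DeLong against the tumoral model on pooled out-of-fold scores
  add_delong <- function(summary, level) {
    ref <- scores_out[["tumoral"]][[level]]
    p <- vapply(seq_len(nrow(summary)), function(g) {
      key <- if (summary$region[g] == "tumoral") return(NA_real_)
             else sprintf("%s_%gmm", summary$region[g], summary$distance_mm[g])
      cur <- scores_out[[key]][[level]]
      merged <- merge(ref, cur, by = intersect(names(ref), c("patient_id", "view")))
      delong_test(merged$score.y, merged$score.x, merged$label.x)$p
    }, numeric(1))
    summary$p_vs_tumoral <- p
    summary
  }
  roi <- add_delong(roi, "roi")
  patient <- add_delong(patient, "patient")

  structure(list(roi = roi, patient = patient, scores = scores_out,
                 plan = plan, feature_table = feature_table,
                 aggregate = aggregate),
            class = "perirad_study")
}

#' @exportS3Method base::print
print.perirad_study <- function(x, ...) {
  cat("perirad_study: patient-level summary\n")
  print(x$patient, digits = 3)
  invisible(x)
}

#' Subgroup AUCs (stratified analysis)
#'
#' Recomputes patient-level AUCs of selected region models inside subgroups
#' defined by a per-patient variable (e.g. mass size <= / > 20 mm). Subgroups
#' lacking either class are reported as `NA` rather than raising an error.
#'
#' @param study a `perirad_study`
#' @param meta per-image metadata with `patient_id` and the grouping variable
#' @param variable column of `meta` to stratify on
#' @param breaks cut points for a numeric variable (default 20, the mass-size
#'   convention in mm)
#' @param models score keys to evaluate (default tumoral / peritumoral 2 mm /
#'   combined 2 mm)
#' @return data.frame: group x model AUCs with group sizes
#' @export
subgroup_auc <- function(study, meta, variable = "mass_size_mm", breaks = 20,
                         models = c("tumoral", "peritumoral_2mm", "combined_2mm")) {
  per_pat <- meta[!duplicated(meta$patient_id),
                  c("patient_id", variable)]
  v <- per_pat[[variable]]
  grp <- if (is.numeric(v)) cut(v, c(-Inf, breaks, Inf)) else factor(v)
  rows <- list()
  for (g in levels(grp)) {
    ids <- per_pat$patient_id[grp == g]
    row <- list(group = g, n = length(ids))
    for (mkey in models) {
      sc <- study$scores[[mkey]]$patient
      sc <- sc[sc$patient_id %in% ids, ]
      row[[mkey]] <- if (nrow(sc) > 1 && length(unique(sc$label)) == 2)
        auc(sc$score, sc$label) else NA_real_
    }
    rows[[g]] <- as.data.frame(row, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
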