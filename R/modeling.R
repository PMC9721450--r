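#' Feature selection configuration
#'
#' @param correlation_threshold pairs with |Pearson r| above this are reduced
#'   to their more label-relevant member (default 0.9)
#' @param relevance_metric how relevance to the benign/malignant label is
#'   measured when breaking a correlated pair; currently absolute
#'   point-biserial correlation
#' @return an object of class `selection_config`
#' @export
selection_config <- function(correlation_threshold = 0.9,
                             relevance_metric = "point_biserial") {
  if (correlation_threshold <= 0 || correlation_threshold > 1)
    stop("correlation_threshold must be in (0, 1]", call. = FALSE)
  structure(list(correlation_threshold = correlation_threshold,
                 relevance_metric = relevance_metric),
            class = "selection_config")
}

label_to_binary <- function(labels) {
  if (is.numeric(labels)) {
    y <- as.integer(labels != 0)
  } else {
    y <- as.integer(as.character(labels) == "malignant")
    if (all(y == 0) && !all(labels %in% c("benign", "malignant")))
      stop("labels must be benign/malignant or 0/1", call. = FALSE)
  }
  y
}

#' Correlation-threshold feature filter
#'
#' Removes redundant features: offending pairs (|Pearson r| above the
#' threshold) are examined greedily in descending |r| (ties broken
#' lexicographically by name pair) and the member with the lower relevance —
#' absolute point-biserial correlation with the label, 0 for a constant
#' feature — is dropped, until no surviving pair exceeds the threshold.
#'
#' @param x numeric matrix or data.frame of features (columns named)
#' @param labels benign/malignant factor, character, or 0/1 vector
#' @param config a [selection_config()]
#' @return character vector of surviving feature names
#' @export
correlation_filter <- function(x, labels, config = selection_config()) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(colnames(x))
  y <- label_to_binary(labels)
  nm <- colnames(x)
  stopifnot(!is.null(nm), !anyDuplicated(nm))

  sds <- apply(x, 2, stats::sd)
  relevance <- rep(0, ncol(x))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) relevance[ok] <- abs(suppressWarnings(stats::cor(x[, ok, drop = FALSE], y)))
  names(relevance) <- nm

  cm <- suppressWarnings(stats::cor(x))
  cm[is.na(cm)] <- 0
  cm[lower.tri(cm, diag = TRUE)] <- 0
  off <- which(abs(cm) > config$correlation_threshold, arr.ind = TRUE)
  if (nrow(off) == 0) return(nm)
  a <- nm[off[, 1]]; b <- nm[off[, 2]]
  r <- abs(cm[off])
  o <- order(-r, pmin(a, b), pmax(a, b))
  keep <- stats::setNames(rep(TRUE, ncol(x)), nm)
  for (k in o) {
    fa <- a[k]; fb <- b[k]
    if (!keep[fa] || !keep[fb]) next
    drop <- if (relevance[fa] < relevance[fb]) fa
            else if (relevance[fb] < relevance[fa]) fb
            else max(fa, fb)  # relevance tie: drop the lexicographically later
    keep[drop] <- FALSE
  }
  nm[keep[nm]]
}

#' Fit an L1-penalised logistic regression
#'
#' Features are standardized by the training-set mean and standard deviation
#' (constant features get unit scale) and a lasso-penalised binomial model is
#' fitted. When a validation set is supplied the penalty is chosen from
#' `penalty_grid` by validation AUC (ties resolved toward the stronger
#' penalty); otherwise `penalty` must be a single value.
#'
#' @param x training feature matrix/data.frame
#' @param labels training labels (benign/malignant or 0/1)
#' @param selected_names features to use (default: all columns)
#' @param penalty_grid candidate lasso penalties (glmnet lambda)
#' @param xval,valid_labels optional validation features and labels
#' @param penalty fixed penalty overriding grid search
#' @return an object of class `perirad_model`
#' @export
fit_l1_logistic <- function(x, labels, selected_names = NULL,
                            penalty_grid = c(0.01, 0.1, 1, 10),
                            xval = NULL, valid_labels = NULL, penalty = NULL) {
  x <- as.matrix(x)
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2)
    stop("training data contain a single class; both classes are required",
         call. = FALSE)
  if (is.null(selected_names)) selected_names <- colnames(x)
  x <- x[, selected_names, drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- scale(x, center, scale)

  lambdas <- sort(unique(if (is.null(penalty)) penalty_grid else penalty),
                  decreasing = TRUE)
  # glmnet requires >= 2 columns; pad single-feature fits with a zero dummy
  pad <- ncol(z) == 1
  zfit <- if (pad) cbind(z, .pad. = 0) else z
  fit <- withCallingHandlers(
    glmnet::glmnet(zfit, y, family = "binomial", alpha = 1,
                   lambda = lambdas, standardize = FALSE),
    # desk-scale folds legitimately carry few cases per class
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (is.null(penalty) && length(lambdas) > 1) {
    if (is.null(xval)) stop("penalty grid search requires a validation set",
                            call. = FALSE)
    zv <- scale(as.matrix(xval)[, selected_names, drop = FALSE], center, scale)
    if (pad) zv <- cbind(zv, .pad. = 0)
    yv <- label_to_binary(valid_labels)
    val_auc <- vapply(lambdas, function(l) {
      pr <- as.numeric(stats::predict(fit, zv, s = l, type = "response"))
      if (length(unique(yv)) < 2) 0.5 else auc(pr, yv)
    }, numeric(1))
    # lambdas are in decreasing order, so which.max prefers stronger penalty
    lambda <- lambdas[which.max(val_auc)]
  } else {
    lambda <- lambdas[length(lambdas)]
  }
  cf <- as.numeric(stats::coef(fit, s = lambda))
  if (pad) cf <- cf[1:2]
  structure(list(selected_feature_names = selected_names,
                 center = center, scale = scale,
                 intercept = cf[1],
                 coefficients = stats::setNames(cf[-1], selected_names),
                 penalty = lambda),
            class = "perirad_model")
}

#' @exportS3Method base::print
print.perirad_model <- function(x, ...) {
  cat(sprintf("perirad_model: %d features (%d nonzero), penalty %g\n",
              length(x$coefficients), sum(x$coefficients != 0), x$penalty))
  invisible(x)
}

#' Predict malignancy probability
#'
#' @param object a `perirad_model`
#' @param newdata feature matrix/data.frame containing all selected features
#' @param ... unused
#' @return numeric vector of probabilities in [0, 1]
#' @export
predict.perirad_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$selected_feature_names, colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  z <- scale(newdata[, object$selected_feature_names, drop = FALSE],
             object$center, object$scale)
  eta <- object$intercept + as.numeric(z %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `perirad_model`
#' @param path file path
#' @return `write_model` returns the path invisibly; `read_model` the model
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$coefficients <- unlist(obj$coefficients)
  structure(obj, class = "perirad_model")
}
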