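make_feature_frame <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c("benign", "malignant"), length.out = n)
  signal <- rnorm(n) + 1.5 * (y == "malignant")
  data.frame(
    f_signal = signal,
    f_dup = signal,                       # exact duplicate
    f_noisy_copy = signal + rnorm(n, 0, 0.05),
    f_noise = rnorm(n),
    f_const = rep(1, n),
    label = y, stringsAsFactors = FALSE)
}

test_that("a duplicated feature column keeps exactly one copy", {
  df <- make_feature_frame()
  kept <- correlation_filter(df[, c("f_signal", "f_dup", "f_noise")], df$label)
  expect_length(intersect(kept, c("f_signal", "f_dup")), 1)
  expect_true("f_noise" %in% kept)
})

test_that("of three mutually correlated features only the most relevant survives", {
  set.seed(2)
  n <- 60
  y <- rep(0:1, each = n / 2)
  base <- rnorm(n) + 2 * y
  x <- cbind(a = base + rnorm(n, 0, 0.10),
             b = base + rnorm(n, 0, 0.02),
             c = base + rnorm(n, 0, 0.30))  # noisiest, weakest association
  cm <- abs(cor(x))
  stopifnot(all(cm[upper.tri(cm)] > 0.9))
  kept <- correlation_filter(x, y)
  expect_length(kept, 1)
  rel <- abs(cor(x, y))
  expect_equal(kept, rownames(rel)[which.max(rel)])
  # oracle: the surviving set must contain no pair above the threshold and
  # be maximal under the greedy relevance rule
  expect_true(all(abs(cor(x[, kept, drop = FALSE]))[upper.tri(diag(length(kept)))] <= 0.9))
})

test_that("no surviving pair exceeds the threshold, and filtering is idempotent", {
  df <- make_feature_frame(n = 80, seed = 3)
  x <- df[, setdiff(names(df), "label")]
  kept <- correlation_filter(x, df$label)
  cm <- abs(suppressWarnings(cor(x[, kept])))
  cm[is.na(cm)] <- 0
  expect_true(all(cm[upper.tri(cm)] <= 0.9))
  expect_identical(correlation_filter(x[, kept], df$label), kept)
})

test_that("threshold 1.0 only removes exact duplicates", {
  df <- make_feature_frame()
  x <- df[, c("f_signal", "f_noisy_copy", "f_noise")]
  kept <- correlation_filter(x, df$label, selection_config(1.0))
  expect_setequal(kept, colnames(x))
})

test_that("a perfectly separating feature reaches training AUC 1", {
  df <- make_feature_frame(n = 30, seed = 4)
  x <- data.frame(sep = ifelse(df$label == "malignant", 1, 0) + rnorm(30, 0, 0.01))
  m <- fit_l1_logistic(x, df$label, penalty = 0.01)
  expect_equal(auc(predict(m, x), df$label), 1.0)
})

test_that("a nearly unpenalised fit matches direct likelihood maximisation", {
  # tiny non-separable data so the MLE exists
  x <- matrix(c(0.1, 0.9, 0.4, 0.6, 0.35, 0.65, 0.2, 0.8), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(0, 1, 1, 0, 0, 1, 0, 1)
  m <- fit_l1_logistic(x, y, penalty = 1e-8)
  z <- (x - mean(x)) / sd(x)
  nll <- function(b) {
    eta <- b[1] + b[2] * z
    sum(log(1 + exp(eta))) - sum(y * eta)
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_lt(abs(m$intercept - opt$par[1]), 1e-3)
  expect_lt(abs(m$coefficients[["f"]] - opt$par[2]), 1e-3)
})

test_that("a huge penalty zeroes all coefficients and predicts the base rate", {
  df <- make_feature_frame(n = 50, seed = 5)
  x <- df[, c("f_signal", "f_noise")]
  m <- fit_l1_logistic(x, df$label, penalty = 1e4)
  expect_true(all(m$coefficients == 0))
  pr <- predict(m, x)
  expect_equal(unname(pr), rep(mean(df$label == "malignant"), 50),
               tolerance = 1e-6)
})

test_that("single-class training data and missing features are errors", {
  df <- make_feature_frame()
  x <- df[, c("f_signal", "f_noise")]
  expect_error(fit_l1_logistic(x, rep("benign", nrow(x)), penalty = 1),
               "single class")
  m <- fit_l1_logistic(x, df$label, penalty = 0.1)
  expect_error(predict(m, df[, "f_noise", drop = FALSE]), "f_signal")
})

test_that("predictions are probabilities, monotone and label-flip symmetric", {
  df <- make_feature_frame(n = 60, seed = 6)
  x <- df[, c("f_signal", "f_noise")]
  m <- fit_l1_logistic(x, df$label, penalty = 0.05)
  pr <- predict(m, x)
  expect_true(all(pr >= 0 & pr <= 1))
  # flipping every label must mirror the probabilities
  flipped <- ifelse(df$label == "malignant", "benign", "malignant")
  m2 <- fit_l1_logistic(x, flipped, penalty = 0.05)
  expect_equal(predict(m2, x), 1 - pr, tolerance = 1e-4)
  # monotone in the coefficient direction
  grid <- data.frame(f_signal = seq(-2, 4, length.out = 20), f_noise = 0)
  pg <- predict(m, grid)
  if (m$coefficients[["f_signal"]] > 0) expect_true(all(diff(pg) >= 0))
})

test_that("validation AUC drives the penalty choice", {
  df <- make_feature_frame(n = 120, seed = 7)
  x <- df[, c("f_signal", "f_noise")]
  tr <- 1:80; va <- 81:120
  m <- fit_l1_logistic(x[tr, ], df$label[tr], penalty_grid = c(0.01, 0.1, 1, 10),
                       xval = x[va, ], valid_labels = df$label[va])
  expect_true(m$penalty %in% c(0.01, 0.1, 1, 10))
  # with clear signal, the all-zero model (penalty 10) cannot win
  expect_lt(m$penalty, 10)
})

test_that("models survive a JSON round-trip", {
  df <- make_feature_frame()
  x <- df[, c("f_signal", "f_noise")]
  m <- fit_l1_logistic(x, df$label, penalty = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
})
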