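test_that("AUC handles separation, pair counting and total ties", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.3, 0.4, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random small instances", {
  set.seed(71)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:2, 1))  # coarse scores force ties
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong variance matches the direct structural-component oracle", {
  set.seed(72)
  for (rep in 1:50) {
    n <- sample(5:8, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sa <- round(runif(n), 1)
    sb <- round(runif(n), 1)
    res <- delong_test(sa, sb, y)
    orc <- oracle_delong(sa, sb, y)
    expect_equal(res$auc_a, orc$auc_a, tolerance = 1e-12)
    expect_equal(res$auc_b, orc$auc_b, tolerance = 1e-12)
    expect_equal(res$var_diff, orc$var_diff, tolerance = 1e-12)
    if (!res$degenerate) {
      expect_equal(res$z, (orc$auc_a - orc$auc_b) / sqrt(orc$var_diff),
                   tolerance = 1e-12)
      expect_equal(res$p, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
    }
  }
})

test_that("self-comparison and swapped arguments behave as expected", {
  set.seed(73)
  y <- rep(c(0, 1), each = 10)
  s <- rnorm(20) + y
  self <- delong_test(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
  s2 <- rnorm(20) + 0.3 * y
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("DeLong results agree with an established implementation", {
  set.seed(74)
  y <- rep(c(0, 1), each = 25)
  sa <- rnorm(50) + y
  sb <- rnorm(50) + 0.4 * y
  res <- delong_test(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                        pROC::roc(y, sb, quiet = TRUE), method = "delong")
  expect_equal(unname(res$z), unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  ci <- delong_ci(sa, y)
  ref_ci <- as.numeric(pROC::ci.auc(pROC::roc(y, sa, quiet = TRUE),
                                    method = "delong"))
  expect_equal(ci$ci95, ref_ci[c(1, 3)], tolerance = 1e-4)
})

test_that("cross-validation plan rotates 3:1:1 over stratified folds", {
  ids <- sprintf("P%02d", 1:10)
  labs <- rep(c("benign", "malignant"), 5)
  plan <- make_cv_plan(ids, labs, k = 5, seed = 1)
  expect_setequal(plan$assignment$fold, 0:4)
  sizes <- table(plan$assignment$fold)
  expect_true(all(sizes == 2))
  # stratification: both classes in every fold
  for (f in 0:4) {
    labf <- plan$assignment$label[plan$assignment$fold == f]
    expect_setequal(labf, c("benign", "malignant"))
  }
  tests <- lapply(plan$rotations, function(r)
    plan$assignment$patient_id[plan$assignment$fold == r$test])
  expect_setequal(unlist(tests), ids)
  expect_equal(sum(lengths(tests)), 10)
  for (r in plan$rotations) {
    expect_length(r$train, 3)
    expect_false(r$test %in% r$train)
    expect_false(r$validation %in% r$train)
    expect_false(r$test == r$validation)
  }
  expect_identical(make_cv_plan(ids, labs, k = 5, seed = 1), plan)
  expect_false(identical(make_cv_plan(ids, labs, k = 5, seed = 2), plan))
})

test_that("cv plan errors when a class cannot reach every fold", {
  ids <- sprintf("P%02d", 1:8)
  labs <- c("malignant", rep("benign", 7))
  expect_error(make_cv_plan(ids, labs, k = 5, seed = 1), "both classes")
})

test_that("patient aggregation rules", {
  s <- c(0.2, 0.8, 0.5)
  p <- c("A", "A", "B")
  expect_equal(unname(patient_level_scores(s, p, "max")), c(0.8, 0.5))
  expect_equal(unname(patient_level_scores(s, p, "mean")), c(0.5, 0.5))
  expect_equal(unname(patient_level_scores(0.7, "X")[["X"]]), 0.7)
})

test_that("max-rule patient AUC dominates min-rule when one view carries signal", {
  set.seed(75)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  informative <- 0.25 + 0.5 * y + rnorm(n, 0, 0.1)   # one view sees the lesion
  blind <- runif(n, 0.2, 0.6)                        # the other does not
  scores <- c(informative, blind)
  pid <- c(sprintf("P%03d", 1:n), sprintf("P%03d", 1:n))
  smax <- patient_level_scores(scores, pid, "max")
  smin <- patient_level_scores(scores, pid, "min")
  ylab <- y[order(sprintf("P%03d", 1:n))]
  expect_gte(auc(smax, ylab), auc(smin, ylab))
})

test_that("operating point maximizes Youden's J and is degenerate-safe", {
  op <- operating_point(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  flat <- operating_point(rep(0.4, 8), rep(c(0, 1), 4))
  expect_equal(flat$youden, 0)
  expect_equal(flat$sensitivity, 1)
  expect_equal(flat$specificity, 0)
  set.seed(76)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)
    op <- operating_point(s, y)
    orc <- oracle_operating_point(s, y)
    expect_equal(op$youden, orc$j, tolerance = 1e-12)
  }
})

test_that("run_study produces the 11-model tables at both levels", {
  ds <- small_phantom()
  res <- fixture("small_study", function()
    run_study(small_phantom(), distances_mm = 1:5, seed = 42))
  for (level in c("roi", "patient")) {
    tab <- res[[level]]
    expect_equal(nrow(tab), 11)
    expect_setequal(tab$region, c("tumoral", "peritumoral", "combined"))
    expect_true(all(tab$auc >= 0 & tab$auc <= 1))
    expect_true(all(tab$ci_lo <= tab$auc + 1e-9 & tab$auc <= tab$ci_hi + 1e-9))
    expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
    expect_true(all(is.na(tab$p_vs_tumoral) == (tab$region == "tumoral")))
  }
  expect_equal(res$roi$n_pos[1] + res$roi$n_neg[1], 24)       # views
  expect_equal(res$patient$n_pos[1] + res$patient$n_neg[1], 12)  # patients
})

test_that("subgroup AUCs handle empty strata gracefully", {
  res <- fixture("small_study", function()
    run_study(small_phantom(), distances_mm = 1:5, seed = 42))
  ds <- small_phantom()
  sg <- subgroup_auc(res, ds$meta, variable = "mass_size_mm", breaks = 10)
  expect_equal(nrow(sg), 2)
  expect_true(all(c("tumoral", "peritumoral_2mm", "combined_2mm") %in% names(sg)))
  # an impossible cut leaves an empty stratum -> NA, no error
  sg2 <- subgroup_auc(res, ds$meta, variable = "mass_size_mm", breaks = 1000)
  expect_true(all(is.na(sg2[sg2$n == 0, "tumoral"])))
})
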