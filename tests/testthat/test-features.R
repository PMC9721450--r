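test_that("discretization follows the fixed-bin-width mapping", {
  px <- matrix(c(0, 10, 20, 35), 2, 2)
  m <- matrix(TRUE, 2, 2)
  lev <- discretize(px, m, feature_config(bin_value = 10))
  expect_equal(sort(lev[m]), c(1, 2, 3, 4))
  expect_equal(attr(lev, "n_levels"), 4)
  # constant region maps to the single level 1
  levc <- discretize(matrix(7, 3, 3), matrix(TRUE, 3, 3), feature_config())
  expect_true(all(levc == 1))
})

test_that("discretized histogram equals brute-force per-pixel binning", {
  set.seed(11)
  for (cfg in list(feature_config(bin_value = 5),
                   feature_config("fixed_bin_count", bin_value = 6))) {
    px <- matrix(runif(49, 0, 90), 7, 7)
    m <- matrix(runif(49) < 0.8, 7, 7); m[4, 4] <- TRUE
    lev <- discretize(px, m, cfg)
    v <- px[m]
    expected <- integer(length(v))
    for (i in seq_along(v)) {
      expected[i] <- if (cfg$discretization == "fixed_bin_width")
        floor((v[i] - min(v)) / cfg$bin_value) + 1
      else min(cfg$bin_value,
               floor(cfg$bin_value * (v[i] - min(v)) / (max(v) - min(v))) + 1)
    }
    expect_equal(lev[m], expected)
  }
})

test_that("first-order features on simple regions", {
  m <- matrix(TRUE, 2, 2)
  fv <- first_order_features(matrix(5, 2, 2), m)
  expect_equal(unname(fv[c("firstorder.Variance", "firstorder.Entropy",
                           "firstorder.Uniformity")]), c(0, 0, 1))
  fv2 <- first_order_features(matrix(1:4, 2, 2), m)
  expect_equal(unname(fv2["firstorder.Mean"]), 2.5)
  expect_equal(unname(fv2["firstorder.Range"]), 3)
})

test_that("all 18 first-order features match the direct-formula oracle", {
  set.seed(21)
  for (rep in 1:20) {
    px <- matrix(rnorm(25, 100, 30), 5, 5)
    m <- matrix(runif(25) < 0.8, 5, 5); m[3, 3] <- TRUE
    cfg <- feature_config(bin_value = 10)
    fv <- first_order_features(px, m, cfg)
    lev <- discretize(px, m, cfg)
    expected <- oracle_first_order(px[m], lev[m])
    expect_equal(unname(fv), unname(expected), tolerance = 1e-9)
  }
})

test_that("shape features scale with pixel spacing", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  f1 <- shape2d_features(m, 1)
  expect_equal(unname(f1["shape2d.Area"]), 100)
  expect_equal(unname(f1["shape2d.Perimeter"]), 40)
  f05 <- shape2d_features(m, 0.5)
  expect_equal(unname(f05["shape2d.Area"]), 25)
})

test_that("elongation of a 2:1 ellipse is close to 0.5", {
  n <- 64
  r <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  m <- ((r - 32) / 20)^2 + ((cc - 32) / 10)^2 <= 1
  f <- shape2d_features(m, 1)
  expect_lt(abs(f[["shape2d.Elongation"]] - 0.5) / 0.5, 0.05)
  expect_gt(f[["shape2d.MajorAxisLength"]], f[["shape2d.MinorAxisLength"]])
})

test_that("the GLCM of a 2x2 toy matches hand enumeration", {
  lev <- matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)
  attr(lev, "n_levels") <- 2L
  cfg <- feature_config(angles = 0)
  P <- glcm_matrix(lev, cfg)[["0"]]
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  fv <- glcm_features(lev, cfg)
  expect_equal(unname(fv["glcm.Contrast"]), 0.5)
})

test_that("constant regions have zero GLCM contrast and entropy", {
  lev <- matrix(1L, 4, 4)
  attr(lev, "n_levels") <- 1L
  fv <- glcm_features(lev, feature_config())
  expect_equal(unname(fv["glcm.Contrast"]), 0)
  expect_equal(unname(fv["glcm.JointEntropy"]), 0)
})

test_that("single-pixel masks flag the GLCM as undefined", {
  lev <- matrix(NA_integer_, 3, 3); lev[2, 2] <- 1L
  attr(lev, "n_levels") <- 1L
  expect_warning(fv <- glcm_features(lev, feature_config()), "undefined")
  expect_true(all(is.na(fv)))
})

test_that("GLCM features match the pair-enumeration oracle on random regions", {
  set.seed(41)
  cfg <- feature_config()
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  for (rep in 1:20) {
    lev <- random_region(6, 6, L = 4)
    fv <- glcm_features(lev, cfg)
    per_angle <- sapply(offs, function(o) {
      oracle_glcm_features(oracle_glcm_matrix(lev, o[1], o[2], 4))
    })
    expect_equal(unname(fv), unname(rowMeans(per_angle)), tolerance = 1e-9)
  }
})

test_that("horizontal run counting reproduces the worked example", {
  lev <- matrix(c(1, 1, 2, 2, 2, 2, 3, 3, 3), 3, 3, byrow = TRUE)
  P <- perirad:::run_length_counts(lev, 0L, 1L, 3L)
  # runs: (1,2), (2,1), (2,3), (3,3)
  expect_equal(sum(P), 4)
  expect_equal(P[1, 2], 1)
  expect_equal(P[2, 1], 1)
  expect_equal(P[2, 3], 1)
  expect_equal(P[3, 3], 1)
})

test_that("a constant region is a single size zone", {
  lev <- matrix(1L, 3, 4)
  attr(lev, "n_levels") <- 1L
  P <- perirad:::size_zone_counts(lev, 1L)
  expect_equal(dim(P), c(1L, 12L))
  expect_equal(P[1, 12], 1)
  expect_equal(sum(P), 1)
})

test_that("texture matrices equal brute-force counting on random regions", {
  set.seed(51)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (rep in 1:25) {
    lev <- random_region(5, 5, L = 3)
    L <- 3L
    for (d in dirs) {
      a <- perirad:::run_length_counts(lev, d[1], d[2], L)
      b <- oracle_glrlm_matrix(lev, d[1], d[2], L)
      expect_equal(a, b)
    }
    expect_equal(perirad:::size_zone_counts(lev, L), oracle_glszm_matrix(lev, L))
    expect_equal(perirad:::dependence_counts(lev, L), oracle_gldm_matrix(lev, L))
  }
})

test_that("extract_all is complete, finite and deterministic", {
  ds <- small_phantom()
  fv <- extract_all(ds$images[[1]], ds$masks[[1]])
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())
  expect_length(fv, 18 + 9 + 24 + 16 + 16 + 14)
  fv2 <- extract_all(ds$images[[1]], ds$masks[[1]])
  expect_identical(fv, fv2)
  expect_error(extract_all(ds$images[[1]], matrix(FALSE, 192, 192)), "empty")
})

test_that("angle-averaged GLCM features are invariant under 90-degree rotation", {
  set.seed(61)
  px <- matrix(runif(100, 0, 200), 10, 10)
  m <- matrix(runif(100) < 0.85, 10, 10); m[5, 5] <- TRUE
  cfg <- feature_config(bin_value = 40)
  rot <- function(x) t(x)[, nrow(x):1]
  f1 <- glcm_features(discretize(px, m, cfg), cfg)
  f2 <- glcm_features(discretize(rot(px), rot(m), cfg), cfg)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("features depend only on pixels inside the mask", {
  set.seed(62)
  px <- matrix(runif(64, 0, 100), 8, 8)
  m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
  f1 <- extract_all(px, m)
  px2 <- px
  px2[!m] <- px2[!m] + runif(sum(!m), -50, 50)
  f2 <- extract_all(px2, m)
  expect_identical(f1, f2)
})
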