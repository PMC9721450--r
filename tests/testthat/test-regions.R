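test_that("perfectly bimodal image yields the exact support as body mask", {
  px <- matrix(0, 64, 64)
  supp <- disk_mask(64, c(32, 32), 20)
  px[supp] <- 1000
  expect_identical(compute_body_mask(px), supp)
})

test_that("body mask of a phantom MLO view covers breast and pectoral wedge", {
  ds <- small_phantom()
  i <- which(ds$meta$view == "MLO")[1]
  body <- compute_body_mask(ds$images[[i]])
  n <- nrow(ds$images[[i]]$pixels)
  truth <- perirad:::breast_support(n) | perirad:::pectoral_support(n)
  dice <- 2 * sum(body & truth) / (sum(body) + sum(truth))
  expect_gte(dice, 0.99)
})

test_that("constant image cannot be Otsu-thresholded", {
  expect_error(compute_body_mask(matrix(5, 10, 10)), "Otsu")
})

test_that("dilation by zero distance is the identity", {
  m <- disk_mask(32, c(16, 16), 5)
  expect_identical(dilate_mask(m, 0, 1), m)
})

test_that("dilating a single pixel by 2 mm at 1 mm spacing gives the 13-pixel disk", {
  m <- matrix(FALSE, 11, 11); m[6, 6] <- TRUE
  out <- dilate_mask(m, 2, 1)
  # offsets with dx^2 + dy^2 <= 4
  expected <- matrix(FALSE, 11, 11)
  for (dr in -2:2) for (dc in -2:2)
    if (dr^2 + dc^2 <= 4) expected[6 + dr, 6 + dc] <- TRUE
  expect_identical(out, expected)
  expect_equal(sum(out), 13)
})

test_that("dilation matches the brute-force distance definition, including anisotropy", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(15 * 15) < 0.08, 15, 15)
    if (!any(m)) m[8, 8] <- TRUE
    sp <- sample(list(c(1, 1), c(0.5, 1), c(0.7, 0.3)), 1)[[1]]
    d <- runif(1, 0.5, 3)
    out <- dilate_mask(m, d, sp)
    src <- which(m, arr.ind = TRUE)
    expected <- matrix(FALSE, 15, 15)
    for (r in 1:15) for (cc in 1:15) {
      dists <- sqrt(((r - src[, 1]) * sp[1])^2 + ((cc - src[, 2]) * sp[2])^2)
      expected[r, cc] <- min(dists) <= d + 1e-9
    }
    expect_identical(out, expected)
  }
})

test_that("dilation is monotone in distance", {
  set.seed(32)
  m <- matrix(runif(20 * 20) < 0.05, 20, 20); m[10, 10] <- TRUE
  d1 <- dilate_mask(m, 1.2, 0.5)
  d2 <- dilate_mask(m, 2.7, 0.5)
  expect_true(all(d2[d1]))
})

test_that("halving the pixel spacing doubles the ring thickness in pixels", {
  thickness <- function(sp) {
    m <- matrix(FALSE, 61, 61); m[31, 31] <- TRUE
    out <- dilate_mask(m, 3, sp)
    (sum(out[31, ]) - 1) / 2  # radius in pixels along the central row
  }
  expect_lte(abs(thickness(0.25) - 2 * thickness(0.5)), 1)
})

test_that("region sets satisfy the set-algebra and nesting invariants", {
  ds <- small_phantom()
  rsets <- small_region_sets()
  for (i in seq_along(rsets)) {
    rs <- rsets[[i]]
    for (d in as.character(1:5)) {
      ring <- rs$rings[[d]]; comb <- rs$combineds[[d]]
      expect_false(any(ring & rs$tumor))
      expect_identical(comb, rs$tumor | ring)
      expect_true(all(rs$body[ring]))
      expect_equal(sum(comb) - sum(rs$tumor), sum(ring))
    }
    for (d1 in 1:4) for (d2 in (d1 + 1):5) {
      r1 <- rs$rings[[as.character(d1)]]
      inner <- rs$combineds[[as.character(d2)]] & !rs$tumor
      expect_true(all(inner[r1]))
    }
  }
})

test_that("a tumor at the breast edge gets a ring clipped to the body", {
  px <- matrix(0, 96, 96)
  body <- disk_mask(96, c(48, 48), 30)
  px[body] <- 1000
  tumor <- disk_mask(96, c(48, 74), 6)  # touches the body boundary
  img <- mammogram_from_matrix(px, spacing = 1)
  rs <- build_region_set(img, tumor, 3)
  ring <- rs$rings[["3"]]
  expect_gt(sum(ring), 0)
  expect_true(all(body[ring]))
  # without clipping the ring would spill outside the body
  expect_gt(sum(dilate_mask(tumor, 3, 1) & !tumor & !body), 0)
})

test_that("ring area approximates the analytic annulus for a circular tumor", {
  # 10 mm tumor with a 3 mm ring at mammographic 0.5 mm/px spacing; at
  # coarser spacing the few-pixel-thin discrete ring is systematically
  # under the analytic area
  n <- 96
  px <- matrix(1000, n, n)
  tumor <- disk_mask(n, c(48, 48), 20)  # 10 mm at 0.5 mm/px
  img <- mammogram_from_matrix(px, spacing = 0.5)
  rs <- build_region_set(img, tumor, 3, body = matrix(TRUE, n, n))
  analytic <- pi * (13^2 - 10^2)
  measured <- sum(rs$rings[["3"]]) * 0.25
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("empty rings are flagged and warned about", {
  px <- matrix(0, 48, 48)
  body <- disk_mask(48, c(24, 24), 10)
  px[body] <- 1000
  img <- mammogram_from_matrix(px, spacing = 1)
  expect_warning(rs <- build_region_set(img, body, 2, body = body), "empty")
  expect_true(rs$empty[["2"]])
})

test_that("region construction is deterministic", {
  ds <- small_phantom()
  a <- build_region_set(ds$images[[1]], ds$masks[[1]], 1:3)
  b <- build_region_set(ds$images[[1]], ds$masks[[1]], 1:3)
  expect_identical(a, b)
})
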