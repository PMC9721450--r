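#' Radiomics feature configuration
#'
#' Controls gray-level discretization and co-occurrence geometry for the
#' texture feature families. The default is a fixed bin width of 25 intensity
#' units — the common radiomics convention — with the four 2D angles and
#' feature aggregation by averaging over angles.
#'
#' @param discretization `"fixed_bin_width"` (default) or `"fixed_bin_count"`
#' @param bin_value the bin width (intensity units) or bin count
#' @param glcm_distance pixel offset distance for co-occurrence pairs
#' @param angles angles in degrees, a subset of `c(0, 45, 90, 135)`
#' @param normalize_matrices normalize each co-occurrence matrix to sum 1
#' @return an object of class `feature_config`
#' @export
feature_config <- function(discretization = c("fixed_bin_width", "fixed_bin_count"),
                           bin_value = 25, glcm_distance = 1,
                           angles = c(0, 45, 90, 135),
                           normalize_matrices = TRUE) {
  discretization <- match.arg(discretization)
  if (bin_value <= 0) stop("bin_value must be > 0", call. = FALSE)
  if (length(angles) == 0 || !all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a nonempty subset of {0, 45, 90, 135}", call. = FALSE)
  if (glcm_distance < 1) stop("glcm_distance must be >= 1", call. = FALSE)
  structure(list(discretization = discretization, bin_value = bin_value,
                 glcm_distance = as.integer(glcm_distance), angles = angles,
                 normalize_matrices = isTRUE(normalize_matrices)),
            class = "feature_config")
}

#' Discretize masked intensities into gray levels
#'
#' Fixed bin width maps v to `floor((v - min) / w) + 1`; fixed bin count maps
#' the observed range onto `1..N` equal bins. A constant region maps to the
#' single level 1.
#'
#' @param image numeric matrix or `mammogram_image`
#' @param mask logical matrix
#' @param config a [feature_config()]
#' @return integer matrix of levels with `NA` outside the mask;
#'   attribute `n_levels` gives the number of level bins
#' @export
discretize <- function(image, mask, config = feature_config()) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  mask <- as_binary_matrix(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- px[mask]
  if (config$discretization == "fixed_bin_width") {
    lev <- floor((v - min(v)) / config$bin_value) + 1
  } else {
    n <- as.integer(config$bin_value)
    rng <- range(v)
    if (diff(rng) == 0) lev <- rep(1L, length(v))
    else lev <- pmin(n, floor(n * (v - rng[1]) / diff(rng)) + 1)
  }
  out <- matrix(NA_integer_, nrow(px), ncol(px))
  out[mask] <- as.integer(lev)
  attr(out, "n_levels") <- max(lev)
  out
}

eps_log <- .Machine$double.eps

# first-order statistics on the masked raw intensities; entropy and
# uniformity use the discretized histogram (population moments, N denominator)
#' First-order intensity features
#'
#' Eighteen standard first-order statistics of the masked raw intensities.
#' Entropy and uniformity are computed on the discretized histogram given by
#' `config`; all moments use the population (N) denominator.
#'
#' @inheritParams discretize
#' @return named numeric vector of 18 features
#' @export
first_order_features <- function(image, mask, config = feature_config()) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  mask <- as_binary_matrix(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- px[mask]
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sk <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  vr <- v[v >= q[1] & v <= q[5]]
  lev <- discretize(px, mask, config)
  p <- tabulate(lev[mask]) / n
  p <- p[p > 0]
  c(firstorder.Mean = m,
    firstorder.Median = q[3],
    firstorder.Variance = m2,
    firstorder.Skewness = sk,
    firstorder.Kurtosis = ku,
    firstorder.Energy = sum(v^2),
    firstorder.Entropy = -sum(p * log2(p)),
    firstorder.Minimum = min(v),
    firstorder.Maximum = max(v),
    firstorder.Range = max(v) - min(v),
    firstorder.MeanAbsoluteDeviation = mean(abs(v - m)),
    firstorder.RobustMeanAbsoluteDeviation = mean(abs(vr - mean(vr))),
    firstorder.RootMeanSquared = sqrt(mean(v^2)),
    firstorder.Uniformity = sum(p^2),
    firstorder.Percentile10 = q[1],
    firstorder.Percentile90 = q[5],
    firstorder.InterquartileRange = q[4] - q[2],
    firstorder.RobustRange = q[5] - q[1])
}

#' 2D shape features of a mask
#'
#' Area and perimeter are measured in physical units from the pixel grid
#' (perimeter as the total length of exposed pixel edges); axis lengths,
#' elongation and eccentricity come from the eigenvalues of the pixel-centre
#' covariance (axis length `4 * sqrt(lambda)`, the ellipse convention);
#' maximum diameter is the largest pairwise distance between boundary pixel
#' centres.
#'
#' @param mask logical matrix
#' @param spacing_mm pixel spacing, one value or (row, col), mm/pixel
#' @return named numeric vector of 8 features (mm / mm^2)
#' @export
shape2d_features <- function(mask, spacing_mm) {
  mask <- as_binary_matrix(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sp <- check_spacing(spacing_mm)
  n <- sum(mask)
  area <- n * sp[1] * sp[2]

  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(pad); nc <- ncol(pad)
  # exposed horizontal edges (between vertically adjacent cells) have length
  # equal to the column spacing; vertical edges the row spacing
  vdiff <- pad[-1, ] != pad[-nr, ]
  hdiff <- pad[, -1] != pad[, -nc]
  perimeter <- sum(vdiff) * sp[2] + sum(hdiff) * sp[1]

  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(idx[, 1] * sp[1], idx[, 2] * sp[2])
  if (n > 1) {
    cc <- sweep(xy, 2, colMeans(xy))
    covm <- crossprod(cc) / n
    ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0

  # boundary pixels: in mask with at least one 4-neighbour outside
  below <- rbind(mask[-1, , drop = FALSE], FALSE)
  above <- rbind(FALSE, mask[-nrow(mask), , drop = FALSE])
  rightn <- cbind(mask[, -1, drop = FALSE], FALSE)
  leftn <- cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
  b <- mask & !(below & above & rightn & leftn)
  bxy <- xy[b[mask], , drop = FALSE]
  if (nrow(bxy) > 2) {
    hull <- grDevices::chull(bxy)
    bxy <- bxy[hull, , drop = FALSE]
  }
  maxdiam <- if (nrow(bxy) > 1) sqrt(max(as.matrix(stats::dist(bxy))^2)) else
    sqrt(sum(sp^2))

  c(shape2d.Area = area,
    shape2d.Perimeter = perimeter,
    shape2d.PerimeterAreaRatio = perimeter / area,
    shape2d.MajorAxisLength = major,
    shape2d.MinorAxisLength = minor,
    shape2d.Elongation = elong,
    shape2d.Eccentricity = ecc,
    shape2d.Circularity = 2 * sqrt(pi * area) / perimeter,
    shape2d.MaximumDiameter = maxdiam)
}
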