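# Texture matrix families on discretized gray levels. All builders take an
# integer level matrix with NA outside the mask (as returned by discretize())
# and count strictly inside the mask; features follow the standard
# (IBSI-consistent) definitions with log base 2.

angle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop("unsupported angle: ", angle, call. = FALSE))
}

crop_levels <- function(lev) {
  inm <- !is.na(lev)
  rr <- range(which(rowSums(inm) > 0))
  cc <- range(which(colSums(inm) > 0))
  out <- lev[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  attr(out, "n_levels") <- attr(lev, "n_levels")
  out
}

# paired level values at a pixel offset, both endpoints inside the mask
offset_pairs <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  rlo <- max(1, 1 - dr); rhi <- min(nr, nr - dr)
  clo <- max(1, 1 - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(cbind(integer(0), integer(0)))
  r1 <- rlo:rhi
  c1 <- clo:chi
  A <- lev[r1, c1, drop = FALSE]
  B <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  cbind(A[ok], B[ok])
}

n_levels_of <- function(lev) {
  L <- attr(lev, "n_levels")
  if (is.null(L)) L <- max(lev, na.rm = TRUE)
  as.integer(L)
}

#' Gray-level co-occurrence matrices
#'
#' One symmetric matrix per configured angle, counting level pairs at the
#' configured pixel distance within the mask; each matrix is normalized to
#' sum 1 when `normalize_matrices` is set. Angles with no valid pixel pair
#' yield `NULL`.
#'
#' @param levels integer level matrix with `NA` outside the mask
#'   (see [discretize()])
#' @param config a [feature_config()]
#' @return named list of L x L matrices, one per angle
#' @export
glcm_matrix <- function(levels, config = feature_config()) {
  lev <- crop_levels(levels)
  L <- n_levels_of(lev)
  out <- stats::setNames(vector("list", length(config$angles)),
                         as.character(config$angles))
  for (a in seq_along(config$angles)) {
    off <- angle_offset(config$angles[a], config$glcm_distance)
    pr <- offset_pairs(lev, off[1], off[2])
    if (nrow(pr) == 0) next
    counts <- tabulate((pr[, 1] - 1L) * L + pr[, 2], nbins = L * L)
    P <- matrix(counts, L, L, byrow = TRUE)
    P <- P + t(P)
    if (config$normalize_matrices) P <- P / sum(P)
    out[[a]] <- P
  }
  out
}

glcm_features_from_matrix <- function(P) {
  P <- P / sum(P)
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  ux <- sum(i * P); uy <- sum(j * P)
  sigx <- sqrt(sum((i - ux)^2 * P)); sigy <- sqrt(sum((j - uy)^2 * P))
  dif <- abs(i - j)
  kd <- 0:(L - 1)
  pd <- vapply(kd, function(k) sum(P[dif == k]), numeric(1))
  s <- i + j
  ks <- 2:(2 * L)
  ps <- vapply(ks, function(k) sum(P[s == k]), numeric(1))
  da <- sum(kd * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + eps_log))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  # MCC: sqrt of the second-largest eigenvalue of Q, restricted to occupied
  # levels so empty bins do not produce 0/0
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Psub <- P[occ, occ, drop = FALSE]
    A <- Psub / px[occ]
    B <- sweep(Psub, 2, py[occ], `/`)
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  }
  corr <- if (sigx * sigy > 0) (sum(i * j * P) - ux * uy) / (sigx * sigy) else 1
  c(Autocorrelation = sum(i * j * P),
    JointAverage = ux,
    ClusterProminence = sum((i + j - ux - uy)^4 * P),
    ClusterShade = sum((i + j - ux - uy)^3 * P),
    ClusterTendency = sum((i + j - ux - uy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / L)^2)),
    Id = sum(P / (1 + dif)),
    Idn = sum(P / (1 + dif / L)),
    InverseVariance = sum((P / (dif^2 + (dif == 0)))[dif > 0]),
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sum((i - ux)^2 * P),
    MCC = mcc)
}

#' Gray-level co-occurrence features
#'
#' The 24 GLCM features, computed per angle and averaged over the configured
#' angles. If no angle has a valid pixel pair (e.g. a single-pixel mask) the
#' feature set is undefined and returned as `NA` with a warning.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 24 features (prefix `glcm.`)
#' @export
glcm_features <- function(levels, config = feature_config()) {
  mats <- glcm_matrix(levels, config)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  nm <- names(glcm_features_from_matrix(matrix(1)))
  if (length(mats) == 0) {
    warning("GLCM undefined: no valid pixel pairs at any configured angle",
            call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(nm)), paste0("glcm.", nm)))
  }
  vals <- vapply(mats, glcm_features_from_matrix, numeric(length(nm)))
  stats::setNames(rowMeans(vals), paste0("glcm.", nm))
}

# ---- run-length ----

run_length_counts <- function(lev, dr, dc, L) {
  ok <- !is.na(lev)
  r <- row(lev)[ok]; cc <- col(lev)[ok]; v <- lev[ok]
  line <- r * dc - cc * dr
  pos <- r * dr + cc * dc
  o <- order(line, pos)
  line <- line[o]; pos <- pos[o]; v <- v[o]
  step <- dr * dr + dc * dc
  newrun <- c(TRUE, diff(line) != 0 | diff(pos) != step | diff(v) != 0)
  id <- cumsum(newrun)
  len <- tabulate(id)
  rl <- v[newrun]
  maxlen <- max(len)
  matrix(tabulate((rl - 1L) * maxlen + len, nbins = L * maxlen),
         L, maxlen, byrow = TRUE)
}

rlm_style_features <- function(P, Np, prefix, names16) {
  Nr <- sum(P)
  p <- P / Nr
  i <- row(P); j <- col(P)
  ri <- rowSums(P); cj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(
    sum(p / j^2), sum(p * j^2),
    sum(ri^2) / Nr, sum(ri^2) / Nr^2,
    sum(cj^2) / Nr, sum(cj^2) / Nr^2,
    Nr / Np,
    sum((i - mu_i)^2 * p), sum((j - mu_j)^2 * p),
    -sum(p[p > 0] * log2(p[p > 0])),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2))
  stats::setNames(vals, paste0(prefix, names16))
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                 "RunPercentage", "GrayLevelVariance", "RunVariance",
                 "RunEntropy", "LowGrayLevelRunEmphasis",
                 "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

#' Gray-level run-length features
#'
#' Runs of equal gray level are counted along the four 2D directions
#' (horizontal, vertical and both diagonals), restricted to the mask; the 16
#' standard features are computed per direction and averaged.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features (prefix `glrlm.`)
#' @export
glrlm_features <- function(levels, config = feature_config()) {
  lev <- crop_levels(levels)
  L <- n_levels_of(lev)
  Np <- sum(!is.na(lev))
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  vals <- vapply(dirs, function(d) {
    rlm_style_features(run_length_counts(lev, d[1], d[2], L), Np, "glrlm.",
                       glrlm_names)
  }, numeric(16))
  stats::setNames(rowMeans(vals), rownames(vals))
}

# ---- size-zone ----

size_zone_counts <- function(lev, L) {
  ok <- !is.na(lev)
  n <- sum(ok)
  idx <- matrix(NA_integer_, nrow(lev), ncol(lev))
  idx[ok] <- seq_len(n)
  edges <- integer(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nr <- nrow(lev); nc <- ncol(lev)
    r1 <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    A <- lev[r1, c1, drop = FALSE]
    B <- lev[r1 + o[1], c1 + o[2], drop = FALSE]
    same <- !is.na(A) & !is.na(B) & A == B
    if (any(same)) {
      ia <- idx[r1, c1, drop = FALSE][same]
      ib <- idx[r1 + o[1], c1 + o[2], drop = FALSE][same]
      edges <- c(edges, rbind(ia, ib))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  zsize <- tabulate(memb)
  zlev <- lev[ok][match(seq_along(zsize), memb)]
  maxsize <- max(zsize)
  matrix(tabulate((zlev - 1L) * maxsize + zsize, nbins = L * maxsize),
         L, maxsize, byrow = TRUE)
}

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                 "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                 "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                 "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                 "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone features
#'
#' Zones are 8-connected components of equal gray level within the mask;
#' a single matrix (level x zone size) yields the 16 standard features.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features (prefix `glszm.`)
#' @export
glszm_features <- function(levels, config = feature_config()) {
  lev <- crop_levels(levels)
  L <- n_levels_of(lev)
  Np <- sum(!is.na(lev))
  rlm_style_features(size_zone_counts(lev, L), Np, "glszm.", glszm_names)
}

# ---- dependence ----

dependence_counts <- function(lev, L) {
  nr <- nrow(lev); nc <- ncol(lev)
  pad <- matrix(NA_integer_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lev
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc, drop = FALSE]
    same <- !is.na(nb) & !is.na(lev) & nb == lev
    dep <- dep + same
  }
  ok <- !is.na(lev)
  # dependence includes the centre pixel, so every pixel has dependence >= 1
  d <- dep[ok] + 1L
  v <- lev[ok]
  maxdep <- max(d)
  matrix(tabulate((v - 1L) * maxdep + d, nbins = L * maxdep),
         L, maxdep, byrow = TRUE)
}

#' Gray-level dependence features
#'
#' A pixel's dependence is the number of 8-neighbours inside the mask with
#' the same gray level (cutoff alpha = 0), plus one for the pixel itself; the
#' level-by-dependence matrix yields 14 standard features.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 14 features (prefix `gldm.`)
#' @export
gldm_features <- function(levels, config = feature_config()) {
  lev <- crop_levels(levels)
  L <- n_levels_of(lev)
  P <- dependence_counts(lev, L)
  Nz <- sum(P)
  p <- P / Nz
  i <- row(P); j <- col(P)
  ri <- rowSums(P); cj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(ri^2) / Nz,
    DependenceNonUniformity = sum(cj^2) / Nz,
    DependenceNonUniformityNormalized = sum(cj^2) / Nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2))
  stats::setNames(vals, paste0("gldm.", names(vals)))
}

#' Names of all features produced by [extract_all()]
#'
#' @param config a [feature_config()]
#' @return character vector of feature names in stable extraction order
#' @export
feature_names <- function(config = feature_config()) {
  toy <- matrix(c(1, 2, 3, 4), 2)
  m <- matrix(TRUE, 2, 2)
  names(extract_all(structure(list(pixels = toy, spacing_mm = c(1, 1)),
                              class = "mammogram_image"), m, config))
}

#' Extract the full radiomics feature vector
#'
#' Concatenates, in stable order, the first-order (18), 2D shape (9), GLCM
#' (24), GLRLM (16), GLSZM (16) and GLDM (14) feature fragments for one
#' (image, mask) pair — 97 features with the default configuration.
#'
#' @param image a `mammogram_image` or numeric matrix (then `spacing_mm`
#'   defaults to 1 mm)
#' @param mask logical matrix
#' @param config a [feature_config()]
#' @return named numeric vector
#' @export
extract_all <- function(image, mask, config = feature_config()) {
  if (!inherits(image, "mammogram_image")) {
    stopifnot(is.matrix(image))
    image <- structure(list(pixels = image, spacing_mm = c(1, 1)),
                       class = "mammogram_image")
  }
  mask <- as_binary_matrix(mask)
  if (!any(mask)) stop("cannot extract features from an empty region", call. = FALSE)
  lev <- discretize(image$pixels, mask, config)
  c(first_order_features(image$pixels, mask, config),
    shape2d_features(mask, image$spacing_mm),
    glcm_features(lev, config),
    glrlm_features(lev, config),
    glszm_features(lev, config),
    gldm_features(lev, config))
}
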