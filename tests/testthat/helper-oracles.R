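# Brute-force reference implementations used as independent oracles.
# Everything here is written as explicit per-pixel / per-pair loops and must
# stay independent of the package's vectorized code paths.

oracle_first_order <- function(v, levels_in_mask) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  vr <- v[v >= q[1] & v <= q[5]]
  counts <- table(levels_in_mask)
  p <- as.numeric(counts) / n
  c(Mean = m,
    Median = q[3],
    Variance = m2,
    Skewness = if (m2 > 0) (sum((v - m)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((v - m)^4) / n) / m2^2 else 0,
    Energy = sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    Maximum = max(v),
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = sum(abs(v - m)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(vr - mean(vr))) / length(vr),
    RootMeanSquared = sqrt(sum(v^2) / n),
    Uniformity = sum(p^2),
    Percentile10 = q[1],
    Percentile90 = q[5],
    InterquartileRange = q[4] - q[2],
    RobustRange = q[5] - q[1])
}

# co-occurrence by exhaustive pixel-pair enumeration (symmetric)
oracle_glcm_matrix <- function(lev, dr, dc, L) {
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(lev))) for (cc in seq_len(ncol(lev))) {
    a <- lev[r, cc]
    if (is.na(a)) next
    r2 <- r + dr; c2 <- cc + dc
    if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
    b <- lev[r2, c2]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_features <- function(P) {
  P <- P / sum(P)
  L <- nrow(P)
  eps <- .Machine$double.eps
  px <- py <- numeric(L)
  for (i in 1:L) for (j in 1:L) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  ux <- 0; uy <- 0
  for (i in 1:L) for (j in 1:L) { ux <- ux + i * P[i, j]; uy <- uy + j * P[i, j] }
  sigx2 <- 0; sigy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    sigx2 <- sigx2 + (i - ux)^2 * P[i, j]; sigy2 <- sigy2 + (j - uy)^2 * P[i, j]
  }
  acc <- contrast <- cp <- cs <- ct <- je <- hxy <- idm <- idmn <- idq <- idn <-
    iv <- ss <- corr_num <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    acc <- acc + i * j * p
    contrast <- contrast + (i - j)^2 * p
    cp <- cp + (i + j - ux - uy)^4 * p
    cs <- cs + (i + j - ux - uy)^3 * p
    ct <- ct + (i + j - ux - uy)^2 * p
    je <- je + p^2
    if (p > 0) hxy <- hxy - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / L)^2)
    idq <- idq + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / L)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - ux)^2 * p
    corr_num <- corr_num + (i - ux) * (j - uy) * p
  }
  pd <- numeric(L)        # index k+1 for k = 0..L-1
  ps <- numeric(2 * L - 1)  # index k-1 for k = 2..2L
  for (i in 1:L) for (j in 1:L) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- sum((0:(L - 1)) * pd)
  dv <- sum(((0:(L - 1)) - da)^2 * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sa <- sum((2:(2 * L)) * ps)
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j] + eps)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Q <- matrix(0, length(occ), length(occ))
    for (ii in seq_along(occ)) for (jj in seq_along(occ)) {
      for (kk in seq_along(occ)) {
        Q[ii, jj] <- Q[ii, jj] +
          P[occ[ii], occ[kk]] * P[occ[jj], occ[kk]] / (px[occ[ii]] * py[occ[kk]])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = acc, JointAverage = ux,
    ClusterProminence = cp, ClusterShade = cs, ClusterTendency = ct,
    Contrast = contrast,
    Correlation = if (sigx2 * sigy2 > 0) corr_num / sqrt(sigx2 * sigy2) else 1,
    DifferenceAverage = da, DifferenceEntropy = de, DifferenceVariance = dv,
    JointEnergy = je, JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Idm = idm, Idmn = idmn, Id = idq, Idn = idn,
    InverseVariance = iv, MaximumProbability = max(P),
    SumAverage = sa, SumEntropy = se, SumSquares = ss, MCC = mcc)
}

# run-length counts by explicit per-line scanning
oracle_glrlm_matrix <- function(lev, dr, dc, L) {
  nr <- nrow(lev); nc <- ncol(lev)
  starts <- list()
  for (r in 1:nr) for (cc in 1:nc) {
    pr <- r - dr; pc <- cc - dc
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, cc)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur_lev <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && cc >= 1 && cc <= nc) {
      v <- lev[r, cc]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; cc <- cc + dc
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  maxlen <- max(vapply(runs, `[`, 0, 2))
  P <- matrix(0, L, maxlen)
  for (rn in runs) P[rn[1], rn[2]] <- P[rn[1], rn[2]] + 1
  P
}

# size zones by explicit stack-based flood fill, 8-connectivity
oracle_glszm_matrix <- function(lev, L) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in 1:nr) for (cc in 1:nc) {
    if (is.na(lev[r, cc]) || seen[r, cc]) next
    target <- lev[r, cc]
    stack <- list(c(r, cc)); seen[r, cc] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || is.na(lev[r2, c2]) || lev[r2, c2] != target) next
        seen[r2, c2] <- TRUE
        stack[[length(stack) + 1]] <- c(r2, c2)
      }
    }
    zones[[length(zones) + 1]] <- c(target, size)
  }
  maxsize <- max(vapply(zones, `[`, 0, 2))
  P <- matrix(0, L, maxsize)
  for (z in zones) P[z[1], z[2]] <- P[z[1], z[2]] + 1
  P
}

# dependence counts by explicit neighbour loop (alpha = 0, centre included)
oracle_gldm_matrix <- function(lev, L) {
  nr <- nrow(lev); nc <- ncol(lev)
  deps <- list()
  for (r in 1:nr) for (cc in 1:nc) {
    if (is.na(lev[r, cc])) next
    d <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(lev[r2, c2]) && lev[r2, c2] == lev[r, cc]) d <- d + 1
    }
    deps[[length(deps) + 1]] <- c(lev[r, cc], d)
  }
  maxdep <- max(vapply(deps, `[`, 0, 2))
  P <- matrix(0, L, maxdep)
  for (d in deps) P[d[1], d[2]] <- P[d[1], d[2]] + 1
  P
}

oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# DeLong structural components by explicit psi loops
oracle_delong <- function(sa, sb, y) {
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  comp <- function(s) {
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + psi(s[pos[i]], s[neg[j]])
      v10[i] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + psi(s[pos[i]], s[neg[j]])
      v01[j] <- acc / m
    }
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  ca <- comp(sa); cb <- comp(sb)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  list(auc_a = ca$auc, auc_b = cb$auc,
       var_diff = S[1, 1] + S[2, 2] - 2 * S[1, 2], S = S)
}

oracle_operating_point <- function(scores, y) {
  cand <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in cand) {
    sens <- sum(scores >= t & y == 1) / sum(y == 1)
    spec <- sum(scores < t & y == 0) / sum(y == 0)
    if (is.null(best) || sens + spec - 1 > best$j + 1e-12)
      best <- list(threshold = t, sens = sens, spec = spec, j = sens + spec - 1)
  }
  best
}

# random discretized test region: ~75% mask coverage, few gray levels
random_region <- function(nr, nc, L = 4, coverage = 0.75) {
  lev <- matrix(sample.int(L, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < coverage, nr, nc)
  if (!any(mask)) mask[sample.int(nr * nc, 1)] <- TRUE
  lev[!mask] <- NA
  storage.mode(lev) <- "integer"
  attr(lev, "n_levels") <- L
  lev
}
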