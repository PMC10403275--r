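## Independent oracles used across test files. These deliberately avoid the
## package's own code paths: plain loops and enumerations only.

## exhaustive pair-enumeration segregation profile
bruteProfile <- function(M, part) {
  nets <- unique(part)
  res <- lapply(nets, function(nw) {
    ins <- which(part == nw)
    outs <- which(part != nw)
    wvals <- c()
    for (a in ins) for (b in ins) if (a < b) wvals <- c(wvals, M[a, b])
    bvals <- c()
    for (a in ins) for (b in outs) bvals <- c(bvals, M[a, b])
    w <- mean(wvals); btw <- mean(bvals)
    data.frame(network = nw, within = w, between = btw,
               segregation = (w - btw) / w)
  })
  pn <- do.call(rbind, res)
  list(perNetwork = pn, wholeBrain = mean(pn$segregation))
}

## random thresholded symmetric z-matrix with a given partition
randomZMatrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, -0.3, 0.9), n, n)
  Z <- (A + t(A)) / 2
  Z[Z < 0] <- 0
  diag(Z) <- 0
  Z
}

## grid-scan Johnson-Neyman oracle: boundaries of |t(m)| = t_c located by
## sign changes over a dense grid of standardized moderator values
gridJN <- function(b1, b3, v1, v3, c13, tc, lo, hi, nGrid = 1e5) {
  m <- seq(lo, hi, length.out = nGrid)
  tt <- abs((b1 + b3 * m) / sqrt(v1 + 2 * m * c13 + m^2 * v3)) - tc
  sgn <- sign(tt)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  # linear interpolation at each crossing
  vapply(idx, function(i) {
    m[i] + (m[i + 1] - m[i]) * tt[i] / (tt[i] - tt[i + 1])
  }, numeric(1))
}

## leave-one-out Cook's distance oracle: D_i = sum_j (yhat_j - yhat_j(i))^2
## / (p * s^2), with s^2 the full-fit residual mean square
looCooks <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  beta <- solve(crossprod(X), crossprod(X, y))
  yhat <- X %*% beta
  s2 <- sum((y - yhat)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    bi <- solve(crossprod(Xi), crossprod(Xi, yi))
    sum((yhat - X %*% bi)^2) / (p * s2)
  }, numeric(1))
}

## brute-force sphere voxelization by lattice enumeration around the center
bruteSphereCount <- function(center, radius, voxdim, origin, reach = 20) {
  cnt <- 0L
  for (i in -reach:reach) for (j in -reach:reach) for (k in -reach:reach) {
    ctr <- origin + c(i, j, k) * voxdim
    if (sum((ctr - center)^2) <= radius^2 + 1e-9) cnt <- cnt + 1L
  }
  cnt
}

## does a JN region confine significance to the lower end of the observed
## moderator range? (significant interval touches the low end, stops before
## the high end, and any second significant interval lies above the range)
jnLowAgeOnly <- function(jn) {
  lo <- jn@observedRange[1]; hi <- jn@observedRange[2]
  b <- boundaries(jn)
  if (jn@side == "below" && length(b) == 1)
    return(b > lo && b < hi)
  if (jn@side == "outside" && length(b) == 2)
    return(b[1] > lo && b[1] < hi && b[2] >= hi)
  FALSE
}

## tiny three-network partition used in several tests
toyPartition <- function(n = 20, nets = c("A", "B", "C"), seed = 1) {
  set.seed(seed)
  repeat {
    p <- sample(nets, n, replace = TRUE)
    if (all(table(factor(p, nets)) >= 2)) return(p)
  }
}
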