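# Deliberately naive brute-force oracles, independent of the package's
# vectorised implementations.

# Dice/IoU by explicit pixel loops.
bfDiceIoU <- function(predLab, refLab, cl) {
  np <- 0; nr <- 0; ni <- 0
  for (i in seq_len(nrow(predLab))) for (j in seq_len(ncol(predLab))) {
    p <- predLab[i, j] == cl; r <- refLab[i, j] == cl
    np <- np + p; nr <- nr + r; ni <- ni + (p && r)
  }
  if (np + nr == 0) return(c(dice = 1, iou = 1))
  if (np == 0 || nr == 0) return(c(dice = 0, iou = 0))
  c(dice = 2 * ni / (np + nr), iou = ni / (np + nr - ni))
}

# Surface pixels by explicit neighbour checks (border counts outside).
bfSurface <- function(lab, cl) {
  out <- NULL
  h <- nrow(lab); w <- ncol(lab)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (lab[i, j] != cl) next
    nb <- c(if (i > 1) lab[i - 1, j] == cl else FALSE,
            if (i < h) lab[i + 1, j] == cl else FALSE,
            if (j > 1) lab[i, j - 1] == cl else FALSE,
            if (j < w) lab[i, j + 1] == cl else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

# ASD / HD95 by all-pairs O(N^2) distance loops.
bfSurfaceDistances <- function(predLab, refLab, cl, spacing) {
  P <- bfSurface(predLab, cl); R <- bfSurface(refLab, cl)
  mm <- function(ij) c((ij[1] - 1) * spacing[1], (ij[2] - 1) * spacing[2])
  dPR <- numeric(nrow(P)); dRP <- numeric(nrow(R))
  for (a in seq_len(nrow(P))) {
    best <- Inf
    for (b in seq_len(nrow(R))) {
      d <- sqrt(sum((mm(P[a, ]) - mm(R[b, ]))^2))
      if (d < best) best <- d
    }
    dPR[a] <- best
  }
  for (a in seq_len(nrow(R))) {
    best <- Inf
    for (b in seq_len(nrow(P))) {
      d <- sqrt(sum((mm(R[a, ]) - mm(P[b, ]))^2))
      if (d < best) best <- d
    }
    dRP[a] <- best
  }
  c(asd = (mean(dPR) + mean(dRP)) / 2,
    hd95 = unname(quantile(c(dPR, dRP), 0.95, type = 7)))
}

# Generalized Dice Loss by explicit double loop over classes and pixels.
bfGDL <- function(P, R) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(P))) {
    vol <- sum(R[, l])
    w <- if (vol > 0) 1 / vol^2 else 0
    for (n in seq_len(nrow(P))) {
      num <- num + w * R[n, l] * P[n, l]
      den <- den + w * (R[n, l] + P[n, l])
    }
  }
  1 - 2 * num / (den + 1e-12)
}

# Laplace sampler via inverse CDF.
rlaplace <- function(n, mu, b) {
  u <- runif(n)
  mu - b * sign(u - 0.5) * log(1 - 2 * abs(u - 0.5))
}

# Random label-mask pair on a small grid with a handful of blobs per class.
randomMaskPair <- function(dim = 24, spacing = 0.35) {
  lab <- function() {
    m <- matrix(0L, dim, dim)
    for (cl in 1:3) {
      for (k in 1:2) {
        ci <- sample(2:(dim - 1), 1); cj <- sample(2:(dim - 1), 1)
        r <- sample(1:3, 1)
        ii <- pmax(1, ci - r):pmin(dim, ci + r)
        jj <- pmax(1, cj - r):pmin(dim, cj + r)
        m[ii, jj] <- cl
      }
    }
    m
  }
  list(pred = labelMask(lab(), spacing), ref = labelMask(lab(), spacing))
}

# Phantom at test scale (0.7 mm spacing keeps the mm geometry of the default
# 512 px / 0.35 mm field).
testPhantom <- function(thetaLeft = 45, thetaRight = 40, imageSize = 256L, ...) {
  generatePhantom(phantomSpec(imageSize = imageSize, thetaLeft = thetaLeft,
                              thetaRight = thetaRight, ...))
}

# Random softmax matrix (rows sum to 1).
randomProbs <- function(n, C) {
  z <- matrix(rexp(n * C), n, C)
  z / rowSums(z)
}

expect_angle_equal <- function(a, b, tol) {
  expect_lt(abs(a - b), tol)
}
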