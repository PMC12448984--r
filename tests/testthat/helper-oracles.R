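# Small-data builders and independent reference implementations used as
# oracles. Nothing here may call back into the code paths under test.

rand_dataset <- function(n, p, miss = 0, seed = 1, chrom = NULL) {
  set.seed(seed)
  g <- matrix(rbinom(n * p, 2L, runif(p, 0.2, 0.8)[rep(seq_len(p),
                                                       each = n)]),
              n, p)
  if (miss > 0) g[sample(length(g), round(miss * length(g)))] <- NA
  variants <- data.frame(
    chrom = if (is.null(chrom)) rep("1", p) else chrom,
    pos = seq_len(p) * 10L,
    id = paste0("rs", seq_len(p)),
    a1 = sample(c("A", "C", "G", "T"), p, replace = TRUE),
    a2 = sample(c("A", "C", "G", "T"), p, replace = TRUE),
    stringsAsFactors = FALSE)
  genotype_dataset(g, variants)
}

# Douglas-Rachford solver for min 1/2||x-z||^2 + t2||x||_1 + t1||x||_2,
# built only from the two elementary proxes (never from the composed
# formula under test).
dr_prox_oracle <- function(z, t2, t1, gamma = 1, iters = 4000) {
  prox_f <- function(v, gam) {             # 1/2||x-z||^2 + t2||x||_1
    w <- (v + gam * z) / (1 + gam)
    th <- gam * t2 / (1 + gam)
    sign(w) * pmax(abs(w) - th, 0)
  }
  prox_g <- function(v, gam) {             # t1 ||x||_2
    nv <- sqrt(sum(v^2))
    if (nv <= gam * t1) rep(0, length(v)) else v * (1 - gam * t1 / nv)
  }
  u <- z
  for (i in seq_len(iters)) {
    x <- prox_g(u, gamma)
    w <- prox_f(2 * x - u, gamma)
    u <- u + w - x
  }
  prox_g(u, gamma)
}

# full-gradient FISTA for the multitask (sparse) group lasso on an
# explicitly materialized block-diagonal design; per-task intercepts are
# assumed removed by centering beforehand (gaussian only)
fista_reference <- function(Xlist, ylist, grp_sizes, wg,
                            lambda1, lambda2 = 0, iters = 50000,
                            tol = 1e-13) {
  Tn <- length(Xlist)
  p <- ncol(Xlist[[1]])
  n <- sum(vapply(ylist, length, 1))
  # dense block-diagonal X
  Xb <- matrix(0, n, p * Tn)
  yb <- numeric(n)
  r0 <- 0
  for (t in seq_len(Tn)) {
    nt <- nrow(Xlist[[t]])
    Xb[r0 + seq_len(nt), (t - 1) * p + seq_len(p)] <- Xlist[[t]]
    yb[r0 + seq_len(nt)] <- ylist[[t]]
    r0 <- r0 + nt
  }
  # group structure: block g spans rows (SNPs) of that group x all tasks
  goff <- c(0, cumsum(grp_sizes))
  blocks <- lapply(seq_along(grp_sizes), function(g) {
    unlist(lapply(seq_len(Tn), function(t)
      (t - 1) * p + (goff[g] + 1):goff[g + 1]))
  })
  L <- max(eigen(crossprod(Xb), symmetric = TRUE,
                 only.values = TRUE)$values) / n
  b <- bprev <- rep(0, p * Tn)
  v <- b
  tk <- 1
  obj <- function(b) {
    r <- yb - Xb %*% b
    val <- sum(r^2) / (2 * n)
    for (g in seq_along(blocks)) {
      bg <- b[blocks[[g]]]
      val <- val + lambda1 * wg[g] * sqrt(sum(bg^2)) +
        lambda2 * wg[g] * sum(abs(bg))
    }
    val
  }
  oprev <- Inf
  for (i in seq_len(iters)) {
    grad <- -crossprod(Xb, yb - Xb %*% v) / n
    z <- v - grad / L
    for (g in seq_along(blocks)) {
      idx <- blocks[[g]]
      x <- z[idx]
      x <- sign(x) * pmax(abs(x) - lambda2 * wg[g] / L, 0)
      nx <- sqrt(sum(x^2))
      z[idx] <- if (nx <= lambda1 * wg[g] / L) 0 else
        x * (1 - lambda1 * wg[g] / (L * nx))
    }
    bprev <- b
    b <- z
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- b + ((tk - 1) / tk1) * (b - bprev)
    tk <- tk1
    if (i %% 200 == 0) {
      o <- obj(b)
      if (abs(oprev - o) < tol * max(1, o)) break
      oprev <- o
    }
  }
  matrix(b, p, Tn)
}

# population-differentiation estimator from per-population frequency
# vectors (two populations): ratio of the among-population variance to
# the mean heterozygosity
fst_estimate <- function(f1, f2) {
  pbar <- (f1 + f2) / 2
  mean((f1 - f2)^2 / 2) / mean(pbar * (1 - pbar))
}

# total within-cluster Ward cost of a contiguous partition given a banded
# similarity (same cost the segmentation minimizes, computed naively)
partition_cost <- function(bounds, band) {
  h <- nrow(band)
  tot <- 0
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i] + 1; bnd <- bounds[i + 1]
    m <- bnd - a + 1
    S <- m
    if (m > 1) {
      for (j in a:(bnd - 1)) {
        for (k in (j + 1):bnd) {
          if (k - j <= h) S <- S + 2 * band[k - j, j]
        }
      }
    }
    tot <- tot + 0.5 * (m - S / m)
  }
  tot
}

# all contiguous partitions of p items into K groups (boundary sets)
all_contiguous_partitions <- function(p, K) {
  if (K == 1) return(list(c(0, p)))
  cuts <- utils::combn(seq_len(p - 1), K - 1)
  lapply(seq_len(ncol(cuts)), function(i) c(0, cuts[, i], p))
}

# independent per-SNP trend statistic: n * cor(g, y)^2
trend_chisq_oracle <- function(g, y) {
  apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    if (stats::sd(col) == 0 || stats::sd(y) == 0) return(0)
    length(y) * stats::cor(col, y)^2
  })
}
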