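#' Standardize a genotype matrix
#'
#' Mean-imputes missing genotypes per SNP, then centers each SNP to mean 0
#' and scales to unit variance (denominator n - 1). Zero-variance columns
#' become all-zero.
#'
#' @param x a [genotype_dataset] or numeric matrix.
#' @return numeric matrix of the same dimensions.
#' @export
standardize_genotypes <- function(x) {
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else x
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  ctr <- colMeans(g)
  sds <- apply(g, 2, stats::sd)
  sds[sds == 0] <- Inf  # constant columns -> zeros
  sweep(sweep(g, 2, ctr), 2, sds, "/")
}

#' Principal-component scores of a standardized genotype matrix
#'
#' Computes the top k principal components (scores = left singular vectors
#' scaled by singular values), using the n x n crossproduct when p > n.
#' A deterministic sign convention is applied: the largest-magnitude loading
#' of each component is positive.
#'
#' @param X standardized matrix (see [standardize_genotypes]).
#' @param k number of components, at most min(n, p).
#' @return object of class `pc_scores`: list with `scores` (n x k),
#'   `explained` (variance explained per component), `total_variance`, `k`.
#' @export
pca_scores <- function(X, k = 4) {
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stop("k must be at most min(n, p)")
  total_var <- sum(apply(X, 2, stats::var))
  if (p > n) {
    K <- tcrossprod(X)              # X X'
    e <- eigen(K, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    d <- sqrt(ev[seq_len(k)])
    scores <- e$vectors[, seq_len(k), drop = FALSE] *
      rep(d, each = n)
    varexp <- ev[seq_len(k)] / (n - 1)
    # sign via loadings v_j = X' u_j / d_j
    for (j in seq_len(k)) {
      if (d[j] <= 0) next
      v <- crossprod(X, e$vectors[, j]) / d[j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  } else {
    s <- svd(X, nu = k, nv = k)
    scores <- s$u * rep(s$d[seq_len(k)], each = n)
    varexp <- s$d[seq_len(k)]^2 / (n - 1)
    for (j in seq_len(k)) {
      v <- s$v[, j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, explained = varexp,
                 total_variance = total_var, k = k),
            class = "pc_scores")
}

# k-means++ seeding
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = pr)
      centers[j, ] <- X[idx, ]
      nd <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

#' Assign samples to populations (tasks) by k-means on PC scores
#'
#' Runs k-means with k-means++ seeding and `n_restarts` restarts, keeping
#' the solution with the lowest within-cluster inertia (ties broken by
#' restart order). With `T = "auto"`, the number of populations is chosen
#' among 2..8 at the elbow of the inertia curve (largest second difference).
#' Deterministic given `seed`.
#'
#' @param scores a `pc_scores` object or numeric matrix of coordinates.
#' @param T number of populations, or `"auto"`.
#' @param n_restarts k-means restarts.
#' @param seed integer seed.
#' @return object of class `task_assignment`: list with `task` (integer
#'   vector in 1..T), `T`, `n_t` (per-task counts), `inertia`.
#' @export
assign_populations <- function(scores, T = "auto", n_restarts = 20,
                               seed = 1) {
  X <- if (inherits(scores, "pc_scores")) scores$scores else as.matrix(scores)
  n <- nrow(X)
  run_km <- function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cen <- kmeanspp_centers(X, k)
      km <- suppressWarnings(stats::kmeans(X, centers = cen,
                                           iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  }
  set.seed(seed)
  if (identical(T, "auto")) {
    ks <- 1:8
    ks <- ks[ks <= n]
    fits <- vector("list", length(ks))
    inert <- numeric(length(ks))
    for (i in seq_along(ks)) {
      if (ks[i] == 1L) {
        inert[i] <- sum(scale(X, scale = FALSE)^2)
      } else {
        fits[[i]] <- run_km(ks[i])
        inert[i] <- fits[[i]]$tot.withinss
      }
    }
    if (length(ks) > 2) {
      d2 <- diff(diff(inert))           # second difference of inertia
      pick <- which.max(d2) + 1L        # elbow
    } else pick <- length(ks)
    if (ks[pick] == 1L) {
      return(structure(list(task = rep(1L, n), T = 1L, n_t = n,
                            inertia = inert[1]),
                       class = "task_assignment"))
    }
    km <- fits[[pick]]
  } else {
    T <- as.integer(T)
    if (n < T) stop("fewer samples than populations")
    if (T == 1L) {
      return(structure(list(task = rep(1L, n), T = 1L, n_t = n,
                            inertia = 0), class = "task_assignment"))
    }
    km <- run_km(T)
  }
  task <- as.integer(km$cluster)
  structure(list(task = task, T = length(unique(task)),
                 n_t = as.integer(table(task)),
                 inertia = km$tot.withinss),
            class = "task_assignment")
}

#' Turn known population labels into a task assignment
#' @param labels vector of population labels, one per sample.
#' @return A `task_assignment` whose task indices follow the order of first
#'   appearance of the labels.
#' @export
tasks_from_labels <- function(labels) {
  lev <- unique(labels)
  task <- match(labels, lev)
  structure(list(task = task, T = length(lev),
                 n_t = as.integer(table(factor(task, seq_along(lev)))),
                 inertia = NA_real_, labels = lev),
            class = "task_assignment")
}

#' @exportS3Method base::print
print.task_assignment <- function(x, ...) {
  cat("task_assignment:", x$T, "populations; sizes:",
      paste(x$n_t, collapse = ", "), "\n")
  invisible(x)
}

#' PC-adjusted phenotype
#'
#' Removes population-structure signal from a phenotype before single-task
#' ("adjusted") baselines. Quantitative phenotypes are replaced by the
#' residual of a linear regression on the PC scores; binary phenotypes by
#' the residual y - fitted probability of a logistic regression on the
#' scores. Both are returned as quantitative phenotypes. `literal = TRUE`
#' instead subtracts the residuals from the observed phenotype (i.e. returns
#' the fitted values), an alternative adjustment kept behind a flag.
#'
#' @param pheno a [phenotype_table].
#' @param scores a `pc_scores` object or matrix aligned to the phenotype.
#' @param literal use the subtract-residuals variant.
#' @return A quantitative [phenotype_table].
#' @export
adjust_phenotype <- function(pheno, scores, literal = FALSE) {
  X <- if (inherits(scores, "pc_scores")) scores$scores else as.matrix(scores)
  y <- pheno$values
  stopifnot(length(y) == nrow(X))
  if (pheno$kind == "quantitative") {
    fit <- stats::lm.fit(cbind(1, X), y)
    res <- fit$residuals
  } else {
    res <- tryCatch({
      fit <- stats::glm.fit(cbind(1, X), y,
                            family = stats::binomial())
      if (any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10))
        stop("separation")
      y - fit$fitted.values
    }, error = function(e) {
      warning("separation in logistic adjustment; ridge-stabilized fit used")
      co <- ridge_logistic(cbind(1, X), y, lambda = 1e-4)
      y - stats::plogis(cbind(1, X) %*% co)
    }, warning = function(w) {
      warning("separation in logistic adjustment; ridge-stabilized fit used")
      co <- ridge_logistic(cbind(1, X), y, lambda = 1e-4)
      y - stats::plogis(cbind(1, X) %*% co)
    })
  }
  adj <- if (literal) y - res else as.numeric(res)
  phenotype_table(adj, "quantitative", pheno$sample_ids)
}

# small IRLS ridge logistic regression (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-4, iters = 100) {
  b <- rep(0, ncol(X))
  pen <- c(0, rep(lambda, ncol(X) - 1))
  for (i in seq_len(iters)) {
    eta <- as.numeric(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    H <- crossprod(X, X * w) + diag(pen, ncol(X))
    gr <- crossprod(X, y - mu) - pen * b
    step <- solve(H, gr)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  b
}
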