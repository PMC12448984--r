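#' Proximal operator of the sparse group penalty
#'
#' Exact proximal operator of `t2 * ||x||_1 + t1 * ||x||_2`: elementwise
#' soft-thresholding by `t2` followed by group shrinkage of the whole block
#' by `max(0, 1 - t1 / ||.||_2)`.
#'
#' @param z numeric vector (one flattened group block).
#' @param t2 elementwise l1 threshold, >= 0.
#' @param t1 group l2 threshold, >= 0.
#' @return The prox, a vector like `z`.
#' @export
prox_sparse_group <- function(z, t2, t1) {
  stopifnot(t1 >= 0, t2 >= 0)
  x <- sign(z) * pmax(abs(z) - t2, 0)
  nz <- sqrt(sum(x^2))
  if (nz <= t1) return(rep(0, length(z)))
  x * (1 - t1 / nz)
}

# observation weights: pooled 1/n or balanced 1/(T n_t), in design row order
obs_weights <- function(design, task_weighting = c("global", "balanced")) {
  task_weighting <- match.arg(task_weighting)
  n <- nrow(design$X)
  if (task_weighting == "global") return(rep(1 / n, n))
  rep(1 / (design$T * design$n_t), design$n_t)
}

# per-task linear scores for a coefficient matrix on a block design
design_predict <- function(design, B, intercept) {
  n <- nrow(design$X)
  pred <- numeric(n)
  for (t in seq_len(design$T)) {
    rows <- (design$task_off[t] + 1L):design$task_off[t + 1L]
    pred[rows] <- design$X[rows, , drop = FALSE] %*% B[, t] + intercept[t]
  }
  pred
}

#' Primal objective of the sparse multitask group lasso
#'
#' `(1/n) sum loss + lambda1 sum_g w_g ||B^(g)||_F +
#'  lambda2 sum_g w_g ||B^(g)||_1`, where the quadratic loss carries a 1/2
#' factor and the logistic loss is the log-loss.
#'
#' @param design a [build_block_design] result.
#' @param B p x T coefficient matrix.
#' @param intercept per-task intercepts (default 0).
#' @param lambda1,lambda2 penalty levels.
#' @param groups group specification (see [smuglasso]).
#' @param weights group weight rule.
#' @param task_weighting `"global"` (loss scaled 1/n, the printed
#'   objective) or `"balanced"` (each task scaled 1/(T n_t), so small
#'   populations are not dominated).
#' @return The objective value.
#' @export
primal_objective <- function(design, B, lambda1, lambda2,
                             intercept = rep(0, design$T), groups = NULL,
                             weights = "sqrt_pg",
                             task_weighting = "global") {
  grp_off <- resolve_groups(groups, design$p)
  wg <- group_weights(grp_off, design$T, weights)
  pred <- design_predict(design, B, intercept)
  w <- obs_weights(design, task_weighting)
  lossv <- if (design$family == "gaussian") {
    sum(w * (design$y - pred)^2) / 2
  } else {
    z <- pred
    sum(w * (pmax(z, 0) + log1p(exp(-abs(z))) - design$y * z))
  }
  pen <- 0
  for (g in seq_len(length(grp_off) - 1L)) {
    Bg <- B[(grp_off[g] + 1L):grp_off[g + 1L], , drop = FALSE]
    pen <- pen + lambda1 * wg[g] * sqrt(sum(Bg^2)) +
      lambda2 * wg[g] * sum(abs(Bg))
  }
  lossv + pen
}

# intercept-only fit: residual-type vector (times-n scale) and intercepts
null_residual <- function(design) {
  y <- design$y
  ic <- numeric(design$T)
  r <- numeric(length(y))
  for (t in seq_len(design$T)) {
    rows <- (design$task_off[t] + 1L):design$task_off[t + 1L]
    m <- mean(y[rows])
    if (design$family == "gaussian") {
      ic[t] <- m
      r[rows] <- y[rows] - m
    } else {
      m <- min(max(m, 1e-12), 1 - 1e-12)
      ic[t] <- stats::qlogis(m)
      r[rows] <- y[rows] - m
    }
  }
  list(residual = r, intercept = ic)
}

#' Smallest penalty level with an all-zero solution
#'
#' Computes the entry point of the regularization path: the smallest
#' `lambda1` (with `lambda2 = alpha * lambda1`) at which B = 0 (with
#' intercepts fitted) satisfies the optimality conditions, i.e. for every
#' group g, `||soft(grad_g, alpha * lambda1 * w_g)||_2 <= lambda1 * w_g`.
#' Solved in closed form for `alpha = 0` and by per-group bisection
#' otherwise.
#'
#' @param design a `block_design`.
#' @param alpha mixing ratio lambda2 / lambda1.
#' @param groups,weights group specification.
#' @param task_weighting loss weighting (see [primal_objective]).
#' @return The scalar `lambda1_max`.
#' @export
lambda_max <- function(design, alpha = 0, groups = NULL,
                       weights = "sqrt_pg", task_weighting = "global") {
  stopifnot(alpha >= 0)
  grp_off <- resolve_groups(groups, design$p)
  wg <- group_weights(grp_off, design$T, weights)
  nr <- null_residual(design)
  w <- obs_weights(design, task_weighting)
  V <- matrix(0, design$p, design$T)
  for (t in seq_len(design$T)) {
    rows <- (design$task_off[t] + 1L):design$task_off[t + 1L]
    V[, t] <- crossprod(design$X[rows, , drop = FALSE],
                        w[rows] * nr$residual[rows])
  }
  lam <- 0
  for (g in seq_len(length(grp_off) - 1L)) {
    vg <- V[(grp_off[g] + 1L):grp_off[g + 1L], , drop = FALSE]
    nv <- sqrt(sum(vg^2))
    if (nv == 0) next
    if (alpha == 0) {
      lam <- max(lam, nv / wg[g])
    } else {
      f <- function(l) {
        s <- pmax(abs(vg) - alpha * l * wg[g], 0)
        sqrt(sum(s^2)) - l * wg[g]
      }
      hi <- nv / wg[g]   # f(hi) <= 0 always
      lo <- 0
      for (i in 1:100) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) lo <- mid else hi <- mid
      }
      lam <- max(lam, hi)
    }
  }
  lam
}

#' Duality gap of a candidate solution
#'
#' Builds a dual-feasible point by rescaling the (per-task centered)
#' residual so that every group satisfies the sparse-group dual constraint
#' `||soft(X_g' theta * n, lambda2 * w_g)||_2 <= lambda1 * w_g`, and returns
#' the primal-dual gap (nonnegative up to rounding). The gap certifies
#' suboptimality and drives the solver's stopping rule and gap-safe
#' screening.
#'
#' @inheritParams primal_objective
#' @return list with `gap`, `dual_point` (theta, length n, in task order)
#'   and `scale` (the feasibility rescaling applied).
#' @export
duality_gap <- function(design, B, lambda1, lambda2,
                        intercept = NULL, groups = NULL,
                        weights = "sqrt_pg", task_weighting = "global") {
  grp_off <- resolve_groups(groups, design$p)
  wg <- group_weights(grp_off, design$T, weights)
  if (is.null(intercept)) intercept <- numeric(design$T)
  pred <- design_predict(design, B, intercept)
  w <- obs_weights(design, task_weighting)
  y <- design$y
  if (design$family == "gaussian") {
    rbar <- y - pred
    for (t in seq_len(design$T)) {
      rows <- (design$task_off[t] + 1L):design$task_off[t + 1L]
      rbar[rows] <- rbar[rows] - mean(rbar[rows])
    }
  } else {
    rbar <- y - stats::plogis(pred)
  }
  tb <- w * rbar                        # dual direction theta = s * tb
  V <- matrix(0, design$p, design$T)
  for (t in seq_len(design$T)) {
    rows <- (design$task_off[t] + 1L):design$task_off[t + 1L]
    V[, t] <- crossprod(design$X[rows, , drop = FALSE], tb[rows])
  }
  s_cap <- if (design$family == "gaussian") {
    den <- sum(tb^2 / w)
    if (den > 0) min(max(sum(tb * y) / den, 0), 2) else 1
  } else 1
  if (s_cap <= 0) s_cap <- 1
  s <- s_cap
  if (lambda1 > 0 || lambda2 > 0) {
    for (g in seq_len(length(grp_off) - 1L)) {
      vg <- V[(grp_off[g] + 1L):grp_off[g + 1L], , drop = FALSE]
      stn <- function(sc) {
        sq <- pmax(abs(vg) * sc - lambda2 * wg[g], 0)
        sqrt(sum(sq^2))
      }
      if (stn(s) <= lambda1 * wg[g]) next
      if (lambda2 == 0) {
        nv <- sqrt(sum(vg^2))
        s <- min(s, lambda1 * wg[g] / nv)
      } else if (lambda1 == 0) {
        mx <- max(abs(vg))
        if (mx > 0) s <- min(s, lambda2 * wg[g] / mx)
      } else {
        lo <- 0; hi <- s
        for (i in 1:60) {
          mid <- (lo + hi) / 2
          if (stn(mid) <= lambda1 * wg[g]) lo <- mid else hi <- mid
        }
        s <- lo
      }
    }
  }
  dual <- if (design$family == "gaussian") {
    s * sum(tb * y) - 0.5 * s^2 * sum(tb^2 / w)
  } else {
    a <- pmin(pmax(y - s * rbar, 0), 1)
    h <- ifelse(a <= 0 | a >= 1, 0, a * log(a) + (1 - a) * log1p(-a))
    -sum(w * h)
  }
  primal <- primal_objective(design, B, lambda1, lambda2, intercept,
                             groups, weights, task_weighting)
  gap <- max(primal - dual, 0)
  list(gap = gap, dual_point = s * tb, scale = s)
}

#' Fit the sparse multitask group lasso
#'
#' Solves, over the block-diagonal multitask design,
#' \deqn{\min_B \frac1n \sum_t \sum_m L(y, x^\top \beta^{(t)})
#'   + \lambda_1 \sum_g w_g \|B^{(g)}\|_F
#'   + \lambda_2 \sum_g w_g \|B^{(g)}\|_1}
#' with `w_g = sqrt(p_g)`, by cyclic block proximal gradient descent over
#' LD-groups with per-group Lipschitz steps, unpenalized per-task intercepts
#' refit every epoch, duality-gap stopping and gap-safe screening of
#' certifiably inactive groups. The group-Frobenius term selects LD-groups
#' across all populations; the elementwise l1 term sparsifies the selection
#' per population. `lambda2 = 0` is the plain multitask group lasso
#' (see [muglasso]); a single task with singleton groups and `lambda1 = 0`
#' is the lasso.
#'
#' When `lambda1` is not supplied, a geometric path of `nlambda` values from
#' `lambda1_max` down to `lambda_min_ratio * lambda1_max` is fitted with
#' warm starts.
#'
#' @param x a [genotype_dataset], numeric genotype matrix, or a prebuilt
#'   `block_design`.
#' @param y a [phenotype_table] or numeric vector (ignored when `x` is a
#'   `block_design`).
#' @param tasks a `task_assignment`, a per-sample label vector, or `NULL`
#'   (single task).
#' @param groups an [ld_partition], an integer vector of group ids
#'   (contiguous runs), or `NULL` for singleton groups.
#' @param family `"gaussian"` or `"binomial"`; taken from the phenotype when
#'   omitted.
#' @param lambda1 scalar or decreasing vector of group-penalty levels; path
#'   generated when `NULL`.
#' @param alpha elementwise-penalty mixing: `lambda2 = alpha * lambda1`.
#' @param lambda2 explicit elementwise penalty (overrides `alpha`; scalar or
#'   vector aligned with `lambda1`).
#' @param nlambda,lambda_min_ratio path grid controls.
#' @param weights `"sqrt_pg"` (default) or `"sqrt_pgT"`.
#' @param tol relative duality-gap tolerance.
#' @param max_epochs epoch cap per lambda.
#' @param screen use gap-safe screening.
#' @param screen_every epochs between gap/screen evaluations.
#' @param stop_at_groups stop the path early once a fit selects more than
#'   this many groups (the overshooting point is kept); `NULL` fits the
#'   whole grid. Used by stability selection to avoid needlessly deep
#'   path points.
#' @param task_weighting `"global"` scales the pooled loss by 1/n (the
#'   printed objective: larger populations dominate); `"balanced"` scales
#'   each task's loss by 1/(T n_t) so every population carries equal
#'   weight regardless of size.
#' @return Object of class `smuglasso`: coefficients `B` (p x T x nlambda),
#'   `intercept` (T x nlambda), `lambda1`, `lambda2`, `gap`, `converged`,
#'   `epochs`, `family`, group structure, and the task layout needed by
#'   `predict`.
#' @seealso [cv_smuglasso], [muglasso], [active_groups]
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(200 * 30, 2, 0.4), 200, 30)
#' b <- c(rep(0.5, 5), rep(0, 25))
#' y <- x %*% b + rnorm(200)
#' groups <- rep(1:6, each = 5)
#' fit <- smuglasso(x, y, groups = groups, alpha = 0.3)
#' plot(fit)
#' @export
smuglasso <- function(x, y = NULL, tasks = NULL, groups = NULL,
                      family = NULL, lambda1 = NULL, alpha = 0.3,
                      lambda2 = NULL, nlambda = 50,
                      lambda_min_ratio = 0.01,
                      weights = c("sqrt_pg", "sqrt_pgT"), tol = 1e-6,
                      max_epochs = 5000, screen = TRUE, screen_every = 10,
                      stop_at_groups = NULL,
                      task_weighting = c("global", "balanced")) {
  weights <- match.arg(weights)
  task_weighting <- match.arg(task_weighting)
  design <- if (inherits(x, "block_design")) x
  else build_block_design(x, y, tasks)
  if (!is.null(family)) design$family <- match.arg(family,
                                                   c("gaussian", "binomial"))
  grp_off <- resolve_groups(groups, design$p)
  wg <- group_weights(grp_off, design$T, weights)
  G <- length(wg)

  if (!is.null(lambda2)) {
    if (is.null(lambda1)) stop("lambda2 given without lambda1")
    stopifnot(length(lambda2) %in% c(1L, length(lambda1)))
    if (length(lambda2) == 1L) lambda2 <- rep(lambda2, length(lambda1))
    alpha <- NA_real_
  }
  w_obs <- obs_weights(design, task_weighting)
  if (is.null(lambda1)) {
    lmax <- lambda_max(design, alpha, groups, weights, task_weighting)
    if (lmax <= 0) lmax <- 1e-3
    lambda1 <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  if (is.null(lambda2)) lambda2 <- alpha * lambda1
  nl <- length(lambda1)
  if (nl > 1 && any(diff(lambda1) > 0))
    stop("lambda1 must be decreasing along the path")

  B <- matrix(0, design$p, design$T)
  ic <- numeric(design$T)
  Ba <- array(0, c(design$p, design$T, nl))
  ica <- matrix(0, design$T, nl)
  gap <- conv <- ep <- numeric(nl)
  objective <- vector("list", nl)
  loss_code <- if (design$family == "gaussian") 0L else 1L
  lip <- smg_lipschitz_cpp(design$X, as.integer(design$task_off), grp_off,
                           w_obs)
  for (i in seq_len(nl)) {
    r <- smg_fit_cpp(design$X, design$y, as.integer(design$task_off),
                     grp_off, wg, w_obs, lambda1[i], lambda2[i], loss_code,
                     tol, as.integer(max_epochs), screen,
                     as.integer(screen_every), B, ic,
                     lip$opnorm, lip$curv)
    B <- r$B; ic <- as.numeric(r$intercept)
    Ba[, , i] <- B
    ica[, i] <- ic
    gap[i] <- r$gap; conv[i] <- r$converged; ep[i] <- r$epochs
    objective[[i]] <- as.numeric(r$objective)
    if (!is.null(stop_at_groups) && i < nl) {
      thr <- if (lambda2[i] > 0) 0 else 1e-2
      ng <- 0L
      for (g in seq_len(G)) {
        rows <- (grp_off[g] + 1L):grp_off[g + 1L]
        if (max(abs(B[rows, , drop = FALSE])) > thr) ng <- ng + 1L
      }
      if (ng > stop_at_groups) {
        keep <- seq_len(i)
        Ba <- Ba[, , keep, drop = FALSE]
        ica <- ica[, keep, drop = FALSE]
        lambda1 <- lambda1[keep]; lambda2 <- lambda2[keep]
        gap <- gap[keep]; conv <- conv[keep]; ep <- ep[keep]
        objective <- objective[keep]
        break
      }
    }
  }
  structure(list(B = Ba, intercept = ica, lambda1 = lambda1,
                 lambda2 = lambda2, alpha = alpha, gap = gap,
                 converged = as.logical(conv), epochs = ep,
                 objective = objective,
                 family = design$family, grp_off = grp_off, weights = wg,
                 weight_rule = weights, task_weighting = task_weighting,
                 T = design$T, p = design$p,
                 n_t = design$n_t, tol = tol,
                 call = match.call()),
            class = "smuglasso")
}

#' Multitask group lasso (no elementwise penalty)
#'
#' The `lambda2 = 0` special case of [smuglasso]. Population-specific
#' selection then requires the post-processing of [active_groups] with its
#' default coefficient threshold 1e-2.
#'
#' @inheritParams smuglasso
#' @param ... passed to [smuglasso].
#' @return A `smuglasso` fit with `alpha = 0`.
#' @export
muglasso <- function(x, y = NULL, tasks = NULL, groups = NULL, ...) {
  smuglasso(x, y, tasks = tasks, groups = groups, alpha = 0, ...)
}

# index of a lambda value on the path
lambda_index <- function(object, s = NULL) {
  if (is.null(s)) return(length(object$lambda1))
  if (length(s) == 1 && s >= 1 && s == round(s) &&
      s <= length(object$lambda1)) return(as.integer(s))
  which.min(abs(object$lambda1 - s))
}

#' @exportS3Method base::print
print.smuglasso <- function(x, ...) {
  G <- length(x$weights)
  cat("smuglasso fit:", x$p, "SNPs in", G, "groups,", x$T, "task(s),",
      x$family, "loss\n")
  nl <- length(x$lambda1)
  cat(sprintf("  lambda1: %.4g .. %.4g (%d values), alpha = %s\n",
              x$lambda1[1], x$lambda1[nl], nl,
              ifelse(is.na(x$alpha), "explicit lambda2", x$alpha)))
  ng <- vapply(seq_len(nl), function(i) {
    sum(rowSums(group_norms(x, i) > 0) > 0)
  }, 1)
  cat("  active groups along path:", paste(ng, collapse = " "), "\n")
  invisible(x)
}

# G x T matrix of per-(group, task) max |coefficient|
group_norms <- function(object, i) {
  B <- object$B[, , i, drop = FALSE][, , 1, drop = FALSE]
  dim(B) <- c(object$p, object$T)
  G <- length(object$weights)
  out <- matrix(0, G, object$T)
  for (g in seq_len(G)) {
    rows <- (object$grp_off[g] + 1L):object$grp_off[g + 1L]
    out[g, ] <- apply(abs(B[rows, , drop = FALSE]), 2, max)
  }
  out
}

#' Extract coefficients
#' @param object a `smuglasso` fit.
#' @param s lambda1 value or path index (default: last).
#' @param ... unused.
#' @return p x T coefficient matrix.
#' @export
coef.smuglasso <- function(object, s = NULL, ...) {
  i <- lambda_index(object, s)
  B <- object$B[, , i]
  matrix(B, object$p, object$T)
}

#' Predict from a fitted sparse multitask group lasso
#' @param object a `smuglasso` fit.
#' @param newx genotype matrix or [genotype_dataset].
#' @param tasks task of each new sample (`task_assignment`, labels, or
#'   `NULL` = task 1).
#' @param s lambda1 value or path index.
#' @param type `"link"` or `"response"` (probabilities for binomial).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.smuglasso <- function(object, newx, tasks = NULL, s = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  g <- if (inherits(newx, "genotype_dataset")) newx$genotypes
  else as.matrix(newx)
  task <- if (is.null(tasks)) rep(1L, nrow(g))
  else if (inherits(tasks, "task_assignment")) tasks$task
  else as.integer(factor(tasks))
  i <- lambda_index(object, s)
  B <- coef(object, i)
  X <- standardize_matrix_by_task(g, task)
  eta <- numeric(nrow(g))
  for (t in unique(task)) {
    rows <- which(task == t)
    eta[rows] <- X[rows, , drop = FALSE] %*% B[, t] +
      object$intercept[t, i]
  }
  if (type == "response" && object$family == "binomial")
    stats::plogis(eta)
  else eta
}

# standardize within task, in place (rows keep their original order)
standardize_matrix_by_task <- function(g, task) {
  X <- matrix(0, nrow(g), ncol(g))
  for (t in unique(task)) {
    rows <- which(task == t)
    X[rows, ] <- standardize_genotypes(g[rows, , drop = FALSE])
  }
  X
}

#' @export
residuals.smuglasso <- function(object, newx, y, tasks = NULL, s = NULL,
                                ...) {
  yv <- if (inherits(y, "phenotype_table")) y$values else as.numeric(y)
  yv - predict(object, newx, tasks, s, type = "response")
}

#' Plot the regularization path
#'
#' One line per (group, task): Frobenius norm of the group-task coefficient
#' block against `lambda1` on a log axis.
#' @param x a `smuglasso` fit.
#' @param ... passed to `matplot`.
#' @export
plot.smuglasso <- function(x, ...) {
  nl <- length(x$lambda1)
  G <- length(x$weights)
  M <- matrix(0, nl, G * x$T)
  for (i in seq_len(nl)) M[i, ] <- as.numeric(group_norms(x, i))
  graphics::matplot(x$lambda1, M, type = "l", log = "x",
                    xlab = expression(lambda[1]),
                    ylab = "max |coefficient| per (group, task)", ...)
  invisible(x)
}

#' @exportS3Method base::summary
summary.smuglasso <- function(object, s = NULL, ...) {
  i <- lambda_index(object, s)
  act <- active_groups(object, s = i)
  cat("smuglasso at lambda1 =", signif(object$lambda1[i], 4),
      " lambda2 =", signif(object$lambda2[i], 4), "\n")
  cat("  duality gap:", format(object$gap[i]),
      " converged:", object$converged[i], "\n")
  cat("  active (group, task) pairs:", sum(act), "of",
      length(act), "\n")
  cat("  active groups (any task):", sum(rowSums(act) > 0), "\n")
  invisible(list(active = act, lambda1 = object$lambda1[i],
                 lambda2 = object$lambda2[i], gap = object$gap[i]))
}

#' Per-(group, task) selection mask of a fit
#'
#' A group is active for a task when the largest absolute coefficient in
#' its block-column exceeds `threshold`. The default threshold depends on
#' the penalty: with an elementwise penalty (`lambda2 > 0`) exact zeros
#' arise from the proximal step, so the threshold is 0 (any nonzero
#' coefficient); without it (the plain multitask group lasso) the
#' conventional post-processing threshold 1e-2 is applied.
#'
#' @param object a `smuglasso` fit.
#' @param s lambda1 value or path index.
#' @param threshold coefficient magnitude threshold; see above.
#' @return G x T logical matrix.
#' @export
active_groups <- function(object, s = NULL, threshold = NULL) {
  i <- lambda_index(object, s)
  if (is.null(threshold))
    threshold <- if (object$lambda2[i] > 0) 0 else 1e-2
  group_norms(object, i) > threshold
}
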