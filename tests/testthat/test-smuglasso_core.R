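test_that("prox_sparse_group matches its definition", {
  expect_equal(prox_sparse_group(numeric(5), 1, 1), numeric(5))
  z <- rnorm(8)
  expect_equal(prox_sparse_group(z, 0, 0), z)
  # worked example: soft((3,-1), 1) = (2, 0); norm 2 -> shrink by 1/2
  expect_equal(prox_sparse_group(c(3, -1), 1, 1), c(1, 0))
  # against the Douglas-Rachford oracle on random blocks
  set.seed(1)
  for (i in 1:50) {
    d <- sample(1:12, 1)
    z <- rnorm(d, sd = 2)
    t2 <- runif(1, 0, 1.5)
    t1 <- runif(1, 0, 1.5)
    expect_equal(prox_sparse_group(z, t2, t1),
                 dr_prox_oracle(z, t2, t1), tolerance = 1e-7)
  }
})

test_that("the block design stacks per-task standardized blocks and its
           implicit product matches the dense construction", {
  ds <- rand_dataset(20, 5, seed = 2)
  y <- rnorm(20)
  task <- rep(1:2, each = 10)
  des <- build_block_design(ds, y, task)
  expect_equal(des$n_t, c(10L, 10L))
  # per-task columns have mean 0 / sd 1 (non-constant ones)
  for (t in 1:2) {
    rows <- (des$task_off[t] + 1):des$task_off[t + 1]
    expect_lt(max(abs(colMeans(des$X[rows, ]))), 1e-12)
  }
  # X~ b against an explicit dense block-diagonal matrix
  B <- matrix(rnorm(10), 5, 2)
  dense <- matrix(0, 20, 10)
  dense[1:10, 1:5] <- des$X[1:10, ]
  dense[11:20, 6:10] <- des$X[11:20, ]
  pred_dense <- dense %*% as.vector(B)
  pred_pkg <- numeric(20)
  for (t in 1:2) {
    rows <- (des$task_off[t] + 1):des$task_off[t + 1]
    pred_pkg[rows] <- des$X[rows, ] %*% B[, t]
  }
  expect_equal(pred_pkg, as.vector(pred_dense))
  # single task degenerates to the standardized matrix
  d1 <- build_block_design(ds, y)
  expect_equal(d1$X, standardize_genotypes(ds))
  expect_error(build_block_design(ds, y, c(rep(1, 19), 2)), "2 samples")
})

test_that("permuting samples within a task leaves the objective
           unchanged", {
  ds <- rand_dataset(30, 6, seed = 3)
  y <- rnorm(30)
  task <- rep(1:2, each = 15)
  des <- build_block_design(ds, y, task)
  perm <- c(sample(1:15), sample(16:30))
  des2 <- build_block_design(
    genotype_dataset(ds$genotypes[perm, ], ds$variants), y[perm],
    task[perm])
  B <- matrix(rnorm(12), 6, 2)
  for (a in c(0, 0.5)) {
    expect_equal(
      primal_objective(des, B, 0.3, a * 0.3, groups = rep(1:2, each = 3)),
      primal_objective(des2, B, 0.3, a * 0.3, groups = rep(1:2, each = 3)))
  }
})

test_that("primal_objective matches closed forms and an independent
           re-evaluation", {
  set.seed(4)
  ds <- rand_dataset(30, 6, seed = 4)
  y <- rnorm(30)
  task <- rep(1:2, c(14, 16))
  des <- build_block_design(ds, y, task)
  groups <- rep(1:2, each = 3)
  # B = 0, centered y: value = ||y~||^2 / (2n) after per-task centering
  yc <- y
  ic <- c(mean(y[task == 1]), mean(y[task == 2]))
  expect_equal(primal_objective(des, matrix(0, 6, 2), 0.5, 0.2,
                                intercept = ic, groups = groups),
               sum((des$y - ic[rep(1:2, c(14, 16))])^2) / 60)
  # lambda = 0: plain loss
  B <- matrix(rnorm(12), 6, 2)
  expect_equal(primal_objective(des, B, 0, 0, groups = groups),
               primal_objective(des, B, 0, 0))
  # random instance vs formula written out independently
  l1 <- 0.4; l2 <- 0.15
  pred <- numeric(30)
  Xs <- des$X
  for (t in 1:2) {
    rows <- (des$task_off[t] + 1):des$task_off[t + 1]
    pred[rows] <- Xs[rows, ] %*% B[, t] + ic[t]
  }
  pen <- 0
  for (g in 1:2) {
    idx <- which(groups == g)
    pen <- pen + sqrt(3) * (l1 * sqrt(sum(B[idx, ]^2)) +
                              l2 * sum(abs(B[idx, ])))
  }
  expect_equal(primal_objective(des, B, l1, l2, intercept = ic,
                                groups = groups),
               sum((des$y - pred)^2) / 60 + pen)
})

test_that("lambda_max is the exact entry point of the path", {
  set.seed(5)
  ds <- rand_dataset(80, 24, seed = 5)
  y <- rnorm(80)
  task <- rep(1:2, each = 40)
  groups <- rep(1:4, each = 6)
  des <- build_block_design(ds, y, task)
  for (a in c(0, 0.3, 1)) {
    lmax <- lambda_max(des, alpha = a, groups = groups)
    hi <- smuglasso(des, groups = groups, lambda1 = lmax, alpha = a)
    lo <- smuglasso(des, groups = groups, lambda1 = 0.99 * lmax,
                    alpha = a)
    expect_true(all(coef(hi) == 0))
    expect_true(any(coef(lo) != 0))
  }
  # centered-null response: lambda_max = 0
  des0 <- build_block_design(ds, rep(2, 80), task)
  expect_equal(lambda_max(des0, alpha = 0.3, groups = groups), 0)
})

test_that("duality gap is zero at the path entry, positive away from the
           optimum, and below tolerance at the solution", {
  set.seed(6)
  ds <- rand_dataset(60, 12, seed = 6)
  y <- rnorm(60)
  groups <- rep(1:3, each = 4)
  des <- build_block_design(ds, y)
  lmax <- lambda_max(des, alpha = 0.3, groups = groups)
  ic <- mean(y)
  g0 <- duality_gap(des, matrix(0, 12, 1), lmax, 0.3 * lmax,
                    intercept = ic, groups = groups)
  expect_lt(g0$gap, 1e-10)
  # random point: weak duality
  Brand <- matrix(rnorm(12), 12, 1)
  expect_gt(duality_gap(des, Brand, lmax / 2, 0.15 * lmax,
                        intercept = ic, groups = groups)$gap, 0)
  # solver's solution: gap under tolerance; R gap agrees with C++ gap
  fit <- smuglasso(des, groups = groups, lambda1 = lmax / 3, alpha = 0.3,
                   tol = 1e-8)
  gr <- duality_gap(des, coef(fit), lmax / 3, 0.3 * lmax / 3,
                    intercept = fit$intercept[, 1], groups = groups)
  expect_lt(gr$gap, 1e-8 * max(1, primal_objective(
    des, coef(fit), lmax / 3, 0.3 * lmax / 3, fit$intercept[, 1],
    groups)))
})

test_that("the objective is monotone and the gap certifies convergence
           across random instances and both losses", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(50:120, 1)
    p <- sample(20:60, 1)
    Tn <- sample(1:3, 1)
    fam <- sample(c("gaussian", "binomial"), 1)
    ds <- rand_dataset(n, p, seed = 100 + i)
    task <- sort(rep_len(seq_len(Tn), n))
    eta <- rowSums(standardize_genotypes(ds)[, 1:3, drop = FALSE]) * 0.5
    y <- if (fam == "binomial") rbinom(n, 1, plogis(eta)) else
      eta + rnorm(n)
    groups <- sort(rep_len(seq_len(max(2, p %/% 7)), p))
    fit <- smuglasso(ds$genotypes, y, tasks = task, groups = groups,
                     family = fam, nlambda = 5, lambda_min_ratio = 0.1)
    expect_true(all(fit$converged))
    des <- build_block_design(ds$genotypes, y, task)
    des$family <- fam
    for (j in seq_along(fit$lambda1)) {
      primal <- primal_objective(des, coef(fit, s = j), fit$lambda1[j],
                                 fit$lambda2[j], fit$intercept[, j],
                                 groups)
      expect_lte(fit$gap[j], 1e-6 * max(1, primal) + 1e-14)
      obj <- fit$objective[[j]]
      if (length(obj) > 1)
        expect_true(all(diff(obj) <= 1e-12 * pmax(1, obj[-length(obj)])))
    }
  }
})

test_that("gap-safe screening never changes the solution", {
  set.seed(8)
  for (i in 1:4) {
    n <- 60; p <- 40
    ds <- rand_dataset(n, p, seed = 200 + i)
    task <- rep(1:2, each = 30)
    y <- rnorm(n) + standardize_genotypes(ds)[, 1] * 0.8
    groups <- rep(1:8, each = 5)
    fam <- if (i %% 2 == 0) "binomial" else "gaussian"
    if (fam == "binomial") y <- as.numeric(y > 0)
    a <- smuglasso(ds$genotypes, y, tasks = task, groups = groups,
                   family = fam, nlambda = 8, alpha = 0.3, tol = 1e-8,
                   screen = TRUE)
    b <- smuglasso(ds$genotypes, y, tasks = task, groups = groups,
                   family = fam, nlambda = 8, alpha = 0.3, tol = 1e-8,
                   screen = FALSE)
    expect_lt(max(abs(a$B - b$B)), 1e-8)
  }
})

test_that("reductions: orthonormal-design lasso equals the closed-form
           soft threshold", {
  # orthonormal X (scaled so X'X/n = I), single task, singleton groups
  set.seed(9)
  n <- 8; p <- 4
  # orthonormal columns, also orthogonal to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1)] *
    sqrt(n)
  y <- rnorm(n)
  yc <- y - mean(y)
  lam <- 0.2
  des <- list(X = Q, y = y, task_off = c(0L, n), order = 1:n,
              family = "gaussian", n_t = n, p = p, T = 1L)
  class(des) <- "block_design"
  fit <- smuglasso(des, lambda1 = lam, alpha = 0, tol = 1e-12,
                   max_epochs = 50000)
  closed <- sign(crossprod(Q, yc) / n) *
    pmax(abs(crossprod(Q, yc) / n) - lam, 0)
  expect_equal(coef(fit)[, 1], as.vector(closed), tolerance = 1e-10)
})

test_that("reductions: T = 1 singleton-group fits match glmnet for both
           penalty routes and both losses", {
  set.seed(10)
  n <- 120; p <- 30
  ds <- rand_dataset(n, p, seed = 10)
  X <- standardize_genotypes(ds)
  b0 <- c(rep(0.6, 3), rep(0, p - 3))
  y <- as.numeric(X %*% b0 + rnorm(n))
  lam <- 0.08
  # lasso via the group term and via the elementwise term are identical
  f1 <- smuglasso(ds$genotypes, y, lambda1 = lam, alpha = 0,
                  tol = 1e-11, max_epochs = 50000)
  f2 <- smuglasso(ds$genotypes, y, lambda1 = 0, lambda2 = lam,
                  tol = 1e-11, max_epochs = 50000)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  gl <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(coef(f1)[, 1], as.numeric(gl$beta), tolerance = 1e-6)
  # logistic
  yb <- rbinom(n, 1, plogis(X %*% b0))
  fb <- smuglasso(ds$genotypes, yb, lambda1 = 0.03, alpha = 0,
                  family = "binomial", tol = 1e-11, max_epochs = 50000)
  glb <- glmnet::glmnet(X, yb, family = "binomial", lambda = 0.03,
                        standardize = FALSE, thresh = 1e-14)
  expect_equal(coef(fb)[, 1], as.numeric(glb$beta), tolerance = 1e-5)
})

test_that("reductions: lambda2 = 0 matches an independent multitask
           group-lasso reference solver", {
  set.seed(11)
  n <- 100; p <- 40; G <- 8
  ds <- rand_dataset(n, p, seed = 11)
  task <- rep(1:2, each = 50)
  groups <- rep(seq_len(G), each = p / G)
  des <- build_block_design(ds, rnorm(n), task)
  # center y per task so intercepts vanish on both sides
  y <- rnorm(n) + standardize_genotypes(ds)[, 1] * 0.7
  y[task == 1] <- y[task == 1] - mean(y[task == 1])
  y[task == 2] <- y[task == 2] - mean(y[task == 2])
  des <- build_block_design(ds, y, task)
  lam <- 0.05
  fit <- smuglasso(des, groups = groups, lambda1 = lam, alpha = 0,
                   tol = 1e-12, max_epochs = 100000)
  Xl <- list(des$X[1:50, ], des$X[51:100, ])
  yl <- list(des$y[1:50], des$y[51:100])
  ref <- fista_reference(Xl, yl, rep(p / G, G), sqrt(rep(p / G, G)),
                         lambda1 = lam)
  expect_lt(max(abs(coef(fit) - ref)), 1e-6)
  # and with the elementwise term active (sparse multitask group lasso)
  fit2 <- smuglasso(des, groups = groups, lambda1 = lam, alpha = 0.5,
                    tol = 1e-12, max_epochs = 100000)
  ref2 <- fista_reference(Xl, yl, rep(p / G, G), sqrt(rep(p / G, G)),
                          lambda1 = lam, lambda2 = 0.5 * lam)
  expect_lt(max(abs(coef(fit2) - ref2)), 1e-6)
})

test_that("warm-started paths equal cold-started fits", {
  set.seed(12)
  ds <- rand_dataset(70, 24, seed = 12)
  y <- rnorm(70)
  groups <- rep(1:4, each = 6)
  path <- smuglasso(ds$genotypes, y, groups = groups, nlambda = 6,
                    alpha = 0.3, tol = 1e-10)
  for (i in c(2, 4, 6)) {
    cold <- smuglasso(ds$genotypes, y, groups = groups,
                      lambda1 = path$lambda1[i], alpha = 0.3, tol = 1e-10)
    expect_lt(max(abs(path$B[, , i] - coef(cold))), 1e-6)
  }
  # active groups mostly non-decreasing along the path
  act <- vapply(seq_along(path$lambda1), function(i)
    sum(rowSums(active_groups(path, i)) > 0), 1)
  expect_gte(mean(diff(act) >= 0), 0.9)
})

test_that("huge penalties give the intercept-only model", {
  ds <- rand_dataset(40, 10, seed = 13)
  y <- rnorm(40, mean = 3)
  task <- rep(1:2, each = 20)
  fit <- smuglasso(ds$genotypes, y, tasks = task, lambda1 = 100,
                   alpha = 0.3)
  expect_true(all(coef(fit) == 0))
  expect_equal(fit$intercept[, 1],
               c(mean(y[1:20]), mean(y[21:40])))
})

test_that("balanced task weighting reduces to the global loss for equal
           tasks and changes it otherwise", {
  ds <- rand_dataset(60, 10, seed = 14)
  y <- rnorm(60)
  equal_task <- rep(1:2, each = 30)
  f_g <- smuglasso(ds$genotypes, y, tasks = equal_task, lambda1 = 0.05,
                   alpha = 0.3, task_weighting = "global", tol = 1e-10)
  f_b <- smuglasso(ds$genotypes, y, tasks = equal_task, lambda1 = 0.05,
                   alpha = 0.3, task_weighting = "balanced", tol = 1e-10)
  expect_equal(f_g$B, f_b$B, tolerance = 1e-7)
  skew_task <- rep(1:2, c(45, 15))
  f_g2 <- smuglasso(ds$genotypes, y, tasks = skew_task, lambda1 = 0.05,
                    alpha = 0.3, task_weighting = "global")
  f_b2 <- smuglasso(ds$genotypes, y, tasks = skew_task, lambda1 = 0.05,
                    alpha = 0.3, task_weighting = "balanced")
  expect_false(isTRUE(all.equal(f_g2$B, f_b2$B)))
  expect_true(all(f_b2$converged))
})

test_that("active_groups applies the right threshold per penalty", {
  fit <- list(B = array(c(0.005, 0.009, 0.005, 0.02), c(2, 1, 2)),
              lambda1 = c(1, 1), lambda2 = c(0, 0),
              grp_off = c(0L, 2L), weights = sqrt(2), p = 2L, T = 1L)
  class(fit) <- "smuglasso"
  # group-lasso post-processing at 1e-2: (0.005, 0.009) inactive
  expect_false(active_groups(fit, s = 1)[1, 1])
  # (0.005, 0.02) active under the max rule
  expect_true(active_groups(fit, s = 2)[1, 1])
  # with the elementwise penalty any exact nonzero counts
  fit$lambda2 <- c(0.1, 0.1)
  expect_true(active_groups(fit, s = 1)[1, 1])
  fit$B[, , 1] <- 0
  expect_false(active_groups(fit, s = 1)[1, 1])
})

test_that("cross-validation selects sensible penalties and is
           reproducible", {
  set.seed(15)
  n <- 150; p <- 30
  ds <- rand_dataset(n, p, seed = 15)
  X <- standardize_genotypes(ds)
  groups <- rep(1:6, each = 5)
  # strong signal, n >> p: support of the selected model covers the true
  # group
  y <- as.numeric(X[, 1:5] %*% rep(1, 5) + rnorm(n))
  cv <- cv_smuglasso(ds$genotypes, y, groups = groups,
                     alpha = c(0, 0.3), nlambda = 8, seed = 3)
  act <- which(abs(coef(cv)[, 1]) > 0)
  expect_true(all(1:5 %in% act))
  cv2 <- cv_smuglasso(ds$genotypes, y, groups = groups,
                      alpha = c(0, 0.3), nlambda = 8, seed = 3)
  expect_equal(cv$cv_table, cv2$cv_table)   # same folds, same table
  # pure-noise phenotype: 1se rule lands at or near the sparse end
  y0 <- rnorm(n)
  cv0 <- cv_smuglasso(ds$genotypes, y0, groups = groups, alpha = c(0),
                      nlambda = 8, seed = 4)
  expect_lte(sum(abs(coef(cv0)) > 0), p / 3)
})
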