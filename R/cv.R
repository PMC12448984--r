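#' Cross-validated sparse multitask group lasso
#'
#' 3-fold cross-validation over a `(lambda1, alpha)` grid, with folds
#' stratified jointly by task and phenotype (binary) or by task and
#' phenotype quartile (quantitative). The selection criterion is the mean
#' f1-score over folds for binary phenotypes (prediction threshold 0.5) and
#' RMSE for quantitative ones; ties prefer the sparser model (larger
#' `lambda1`, then larger `lambda2`). With `rule = "1se"` (the default,
#' as in cv.glmnet) the sparsest candidate whose mean score is within one
#' standard error of the best is selected - the usual choice when the fit
#' feeds stability selection; `rule = "best"` takes the optimum itself.
#'
#' @inheritParams smuglasso
#' @param alpha vector of candidate mixing ratios.
#' @param nlambda path length per alpha.
#' @param nfolds number of folds.
#' @param rule `"1se"` or `"best"`.
#' @param seed seed for the fold assignment.
#' @param ... passed to [smuglasso].
#' @return Object of class `cv_smuglasso`: `lambda1`, `lambda2`, `alpha`
#'   (selected), `cv_table` (per-candidate mean metric), `metric`, and
#'   `fit`, the full-data path fit at the selected alpha (the selected
#'   lambda1 is `fit$lambda1[sel_index]`).
#' @export
cv_smuglasso <- function(x, y, tasks = NULL, groups = NULL, family = NULL,
                         alpha = c(0, 0.1, 0.3, 0.5, 1), nlambda = 20,
                         lambda_min_ratio = 0.01, nfolds = 3,
                         rule = c("1se", "best"), seed = 1, ...) {
  rule <- match.arg(rule)
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else as.matrix(x)
  yv <- if (inherits(y, "phenotype_table")) y$values else as.numeric(y)
  kind <- if (inherits(y, "phenotype_table")) y$kind
  else if (all(yv %in% c(0, 1))) "binary" else "quantitative"
  if (!is.null(family))
    kind <- if (family == "binomial") "binary" else "quantitative"
  task <- if (is.null(tasks)) rep(1L, nrow(g))
  else if (inherits(tasks, "task_assignment")) tasks$task
  else as.integer(factor(tasks))
  n <- nrow(g)
  metric <- if (kind == "binary") "f1" else "rmse"

  # stratified folds: task x phenotype class (quartile bins if quantitative)
  ybin <- if (kind == "binary") yv
  else as.integer(cut(yv, stats::quantile(yv, 0:4 / 4),
                      include.lowest = TRUE))
  strata <- interaction(task, ybin, drop = TRUE)
  if (any(table(strata) < nfolds))
    stop("stratum too small for ", nfolds, "-fold CV: ",
         names(which(table(strata) < nfolds))[1])
  set.seed(seed)
  fold <- integer(n)
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }

  fam <- if (kind == "binary") "binomial" else "gaussian"
  results <- list()
  fits_full <- list()
  for (a in alpha) {
    full <- smuglasso(g, yv, tasks = task, groups = groups, family = fam,
                      alpha = a, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio, ...)
    fits_full[[as.character(a)]] <- full
    lam <- full$lambda1
    scores <- matrix(NA_real_, nfolds, length(lam))
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit <- smuglasso(g[tr, , drop = FALSE], yv[tr], tasks = task[tr],
                       groups = groups, family = fam, lambda1 = lam,
                       alpha = a, ...)
      Xte <- standardize_matrix_by_task(g[!tr, , drop = FALSE], task[!tr])
      yte <- yv[!tr]; tte <- task[!tr]
      for (i in seq_along(lam)) {
        B <- coef(fit, i)
        eta <- numeric(nrow(Xte))
        for (t in unique(tte)) {
          rows <- which(tte == t)
          eta[rows] <- Xte[rows, , drop = FALSE] %*% B[, t] +
            fit$intercept[t, i]
        }
        pr <- if (fam == "binomial") stats::plogis(eta) else eta
        scores[f, i] <- if (metric == "f1") {
          f1_score(yte, pr >= 0.5)
        } else {
          sqrt(mean((yte - pr)^2))
        }
      }
    }
    results[[as.character(a)]] <-
      data.frame(alpha = a, lambda1 = lam, lambda2 = a * lam,
                 score = colMeans(scores),
                 se = apply(scores, 2, stats::sd) / sqrt(nfolds))
  }
  tab <- do.call(rbind, results)
  rownames(tab) <- NULL
  higher_better <- metric == "f1"
  best_i <- if (higher_better) which.max(tab$score) else which.min(tab$score)
  tol <- if (rule == "1se") tab$se[best_i] else 1e-12
  ok <- if (higher_better) tab$score >= tab$score[best_i] - tol
  else tab$score <= tab$score[best_i] + tol
  cand <- tab[ok, , drop = FALSE]
  cand <- cand[order(-cand$lambda1, -cand$lambda2), , drop = FALSE]
  sel <- cand[1, ]
  fit <- fits_full[[as.character(sel$alpha)]]
  structure(list(lambda1 = sel$lambda1, lambda2 = sel$lambda2,
                 alpha = sel$alpha, cv_table = tab, metric = metric,
                 sel_index = which(fit$lambda1 == sel$lambda1)[1],
                 fit = fit),
            class = "cv_smuglasso")
}

f1_score <- function(y, pred) {
  tp <- sum(y == 1 & pred)
  fp <- sum(y == 0 & pred)
  fn <- sum(y == 1 & !pred)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @exportS3Method base::print
print.cv_smuglasso <- function(x, ...) {
  cat("cv_smuglasso (", x$metric, "):",
      "selected lambda1 =", signif(x$lambda1, 4),
      " lambda2 =", signif(x$lambda2, 4),
      " (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' @export
coef.cv_smuglasso <- function(object, ...) {
  coef(object$fit, s = object$sel_index)
}
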