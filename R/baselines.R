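#' Per-SNP trend test
#'
#' Score (Cochran-Armitage-type) chi-square statistic with 1 df for the
#' association of each SNP dosage with the phenotype, computed as
#' n * cor(g, y)^2. Missing genotypes are mean-imputed.
#'
#' @param x genotype matrix or [genotype_dataset].
#' @param y phenotype vector (binary 0/1 or quantitative).
#' @return numeric vector of chi-square statistics (0 for constant SNPs).
#' @export
trend_test <- function(x, y) {
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else as.matrix(x)
  X <- standardize_genotypes(g)
  yv <- as.numeric(y)
  n <- length(yv)
  ys <- (yv - mean(yv))
  sy <- sqrt(sum(ys^2))
  if (sy == 0) return(rep(0, ncol(X)))
  r <- as.numeric(crossprod(X, ys)) / ((n - 1) * sy / sqrt(n - 1))
  # r is cor(g, y) since X columns have sd 1: x'ys / ((n-1) sd_y)
  chi <- n * r^2
  chi[!is.finite(chi)] <- 0
  chi
}

#' Genomic-control inflation factor
#'
#' Median of the chi-square statistics divided by the median of the
#' chi-square distribution with 1 df (0.4549...). Values near 1 indicate no
#' stratification inflation.
#'
#' @param chisq vector of 1-df chi-square statistics.
#' @return The inflation factor lambda_GC.
#' @export
genomic_control <- function(chisq) {
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Covariate-adjusted per-SNP score test
#'
#' Score test for each SNP added to a null model of the phenotype on
#' covariates (top principal components): linear regression for
#' quantitative phenotypes, logistic for binary ones. Vectorized over SNPs.
#'
#' @param x genotype matrix or [genotype_dataset].
#' @param y phenotype vector.
#' @param covariates n x k matrix (e.g. PC scores); may be `NULL`.
#' @param family `"gaussian"` or `"binomial"`.
#' @return list with `chisq`, `p_value` per SNP.
#' @export
score_test_adjusted <- function(x, y, covariates = NULL,
                                family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else as.matrix(x)
  X <- standardize_genotypes(g)
  yv <- as.numeric(y)
  n <- length(yv)
  C <- cbind(rep(1, n), covariates)
  if (family == "gaussian") {
    fit <- stats::lm.fit(C, yv)
    res <- fit$residuals
    sigma2 <- sum(res^2) / (n - ncol(C))
    U <- as.numeric(crossprod(X, res))
    A <- crossprod(C, X)                       # k x p
    M <- solve(crossprod(C))
    V <- (colSums(X^2) - colSums(A * (M %*% A))) * sigma2
  } else {
    fit <- stats::glm.fit(C, yv, family = stats::binomial())
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    U <- as.numeric(crossprod(X, yv - mu))
    Cw <- C * w
    A <- crossprod(Cw, X)                      # C' W X
    M <- solve(crossprod(C, Cw))               # (C' W C)^-1
    V <- colSums(X^2 * w) - colSums(A * (M %*% A))
  }
  chisq <- ifelse(V > 1e-12, U^2 / V, 0)
  list(chisq = chisq, p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Run a comparison baseline
#'
#' The single-SNP and single-task comparison partners of the multitask
#' model. "Stratified" methods fit each population independently on its own
#' phenotype; "adjusted" methods pool all samples and use the PC-adjusted
#' (quantitative) phenotype. Lasso variants reuse the [smuglasso] solver
#' with one task and singleton groups; group-lasso variants keep the
#' LD-group partition.
#'
#' @param method one of `"adjusted_gwas"`, `"stratified_lasso"`,
#'   `"adjusted_lasso"`, `"stratified_group_lasso"`,
#'   `"adjusted_group_lasso"`.
#' @param x genotype matrix or [genotype_dataset].
#' @param y [phenotype_table] or numeric vector.
#' @param tasks task labels (required for stratified methods and for
#'   shaping per-task output).
#' @param scores `pc_scores` or matrix, required for adjusted methods.
#' @param part [ld_partition], required for group-lasso methods.
#' @param lambda1 optional fixed penalty level(s) (per task for stratified
#'   methods); chosen by [cv_smuglasso] when `NULL`.
#' @param alpha_gwas significance threshold for `adjusted_gwas`
#'   (genome-wide 5e-8 by default).
#' @param nlambda,seed CV controls.
#' @return list with `method`, `snp_selected` (p x T logical; identical
#'   columns for pooled methods), `group_selected` (G x T, when a partition
#'   is given), and method details (`p_value` or `lambda1`).
#' @export
run_baseline <- function(method, x, y, tasks = NULL, scores = NULL,
                         part = NULL, lambda1 = NULL, alpha_gwas = 5e-8,
                         nlambda = 20, seed = 1) {
  method <- match.arg(method, c("adjusted_gwas", "stratified_lasso",
                                "adjusted_lasso", "stratified_group_lasso",
                                "adjusted_group_lasso"))
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else as.matrix(x)
  ph <- if (inherits(y, "phenotype_table")) y
  else phenotype_table(as.numeric(y))
  task <- if (is.null(tasks)) rep(1L, nrow(g))
  else if (inherits(tasks, "task_assignment")) tasks$task
  else as.integer(factor(tasks))
  Tn <- max(task)
  p <- ncol(g)
  grouped <- method %in% c("stratified_group_lasso", "adjusted_group_lasso")
  if (grouped && is.null(part)) stop(method, " needs an LD-group partition")
  groups <- if (grouped) part else NULL

  if (method == "adjusted_gwas") {
    if (is.null(scores)) stop("adjusted_gwas needs PC scores")
    sc <- if (inherits(scores, "pc_scores")) scores$scores else scores
    fam <- if (ph$kind == "binary") "binomial" else "gaussian"
    st <- score_test_adjusted(g, ph$values, sc, fam)
    sel <- st$p_value < alpha_gwas
    snp_sel <- matrix(sel, p, Tn)
    out <- list(method = method, snp_selected = snp_sel,
                p_value = st$p_value, chisq = st$chisq)
  } else if (method %in% c("stratified_lasso", "stratified_group_lasso")) {
    fam <- if (ph$kind == "binary") "binomial" else "gaussian"
    snp_sel <- matrix(FALSE, p, Tn)
    lam_used <- numeric(Tn)
    for (t in seq_len(Tn)) {
      rows <- which(task == t)
      if (is.null(lambda1)) {
        cvf <- cv_smuglasso(g[rows, , drop = FALSE], ph$values[rows],
                            groups = groups, family = fam, alpha = 0,
                            nlambda = nlambda, seed = seed)
        co <- coef(cvf)
        lam_used[t] <- cvf$lambda1
      } else {
        lt <- if (length(lambda1) >= Tn) lambda1[t] else lambda1
        fit <- smuglasso(g[rows, , drop = FALSE], ph$values[rows],
                         groups = groups, family = fam,
                         lambda1 = lt, alpha = 0)
        co <- coef(fit)
        lam_used[t] <- lt
      }
      snp_sel[, t] <- abs(co[, 1]) > if (grouped) 1e-2 else 0
    }
    out <- list(method = method, snp_selected = snp_sel,
                lambda1 = lam_used)
  } else { # adjusted lasso / group lasso
    if (is.null(scores)) stop(method, " needs PC scores for adjustment")
    adj <- adjust_phenotype(ph, scores)
    if (is.null(lambda1)) {
      cvf <- cv_smuglasso(g, adj$values, groups = groups,
                          family = "gaussian", alpha = 0,
                          nlambda = nlambda, seed = seed)
      co <- coef(cvf)
      lam_used <- cvf$lambda1
    } else {
      fit <- smuglasso(g, adj$values, groups = groups,
                       family = "gaussian", lambda1 = lambda1, alpha = 0)
      co <- coef(fit)
      lam_used <- lambda1
    }
    sel <- abs(co[, 1]) > if (grouped) 1e-2 else 0
    out <- list(method = method, snp_selected = matrix(sel, p, Tn),
                lambda1 = lam_used)
  }
  if (!is.null(part))
    out$group_selected <- expand_snp_to_group(out$snp_selected, part)
  out
}
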