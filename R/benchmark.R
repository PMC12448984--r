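#' Run the scaled two-population benchmark for one seed
#'
#' Generates the scaled benchmark study (see [two_population_scenario]),
#' runs the full pipeline (population assignment, shared LD-groups,
#' stability-selected sparse multitask group lasso), the stratified group
#' lasso comparison partner, and the stability-index comparison of
#' group-level versus single-SNP selection, and evaluates everything
#' against the simulation ground truth.
#'
#' @param seed integer seed driving the whole run.
#' @param B subsamples for stability selection.
#' @param q per-subsample cap on selected groups
#'   (see [smuglasso_path_selector]).
#' @param q_snp per-subsample cap on selected SNPs for the single-SNP
#'   (lasso) methods.
#' @param alpha elementwise mixing for the sparse multitask group lasso.
#' @param index_runs subsamples for the stability index.
#' @param stability_methods which methods to include in the
#'   stability-index comparison (default: the four baselines of the
#'   group-level vs single-SNP contrast).
#' @param tol duality-gap tolerance for the per-subsample selection fits.
#' @return list of metrics: `group_precision`, `group_recall` (stability-
#'   selected multitask model, group level), `specific_snp_recall_smuglasso`
#'   and `specific_snp_recall_stratified` (recall on population-specific
#'   causal SNPs after group expansion), `stability` (named stability
#'   indices), `n_selected_groups`, `n_selected_snps`, `n_truth_groups`,
#'   `counts` (shared/specific classification), and the run objects.
#' @export
benchmark_scaled_run <- function(seed, B = 50, q = 20, q_snp = 100,
                                 alpha = 0.3, index_runs = 10,
                                 stability_methods = c(
                                   "stratified_group_lasso",
                                   "adjusted_group_lasso",
                                   "stratified_lasso", "adjusted_lasso"),
                                 tol = 1e-5) {
  cfg <- two_population_scenario(scaled = TRUE)
  st <- simulate_study(cfg, seed = seed)
  X <- standardize_genotypes(st$dataset)
  sc <- pca_scores(X, k = 2)
  tk <- assign_populations(sc, T = 2, seed = seed)
  lg <- ld_groups(st$dataset, tk)
  part <- lg$shared
  G <- attr(part, "G")
  gid <- group_ids(part)
  truth_all <- sort(unique(unlist(st$causal$causal_by_pop)))
  lab_of_task <- vapply(seq_len(tk$T), function(t)
    names(which.max(table(st$population[tk$task == t]))), "")

  # --- stability-selected sparse multitask group lasso
  sel_fun <- smuglasso_path_selector(part, alpha = alpha, q = q,
                                     nlambda = 15,
                                     lambda_min_ratio = 0.05, tol = tol)
  prof <- stability_selection(sel_fun, st$dataset, st$pheno, tk, B = B,
                              seed = seed)
  sel_any <- rowSums(prof$selected) > 0
  pr <- precision_recall(sel_any, truth_all, part, "group")
  labels <- classify_shared_specific(prof$selected, lab_of_task)

  # --- stratified group lasso, stability-selected per population
  strat_sel <- matrix(FALSE, G, tk$T)
  strat_fun <- smuglasso_path_selector(part, alpha = 0, q = q,
                                       nlambda = 15,
                                       lambda_min_ratio = 0.05, tol = tol)
  for (t in seq_len(tk$T)) {
    rows <- tk$task == t
    pf <- stability_selection(strat_fun, st$dataset$genotypes[rows, ,
                                                              drop = FALSE],
                              st$pheno$values[rows], NULL, B = B,
                              pi = prof$pi, seed = seed)
    strat_sel[, t] <- pf$selected[, 1]
  }

  # recall on population-specific causal SNPs (selected groups expanded
  # to their member SNPs, per task)
  spec_recall <- function(selmat) {
    tp <- 0L; tot <- 0L
    for (t in seq_len(tk$T)) {
      spec <- st$causal$specific[[lab_of_task[t]]]
      snps <- which(gid %in% which(selmat[, t]))
      tp <- tp + length(intersect(spec, snps))
      tot <- tot + length(spec)
    }
    if (tot == 0) NA_real_ else tp / tot
  }

  # --- stability indices over `index_runs` 80% subsamples, indicators at
  # LD-group level (single-SNP selections expanded)
  adj <- adjust_phenotype(st$pheno, sc)
  snp_fun <- smuglasso_path_selector(NULL, alpha = 0, q = q_snp,
                                     nlambda = 8,
                                     lambda_min_ratio = 0.1, tol = tol)
  per_pop <- function(fun, expand) {
    function(x, y, tasks) {
      out <- matrix(FALSE, G, max(tasks))
      for (t in seq_len(max(tasks))) {
        rows <- tasks == t
        m <- fun(x[rows, , drop = FALSE], y[rows], rep(1L, sum(rows)))
        out[, t] <- if (expand) expand_snp_to_group(m[, 1], part)
        else m[, 1]
      }
      out
    }
  }
  method_runs <- list(
    smuglasso = list(fun = sel_fun, x = st$dataset$genotypes,
                     y = st$pheno$values, tasks = tk$task,
                     expand = FALSE),
    muglasso = list(fun = strat_fun, x = st$dataset$genotypes,
                    y = st$pheno$values, tasks = tk$task, expand = FALSE),
    stratified_group_lasso = list(fun = per_pop(strat_fun, FALSE),
                                  x = st$dataset$genotypes,
                                  y = st$pheno$values, tasks = tk$task,
                                  expand = FALSE),
    adjusted_group_lasso = list(fun = strat_fun,
                                x = st$dataset$genotypes,
                                y = adj$values, tasks = NULL,
                                expand = FALSE),
    stratified_lasso = list(fun = per_pop(snp_fun, TRUE),
                            x = st$dataset$genotypes,
                            y = st$pheno$values, tasks = tk$task,
                            expand = FALSE),
    adjusted_lasso = list(fun = snp_fun, x = st$dataset$genotypes,
                          y = adj$values, tasks = NULL, expand = TRUE))
  stab <- vapply(stability_methods, function(m) {
    mr <- method_runs[[m]]
    pf <- stability_selection(mr$fun, mr$x, mr$y, mr$tasks,
                              B = index_runs, fraction = 0.8,
                              seed = seed, keep_runs = TRUE)
    runs <- lapply(pf$runs, function(msk) {
      if (mr$expand) msk <- expand_snp_to_group(msk > 0, part)
      as.numeric(msk)
    })
    stability_index(runs)$index
  }, 1)

  list(group_precision = pr$precision, group_recall = pr$recall,
       n_truth_groups = pr$n_true,
       n_selected_groups = sum(sel_any),
       n_selected_snps = sum(gid %in% which(sel_any)),
       specific_snp_recall_smuglasso = spec_recall(prof$selected),
       specific_snp_recall_stratified = spec_recall(strat_sel),
       stability = stab, labels = labels,
       shared_groups = sum(labels == "shared"),
       specific_groups = sum(startsWith(labels, "specific")),
       profile = prof, partition = part, tasks = tk, study = st)
}
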