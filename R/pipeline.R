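#' Run the full multi-population selection pipeline
#'
#' Chains the four analysis stages on a genotype/phenotype pair:
#' population assignment (PCA + k-means), shared LD-group construction
#' (adjacency-constrained clustering per population, boundary merge),
#' stability selection of the sparse multitask group lasso (per-subsample
#' warm-started paths capped at `q` groups), and classification of the
#' selected LD-groups as shared or population-specific.
#'
#' @param ds a [genotype_dataset].
#' @param pheno a [phenotype_table].
#' @param T number of populations or `"auto"`.
#' @param n_pcs principal components for clustering.
#' @param tasks optional precomputed `task_assignment` (skips PCA/k-means).
#' @param bandwidth,target_size LD-group construction controls
#'   (see [ld_groups]).
#' @param alpha,q,B,fraction,pi stability-selection protocol
#'   (see [smuglasso_path_selector] and [stability_selection]).
#' @param method `"smuglasso"` or `"muglasso"` (the latter sets
#'   `alpha = 0` and applies the 1e-2 post-processing threshold).
#' @param seed seed for every random stage.
#' @param keep_runs keep per-subsample masks (for the stability index).
#' @return list with `tasks`, `scores`, `partition` (shared
#'   [ld_partition]), `per_population` partitions, `profile`
#'   (`selection_profile`), `selected` (G x T), `labels`
#'   (shared/specific classification), `counts` (selected LD-groups and
#'   SNPs per class), `method`.
#' @export
smuglasso_pipeline <- function(ds, pheno, T = 2, n_pcs = 4, tasks = NULL,
                               bandwidth = 100, target_size = 40,
                               alpha = 0.3, q = 20, B = 100,
                               fraction = 0.5, pi = 0.6,
                               method = c("smuglasso", "muglasso"),
                               seed = 1, keep_runs = FALSE) {
  method <- match.arg(method)
  if (is.null(tasks)) {
    X <- standardize_genotypes(ds)
    sc <- pca_scores(X, k = n_pcs)
    tasks <- assign_populations(sc, T = T, seed = seed)
  } else sc <- NULL
  lg <- ld_groups(ds, tasks, bandwidth = bandwidth,
                  target_size = target_size)
  a <- if (method == "muglasso") 0 else alpha
  selfun <- smuglasso_path_selector(lg$shared, alpha = a, q = q,
                                    nlambda = 15, lambda_min_ratio = 0.05)
  prof <- stability_selection(selfun, ds, pheno, tasks, B = B,
                              fraction = fraction, pi = pi, seed = seed,
                              keep_runs = keep_runs)
  sel <- prof$selected
  labels <- classify_shared_specific(sel)
  gid <- group_ids(lg$shared)
  n_snps <- function(groups) sum(gid %in% groups)
  counts <- list(
    shared_groups = sum(labels == "shared"),
    shared_snps = n_snps(which(labels == "shared")),
    specific_groups = vapply(seq_len(ncol(sel)), function(t)
      sum(labels == paste0("specific:", t)), 1L),
    specific_snps = vapply(seq_len(ncol(sel)), function(t)
      n_snps(which(labels == paste0("specific:", t))), 1L))
  list(tasks = tasks, scores = sc, partition = lg$shared,
       per_population = lg$per_population, profile = prof,
       selected = sel, labels = labels, counts = counts, method = method)
}
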