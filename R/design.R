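#' Build the block-diagonal multitask design
#'
#' Reorders samples by task and standardizes every SNP within each task
#' (mean 0, unit variance; missing genotypes mean-imputed per task;
#' constant columns become zero). The full n x pT block-diagonal matrix is
#' never materialized: the per-task blocks are stored once and indexed by
#' task offsets.
#'
#' @param ds a [genotype_dataset] or numeric matrix.
#' @param pheno a [phenotype_table] or numeric vector.
#' @param tasks a `task_assignment`, an integer/factor vector of task
#'   labels, or `NULL` for a single task.
#' @return object of class `block_design`: `X` (n x p, rows grouped by
#'   task), `y`, `task_off` (0-based row offsets, length T + 1), `order`
#'   (original row index of each row of `X`), `family`, `n_t`, `p`, `T`.
#' @export
build_block_design <- function(ds, pheno, tasks = NULL) {
  g <- if (inherits(ds, "genotype_dataset")) ds$genotypes else as.matrix(ds)
  y <- if (inherits(pheno, "phenotype_table")) pheno$values
  else as.numeric(pheno)
  kind <- if (inherits(pheno, "phenotype_table")) pheno$kind
  else if (all(y %in% c(0, 1))) "binary" else "quantitative"
  n <- nrow(g)
  stopifnot(length(y) == n)
  task <- if (is.null(tasks)) rep(1L, n)
  else if (inherits(tasks, "task_assignment")) tasks$task
  else as.integer(factor(tasks))
  Tn <- max(task)
  ord <- order(task)
  cnt <- tabulate(task, Tn)
  if (any(cnt < 2)) stop("every task needs at least 2 samples")
  Xs <- matrix(0, n, ncol(g))
  off <- c(0L, cumsum(cnt))
  for (t in seq_len(Tn)) {
    rows <- ord[(off[t] + 1L):off[t + 1L]]
    Xs[(off[t] + 1L):off[t + 1L], ] <-
      standardize_genotypes(g[rows, , drop = FALSE])
  }
  structure(list(X = Xs, y = y[ord], task_off = off, order = ord,
                 family = if (kind == "binary") "binomial" else "gaussian",
                 n_t = cnt, p = ncol(g), T = Tn),
            class = "block_design")
}

#' @exportS3Method base::print
print.block_design <- function(x, ...) {
  cat("block_design:", nrow(x$X), "samples x", x$p, "SNPs,",
      x$T, "tasks (", x$family, "loss );  n_t:",
      paste(x$n_t, collapse = ", "), "\n")
  invisible(x)
}

# group column offsets (0-based, length G+1) from a groups argument
resolve_groups <- function(groups, p) {
  if (is.null(groups)) return(0:p)                     # singletons
  ids <- if (inherits(groups, "ld_partition")) group_ids(groups)
  else as.integer(groups)
  if (length(ids) != p) stop("group vector length does not match SNP count")
  r <- rle(ids)
  if (any(duplicated(r$values)))
    stop("groups must be contiguous runs of SNP indices")
  as.integer(c(0L, cumsum(r$lengths)))
}

group_weights <- function(grp_off, T, weights = c("sqrt_pg", "sqrt_pgT")) {
  weights <- match.arg(weights)
  pg <- diff(grp_off)
  if (weights == "sqrt_pg") sqrt(pg) else sqrt(pg * T)
}
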