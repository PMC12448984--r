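#' Stability selection over subsamples
#'
#' Draws `B` subsamples of `floor(fraction * n)` samples without
#' replacement, stratified by task and (for binary phenotypes) phenotype,
#' applies a selection procedure to each, and records per-(group, task)
#' selection frequencies. The final selection keeps pairs with frequency at
#' least `pi`.
#'
#' @param fit_fun function `(x, y, tasks) -> logical selection matrix`
#'   (groups or SNPs in rows, tasks in columns; a vector is treated as a
#'   one-column matrix).
#' @param x genotype matrix or [genotype_dataset].
#' @param y [phenotype_table] or numeric vector.
#' @param tasks task labels / `task_assignment` / `NULL`.
#' @param B number of subsamples.
#' @param fraction subsample fraction.
#' @param pi selection-frequency threshold.
#' @param seed integer seed.
#' @param keep_runs also return every subsample's selection mask (needed
#'   for the stability index).
#' @return Object of class `selection_profile`: `frequency` (d x T),
#'   `selected` (`frequency >= pi`), `n_ok` (subsamples that succeeded),
#'   `B`, `pi`, `failed`, and (with `keep_runs`) `runs`, a list of masks.
#' @export
stability_selection <- function(fit_fun, x, y, tasks = NULL, B = 100,
                                fraction = 0.5, pi = 0.6, seed = 1,
                                keep_runs = FALSE) {
  stopifnot(B >= 2)
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else as.matrix(x)
  yv <- if (inherits(y, "phenotype_table")) y$values else as.numeric(y)
  task <- if (is.null(tasks)) rep(1L, nrow(g))
  else if (inherits(tasks, "task_assignment")) tasks$task
  else as.integer(factor(tasks))
  n <- nrow(g)
  binary <- all(yv %in% c(0, 1))
  strata <- if (binary) interaction(task, yv, drop = TRUE)
  else factor(task)
  set.seed(seed)
  freq <- NULL
  runs <- if (keep_runs) list() else NULL
  n_ok <- 0L; failed <- 0L
  for (b in seq_len(B)) {
    idx <- integer(0)
    for (s in levels(strata)) {
      rows <- which(strata == s)
      take <- floor(fraction * length(rows))
      idx <- c(idx, sample(rows, take))
    }
    idx <- sort(idx)
    mask <- tryCatch(
      fit_fun(g[idx, , drop = FALSE], yv[idx], task[idx]),
      error = function(e) NULL)
    if (is.null(mask)) {
      failed <- failed + 1L
      warning("selection failed on subsample ", b)
      next
    }
    mask <- as.matrix(mask) * 1
    if (is.null(freq)) freq <- mask * 0
    freq <- freq + mask
    n_ok <- n_ok + 1L
    if (keep_runs) runs[[n_ok]] <- mask > 0
  }
  if (n_ok == 0) stop("selection failed on every subsample")
  freq <- freq / n_ok
  structure(list(frequency = freq, selected = freq >= pi, n_ok = n_ok,
                 B = B, pi = pi, failed = failed, runs = runs),
            class = "selection_profile")
}

#' @exportS3Method base::print
print.selection_profile <- function(x, ...) {
  cat("selection_profile:", nrow(x$frequency), "units x",
      ncol(x$frequency), "tasks;", x$n_ok, "of", x$B,
      "subsamples; pi =", x$pi, "\n")
  cat("  selected:", sum(x$selected), "unit-task pairs\n")
  invisible(x)
}

#' Stability index of a feature-selection procedure
#'
#' The mean over all unordered pairs of runs of the Pearson correlation
#' between the indicator vectors of selected features. When either vector
#' of a pair is constant (empty or full selection) the pair contributes 1
#' if the two vectors are identical and 0 otherwise.
#'
#' @param selections list of equal-length 0/1 indicator vectors (or a
#'   matrix with runs in columns).
#' @return list with `index`, `pairs` (per-pair correlations), `n_runs`.
#' @export
stability_index <- function(selections) {
  if (is.matrix(selections))
    selections <- lapply(seq_len(ncol(selections)),
                         function(j) selections[, j])
  m <- length(selections)
  if (m < 2) stop("need at least two selection runs")
  d <- unique(vapply(selections, length, 1L))
  if (length(d) != 1) stop("indicator vectors differ in length")
  if (d == 0) stop("indicator vectors are empty")
  pairs <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- selections[[i]]; b <- selections[[j]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        pairs <- c(pairs, as.numeric(all(a == b)))
      } else {
        pairs <- c(pairs, stats::cor(a, b))
      }
    }
  }
  list(index = mean(pairs), pairs = pairs, n_runs = m)
}

#' Expand a SNP-level selection to LD-group level
#'
#' A group is selected when any of its member SNPs is.
#'
#' @param snp_mask logical/0-1 vector of length p, or p x T matrix.
#' @param part an [ld_partition].
#' @return logical vector of length G (or G x T matrix).
#' @export
expand_snp_to_group <- function(snp_mask, part) {
  gid <- group_ids(part)
  G <- attr(part, "G")
  if (is.matrix(snp_mask)) {
    stopifnot(nrow(snp_mask) == length(gid))
    out <- apply(snp_mask, 2, function(cl)
      as.logical(tapply(cl, factor(gid, seq_len(G)), any)))
    out[is.na(out)] <- FALSE
    matrix(as.logical(out), G, ncol(snp_mask))
  } else {
    stopifnot(length(snp_mask) == length(gid))
    v <- tapply(as.logical(snp_mask), factor(gid, seq_len(G)), any)
    v[is.na(v)] <- FALSE
    as.logical(v)
  }
}

#' Classify selected groups as shared or population-specific
#'
#' @param selected G x T logical matrix (e.g. from a `selection_profile`
#'   or [active_groups]).
#' @param labels optional task labels for naming.
#' @return character vector of length G: `"shared"` (selected in every
#'   task), `"specific:<task>"` (exactly one), `"partial"` (some but not
#'   all, T > 2), or `"none"`.
#' @export
classify_shared_specific <- function(selected, labels = NULL) {
  selected <- as.matrix(selected)
  Tn <- ncol(selected)
  stopifnot(Tn >= 2)
  if (is.null(labels)) labels <- as.character(seq_len(Tn))
  k <- rowSums(selected)
  out <- rep("none", nrow(selected))
  out[k == Tn] <- "shared"
  one <- which(k == 1)
  if (length(one)) {
    wt <- apply(selected[one, , drop = FALSE], 1, which.max)
    out[one] <- paste0("specific:", labels[wt])
  }
  out[k > 1 & k < Tn] <- "partial"
  out
}

#' Precision and recall of a selection against simulation ground truth
#'
#' At SNP level, truth is the set of causal SNP indices; at group level, a
#' group is a true positive when it contains at least one causal SNP.
#'
#' @param selected logical vector (length p at SNP level, G at group
#'   level), or integer indices of selected units.
#' @param truth_snps integer vector of causal SNP indices (1-based).
#' @param part an [ld_partition]; required for `level = "group"`.
#' @param level `"snp"` or `"group"`.
#' @param p total number of SNPs (needed when `selected` is an index
#'   vector at SNP level).
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `n_selected`, `n_true`. Recall is `NA` when the truth set is empty.
#' @export
precision_recall <- function(selected, truth_snps, part = NULL,
                             level = c("snp", "group"), p = NULL) {
  level <- match.arg(level)
  if (level == "group") {
    stopifnot(!is.null(part))
    G <- attr(part, "G")
    sel <- to_indicator(selected, G)
    tr_mask <- rep(FALSE, length(group_ids(part)))
    tr_mask[truth_snps] <- TRUE
    tru <- expand_snp_to_group(tr_mask, part)
  } else {
    if (is.null(p)) p <- length(selected)
    sel <- to_indicator(selected, p)
    tru <- rep(FALSE, p)
    tru[truth_snps] <- TRUE
  }
  tp <- sum(sel & tru); fp <- sum(sel & !tru); fn <- sum(!sel & tru)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn,
       n_selected = sum(sel), n_true = sum(tru))
}

to_indicator <- function(x, d) {
  if (is.logical(x)) {
    stopifnot(length(x) == d)
    return(x)
  }
  if (all(x %in% c(0, 1)) && length(x) == d) return(x > 0)
  v <- rep(FALSE, d)
  v[as.integer(x)] <- TRUE
  v
}

#' Precision/recall curve by sweeping the stability threshold
#'
#' @param profile a `selection_profile`.
#' @param truth_snps causal SNP indices.
#' @param part [ld_partition] matching the profile's rows.
#' @param thresholds decreasing vector of frequency thresholds.
#' @return data frame with columns `pi`, `precision`, `recall`.
#' @export
pr_curve <- function(profile, truth_snps, part,
                     thresholds = seq(1, 0, by = -0.05)) {
  freq_any <- apply(profile$frequency, 1, max)
  out <- lapply(thresholds, function(th) {
    pr <- precision_recall(freq_any >= th, truth_snps, part, "group")
    data.frame(pi = th, precision = pr$precision, recall = pr$recall)
  })
  do.call(rbind, out)
}

#' Path-based selection procedure for stability selection
#'
#' Returns a selection function for [stability_selection] implementing the
#' per-subsample rule of Meinshausen-Buehlmann stability selection: fit a
#' warm-started regularization path on the subsample and report the
#' active (group, task) pairs of the densest path point selecting at most
#' `q` groups. Capping the per-subsample selection makes spurious
#' selections scatter across subsamples while reproducible groups recur,
#' so the selection frequency separates them.
#'
#' @param groups [ld_partition] or group id vector (see [smuglasso]).
#' @param alpha elementwise-penalty mixing ratio (0 = multitask group
#'   lasso).
#' @param q cap on the number of groups selected per subsample.
#' @param nlambda,lambda_min_ratio path grid for each subsample.
#' @param family model family passed to [smuglasso].
#' @param muglasso_threshold coefficient threshold applied when
#'   `alpha = 0` (the post-processing of [active_groups]).
#' @param ... further arguments to [smuglasso].
#' @return A function `(x, y, tasks) -> G x T logical matrix`.
#' @export
smuglasso_path_selector <- function(groups, alpha = 0.3, q = 20,
                                    nlambda = 8, lambda_min_ratio = 0.1,
                                    family = NULL,
                                    muglasso_threshold = 1e-2, ...) {
  function(x, y, tasks) {
    fit <- smuglasso(x, y, tasks = tasks, groups = groups, family = family,
                     alpha = alpha, nlambda = nlambda,
                     lambda_min_ratio = lambda_min_ratio,
                     stop_at_groups = q, ...)
    best <- NULL
    for (i in seq_along(fit$lambda1)) {
      act <- active_groups(fit, s = i)
      ng <- sum(rowSums(act) > 0)
      if (ng <= q) best <- act else break
    }
    if (is.null(best)) best <- active_groups(fit, s = 1)
    best
  }
}
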