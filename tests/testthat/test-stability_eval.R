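test_that("stability selection frequencies track the selection
           procedure", {
  set.seed(1)
  x <- matrix(rbinom(200 * 10, 2, 0.5), 200, 10)
  y <- rep(c(0, 1), 100)
  # deterministic procedure: always group 3, task 1
  det <- function(x, y, tasks) {
    m <- matrix(FALSE, 5, 1)
    m[3, 1] <- TRUE
    m
  }
  prof <- stability_selection(det, x, y, B = 10, seed = 2)
  expect_equal(prof$frequency[3, 1], 1)
  expect_equal(sum(prof$frequency), 1)
  expect_true(prof$selected[3, 1])
  # uniformly random selection of one unit: max frequency near the
  # binomial expectation for B = 100 draws over 5 units
  rnd <- function(x, y, tasks) {
    m <- matrix(FALSE, 5, 1)
    m[sample(5, 1), 1] <- TRUE
    m
  }
  prof2 <- stability_selection(rnd, x, y, B = 100, seed = 3)
  expect_equal(sum(prof2$frequency), 1)
  expect_lt(max(prof2$frequency), 0.2 + 3 * sqrt(0.2 * 0.8 / 100))
  # determinism and failure accounting
  prof3 <- stability_selection(rnd, x, y, B = 100, seed = 3)
  expect_identical(prof2$frequency, prof3$frequency)
  flaky <- local({
    k <- 0
    function(x, y, tasks) {
      k <<- k + 1
      if (k == 2) stop("boom")
      matrix(TRUE, 2, 1)
    }
  })
  expect_warning(p4 <- stability_selection(flaky, x, y, B = 4, seed = 4),
                 "failed")
  expect_equal(p4$n_ok, 3)
  expect_equal(p4$frequency[1, 1], 1)
})

test_that("the stability index reproduces hand-computed Pearson values", {
  v <- c(1, 0, 1, 0, 1)
  expect_equal(stability_index(list(v, v, v))$index, 1)
  expect_equal(stability_index(list(c(1, 0, 0, 1), c(0, 1, 1, 0)))$index,
               -1)
  # mean of pairwise correlations {0, 1, 0} = 1/3
  r <- stability_index(list(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 0, 0)))
  expect_equal(r$index, 1 / 3)
  expect_equal(sort(r$pairs), c(0, 0, 1))
  # constant-vector convention: identical -> 1, different -> 0
  expect_equal(stability_index(list(rep(0, 4), rep(0, 4)))$index, 1)
  expect_equal(stability_index(list(rep(0, 4), c(1, 0, 0, 0)))$index, 0)
  expect_error(stability_index(list(c(1, 0))), "two")
  # bounds on random indicators
  set.seed(5)
  runs <- replicate(6, rbinom(20, 1, 0.4), simplify = FALSE)
  idx <- stability_index(runs)$index
  expect_gte(idx, -1)
  expect_lte(idx, 1)
})

test_that("SNP masks expand to LD-groups by the any-member rule", {
  part <- make_partition(list("1" = c(0L, 3L, 6L, 10L)))
  expect_equal(expand_snp_to_group(rep(FALSE, 10), part),
               rep(FALSE, 3))
  m <- rep(FALSE, 10)
  m[5] <- TRUE
  expect_equal(expand_snp_to_group(m, part), c(FALSE, TRUE, FALSE))
  m[1] <- TRUE
  expect_equal(expand_snp_to_group(m, part), c(TRUE, TRUE, FALSE))
  # matrix form, one column per task
  mm <- cbind(m, rep(FALSE, 10))
  em <- expand_snp_to_group(mm, part)
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(em[, 1], c(TRUE, TRUE, FALSE))
  expect_false(any(em[, 2]))
})

test_that("shared / specific classification follows the all-vs-one rule", {
  expect_equal(classify_shared_specific(rbind(c(TRUE, TRUE))), "shared")
  expect_equal(classify_shared_specific(rbind(c(FALSE, TRUE))),
               "specific:2")
  expect_equal(classify_shared_specific(rbind(c(FALSE, FALSE))), "none")
  five <- matrix(FALSE, 1, 5)
  five[1, c(1, 3)] <- TRUE
  expect_equal(classify_shared_specific(five), "partial")
  sel <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))
  expect_equal(classify_shared_specific(sel, labels = c("CEU", "YRI")),
               c("shared", "specific:CEU", "none"))
})

test_that("precision/recall arithmetic and threshold sweep behave", {
  part <- make_partition(list("1" = c(0L, 5L, 10L, 15L, 20L)))
  # 3 selected, 2 true among 4 causal SNPs
  pr <- precision_recall(c(1, 2, 3), truth_snps = c(1, 2, 16, 17),
                         level = "snp", p = 20)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1 / 2)
  # exact match
  sel <- rep(FALSE, 4)
  sel[c(1, 4)] <- TRUE
  prg <- precision_recall(sel, truth_snps = c(2, 18), part = part,
                          level = "group")
  expect_equal(prg$precision, 1)
  expect_equal(prg$recall, 1)
  # empty truth class: recall undefined
  pr0 <- precision_recall(sel, truth_snps = integer(0), part = part,
                          level = "group")
  expect_true(is.na(pr0$recall))
  # recall non-decreasing as pi decreases
  prof <- structure(list(frequency = cbind(c(0.9, 0.5, 0.2, 0))),
                    class = "selection_profile")
  cur <- pr_curve(prof, truth_snps = c(2, 7, 12), part = part)
  expect_true(all(diff(cur$recall) >= 0))
})

test_that("adjusted single-SNP testing controls false positives on null
           simulations", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B"),
                             n_cases = c(150L, 150L),
                             n_controls = c(150L, 150L)),
    n_snps_per_chrom = c("1" = 400), fst = c(0.1, 0.1),
    phenotype_kind = "binary")
  st <- simulate_study(cfg, seed = 6)
  sc <- pca_scores(standardize_genotypes(st$dataset), 2)
  tk <- tasks_from_labels(st$population)
  out <- run_baseline("adjusted_gwas", st$dataset, st$pheno, tk,
                      scores = sc, alpha_gwas = 0.05 / 400)
  expect_lte(sum(out$snp_selected[, 1]), 2)   # ~ p * alpha expected hits
})

test_that("stratified group lasso treats duplicated populations
           symmetrically", {
  set.seed(7)
  g1 <- matrix(rbinom(120 * 20, 2, 0.4), 120, 20)
  x <- rbind(g1, g1)
  X <- standardize_genotypes(g1)
  y1 <- as.numeric(X[, 1:4] %*% rep(0.8, 4) + rnorm(120))
  y <- c(y1, y1)
  task <- rep(1:2, each = 120)
  part <- make_partition(list("1" = seq.int(0L, 20L, 4L)))
  out <- run_baseline("stratified_group_lasso", x, y, task, part = part,
                      lambda1 = 0.1)
  expect_identical(out$snp_selected[, 1], out$snp_selected[, 2])
  expect_true(out$group_selected[1, 1])
})

test_that("the lasso baseline coincides with the singleton-group
           elementwise-penalty fit", {
  set.seed(8)
  x <- matrix(rbinom(150 * 15, 2, 0.5), 150, 15)
  X <- standardize_genotypes(x)
  y <- as.numeric(X[, 1] * 1 + rnorm(150))
  sc <- pca_scores(X, 2)
  lam <- 0.1
  out <- run_baseline("adjusted_lasso", x, phenotype_table(y), NULL,
                      scores = sc, lambda1 = lam)
  adj <- adjust_phenotype(phenotype_table(y), sc)
  direct <- smuglasso(x, adj$values, lambda1 = 0, lambda2 = lam,
                      family = "gaussian")
  expect_equal(out$snp_selected[, 1], abs(coef(direct)[, 1]) > 0)
  expect_error(run_baseline("nope", x, y), "arg")
})

test_that("sparser penalties select fewer groups than the plain
           multitask group lasso at matched lambda1", {
  set.seed(9)
  ds <- rand_dataset(120, 40, seed = 9)
  task <- rep(1:2, each = 60)
  X <- standardize_genotypes(ds)
  y <- as.numeric(X[, 1:5] %*% rep(0.7, 5) + rnorm(120))
  groups <- rep(1:8, each = 5)
  for (lam_frac in c(0.3, 0.5)) {
    des <- build_block_design(ds, y, task)
    lam <- lam_frac * lambda_max(des, 0, groups)
    mug <- smuglasso(des, groups = groups, lambda1 = lam, alpha = 0)
    smug <- smuglasso(des, groups = groups, lambda1 = lam, alpha = 0.5)
    expect_lte(sum(abs(coef(smug)) > 0), sum(abs(coef(mug)) > 0))
  }
})

test_that("the pipeline wrapper returns a coherent selection summary", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B"),
                             n_cases = c(60L, 60L),
                             n_controls = c(60L, 60L)),
    n_snps_per_chrom = c("1" = 120), fst = c(0.1, 0.1),
    causal_spec = data.frame(chrom = "1", start = 10L, end = 16L,
                             populations = "", n_causal = 5L),
    phenotype_kind = "binary", effect_range = log(c(3, 4)))
  st <- simulate_study(cfg, seed = 10)
  out <- smuglasso_pipeline(st$dataset, st$pheno, T = 2, n_pcs = 2,
                            target_size = 20, B = 10, q = 5, seed = 3)
  expect_s3_class(out$profile, "selection_profile")
  expect_equal(length(out$labels), attr(out$partition, "G"))
  expect_equal(out$counts$shared_groups, sum(out$labels == "shared"))
  expect_equal(dim(out$selected),
               c(attr(out$partition, "G"), out$tasks$T))
})
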