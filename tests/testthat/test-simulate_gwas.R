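test_that("Balding-Nichols frequencies concentrate at the ancestral value
           as F -> 0 and reproduce the target differentiation", {
  set.seed(1)
  panc <- runif(2000, 0.05, 0.95)
  near <- draw_population_frequencies(panc, c(1e-6, 1e-6))
  expect_lt(max(abs(near - panc)), 0.02)
  set.seed(2)
  panc <- runif(10000, 0.05, 0.95)
  fr <- draw_population_frequencies(panc, c(0.1, 0.1))
  expect_lt(abs(fst_estimate(fr[, 1], fr[, 2]) - 0.1), 0.02)
  expect_error(draw_population_frequencies(panc, 1.5), "fst")
})

test_that("latent AR(1) copula produces within-block LD and none across", {
  cfg <- sim_config(
    populations = data.frame(label = "P", n = 2000),
    n_snps_per_chrom = c("1" = 60),
    ld_block_min = 10, ld_block_max = 15, within_block_rho = 0.9,
    phenotype_kind = "quantitative")
  set.seed(3)
  sim <- simulate_genotypes(cfg)
  X <- standardize_genotypes(sim$dataset)
  bnd <- sim$blocks[["1"]]
  blk <- findInterval(0:59, bnd, rightmost.closed = FALSE)
  r2 <- cor(X)^2
  same <- abs(outer(blk, blk, "-")) == 0 & abs(outer(1:60, 1:60, "-")) == 1
  diff_blk <- outer(blk, blk, "!=")
  expect_gt(mean(r2[same]), 10 * mean(r2[diff_blk]))

  # independence limit
  cfg0 <- sim_config(
    populations = data.frame(label = "P", n = 2000),
    n_snps_per_chrom = c("1" = 50), within_block_rho = 0,
    phenotype_kind = "quantitative")
  set.seed(4)
  s0 <- simulate_genotypes(cfg0)
  r20 <- cor(standardize_genotypes(s0$dataset))^2
  expect_lt(mean(r20[upper.tri(r20)]), 0.01)
})

test_that("the generator is a pure function of (config, seed)", {
  cfg <- two_population_scenario(scaled = TRUE)
  cfg$n_snps_per_chrom <- c("12" = 100L, "19" = 100L, "21" = 100L,
                            "22" = 100L)
  cfg$causal_spec <- NULL
  cfg$populations$n_cases <- c(30L, 20L)
  cfg$populations$n_controls <- c(40L, 30L)
  a <- simulate_study(cfg, seed = 9)
  b <- simulate_study(cfg, seed = 9)
  expect_identical(a$dataset$genotypes, b$dataset$genotypes)
  expect_identical(a$pheno$values, b$pheno$values)
})

test_that("binary simulation hits per-population case:control targets
           exactly even with beta = 0", {
  cfg <- sim_config(
    populations = data.frame(label = c("CEU", "YRI"),
                             n_cases = c(130L, 40L),
                             n_controls = c(170L, 60L)),
    n_snps_per_chrom = c("1" = 200),
    phenotype_kind = "binary")
  st <- simulate_study(cfg, seed = 5)
  tab <- table(st$population, st$pheno$values)
  expect_equal(tab["CEU", "1"], 130)
  expect_equal(tab["CEU", "0"], 170)
  expect_equal(tab["YRI", "1"], 40)
  expect_equal(tab["YRI", "0"], 60)
})

test_that("quantitative phenotype has the configured noise and recovers a
           single causal effect by OLS", {
  cfg <- sim_config(
    populations = data.frame(label = "P", n = 4000),
    n_snps_per_chrom = c("1" = 50),
    causal_spec = data.frame(chrom = "1", start = 10L, end = 11L,
                             populations = "", n_causal = 1L),
    phenotype_kind = "quantitative", noise_sd = 1,
    effect_range = c(1, 1))
  st <- simulate_study(cfg, seed = 6)
  j <- st$causal$causal_by_pop$P
  fitc <- coef(lm(st$pheno$values ~ st$dataset$genotypes[, j]))
  expect_equal(abs(fitc[2]), 1, tolerance = 0.1, ignore_attr = TRUE)
  # beta = 0 variant: pure noise
  cfg0 <- cfg
  cfg0$causal_spec <- NULL
  st0 <- simulate_study(cfg0, seed = 7)
  expect_equal(var(st0$pheno$values), 1, tolerance = 0.1)
})

test_that("the benchmark scenario emits the documented design counts", {
  cfg <- two_population_scenario()
  expect_equal(sum(cfg$n_snps_per_chrom), 50000)
  expect_equal(sum(cfg$populations$n_cases + cfg$populations$n_controls),
               4000)
  expect_equal(cfg$populations$n_cases, c(1300L, 400L))
  expect_equal(cfg$populations$n_controls, c(1700L, 600L))
  expect_equal(sum(cfg$causal_spec$n_causal), 200)
  set.seed(1)
  tr <- resolve_ground_truth(cfg)
  expect_length(tr$shared, 100)
  expect_length(tr$specific$CEU, 50)
  expect_length(tr$specific$YRI, 50)
  expect_length(unique(unlist(tr$causal_by_pop)), 200)
  # chr21 affects YRI only, chr22 CEU only
  expect_equal(cfg$causal_spec$populations[cfg$causal_spec$chrom == "21"],
               "YRI")
  expect_equal(cfg$causal_spec$populations[cfg$causal_spec$chrom == "22"],
               "CEU")
  # shared and specific sets are disjoint; shared causal in every
  # population's set
  expect_length(intersect(tr$shared, unlist(tr$specific)), 0)
  expect_true(all(tr$shared %in% tr$causal_by_pop$CEU))
  expect_true(all(tr$shared %in% tr$causal_by_pop$YRI))
})

test_that("null SNPs show no association under balanced sampling but the
           stratified design inflates unadjusted tests", {
  # balanced case:control ratios, beta = 0: median trend chi2 at the
  # chi2_1 median
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B"),
                             n_cases = c(150L, 150L),
                             n_controls = c(150L, 150L)),
    n_snps_per_chrom = c("1" = 600), fst = c(0.1, 0.1),
    phenotype_kind = "binary")
  st <- simulate_study(cfg, seed = 11)
  chi <- trend_test(st$dataset, st$pheno$values)
  expect_lt(abs(median(chi) - qchisq(0.5, 1)), 0.12)

  # unequal ratios: lambda_GC > 1 raw, ~1 after PC adjustment
  cfg2 <- sim_config(
    populations = data.frame(label = c("A", "B"),
                             n_cases = c(240L, 60L),
                             n_controls = c(60L, 240L)),
    n_snps_per_chrom = c("1" = 600), fst = c(0.1, 0.1),
    phenotype_kind = "binary")
  st2 <- simulate_study(cfg2, seed = 12)
  lam_raw <- genomic_control(trend_test(st2$dataset, st2$pheno$values))
  sc <- pca_scores(standardize_genotypes(st2$dataset), 2)
  adj <- score_test_adjusted(st2$dataset, st2$pheno$values, sc$scores,
                             "binomial")
  lam_adj <- genomic_control(adj$chisq)
  expect_gt(lam_raw, 1.4)
  expect_lt(abs(lam_adj - 1), 0.15)
})
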