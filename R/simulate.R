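#' Configuration for a multi-population GWAS simulation
#'
#' Describes populations and sample sizes, SNP counts per chromosome,
#' blockwise-LD structure, allele-frequency differentiation, and the causal
#' architecture (shared and population-specific causal SNPs in predefined
#' index ranges).
#'
#' @param populations data frame with columns `label` and, for binary
#'   phenotypes, `n_cases` and `n_controls` (or `n` for quantitative).
#' @param n_snps_per_chrom named integer vector, chromosome -> SNP count.
#' @param ld_block_min,ld_block_max LD block lengths are drawn uniformly in
#'   this range (SNP counts).
#' @param within_block_rho AR(1) autocorrelation of the latent haplotype
#'   Gaussian within a block, in \[0, 1).
#' @param fst Balding-Nichols differentiation parameter per population,
#'   each in (0, 1).
#' @param causal_spec data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open SNP index range within the chromosome),
#'   `populations` (comma-separated labels, "" = all) and `n_causal`.
#' @param phenotype_kind `"binary"` or `"quantitative"`.
#' @param noise_sd residual standard deviation (quantitative).
#' @param effect_range absolute effect sizes are drawn uniformly in this
#'   range, with random sign; shared causal SNPs get the same effect in all
#'   populations. The default corresponds to allelic odds ratios between
#'   2 and 3, the strong-effect regime of benchmark simulations for
#'   variant-selection methods: effects must remain detectable on the
#'   half-size subsamples that stability selection operates on.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(populations, n_snps_per_chrom,
                       ld_block_min = 15, ld_block_max = 60,
                       within_block_rho = 0.9, fst = NULL,
                       causal_spec = NULL, phenotype_kind = "binary",
                       noise_sd = 1, effect_range = log(c(2, 3))) {
  stopifnot(is.data.frame(populations), nrow(populations) >= 1)
  if (is.null(fst)) fst <- rep(0.1, nrow(populations))
  if (length(fst) == 1) fst <- rep(fst, nrow(populations))
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (any(n_snps_per_chrom < 1)) stop("chromosome SNP counts must be positive")
  phenotype_kind <- match.arg(phenotype_kind, c("binary", "quantitative"))
  if (phenotype_kind == "binary" &&
      !all(c("n_cases", "n_controls") %in% names(populations)))
    stop("binary config needs n_cases and n_controls per population")
  if (!is.null(causal_spec)) {
    for (i in seq_len(nrow(causal_spec))) {
      cs <- causal_spec[i, ]
      pmax <- n_snps_per_chrom[[as.character(cs$chrom)]]
      if (is.null(pmax) || cs$start < 0 || cs$end > pmax || cs$start >= cs$end)
        stop("causal range outside its chromosome: row ", i)
      labs <- strsplit(cs$populations, ",")[[1]]
      if (length(labs) && !all(labs %in% populations$label))
        stop("causal_spec names unknown population(s): row ", i)
      if (cs$n_causal > cs$end - cs$start)
        stop("more causal SNPs than SNPs in range: row ", i)
    }
  }
  structure(list(populations = populations,
                 n_snps_per_chrom = n_snps_per_chrom,
                 ld_block_min = ld_block_min, ld_block_max = ld_block_max,
                 within_block_rho = within_block_rho, fst = fst,
                 causal_spec = causal_spec, phenotype_kind = phenotype_kind,
                 noise_sd = noise_sd, effect_range = effect_range),
            class = "sim_config")
}

#' Two-population case-control benchmark scenario
#'
#' The reference simulation design: two populations, CEU (1300 cases, 1700
#' controls) and YRI (400 cases, 600 controls), 50000 SNPs over chromosomes
#' 12, 19, 21 and 22, and 200 causal SNPs of which 50 are CEU-specific
#' (chromosome 22, indices 1000-1050), 50 YRI-specific (chromosome 21,
#' indices 10000-10050) and 100 shared (chromosomes 12 and 19, indices
#' 4000-4050 and 1000-1050). The unequal case:control ratios combined with
#' the allele-frequency differentiation create a population-stratification
#' confounder.
#'
#' With `scaled = TRUE` a desk-scale variant is returned: 1000 samples
#' (CEU 325:425, YRI 100:150), 5000 SNPs over the same four chromosomes and
#' 20 causal SNPs (5 CEU-specific, 5 YRI-specific, 10 shared) in four loci
#' at one tenth of the full design's indices. Locus widths scale with the
#' causal counts (5 causal SNPs within 6 consecutive positions, matching
#' the full design's density of 50 in 51), so each locus spans about one
#' LD-group.
#'
#' @param scaled logical; return the scaled variant.
#' @return A [sim_config].
#' @export
two_population_scenario <- function(scaled = FALSE) {
  if (!scaled) {
    pops <- data.frame(label = c("CEU", "YRI"),
                       n_cases = c(1300L, 400L),
                       n_controls = c(1700L, 600L),
                       stringsAsFactors = FALSE)
    nspc <- c("12" = 12500L, "19" = 12500L, "21" = 12500L, "22" = 12500L)
    causal <- data.frame(
      chrom = c("12", "19", "21", "22"),
      start = c(4000L, 1000L, 10000L, 1000L),
      end   = c(4051L, 1051L, 10051L, 1051L),
      populations = c("", "", "YRI", "CEU"),
      n_causal = c(50L, 50L, 50L, 50L),
      stringsAsFactors = FALSE)
  } else {
    pops <- data.frame(label = c("CEU", "YRI"),
                       n_cases = c(325L, 100L),
                       n_controls = c(425L, 150L),
                       stringsAsFactors = FALSE)
    nspc <- c("12" = 1250L, "19" = 1250L, "21" = 1250L, "22" = 1250L)
    causal <- data.frame(
      chrom = c("12", "19", "21", "22"),
      start = c(400L, 100L, 1000L, 100L),
      end   = c(406L, 106L, 1006L, 106L),
      populations = c("", "", "YRI", "CEU"),
      n_causal = c(5L, 5L, 5L, 5L),
      stringsAsFactors = FALSE)
  }
  # scaled variant: n drops 4-fold, so allelic log-odds are doubled to
  # preserve each locus's non-centrality (n * r^2, r ~ beta) and hence the
  # detection regime of the full-size design
  sim_config(populations = pops, n_snps_per_chrom = nspc,
             fst = c(0.1, 0.1), causal_spec = causal,
             phenotype_kind = "binary",
             effect_range = if (scaled) 2 * log(c(2, 3)) else log(c(2, 3)))
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population allele frequencies around ancestral frequencies:
#' for ancestral frequency p and differentiation F, the population frequency
#' is Beta(p(1-F)/F, (1-p)(1-F)/F), independently per SNP and population,
#' clipped to \[0.01, 0.99\].
#'
#' @param p_ancestral ancestral frequencies in (0, 1); drawn Uniform(0.05,
#'   0.95) when a single count is given instead.
#' @param fst per-population differentiation, each in (0, 1).
#' @return matrix p_snps x n_populations of frequencies.
#' @export
draw_population_frequencies <- function(p_ancestral, fst) {
  if (length(p_ancestral) == 1 && p_ancestral >= 1)
    p_ancestral <- stats::runif(p_ancestral, 0.05, 0.95)
  if (any(p_ancestral <= 0 | p_ancestral >= 1))
    stop("ancestral frequencies must lie in (0, 1)")
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  out <- sapply(fst, function(f) {
    a <- p_ancestral * (1 - f) / f
    b <- (1 - p_ancestral) * (1 - f) / f
    pmin(pmax(stats::rbeta(length(p_ancestral), a, b), 0.01), 0.99)
  })
  matrix(out, nrow = length(p_ancestral))
}

# LD block boundaries for one chromosome (0-based, half-open)
draw_block_boundaries <- function(p, bmin, bmax) {
  b <- 0L
  repeat {
    len <- sample.int(bmax - bmin + 1L, 1L) + bmin - 1L
    nxt <- b[length(b)] + len
    if (nxt >= p) break
    b <- c(b, nxt)
  }
  c(b, p)
}

# haplotype matrix (n x p) for one population/chromosome: latent Gaussian
# AR(1) within blocks, allele = 1 iff latent < qnorm(freq)
draw_haplotypes <- function(n, freqs, boundaries, rho) {
  p <- length(freqs)
  Z <- matrix(0, n, p)
  srho <- sqrt(1 - rho^2)
  for (k in seq_len(length(boundaries) - 1L)) {
    j0 <- boundaries[k] + 1L; j1 <- boundaries[k + 1L]
    Z[, j0] <- stats::rnorm(n)
    if (j1 > j0)
      for (j in (j0 + 1L):j1)
        Z[, j] <- rho * Z[, j - 1L] + srho * stats::rnorm(n)
  }
  thr <- stats::qnorm(freqs)
  (Z < matrix(thr, n, p, byrow = TRUE)) + 0L
}

#' Simulate multi-population genotypes with blockwise LD
#'
#' Genotypes are sums of two independent haplotypes; each haplotype follows
#' a latent Gaussian copula with AR(1) correlation `within_block_rho` inside
#' LD blocks (blocks independent), thresholded at the population-specific
#' allele frequency. Deterministic given the RNG state.
#'
#' @param config a [sim_config].
#' @param n_per_pop optional named vector overriding the number of samples
#'   drawn per population (defaults to `n_cases + n_controls` or `n`).
#' @return list with `dataset` ([genotype_dataset]), `population` (per-sample
#'   label), `frequencies` (p x T matrix), `blocks` (per-chromosome boundary
#'   vectors), `causal` (the resolved ground truth, see
#'   [resolve_ground_truth]).
#' @export
simulate_genotypes <- function(config, n_per_pop = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pops <- config$populations
  Tn <- nrow(pops)
  if (is.null(n_per_pop)) {
    n_per_pop <- if (config$phenotype_kind == "binary")
      pops$n_cases + pops$n_controls else pops$n
  }
  chroms <- names(config$n_snps_per_chrom)
  blocks <- list()
  freq_list <- list()
  for (ch in chroms) {
    p_ch <- config$n_snps_per_chrom[[ch]]
    blocks[[ch]] <- draw_block_boundaries(p_ch, config$ld_block_min,
                                          config$ld_block_max)
    p_anc <- stats::runif(p_ch, 0.05, 0.95)
    freq_list[[ch]] <- draw_population_frequencies(p_anc, config$fst)
  }
  truth <- resolve_ground_truth(config)
  geno <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    mats <- lapply(chroms, function(ch) {
      f <- freq_list[[ch]][, t]
      h1 <- draw_haplotypes(n_per_pop[t], f, blocks[[ch]],
                            config$within_block_rho)
      h2 <- draw_haplotypes(n_per_pop[t], f, blocks[[ch]],
                            config$within_block_rho)
      h1 + h2
    })
    geno[[t]] <- do.call(cbind, mats)
  }
  g <- do.call(rbind, geno)
  pop_of <- rep(pops$label, n_per_pop)
  variants <- data.frame(
    chrom = rep(chroms, config$n_snps_per_chrom),
    pos = unlist(lapply(config$n_snps_per_chrom, function(k)
      seq_len(k) * 1000L), use.names = FALSE),
    stringsAsFactors = FALSE)
  variants$id <- paste0("snp_", variants$chrom, "_",
                        unlist(lapply(config$n_snps_per_chrom, seq_len),
                               use.names = FALSE))
  variants$a1 <- "A"; variants$a2 <- "B"
  ds <- genotype_dataset(g, variants, provenance = "simulated")
  list(dataset = ds, population = pop_of,
       frequencies = do.call(rbind, freq_list), blocks = blocks,
       causal = truth)
}

#' Resolve the causal ground truth of a simulation config
#'
#' Draws the causal SNP indices (uniformly without replacement inside each
#' predefined range) and effect sizes. Shared causal SNPs receive the same
#' effect in every population; specific ones a nonzero effect only in theirs.
#'
#' @param config a [sim_config].
#' @return list with `causal_by_pop` (named list of global 1-based SNP
#'   indices), `shared` (indices causal in all populations), `specific`
#'   (named list, causal in exactly one), `beta` (p x T effect matrix) and
#'   `snp_index` bookkeeping.
#' @export
resolve_ground_truth <- function(config) {
  chroms <- names(config$n_snps_per_chrom)
  offsets <- c(0L, cumsum(as.integer(config$n_snps_per_chrom)))
  names(offsets) <- c(chroms, "end")
  p <- offsets[["end"]]
  labels <- config$populations$label
  Tn <- length(labels)
  beta <- matrix(0, p, Tn, dimnames = list(NULL, labels))
  causal_by_pop <- stats::setNames(rep(list(integer(0)), Tn), labels)
  if (!is.null(config$causal_spec)) {
    for (i in seq_len(nrow(config$causal_spec))) {
      cs <- config$causal_spec[i, ]
      # 1-based global SNP indices of the range
      rng <- (cs$start):(cs$end - 1L) + offsets[[as.character(cs$chrom)]] + 1L
      idx <- sort(sample(rng, cs$n_causal))
      labs <- strsplit(cs$populations, ",")[[1]]
      if (!length(labs)) labs <- labels
      eff <- stats::runif(cs$n_causal, config$effect_range[1],
                          config$effect_range[2]) *
        sample(c(-1, 1), cs$n_causal, replace = TRUE)
      for (lb in labs) {
        beta[idx, lb] <- eff   # same effect across populations
        causal_by_pop[[lb]] <- sort(union(causal_by_pop[[lb]], idx))
      }
    }
  }
  shared <- Reduce(intersect, causal_by_pop)
  specific <- lapply(labels, function(lb) {
    others <- unlist(causal_by_pop[setdiff(labels, lb)])
    setdiff(causal_by_pop[[lb]], others)
  })
  names(specific) <- labels
  list(causal_by_pop = causal_by_pop, shared = shared, specific = specific,
       beta = beta)
}

#' Simulate a phenotype over simulated genotypes
#'
#' Binary: the liability is the genotype-weighted sum of effects plus a
#' population intercept chosen by bisection so that the marginal case
#' probability matches the population's target case fraction; individuals
#' are then accepted by rejection sampling until the per-population case and
#' control targets are met exactly. Quantitative: y = X beta + Gaussian
#' noise.
#'
#' @param sim result of [simulate_genotypes] (a pool of genotypes).
#' @param config the [sim_config] used to generate it.
#' @param max_redraws bound on extra genotype pools drawn per population
#'   before giving up (binary only).
#' @return list with `dataset`, `pheno` ([phenotype_table]), `population`,
#'   `causal` (ground truth), `config`; class `simulated_study`.
#' @export
simulate_phenotype <- function(sim, config, max_redraws = 50) {
  truth <- sim$causal
  labels <- config$populations$label
  if (config$phenotype_kind == "quantitative") {
    g <- sim$dataset$genotypes
    y <- numeric(nrow(g))
    for (t in seq_along(labels)) {
      rows <- which(sim$population == labels[t])
      b <- truth$beta[, t]
      nz <- which(b != 0)
      xb <- if (length(nz))
        g[rows, nz, drop = FALSE] %*% b[nz] else numeric(length(rows))
      y[rows] <- xb + stats::rnorm(length(rows), 0, config$noise_sd)
    }
    out <- list(dataset = sim$dataset, pheno = phenotype_table(
      y, "quantitative", sim$dataset$samples$id),
      population = sim$population, causal = truth, config = config)
    class(out) <- "simulated_study"
    return(out)
  }
  # binary: per-population rejection sampling to exact case/control counts
  geno_kept <- list(); status <- list()
  for (t in seq_along(labels)) {
    ncase <- config$populations$n_cases[t]
    nctrl <- config$populations$n_controls[t]
    b <- truth$beta[, t]
    nz <- which(b != 0)
    target <- ncase / (ncase + nctrl)
    case_g <- NULL; ctrl_g <- NULL
    pool_g <- sim$dataset$genotypes[sim$population == labels[t], ,
                                    drop = FALSE]
    redraws <- 0
    repeat {
      xb <- if (length(nz))
        as.numeric(pool_g[, nz, drop = FALSE] %*% b[nz])
      else numeric(nrow(pool_g))
      ic <- intercept_for_prevalence(xb, target)
      st <- stats::rbinom(length(xb), 1, stats::plogis(xb + ic))
      need_case <- ncase - NROW(case_g)
      need_ctrl <- nctrl - NROW(ctrl_g)
      ic1 <- which(st == 1)[seq_len(min(need_case, sum(st == 1)))]
      ic0 <- which(st == 0)[seq_len(min(need_ctrl, sum(st == 0)))]
      case_g <- rbind(case_g, pool_g[ic1, , drop = FALSE])
      ctrl_g <- rbind(ctrl_g, pool_g[ic0, , drop = FALSE])
      if (NROW(case_g) >= ncase && NROW(ctrl_g) >= nctrl) break
      redraws <- redraws + 1
      if (redraws > max_redraws)
        stop("could not reach case:control targets for population ",
             labels[t], "; effect sizes may be too extreme")
      pool_g <- simulate_genotypes_pool(config, t, ncase + nctrl, sim)
    }
    geno_kept[[t]] <- rbind(case_g, ctrl_g)
    status[[t]] <- c(rep(1, ncase), rep(0, nctrl))
  }
  g <- do.call(rbind, geno_kept)
  rownames(g) <- NULL
  ds <- genotype_dataset(g, sim$dataset$variants,
                         provenance = "simulated case-control")
  out <- list(dataset = ds,
              pheno = phenotype_table(unlist(status), "binary",
                                      ds$samples$id),
              population = rep(labels, vapply(geno_kept, nrow, 1L)),
              causal = truth, config = config)
  class(out) <- "simulated_study"
  out
}

# extra genotype pool for one population (same frequencies/blocks)
simulate_genotypes_pool <- function(config, t, n, sim) {
  chroms <- names(config$n_snps_per_chrom)
  offsets <- c(0L, cumsum(as.integer(config$n_snps_per_chrom)))
  mats <- lapply(seq_along(chroms), function(k) {
    cols <- (offsets[k] + 1L):offsets[k + 1L]
    f <- sim$frequencies[cols, t]
    h1 <- draw_haplotypes(n, f, sim$blocks[[chroms[k]]],
                          config$within_block_rho)
    h2 <- draw_haplotypes(n, f, sim$blocks[[chroms[k]]],
                          config$within_block_rho)
    h1 + h2
  })
  do.call(cbind, mats)
}

# bisection on the logistic intercept so mean case probability hits target
intercept_for_prevalence <- function(xb, target) {
  f <- function(c) mean(stats::plogis(xb + c)) - target
  lo <- -30; hi <- 30
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate a complete multi-population GWAS study
#'
#' Convenience wrapper: draws genotypes (an oversampled pool for binary
#' phenotypes, so that rejection sampling can hit the case:control targets)
#' and the phenotype in one call.
#'
#' @param config a [sim_config].
#' @param seed integer seed; the study is a pure function of
#'   (config, seed).
#' @param oversample pool size multiplier for binary rejection sampling.
#' @return A `simulated_study` (see [simulate_phenotype]).
#' @export
simulate_study <- function(config, seed = 1, oversample = 1.4) {
  set.seed(seed)
  mult <- if (config$phenotype_kind == "binary") oversample else 1
  n_pool <- if (config$phenotype_kind == "binary")
    ceiling((config$populations$n_cases + config$populations$n_controls) *
              mult)
  else config$populations$n
  sim <- simulate_genotypes(config, n_per_pop = n_pool)
  simulate_phenotype(sim, config)
}

#' @exportS3Method base::print
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$dataset$genotypes), "samples x",
      ncol(x$dataset$genotypes), "SNPs;",
      length(unique(x$population)), "populations;",
      x$pheno$kind, "phenotype\n")
  n_causal <- length(unique(unlist(x$causal$causal_by_pop)))
  cat("  causal SNPs:", n_causal, "( shared:", length(x$causal$shared), ")\n")
  invisible(x)
}
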