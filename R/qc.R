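#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Chi-square goodness-of-fit (1 df) of the observed genotype counts against
#' the counts expected under Hardy-Weinberg proportions at the estimated
#' allele frequency. An exact (mid-p) test is available as an alternative.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @param method `"chisq"` (default) or `"exact"` (Levene-Haldane
#'   conditional distribution, mid-p).
#' @return p-value in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  if (method == "chisq") {
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    # conditional distribution of heterozygote count given allele counts
    nA <- 2 * n_AA + n_Aa
    nB <- 2 * n - nA
    het <- seq.int(nA %% 2, min(nA, nB), by = 2L)
    logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
      lgamma((nB - het) / 2 + 1) + het * log(2) +
      lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    p_obs <- pr[match(n_Aa, het)]
    # mid-p: probabilities strictly less extreme, equals at half weight
    min(1, sum(pr[pr < p_obs - 1e-12]) +
          0.5 * sum(pr[abs(pr - p_obs) <= 1e-12]))
  }
}

#' Quality-control filter for a genotype dataset
#'
#' Removes, in order: duplicate variants (same id, or same chromosome,
#' position and alleles; first occurrence kept), SNPs with minor allele
#' frequency below `maf_min`, SNPs departing from Hardy-Weinberg equilibrium
#' in controls at `hwe_p_min` (binary phenotypes only; controls are phenotype
#' 0), SNPs with missingness above `snp_miss_max`, then samples with
#' missingness above `sample_miss_max` (computed over retained SNPs).
#'
#' @param ds a [genotype_dataset].
#' @param pheno a [phenotype_table] (needed for the HWE-in-controls rule).
#' @param maf_min,hwe_p_min,snp_miss_max,sample_miss_max thresholds; defaults
#'   are MAF 5%, HWE p 1e-4, and 10% missingness for SNPs and samples.
#' @return list with elements `dataset` (filtered [genotype_dataset]),
#'   `pheno` (filtered phenotypes) and `report` (class `qc_report`: removal
#'   counts per rule and the thresholds used).
#' @export
qc_filter <- function(ds, pheno = NULL, maf_min = 0.05, hwe_p_min = 1e-4,
                      snp_miss_max = 0.10, sample_miss_max = 0.10) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  vr <- ds$variants
  n0 <- nrow(g); p0 <- ncol(g)

  dup <- duplicated(vr$id) |
    duplicated(paste(vr$chrom, vr$pos, vr$a1, vr$a2, sep = ":"))
  n_dup <- sum(dup)
  keep <- !dup

  maf <- function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    if (is.nan(f)) return(0)
    min(f, 1 - f)
  }
  mafs <- apply(g, 2, maf)
  fail_maf <- keep & (mafs < maf_min)
  n_maf <- sum(fail_maf)
  keep <- keep & !fail_maf

  n_hwe <- 0L
  if (!is.null(pheno) && pheno$kind == "binary") {
    ctrl <- pheno$values == 0
    if (any(ctrl)) {
      hwe_p <- apply(g[ctrl, , drop = FALSE], 2, function(col) {
        col <- col[!is.na(col)]
        hwe_test(sum(col == 2), sum(col == 1), sum(col == 0))
      })
      fail_hwe <- keep & (hwe_p < hwe_p_min)
      n_hwe <- sum(fail_hwe)
      keep <- keep & !fail_hwe
    }
  }

  snp_miss <- colMeans(is.na(g))
  fail_miss <- keep & (snp_miss > snp_miss_max)
  n_miss <- sum(fail_miss)
  keep <- keep & !fail_miss

  if (!any(keep)) stop("qc_filter removed every SNP")
  g2 <- g[, keep, drop = FALSE]

  sample_miss <- rowMeans(is.na(g2))
  keep_s <- sample_miss <= sample_miss_max
  n_smiss <- sum(!keep_s)
  if (!any(keep_s)) stop("qc_filter removed every sample")

  out <- genotype_dataset(g2[keep_s, , drop = FALSE],
                          vr[keep, , drop = FALSE],
                          ds$samples[keep_s, , drop = FALSE],
                          provenance = paste0(ds$provenance, " [qc]"))
  ph2 <- pheno
  if (!is.null(pheno)) {
    ph2 <- phenotype_table(pheno$values[keep_s], pheno$kind,
                           pheno$sample_ids[keep_s])
  }
  report <- structure(list(
    snps_in = p0, snps_out = ncol(out$genotypes),
    samples_in = n0, samples_out = nrow(out$genotypes),
    removed = c(duplicates = n_dup, maf = n_maf, hwe = n_hwe,
                snp_missingness = n_miss, sample_missingness = n_smiss),
    thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   snp_miss_max = snp_miss_max,
                   sample_miss_max = sample_miss_max)),
    class = "qc_report")
  list(dataset = out, pheno = ph2, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report:", x$snps_in, "->", x$snps_out, "SNPs;",
      x$samples_in, "->", x$samples_out, "samples\n")
  print(x$removed)
  invisible(x)
}

#' Box-Cox transform of a quantitative phenotype
#'
#' Profile-likelihood choice of the power parameter over the grid
#' lambda in \[-2, 2\] with step 0.01 (the lambda = 0 branch is the log
#' transform). Non-positive values are shifted by `min + eps` first and the
#' shift is recorded. A constant vector is returned untouched with a warning.
#'
#' @param y numeric vector.
#' @return list with `values` (transformed vector), `lambda`, `shift`.
#' @export
box_cox <- function(y) {
  stopifnot(is.numeric(y), length(y) >= 2)
  if (stats::sd(y) == 0) {
    warning("constant phenotype: Box-Cox skipped, identity transform")
    return(list(values = y, lambda = 1, shift = 0))
  }
  shift <- 0
  if (any(y <= 0)) {
    shift <- -min(y) + 1e-6 * max(abs(y), 1)
    y <- y + shift
  }
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, by = 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  values <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(values = values, lambda = lambda, shift = shift)
}
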