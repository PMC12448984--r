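#' Construct a genotype dataset
#'
#' Container for an n samples x p SNPs allele-count matrix (values 0, 1, 2 or
#' `NA` for missing) together with variant and sample metadata, the unit all
#' other functions in the package operate on.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `a1`, `a2`; one row per SNP in column order. Generated if missing.
#' @param samples data frame with column `id`, one row per sample.
#'   Generated if missing.
#' @param provenance free-text source tag.
#' @return An object of class `genotype_dataset` with elements `genotypes`,
#'   `variants`, `samples`, `provenance`.
#' @export
genotype_dataset <- function(genotypes, variants = NULL, samples = NULL,
                             provenance = "in-memory") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes); p <- ncol(genotypes)
  if (n < 1L || p < 1L) stop("genotype_dataset needs n >= 1 and p >= 1")
  if (!all(is.na(genotypes))) {
    rng <- range(genotypes, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 2L)
      stop("genotype values must be 0, 1, 2 or NA")
  }
  if (is.null(variants)) {
    variants <- data.frame(chrom = rep("1", p), pos = seq_len(p),
                           id = paste0("snp", seq_len(p)),
                           a1 = rep("A", p), a2 = rep("B", p),
                           stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(id = paste0("sample", seq_len(n)),
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(variants) == p, nrow(samples) == n)
  structure(list(genotypes = genotypes, variants = variants,
                 samples = samples, provenance = provenance),
            class = "genotype_dataset")
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "SNPs (", x$provenance, ")\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  chromosomes: %s; missing rate: %.4f\n",
              paste(unique(x$variants$chrom), collapse = ", "), miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset
#'
#' Decodes the SNP-major 2-bit `.bed` format. Genotypes are returned as counts
#' of allele 1 of the `.bim` file (the usual minor/effect allele convention):
#' code `00` is two copies of allele 1, `10` one copy, `11` zero copies, and
#' `01` is missing (`NA`).
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_dataset].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  vr <- utils::read.table(bim, stringsAsFactors = FALSE,
                          col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                          colClasses = c("character", "character", "numeric",
                                         "integer", "character", "character"))
  sm <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(sm); p <- nrow(vr)
  bps <- (n + 3L) %/% 4L             # bytes per SNP
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], PLINK_MAGIC))
    stop("bad .bed magic bytes: not a SNP-major PLINK 1 binary file")
  payload <- raw[-(1:3)]
  if (length(payload) != bps * p)
    stop("corrupt .bed: payload has ", length(payload),
         " bytes, expected ", bps * p)
  bytes <- matrix(as.integer(payload), nrow = bps, ncol = p)
  # decode 2-bit codes, sample s in bits (2s-2, 2s-1) of byte ceiling(s/4)
  decode <- c(2L, NA_integer_, 1L, 0L)  # codes 00, 01, 10, 11
  geno <- matrix(NA_integer_, nrow = n, ncol = p)
  for (k in 0:3) {
    if (k + 1L > n) next
    rows <- seq.int(k + 1L, n, by = 4L)
    byte_rows <- ((rows - 1L) %/% 4L) + 1L
    codes <- bitwAnd(bitwShiftR(bytes[byte_rows, , drop = FALSE], 2L * k), 3L)
    geno[rows, ] <- decode[codes + 1L]
  }
  variants <- vr[, c("chrom", "pos", "id", "a1", "a2")]
  samples <- data.frame(id = as.character(sm[[2]]), stringsAsFactors = FALSE)
  genotype_dataset(geno, variants, samples, provenance = prefix)
}

#' Write a PLINK 1 binary fileset
#'
#' Emits a bit-exact SNP-major `.bed` (magic bytes `6c 1b 01`) with matching
#' `.bim` and `.fam`; [read_plink] inverts it. Missing genotypes are written
#' as the PLINK missing code (`01`).
#'
#' @param ds a [genotype_dataset].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  n <- nrow(g); p <- ncol(g)
  vr <- ds$variants
  utils::write.table(
    data.frame(vr$chrom, vr$id, 0, vr$pos, vr$a1, vr$a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ds$samples$id, ds$samples$id, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  encode <- function(v) { # counts -> 2-bit codes
    out <- integer(length(v))
    out[is.na(v)] <- 1L
    out[!is.na(v) & v == 2L] <- 0L
    out[!is.na(v) & v == 1L] <- 2L
    out[!is.na(v) & v == 0L] <- 3L
    out
  }
  bps <- (n + 3L) %/% 4L
  codes <- matrix(0L, nrow = 4L * bps, ncol = p)
  codes[seq_len(n), ] <- apply(g, 2L, encode)
  idx <- seq.int(1L, 4L * bps, by = 4L)
  bytes <- codes[idx, , drop = FALSE] +
    bitwShiftL(codes[idx + 1L, , drop = FALSE], 2L) +
    bitwShiftL(codes[idx + 2L, , drop = FALSE], 4L) +
    bitwShiftL(codes[idx + 3L, , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Construct a phenotype table
#'
#' @param values numeric vector, binary 0/1 or quantitative.
#' @param kind `"binary"` or `"quantitative"`; guessed from the values when
#'   missing.
#' @param sample_ids character vector aligned to the genotype samples.
#' @return Object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, kind = NULL, sample_ids = NULL) {
  values <- as.numeric(values)
  if (is.null(kind))
    kind <- if (all(values %in% c(0, 1))) "binary" else "quantitative"
  kind <- match.arg(kind, c("binary", "quantitative"))
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary phenotype must contain only 0/1")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(values))
  structure(list(values = values, kind = kind,
                 sample_ids = as.character(sample_ids)),
            class = "phenotype_table")
}

#' Read a phenotype TSV (columns sample_id, phenotype)
#' @param path file path.
#' @param kind optional phenotype kind override.
#' @return A [phenotype_table].
#' @export
read_phenotype <- function(path, kind = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  phenotype_table(d$phenotype, kind = kind, sample_ids = d$sample_id)
}

#' Write a phenotype TSV
#' @param pheno a [phenotype_table].
#' @param path output path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(
    data.frame(sample_id = pheno$sample_ids, phenotype = pheno$values),
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
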