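#' Banded linkage-disequilibrium (r-squared) matrix
#'
#' Squared Pearson correlation of mean-imputed genotype dosages between SNP
#' pairs at most `bandwidth` positions apart, computed per chromosome.
#' Zero-variance SNPs have r-squared 0 against all others.
#'
#' @param ds a [genotype_dataset] or numeric matrix (single chromosome).
#' @param bandwidth band half-width in SNPs.
#' @return A named list of class `similarity_band`, one `bandwidth x p_ch`
#'   matrix per chromosome; entry `[d, j]` is r-squared between SNPs j and
#'   j + d of that chromosome (0 beyond the end).
#' @export
banded_r2 <- function(ds, bandwidth = 100) {
  stopifnot(bandwidth >= 1)
  if (inherits(ds, "genotype_dataset")) {
    chroms <- unique(ds$variants$chrom)
    cols <- lapply(chroms, function(ch) which(ds$variants$chrom == ch))
    g <- ds$genotypes
  } else {
    chroms <- "1"
    cols <- list(seq_len(ncol(ds)))
    g <- ds
  }
  out <- lapply(cols, function(cl) {
    X <- standardize_genotypes(g[, cl, drop = FALSE])
    n <- nrow(X); p <- ncol(X)
    band <- matrix(0, bandwidth, p)
    for (d in seq_len(min(bandwidth, p - 1))) {
      r <- colSums(X[, 1:(p - d), drop = FALSE] *
                     X[, (1 + d):p, drop = FALSE]) / (n - 1)
      band[d, 1:(p - d)] <- r^2
    }
    band
  })
  names(out) <- chroms
  structure(out, bandwidth = bandwidth, class = "similarity_band")
}

#' Greedy LD pruning
#'
#' Left-to-right scan with windows of `window` SNPs sliding by half their
#' span: whenever a retained pair within the window has r-squared above
#' `r2_cutoff`, the SNP with the lower minor allele frequency is removed
#' (ties remove the right one). Applied per chromosome.
#'
#' @param ds a [genotype_dataset].
#' @param r2_cutoff removal threshold in (0, 1).
#' @param window window width in SNPs.
#' @return The pruned [genotype_dataset].
#' @export
ld_prune <- function(ds, r2_cutoff = 0.85, window = 50) {
  stopifnot(r2_cutoff > 0, r2_cutoff < 1)
  g <- ds$genotypes
  keep <- rep(TRUE, ncol(g))
  mafs <- apply(g, 2, function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  for (ch in unique(ds$variants$chrom)) {
    cl <- which(ds$variants$chrom == ch)
    p <- length(cl)
    step <- max(1L, window %/% 2L)
    starts <- unique(c(seq.int(1L, max(1L, p - window + 1L), by = step)))
    for (s in starts) {
      idx <- cl[s:min(s + window - 1L, p)]
      idx <- idx[keep[idx]]
      if (length(idx) < 2) next
      X <- standardize_genotypes(g[, idx, drop = FALSE])
      r2 <- suppressWarnings(stats::cor(X))^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      repeat {
        mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[mx[1], mx[2]] <= r2_cutoff) break
        a <- idx[mx[1]]; b <- idx[mx[2]]
        drop_local <- if (mafs[a] < mafs[b]) mx[1]
        else if (mafs[b] < mafs[a]) mx[2]
        else max(mx)                     # tie: the right one
        keep[idx[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
  }
  genotype_dataset(g[, keep, drop = FALSE],
                   ds$variants[keep, , drop = FALSE], ds$samples,
                   provenance = paste0(ds$provenance, " [pruned]"))
}

#' Adjacency-constrained Ward clustering of one chromosome
#'
#' Agglomerative Ward-style clustering in which only adjacent clusters may
#' merge, on the dissimilarity d = 1 - r-squared (pairs beyond the band at
#' d = 1). Ties are broken by the leftmost pair. Returns the full merge
#' history; use [cut_partition] to extract LD-groups.
#'
#' @param band one chromosome's matrix from [banded_r2] (or a
#'   `similarity_band` of length 1).
#' @param chrom chromosome label attached to the result.
#' @return object of class `ld_dendrogram`: `merge` (hclust convention),
#'   `height` (Ward merge costs), `p`, `band`, `chrom`.
#' @export
constrained_ward <- function(band, chrom = "1") {
  if (inherits(band, "similarity_band")) {
    stopifnot(length(band) == 1)
    chrom <- names(band)
    band <- band[[1]]
  }
  p <- ncol(band)
  d <- ld_dendro_cpp(band)
  structure(list(merge = d$merge, height = as.numeric(d$height), p = p,
                 band = band, chrom = chrom),
            class = "ld_dendrogram")
}

#' Cut a dendrogram into an LD-group partition
#'
#' `fixed_K` performs an exact segmentation: dynamic programming over all
#' contiguous partitions of the chromosome into K groups, minimizing the
#' total within-cluster Ward cost implied by the banded dissimilarities.
#' `height_gap` first picks K at the largest relative jump of the
#' dendrogram's merge heights (K restricted to \[p/200, p/5\]) and then
#' applies the same exact K-segmentation.
#'
#' @param dend an `ld_dendrogram`.
#' @param criterion `"height_gap"` or `"fixed_K"`.
#' @param K group count for `fixed_K`.
#' @param min_size minimum group size (SNPs) enforced by the segmentation.
#' @param max_size maximum group size (`Inf` = unconstrained).
#' @return A single-chromosome [ld_partition].
#' @export
cut_partition <- function(dend, criterion = c("height_gap", "fixed_K"),
                          K = NULL, min_size = 1, max_size = Inf) {
  criterion <- match.arg(criterion)
  p <- dend$p
  if (criterion == "fixed_K") {
    if (is.null(K)) stop("fixed_K needs K")
    if (K > p) stop("K cannot exceed the number of SNPs")
  } else {
    kmin <- max(2L, ceiling(p / 200))
    kmax <- max(kmin, floor(p / 5))
    h <- sort(dend$height)  # greedy merge costs, ascending
    m <- length(h)
    ks <- p - seq_len(m - 1L)   # cutting between h[i] and h[i+1] leaves K
    ok <- ks >= kmin & ks <= kmax
    if (!any(ok)) {
      K <- min(max(kmin, 2L), p)
    } else {
      jump <- (h[-1] - h[-m]) / pmax(h[-m], 1e-12)
      jump[!ok] <- -Inf
      K <- ks[which.max(jump)]
    }
  }
  mx <- if (is.finite(max_size)) as.integer(max_size) else 0L
  bnd <- ld_dp_cut_cpp(dend$band, as.integer(K), as.integer(min_size), mx)
  make_partition(stats::setNames(list(as.integer(bnd)), dend$chrom))
}

#' Build an LD-group partition from per-chromosome boundaries
#'
#' @param boundaries named list (chromosome -> integer vector of 0-based,
#'   half-open group boundaries starting at 0 and ending at p_chrom).
#' @return object of class `ld_partition`: data frame with columns `chrom`,
#'   `start`, `end` (0-based local indices, half-open), `group` (global id),
#'   `p_g`; attributes `p_per_chrom` and `G`.
#' @export
make_partition <- function(boundaries) {
  rows <- lapply(names(boundaries), function(ch) {
    b <- boundaries[[ch]]
    stopifnot(b[1] == 0, all(diff(b) > 0))
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$group <- seq_len(nrow(df))
  df$p_g <- df$end - df$start
  structure(df,
            p_per_chrom = vapply(boundaries, function(b) b[length(b)], 1L),
            G = nrow(df),
            class = c("ld_partition", "data.frame"))
}

#' Per-SNP group ids of a partition
#'
#' @param part an [ld_partition].
#' @return integer vector of length p (SNPs in chromosome-block order)
#'   giving each SNP's group id.
#' @export
group_ids <- function(part) {
  rep(part$group, part$p_g)
}

#' Merge LD-group partitions across populations
#'
#' The shared partition is the common refinement: per chromosome, the union
#' of all populations' group boundaries. Every input group is a union of
#' shared groups, so the result still covers each chromosome with
#' contiguous, non-overlapping, exhaustive groups.
#'
#' @param parts list of [ld_partition] objects over the same SNPs.
#' @return The merged [ld_partition].
#' @export
merge_partitions <- function(parts) {
  stopifnot(length(parts) >= 1)
  ref <- attr(parts[[1]], "p_per_chrom")
  for (pt in parts) {
    pc <- attr(pt, "p_per_chrom")
    if (!identical(sort(names(pc)), sort(names(ref))) ||
        !all(pc[names(ref)] == ref))
      stop("partitions cover different SNP universes")
  }
  bl <- lapply(names(ref), function(ch) {
    b <- sort(unique(unlist(lapply(parts, function(pt)
      c(pt$start[pt$chrom == ch], pt$end[pt$chrom == ch])))))
    as.integer(b)
  })
  names(bl) <- names(ref)
  make_partition(bl)
}

#' Estimate shared LD-groups for a multi-population dataset
#'
#' The grouping stage of the pipeline: for every population and chromosome,
#' compute the banded r-squared, cluster with [constrained_ward], cut with
#' [cut_partition], then merge the per-population partitions into the shared
#' partition by boundary union.
#'
#' @param ds a [genotype_dataset].
#' @param tasks a `task_assignment`.
#' @param bandwidth band half-width in SNPs.
#' @param criterion `"fixed_size"` (default) cuts each chromosome into
#'   `round(p_chrom / target_size)` groups, targeting the LD-group scale
#'   (tens of SNPs) the model is designed around; `"height_gap"` and
#'   `"fixed_K"` are passed to [cut_partition].
#' @param K group count per chromosome for `criterion = "fixed_K"`.
#' @param target_size mean group size (SNPs) for `criterion = "fixed_size"`.
#' @param min_size minimum group size; tiny groups (a few SNPs) defeat
#'   group-level selection and inflate false discoveries, so the pipeline
#'   enforces a floor of a quarter of `target_size` by default.
#' @return list with `per_population` (list of [ld_partition]) and `shared`.
#' @export
ld_groups <- function(ds, tasks, bandwidth = 100,
                      criterion = c("fixed_size", "height_gap", "fixed_K"),
                      K = NULL, target_size = 40,
                      min_size = max(1L, round(target_size / 4)),
                      max_size = 2 * target_size) {
  criterion <- match.arg(criterion)
  parts <- lapply(seq_len(tasks$T), function(t) {
    sub <- genotype_dataset(
      ds$genotypes[tasks$task == t, , drop = FALSE],
      ds$variants, ds$samples[tasks$task == t, , drop = FALSE],
      provenance = ds$provenance)
    band <- banded_r2(sub, bandwidth)
    cuts <- lapply(names(band), function(ch) {
      dend <- constrained_ward(band[[ch]], chrom = ch)
      pt <- if (criterion == "fixed_size")
        cut_partition(dend, "fixed_K",
                      K = max(1L, round(dend$p / target_size)),
                      min_size = min_size, max_size = max_size)
      else cut_partition(dend, criterion, K, min_size = min_size,
                         max_size = max_size)
      c(pt$start[1], pt$end)
    })
    names(cuts) <- names(band)
    make_partition(cuts)
  })
  shared <- merge_partitions(parts)
  if (min_size > 1) {
    pooled <- banded_r2(ds, bandwidth)
    shared <- absorb_small_groups(shared, pooled, min_size)
  }
  list(per_population = parts, shared = shared)
}

# Merge groups smaller than min_size into the adjacent group (same
# chromosome) with the higher mean cross-boundary r^2. The boundary-union
# of per-population partitions produces sub-scale fragments wherever
# nearly-coincident boundaries differ by a few SNPs; fragments that small
# defeat group-level selection, so the pipeline absorbs them.
absorb_small_groups <- function(part, band, min_size) {
  bw <- attr(band, "bandwidth")
  cross_r2 <- function(ch, a_start, a_end, b_start, b_end) {
    # mean within-band r^2 between [a_start,a_end) and [b_start,b_end)
    bm <- band[[ch]]
    tot <- 0; cnt <- 0
    for (i in seq.int(a_start + 1L, a_end)) {
      for (j in seq.int(b_start + 1L, b_end)) {
        d <- abs(j - i)
        if (d >= 1 && d <= bw) {
          tot <- tot + bm[d, min(i, j)]
          cnt <- cnt + 1
        }
      }
    }
    if (cnt == 0) 0 else tot / cnt
  }
  df <- as.data.frame(part)[, c("chrom", "start", "end")]
  repeat {
    sz <- df$end - df$start
    small <- which(sz < min_size)
    if (!length(small)) break
    i <- small[which.min(sz[small])]
    left <- if (i > 1 && df$chrom[i - 1] == df$chrom[i]) i - 1L else NA
    right <- if (i < nrow(df) && df$chrom[i + 1] == df$chrom[i]) i + 1L
    else NA
    if (is.na(left) && is.na(right)) break  # single-group chromosome
    pick <- if (is.na(left)) right
    else if (is.na(right)) left
    else {
      rl <- cross_r2(df$chrom[i], df$start[left], df$end[left],
                     df$start[i], df$end[i])
      rr <- cross_r2(df$chrom[i], df$start[i], df$end[i],
                     df$start[right], df$end[right])
      if (rl >= rr) left else right
    }
    if (pick < i) {
      df$end[pick] <- df$end[i]
    } else {
      df$start[pick] <- df$start[i]
    }
    df <- df[-i, , drop = FALSE]
  }
  bl <- lapply(unique(df$chrom), function(ch) {
    rows <- df[df$chrom == ch, ]
    as.integer(c(rows$start[1], rows$end))
  })
  names(bl) <- unique(df$chrom)
  make_partition(bl)
}

#' Write an LD-group partition as TSV
#' @param part an [ld_partition].
#' @param path output path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(as.data.frame(part)[, c("chrom", "start", "end",
                                             "group", "p_g")],
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
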