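#' Aggregate cells into per-sample pseudo-bulk profiles
#'
#' Sums raw counts over the cells of each sample, scales each sample to
#' counts-per-million, and returns `log2(CPM + 1)`. Summing before
#' normalization makes the profile robust to per-cell depth variation;
#' duplicating every cell leaves the result unchanged.
#'
#' @param x a [count_matrix()].
#' @param sample_labels per-cell sample labels; defaults to `x$cell_sample`.
#' @return a `pseudobulk` object: list with `logcpm` (genes x samples dense
#'   matrix) and `samples` (character vector of sample names).
#' @export
aggregate_pseudobulk <- function(x, sample_labels = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(sample_labels)) sample_labels <- x$cell_sample
  if (is.null(sample_labels)) stop("no sample labels available")
  sample_labels <- as.character(sample_labels)
  stopifnot(length(sample_labels) == ncol(x$counts))
  if (anyNA(sample_labels)) stop("every cell must be labeled")
  groups <- sort(unique(sample_labels))
  design <- Matrix::sparseMatrix(
    i = seq_along(sample_labels),
    j = match(sample_labels, groups),
    x = 1, dims = c(length(sample_labels), length(groups))
  )
  sums <- as.matrix(x$counts %*% design)
  colnames(sums) <- groups
  tot <- colSums(sums)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(groups[tot == 0], collapse = ", "))
  cpm <- sweep(sums, 2, tot, "/") * 1e6
  structure(list(logcpm = log2(cpm + 1), samples = groups),
            class = "pseudobulk")
}

#' Principal component analysis of pseudo-bulk profiles
#'
#' Centered (unscaled) SVD of the samples x genes matrix, the standard view
#' for asking which axis of the design (e.g. time since grafting vs host
#' region) dominates sample-level variation.
#'
#' @param pb a `pseudobulk` object or a genes x samples matrix.
#' @param n_components number of components to keep.
#' @param top_genes optional: restrict to this many top-variance genes
#'   before the SVD (default all genes).
#' @return list: `coords` (samples x components), `var_explained`
#'   (fractions, non-increasing), `sdev`.
#' @export
pseudobulk_pca <- function(pb, n_components = 2, top_genes = NULL) {
  m <- if (inherits(pb, "pseudobulk")) pb$logcpm else as.matrix(pb)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (n_components > min(dim(m)))
    stop("n_components exceeds min(genes, samples)")
  if (!is.null(top_genes) && top_genes < nrow(m)) {
    v <- apply(m, 1, stats::var)
    m <- m[order(v, decreasing = TRUE)[seq_len(top_genes)], , drop = FALSE]
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(min(n_components, ncol(pc$x)))
  list(coords = pc$x[, k, drop = FALSE], var_explained = ve[k],
       sdev = pc$sdev)
}

#' Transcriptome-distance clustering of samples
#'
#' Pairwise distance `1 - Pearson r` between log-CPM profiles, clustered by
#' average-linkage hierarchical clustering — the unbiased sample-similarity
#' view used to ask whether grafts group by time or by host region.
#'
#' @param pb a `pseudobulk` object or genes x samples matrix.
#' @return list: `distance` (samples x samples, zero diagonal, symmetric),
#'   `hclust` (the linkage tree).
#' @export
distance_cluster <- function(pb) {
  m <- if (inherits(pb, "pseudobulk")) pb$logcpm else as.matrix(pb)
  if (ncol(m) < 2) stop("need at least 2 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant profile (zero variance) for sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(m)
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  list(distance = d,
       hclust = stats::hclust(stats::as.dist(d), method = "average"))
}

#' Map samples onto a reference expression panel by rank correlation
#'
#' Spearman correlation between each query sample and each reference
#' condition over their shared genes (optionally the panel's top-variance
#' genes), with the per-sample best match. Rank correlation makes the map
#' invariant to monotone differences in scale between query and panel.
#'
#' @param pb a `pseudobulk` object or genes x samples matrix (rows named by
#'   gene).
#' @param panel genes x reference-conditions matrix (rows named by gene).
#' @param top_genes optional: use this many top-variance panel genes.
#' @param min_shared minimum shared genes required (default 50).
#' @return list (`correlation_map`): `rho` (samples x references Spearman
#'   matrix), `best_match` (named character vector), `n_shared`.
#' @export
correlate_to_reference <- function(pb, panel, top_genes = NULL,
                                   min_shared = 50) {
  m <- if (inherits(pb, "pseudobulk")) pb$logcpm else as.matrix(pb)
  panel <- as.matrix(panel)
  shared <- intersect(rownames(m), rownames(panel))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes (minimum ", min_shared, ")")
  p <- panel[shared, , drop = FALSE]
  if (!is.null(top_genes) && top_genes < nrow(p)) {
    v <- apply(p, 1, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(top_genes)]
    p <- p[keep, , drop = FALSE]
    shared <- rownames(p)
  }
  rho <- stats::cor(m[shared, , drop = FALSE], p, method = "spearman")
  best <- colnames(p)[apply(rho, 1, which.max)]
  names(best) <- rownames(rho)
  list(rho = rho, best_match = best, n_shared = length(shared))
}
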