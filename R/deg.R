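#' Default DEG filter thresholds
#'
#' The standard single-cell DEG filter triple: BH-adjusted p below `alpha`,
#' expression fraction (PCT) above `min_pct` in at least one group, and
#' absolute log2 fold change above `min_abs_log2fc`.
#'
#' @param alpha significance level on adjusted p (default 0.05).
#' @param min_pct minimum expression fraction (default 0.1).
#' @param min_abs_log2fc minimum |log2FC| (default 0.25).
#' @param pct_mode `"max"` (either group may exceed `min_pct`; default) or
#'   `"min"` (both groups must).
#' @return a `deg_thresholds` list.
#' @export
deg_thresholds <- function(alpha = 0.05, min_pct = 0.1,
                           min_abs_log2fc = 0.25,
                           pct_mode = c("max", "min")) {
  stopifnot(alpha > 0, alpha < 1, min_pct >= 0, min_pct < 1,
            min_abs_log2fc >= 0)
  structure(list(alpha = alpha, min_pct = min_pct,
                 min_abs_log2fc = min_abs_log2fc,
                 pct_mode = match.arg(pct_mode)),
            class = "deg_thresholds")
}

#' Log-normalize counts
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p` —
#' the normalization on which the rank test and fold changes operate.
#'
#' @param counts genes x cells matrix (sparse or dense).
#' @param scale_factor per-cell total after scaling (default 1e4).
#' @return dense genes x cells matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cell(s) with zero total counts")
  m <- as.matrix(counts)
  log1p(sweep(m, 2, scale_factor / tot, "*"))
}

# Two-sided Wilcoxon rank-sum p for one gene.
# values: combined vector; is_a: logical group-A membership.
# Exact path enumerates all C(n, nA) group-A rank assignments (used when both
# groups have <= exact_limit observations); otherwise normal approximation
# with tie correction and continuity correction.
wilcoxon_p <- function(values, is_a, exact_limit = 10,
                       subsets = NULL) {
  n <- length(values)
  na <- sum(is_a)
  nb <- n - na
  rk <- rank(values)
  w <- sum(rk[is_a])
  e <- na * (n + 1) / 2
  if (na <= exact_limit && nb <= exact_limit) {
    if (is.null(subsets)) subsets <- utils::combn(n, na)
    sums <- colSums(matrix(rk[subsets], nrow = na))
    return(mean(abs(sums - e) >= abs(w - e) - 1e-9))
  }
  ties <- table(rk)
  sigma2 <- na * nb / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all values tied
  z <- (abs(w - e) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(0, z)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on log-normalized
#' expression (normal approximation with tie correction; exhaustive exact
#' enumeration when both groups have at most `exact_limit` cells), the
#' pseudocounted fold change
#' `log2((meanA + 1) / (meanB + 1))` on de-logged normalized group means,
#' the per-group expression fractions, BH-adjusted p-values, and pass flags
#' under `thresholds`.
#'
#' @param x a [count_matrix()] (raw counts).
#' @param cells_a,cells_b disjoint, nonempty column indices/names/logicals.
#' @param thresholds a [deg_thresholds()].
#' @param scale_factor per-cell normalization total (default 1e4).
#' @param exact_limit largest group size for the exact enumeration path.
#' @return a `deg_table` data frame: gene, log2fc, p, p_adj, pct1, pct2,
#'   passes.
#' @export
wilcoxon_deg <- function(x, cells_a, cells_b,
                         thresholds = deg_thresholds(),
                         scale_factor = 1e4, exact_limit = 10) {
  stopifnot(inherits(x, "count_matrix"))
  resolve <- function(idx) {
    if (is.character(idx)) idx <- match(idx, colnames(x$counts))
    if (is.logical(idx)) idx <- which(idx)
    if (anyNA(idx) || length(idx) == 0) stop("empty or unresolvable group")
    idx
  }
  a <- resolve(cells_a)
  b <- resolve(cells_b)
  if (length(intersect(a, b))) stop("groups overlap")
  sel <- c(a, b)
  norm <- log_normalize(x$counts[, sel, drop = FALSE],
                        scale_factor = scale_factor)
  na <- length(a)
  is_a <- seq_along(sel) <= na
  n <- length(sel)
  subsets <- if (na <= exact_limit && (n - na) <= exact_limit)
    utils::combn(n, na) else NULL

  expA <- expm1(norm[, is_a, drop = FALSE])
  expB <- expm1(norm[, !is_a, drop = FALSE])
  mean_a <- rowMeans(expA)
  mean_b <- rowMeans(expB)
  pct1 <- rowMeans(expA > 0)
  pct2 <- rowMeans(expB > 0)
  p <- vapply(seq_len(nrow(norm)), function(g)
    wilcoxon_p(norm[g, ], is_a, exact_limit = exact_limit,
               subsets = subsets),
    numeric(1))
  out <- data.frame(
    gene = rownames(norm),
    log2fc = log2((mean_a + 1) / (mean_b + 1)),
    p = p,
    p_adj = bh_adjust(p),
    pct1 = pct1,
    pct2 = pct2,
    stringsAsFactors = FALSE
  )
  out$passes <- deg_passes(out, thresholds)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj(i) = min_{k >= rank(i)} ( p(k) * m / k )`, capped at 1, returned
#' in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NAs are rejected.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA p-values")
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[order(o)]
}

# pass flags for a deg table under thresholds
deg_passes <- function(records, thresholds) {
  pct <- if (thresholds$pct_mode == "max")
    pmax(records$pct1, records$pct2) else pmin(records$pct1, records$pct2)
  records$p_adj < thresholds$alpha &
    pct > thresholds$min_pct &
    abs(records$log2fc) > thresholds$min_abs_log2fc
}

#' Filter a DEG table by the standard threshold triple
#'
#' @param records a `deg_table` (from [wilcoxon_deg()]).
#' @param thresholds a [deg_thresholds()].
#' @return list: `records` (the rows passing all criteria, with refreshed
#'   `passes`), `n_pass`.
#' @export
filter_deg <- function(records, thresholds = deg_thresholds()) {
  stopifnot(is.data.frame(records),
            all(c("gene", "log2fc", "p_adj", "pct1", "pct2") %in%
                  names(records)))
  pass <- deg_passes(records, thresholds)
  records$passes <- pass
  list(records = records[pass, , drop = FALSE], n_pass = sum(pass))
}

#' Write a DEG table as TSV
#'
#' @param records a `deg_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
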