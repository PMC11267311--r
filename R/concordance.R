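#' Fold-change quadrant analysis across two comparisons
#'
#' Classifies each shared gene by the signs of its log2 fold changes in two
#' comparisons: quadrant I (+,+), II (-,+), III (-,-), IV (+,-); genes with
#' either coordinate exactly zero go to an explicit `axis` category.
#' Dominance of quadrants I and III (and a strong positive correlation)
#' indicates concordant regulation between the two comparisons — e.g. that
#' host-region differences in grafted cells mirror those of the host brain.
#'
#' @param fc_x,fc_y equal-length log2FC vectors over the same genes.
#' @param genes gene IDs; defaults to names of `fc_x` or an index.
#' @param method correlation flavor: `"pearson"` (default) or `"spearman"`.
#' @return a `quadrant_summary` list: `quadrant` (per-gene factor), `counts`
#'   (named I/II/III/IV/axis, summing to n), `r`, `genes_by_quadrant`.
#' @export
quadrant_analysis <- function(fc_x, fc_y, genes = NULL,
                              method = c("pearson", "spearman")) {
  if (length(fc_x) != length(fc_y)) stop("fold-change vectors differ in length")
  if (length(fc_x) < 2) stop("need at least 2 genes")
  method <- match.arg(method)
  if (is.null(genes))
    genes <- if (!is.null(names(fc_x))) names(fc_x)
             else as.character(seq_along(fc_x))
  q <- rep("axis", length(fc_x))
  q[fc_x > 0 & fc_y > 0] <- "I"
  q[fc_x < 0 & fc_y > 0] <- "II"
  q[fc_x < 0 & fc_y < 0] <- "III"
  q[fc_x > 0 & fc_y < 0] <- "IV"
  q <- factor(q, levels = c("I", "II", "III", "IV", "axis"))
  structure(list(
    quadrant = stats::setNames(q, genes),
    counts = table(q),
    r = stats::cor(fc_x, fc_y, method = method),
    genes_by_quadrant = split(genes, q)
  ), class = "quadrant_summary")
}

#' Genes shared by two DEG tables, with aligned fold changes
#'
#' Builds the input for [quadrant_analysis()] from two comparisons'
#' DEG tables, taking the union (default) or intersection of their passing
#' genes.
#'
#' @param deg_x,deg_y `deg_table` data frames (see [wilcoxon_deg()]).
#' @param mode `"union"` (genes passing in either comparison; default),
#'   `"intersection"`, or `"all"` (every shared gene regardless of flags).
#' @return list: `genes`, `fc_x`, `fc_y`.
#' @export
comparison_pair <- function(deg_x, deg_y,
                            mode = c("union", "intersection", "all")) {
  mode <- match.arg(mode)
  shared <- intersect(deg_x$gene, deg_y$gene)
  if (mode != "all") {
    px <- deg_x$gene[deg_x$passes]
    py <- deg_y$gene[deg_y$passes]
    keep <- if (mode == "union") union(px, py) else intersect(px, py)
    shared <- intersect(shared, keep)
  }
  if (length(shared) == 0) stop("no shared genes under mode '", mode, "'")
  list(genes = shared,
       fc_x = deg_x$log2fc[match(shared, deg_x$gene)],
       fc_y = deg_y$log2fc[match(shared, deg_y$gene)])
}

#' Signed host-alignment score of a gene set
#'
#' Sums the log2 fold changes of a region-characteristic gene set in a
#' target comparison; a positive sum says the target comparison shifts the
#' set the same way as the region program (the graft resembles that host
#' region), a negative sum the opposite.
#'
#' @param gene_set character vector of gene IDs.
#' @param fc named log2FC vector (names are genes), or unnamed with `genes`.
#' @param genes gene IDs for `fc` when it is unnamed.
#' @param per_gene_mean normalize the sum by the number of scored genes?
#' @return an `alignment_score` list: `score`, `sign` (+1/-1/0), `n_scored`,
#'   `n_missing`.
#' @export
alignment_score <- function(gene_set, fc, genes = NULL,
                            per_gene_mean = FALSE) {
  if (!is.null(genes)) names(fc) <- genes
  if (is.null(names(fc))) stop("fc must carry gene names")
  hit <- intersect(gene_set, names(fc))
  if (length(hit) == 0) stop("gene set does not intersect the comparison")
  s <- sum(fc[hit])
  if (per_gene_mean) s <- s / length(hit)
  structure(list(score = s, sign = sign(s), n_scored = length(hit),
                 n_missing = length(setdiff(gene_set, names(fc)))),
            class = "alignment_score")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap between the query list and the set when
#' sampling `|query|` genes from the universe without replacement, with BH
#' adjustment across sets.
#'
#' @param query character vector of genes of interest (must lie within the
#'   universe).
#' @param collection named list of gene sets (e.g. from [read_gmt()]); each
#'   set is intersected with the universe before testing.
#' @param universe character vector of all scorable genes.
#' @return data frame (`ora_result`): set, k (overlap), K (set size in
#'   universe), n (query size), N (universe size), p, q (BH), ordered by p.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
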