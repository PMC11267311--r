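#' Assemble a tagged count matrix
#'
#' Bundles a sparse genes x cells UMI matrix with per-gene species tags
#' (for dual-genome data) and per-cell sample labels. This is the common
#' container consumed by the demultiplexing, pseudo-bulk and
#' differential-expression stages.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes in rows,
#'   cells in columns; dimnames are required.
#' @param gene_species optional character/factor of length `nrow(counts)` with
#'   values `"human"` or `"mouse"`.
#' @param cell_sample optional character/factor of length `ncol(counts)` with
#'   the sample label of each cell.
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `gene_species`, `cell_sample`.
#' @export
count_matrix <- function(counts, gene_species = NULL, cell_sample = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell names")
  if (anyDuplicated(rownames(counts)))
    stop("gene IDs must be unique")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  if (!is.null(gene_species)) {
    gene_species <- as.character(gene_species)
    if (length(gene_species) != nrow(counts))
      stop("gene_species must have one entry per gene")
    bad <- setdiff(unique(gene_species), c("human", "mouse"))
    if (length(bad))
      stop("unknown species tag(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cell_sample)) {
    cell_sample <- as.character(cell_sample)
    if (length(cell_sample) != ncol(counts))
      stop("cell_sample must have one entry per cell")
  }
  structure(
    list(counts = counts, gene_species = gene_species,
         cell_sample = cell_sample),
    class = "count_matrix"
  )
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) /
                (as.double(nrow(x$counts)) * ncol(x$counts))))
  if (!is.null(x$gene_species)) {
    tab <- table(x$gene_species)
    cat("  species tags:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if (!is.null(x$cell_sample)) {
    tab <- table(x$cell_sample)
    cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells
#'
#' @param x a [count_matrix()].
#' @param cells logical, integer or character index into the columns.
#' @return a `count_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (anyNA(cells)) stop("unknown cell barcode(s)")
  count_matrix(x$counts[, cells, drop = FALSE],
               gene_species = x$gene_species,
               cell_sample = if (!is.null(x$cell_sample)) x$cell_sample[cells])
}

# Tag genes as human/mouse from feature-ID prefixes.
species_from_prefix <- function(ids, human_prefix = "GRCh38_",
                                mouse_prefix = "mm10_") {
  sp <- rep(NA_character_, length(ids))
  sp[startsWith(ids, human_prefix)] <- "human"
  sp[startsWith(ids, mouse_prefix)] <- "mouse"
  if (anyNA(sp))
    stop("feature ID(s) match neither species prefix: ",
         paste(utils::head(ids[is.na(sp)], 3), collapse = ", "))
  sp
}

# Internal: restore RNG state after seeded simulation so generators are
# deterministic given (config, seed) without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}
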