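#' Per-cell human-transcript ratio
#'
#' For dual-genome aligned data, the fraction of each cell's UMIs carried by
#' human-tagged features. This is the statistic on which species identity is
#' assigned.
#'
#' @param x a [count_matrix()] with `gene_species` tags.
#' @param level `"umi"` (default; ratio of transcripts) or `"gene"` (ratio
#'   of detected genes).
#' @return named numeric vector of ratios in `[0, 1]`, one per cell.
#' @export
human_ratio <- function(x, level = c("umi", "gene")) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$gene_species)) stop("count matrix has no species tags")
  level <- match.arg(level)
  m <- if (level == "gene") x$counts > 0 else x$counts
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(x$counts)[tot == 0], 5), collapse = ", "))
  hum <- Matrix::colSums(m[x$gene_species == "human", , drop = FALSE])
  r <- as.numeric(hum) / as.numeric(tot)
  names(r) <- colnames(x$counts)
  r
}

#' Classify cells by species from human-transcript ratios
#'
#' Cells with ratio at or above `hi` are called human, at or below `lo`
#' mouse, and the band in between is labeled unknown (both thresholds are
#' closed). The defaults 0.2/0.8 are the conventional cut points for
#' dual-genome demultiplexing of xenograft suspensions.
#'
#' @param ratios numeric vector of human-transcript ratios in `[0, 1]`.
#' @param lo,hi mouse/human thresholds, `0 <= lo < hi <= 1`.
#' @param total_umis optional per-cell totals carried into the output.
#' @return data frame (`species_calls`): barcode, total_umis, human_ratio,
#'   label in `{human, mouse, unknown}`.
#' @export
classify_species <- function(ratios, lo = 0.2, hi = 0.8, total_umis = NA) {
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("thresholds must satisfy 0 <= lo < hi <= 1")
  stopifnot(all(ratios >= 0 & ratios <= 1))
  label <- ifelse(ratios >= hi, "human",
                  ifelse(ratios <= lo, "mouse", "unknown"))
  out <- data.frame(
    barcode = if (is.null(names(ratios))) seq_along(ratios)
              else names(ratios),
    total_umis = total_umis,
    human_ratio = unname(ratios),
    label = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_calls", "data.frame")
  out
}

#' Bimodality diagnostic for the human-ratio distribution
#'
#' Bins ratios into `n_bins` over `[0, 1]`, smooths the histogram with a
#' 3-bin moving average, and locates local maxima. The distribution is
#' flagged bimodal when at least two peaks are separated by a trough
#' strictly below both — the expected signature of a mixed-species run
#' (murine and human droplets aggregate near 0 and 1).
#'
#' @param ratios numeric vector of ratios (>= 2 values).
#' @param n_bins histogram bins (default 50).
#' @return list: `breaks`, `counts`, `smoothed`, `peaks` (bin midpoints of
#'   local maxima), `bimodal` flag.
#' @export
ratio_bimodality <- function(ratios, n_bins = 50) {
  if (length(ratios) < 2) stop("need at least 2 cells")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- graphics::hist(ratios, breaks = breaks, plot = FALSE)$counts
  sm <- vapply(seq_len(n_bins), function(i)
    mean(counts[max(1, i - 1):min(n_bins, i + 1)]), numeric(1))
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  left <- c(-Inf, sm[-n_bins])
  right <- c(sm[-1], -Inf)
  is_peak <- sm > left & sm >= right & sm > 0
  peaks <- which(is_peak)
  bimodal <- FALSE
  if (length(peaks) >= 2) {
    for (a in seq_len(length(peaks) - 1)) {
      i <- peaks[a]; j <- peaks[a + 1]
      trough <- min(sm[(i + 1):(j - 1)])
      if (trough < sm[i] && trough < sm[j]) { bimodal <- TRUE; break }
    }
  }
  list(breaks = breaks, counts = counts, smoothed = sm,
       peaks = mids[peaks], bimodal = bimodal)
}

#' Quality-control filter on cells
#'
#' Removes cells detected in fewer than `min_genes` features or with fewer
#' than `min_umis` total counts. Conventional droplet-QC floors are the
#' defaults; both are configurable and `0/0` is the identity.
#'
#' @param x a [count_matrix()].
#' @param min_genes minimum detected genes per cell.
#' @param min_umis minimum total UMIs per cell.
#' @return list: `matrix` (filtered [count_matrix()]), `report` (list of
#'   input/removed/kept tallies per criterion).
#' @export
qc_filter <- function(x, min_genes = 200, min_umis = 500) {
  stopifnot(inherits(x, "count_matrix"), min_genes >= 0, min_umis >= 0)
  genes_per_cell <- Matrix::colSums(x$counts > 0)
  umis_per_cell <- Matrix::colSums(x$counts)
  fail_genes <- genes_per_cell < min_genes
  fail_umis <- umis_per_cell < min_umis
  keep <- !(fail_genes | fail_umis)
  report <- list(n_input = ncol(x$counts),
                 n_fail_min_genes = sum(fail_genes),
                 n_fail_min_umis = sum(fail_umis),
                 n_kept = sum(keep))
  if (!any(keep))
    warning("all cells removed by QC filter")
  list(matrix = subset_cells(x, which(keep)), report = report)
}

#' Demultiplex a mixed-species count matrix end to end
#'
#' Convenience wrapper: QC filter, human-transcript ratio, species labels.
#'
#' @param x a species-tagged [count_matrix()].
#' @param lo,hi classification thresholds (see [classify_species()]).
#' @param min_genes,min_umis QC floors (see [qc_filter()]).
#' @param keep_unknown keep unknown-band cells in the returned matrix?
#' @return list: `calls` (a `species_calls` data frame for all post-QC
#'   cells), `matrix` (filtered to human+mouse, or all post-QC cells when
#'   `keep_unknown`), `qc_report`.
#' @export
demux_species <- function(x, lo = 0.2, hi = 0.8,
                          min_genes = 200, min_umis = 500,
                          keep_unknown = FALSE) {
  qc <- qc_filter(x, min_genes = min_genes, min_umis = min_umis)
  r <- human_ratio(qc$matrix)
  calls <- classify_species(r, lo = lo, hi = hi,
                            total_umis = Matrix::colSums(qc$matrix$counts))
  keep <- if (keep_unknown) rep(TRUE, nrow(calls))
          else calls$label != "unknown"
  list(calls = calls, matrix = subset_cells(qc$matrix, which(keep)),
       qc_report = qc$report)
}

#' Write species calls as TSV
#'
#' @param calls a `species_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
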