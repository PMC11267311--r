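#' Baseline-normalized fluorescence (dF/F0)
#'
#' F0 is the mean fluorescence over all samples strictly before the
#' stimulus; dF/F0 = F/F0 - 1 per timepoint and cell. Scaling every trace
#' by a constant leaves dF/F0 unchanged.
#'
#' @param traces a `trace_set` (see [trace_set()]).
#' @return a `trace_stats` list: `times`, `stimulus_time`, `f0` (per cell),
#'   `dff` (timepoints x cells), `groups`.
#' @export
dff <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  pre <- traces$times < traces$stimulus_time
  if (sum(pre) < 2) stop("need at least 2 pre-stimulus samples")
  f0 <- colMeans(traces$f[pre, , drop = FALSE])
  if (any(f0 <= 0))
    stop("nonpositive baseline for cell(s): ",
         paste(colnames(traces$f)[f0 <= 0], collapse = ", "))
  d <- sweep(traces$f, 2, f0, "/") - 1
  structure(list(times = traces$times, stimulus_time = traces$stimulus_time,
                 f0 = f0, dff = d, groups = traces$groups),
            class = "trace_stats")
}

#' Detect stimulus responses by threshold crossing
#'
#' A cell responds when some post-stimulus sample has dF/F0 strictly above
#' `theta` (default 0.10, the 10% criterion), optionally sustained for
#' `min_consecutive` samples. Response time is the first qualifying sample
#' time minus the stimulus time; max amplitude is the post-stimulus peak
#' dF/F0.
#'
#' @param stats a `trace_stats` (from [dff()]).
#' @param theta response threshold on dF/F0 (default 0.10).
#' @param min_consecutive samples the crossing must persist (default 1).
#' @return data frame (`response_table`): cell, group, f0, responded,
#'   response_time (NA when not responded), max_amplitude.
#' @export
detect_response <- function(stats, theta = 0.10, min_consecutive = 1L) {
  stopifnot(inherits(stats, "trace_stats"), min_consecutive >= 1)
  post <- which(stats$times > stats$stimulus_time)
  if (length(post) == 0) stop("no post-stimulus samples")
  res <- lapply(seq_len(ncol(stats$dff)), function(j) {
    d <- stats$dff[post, j]
    above <- d > theta
    idx <- NA_integer_
    if (any(above)) {
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      ok <- which(runs$values & runs$lengths >= min_consecutive)
      if (length(ok))
        idx <- ends[ok[1]] - runs$lengths[ok[1]] + 1L
    }
    data.frame(
      cell = colnames(stats$dff)[j],
      group = if (is.null(stats$groups)) NA_character_ else stats$groups[j],
      f0 = stats$f0[j],
      responded = !is.na(idx),
      response_time = if (is.na(idx)) NA_real_ else
        stats$times[post[idx]] - stats$stimulus_time,
      max_amplitude = max(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Per-group calcium activation and fold change versus control
#'
#' Means of per-cell maximum dF/F0 amplitudes by treatment group, and each
#' group's fold activation relative to the control group (e.g.
#' dF_DA / dF_CONT).
#'
#' @param responses a `response_table` (from [detect_response()]) with
#'   group labels.
#' @param control control group label (default `"CONT"`).
#' @return data frame (`group_activation`): group, n, mean_amplitude,
#'   fold_vs_control.
#' @export
group_activation <- function(responses, control = "CONT") {
  stopifnot(inherits(responses, "data.frame"),
            all(c("group", "max_amplitude") %in% names(responses)))
  if (!control %in% responses$group)
    stop("control group '", control, "' not present")
  agg <- stats::aggregate(max_amplitude ~ group, responses, mean)
  names(agg)[2] <- "mean_amplitude"
  agg$n <- as.vector(table(responses$group)[agg$group])
  ctrl <- agg$mean_amplitude[agg$group == control]
  if (ctrl <= 0 && any(agg$mean_amplitude[agg$group != control] != 0))
    stop("control mean amplitude is nonpositive; folds undefined")
  agg$fold_vs_control <- agg$mean_amplitude / ctrl
  agg <- agg[, c("group", "n", "mean_amplitude", "fold_vs_control")]
  class(agg) <- c("group_activation", "data.frame")
  agg
}

#' Correlation clustering of calcium activity
#'
#' Pearson correlation of dF/F0 series across cells, average-linkage
#' hierarchical clustering on `1 - r`, and cluster labels at a requested
#' cut — the unbiased view of whether treatment groups share response
#' dynamics.
#'
#' @param stats a `trace_stats` (from [dff()]) with >= 2 cells.
#' @param k number of clusters to cut (default 2).
#' @return list: `correlation` (cells x cells), `hclust`, `clusters`
#'   (named integer vector).
#' @export
trace_correlation_cluster <- function(stats, k = 2) {
  stopifnot(inherits(stats, "trace_stats"))
  d <- stats$dff
  if (ncol(d) < 2) stop("need at least 2 traces")
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trace(s): ",
         paste(colnames(d)[sds == 0], collapse = ", "))
  r <- stats::cor(d)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(correlation = r, hclust = hc,
       clusters = stats::cutree(hc, k = k))
}
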