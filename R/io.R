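#' Read a 10x-style MTX triplet
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` from a directory, as
#' written by dual-reference aligners (uncompressed). Species are inferred
#' from feature-ID prefixes when both prefixes are present.
#'
#' @param dir directory containing the triplet.
#' @param human_prefix,mouse_prefix feature-ID prefixes marking the genome of
#'   origin; set either to `NULL` to skip species tagging.
#' @return a [count_matrix()].
#' @export
read_10x_counts <- function(dir, human_prefix = "GRCh38_",
                            mouse_prefix = "mm10_") {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("feature/barcode counts do not match matrix dimensions")
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes
  sp <- NULL
  if (!is.null(human_prefix) && !is.null(mouse_prefix) &&
      any(startsWith(features[[1]], human_prefix)) &&
      any(startsWith(features[[1]], mouse_prefix)))
    sp <- species_from_prefix(features[[1]], human_prefix, mouse_prefix)
  count_matrix(m, gene_species = sp)
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x_counts <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(x$counts)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(x$counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' Standard 7-column SWC: node id, type code, x, y, z, radius, parent id
#' (`-1` for the root). Lines starting with `#` are comments. Coordinates
#' and radii are in micrometres.
#'
#' @param path SWC file path.
#' @return a `skeleton` data frame (see [simulate_skeleton()]).
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  as_skeleton(df)
}

#' Write an SWC skeleton
#'
#' @param skeleton a `skeleton` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(skeleton[, c("id", "type", "x", "y", "z",
                                  "radius", "parent")],
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calcium traces from CSV (+ optional YAML sidecar)
#'
#' The CSV has a `time` column followed by one column per cell. The sidecar
#' carries `stimulus_time` (seconds) and optionally `group`, a map from cell
#' ID to treatment group.
#'
#' @param path trace CSV.
#' @param meta optional YAML sidecar path.
#' @param stimulus_time stimulus onset in seconds; overridden by the sidecar.
#' @return a `trace_set` (see [simulate_traces()]).
#' @export
read_traces <- function(path, meta = NULL, stimulus_time = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  groups <- NULL
  if (!is.null(meta)) {
    y <- yaml::read_yaml(meta)
    if (!is.null(y$stimulus_time)) stimulus_time <- y$stimulus_time
    if (!is.null(y$group)) groups <- unlist(y$group)[names(df)[-1]]
  }
  if (is.null(stimulus_time)) stop("stimulus_time must be given or in meta")
  trace_set(times = df$time,
            f = as.matrix(df[, -1, drop = FALSE]),
            stimulus_time = stimulus_time,
            groups = groups)
}

#' Write calcium traces to CSV (+ YAML sidecar)
#'
#' @param traces a `trace_set`.
#' @param path output CSV path.
#' @param meta optional YAML sidecar path for stimulus time and group map.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, meta = NULL) {
  df <- data.frame(time = traces$times, traces$f, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(meta)) {
    y <- list(stimulus_time = traces$stimulus_time)
    if (!is.null(traces$groups))
      y$group <- as.list(stats::setNames(traces$groups, colnames(traces$f)))
    yaml::write_yaml(y, meta)
  }
  invisible(path)
}
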