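#' Configuration for the mixed-species droplet simulator
#'
#' Describes a barnyard-style suspension: human and mouse singlets, a
#' configurable number of 50/50 doublets, and ambient contamination. Ambient
#' RNA is modeled as replacement: a binomial fraction of each droplet's UMIs
#' is swapped for draws from a pooled cross-species ambient profile, so the
#' per-cell depth stays fixed and the expected human ratio of a mouse singlet
#' is exactly `ambient_fraction * ambient_human_share`.
#'
#' @param n_human,n_mouse number of singlets per species.
#' @param n_doublets number of human+mouse doublets.
#' @param ambient_fraction fraction of each droplet's UMIs replaced by
#'   ambient draws, in `[0, 1)`.
#' @param ambient_human_share human share of the ambient pool; default the
#'   human share of singlets.
#' @param mean_umis_per_cell Poisson mean droplet depth (truncated at 1).
#' @param n_genes_per_species genes simulated per genome.
#' @param human_prefix,mouse_prefix feature-ID prefixes.
#' @param seed RNG seed.
#' @return a `barnyard_config` list.
#' @export
barnyard_config <- function(n_human = 1000, n_mouse = 1000, n_doublets = 0,
                            ambient_fraction = 0.01,
                            ambient_human_share = NULL,
                            mean_umis_per_cell = 5000,
                            n_genes_per_species = 500,
                            human_prefix = "GRCh38_", mouse_prefix = "mm10_",
                            seed = 1L) {
  stopifnot(n_human >= 0, n_mouse >= 0, n_doublets >= 0,
            ambient_fraction >= 0, ambient_fraction < 1,
            mean_umis_per_cell > 0, n_genes_per_species >= 1)
  if (n_human + n_mouse + n_doublets == 0)
    stop("at least one droplet must be requested")
  if (is.null(ambient_human_share)) {
    tot <- n_human + n_mouse
    ambient_human_share <- if (tot > 0) n_human / tot else 0.5
  }
  stopifnot(ambient_human_share >= 0, ambient_human_share <= 1)
  structure(list(n_human = n_human, n_mouse = n_mouse,
                 n_doublets = n_doublets,
                 ambient_fraction = ambient_fraction,
                 ambient_human_share = ambient_human_share,
                 mean_umis_per_cell = mean_umis_per_cell,
                 n_genes_per_species = n_genes_per_species,
                 human_prefix = human_prefix, mouse_prefix = mouse_prefix,
                 seed = as.integer(seed)),
            class = "barnyard_config")
}

#' Simulate a mixed-species droplet experiment
#'
#' Each species expresses its own gene pool with a fixed skewed abundance
#' profile. Singlets draw native UMIs from their species' profile; doublets
#' draw native UMIs 50/50 from both. A binomial `ambient_fraction` of every
#' droplet's UMIs is then replaced by draws from the pooled ambient profile.
#' True droplet identities are returned alongside the counts.
#'
#' @param config a [barnyard_config()].
#' @return list with `matrix` (a [count_matrix()] with species-tagged genes)
#'   and `truth` (data frame: barcode, true_label in
#'   `{human, mouse, doublet}`).
#' @export
simulate_barnyard <- function(config) {
  stopifnot(inherits(config, "barnyard_config"))
  with_seed(config$seed, {
    ng <- config$n_genes_per_species
    gene_ids <- c(paste0(config$human_prefix, sprintf("HG%04d", seq_len(ng))),
                  paste0(config$mouse_prefix, sprintf("MG%04d", seq_len(ng))))
    species <- rep(c("human", "mouse"), each = ng)
    # skewed per-species abundance profiles, fixed for the run
    p_h <- rgamma(ng, shape = 0.5); p_h <- p_h / sum(p_h)
    p_m <- rgamma(ng, shape = 0.5); p_m <- p_m / sum(p_m)
    prof_human <- c(p_h, numeric(ng))
    prof_mouse <- c(numeric(ng), p_m)
    s <- config$ambient_human_share
    prof_ambient <- s * prof_human + (1 - s) * prof_mouse

    labels <- rep(c("human", "mouse", "doublet"),
                  c(config$n_human, config$n_mouse, config$n_doublets))
    n_cells <- length(labels)
    totals <- pmax(1L, stats::rpois(n_cells, config$mean_umis_per_cell))

    draw <- function(n, prob) {
      if (n == 0) return(integer(2 * ng))
      as.integer(stats::rmultinom(1, n, prob))
    }
    cols <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      amb <- stats::rbinom(1, totals[i], config$ambient_fraction)
      native <- totals[i] - amb
      cnt <- switch(labels[i],
        human = draw(native, prof_human),
        mouse = draw(native, prof_mouse),
        doublet = {
          nh <- stats::rbinom(1, native, 0.5)
          draw(nh, prof_human) + draw(native - nh, prof_mouse)
        })
      cols[[i]] <- cnt + draw(amb, prof_ambient)
    }
    m <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    rownames(m) <- gene_ids
    colnames(m) <- sprintf("CELL%05d", seq_len(n_cells))
    list(matrix = count_matrix(m, gene_species = species),
         truth = data.frame(barcode = colnames(m), true_label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Five-group planted differential-expression design
#'
#' Mirrors the study design of a pre-graft sample (`D0`) plus grafts in two
#' host regions at two post-transplantation times. Planted region genes are
#' up-shifted (by `2^effect`) in PFC groups relative to HIP groups; planted
#' time genes are up-shifted in 4MPT groups relative to 2MPT/D0 groups.
#'
#' @param groups data frame with columns `group`, `region`
#'   (`PFC`/`HIP`/`none`) and `months` (0/2/4); default the five-group
#'   design.
#' @param n_cells_per_group cells simulated per group.
#' @param n_genes total genes; planted genes are drawn from these. The
#'   default genome size and baseline give per-cell depths near the study's
#'   reported average of ~2262 transcripts per cell.
#' @param n_region_genes,n_time_genes number of planted genes per axis
#'   (disjoint sets). Each planted set is balanced: half its genes are
#'   up-shifted in PFC (resp. 4MPT), half in HIP (resp. pre-4MPT), so
#'   planted programs do not skew library sizes.
#' @param region_effect,time_effect planted |log2FC| magnitudes.
#' @param baseline_mean mean counts per gene per cell for an unshifted gene.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be positive.
#' @param seed RNG seed.
#' @return a `planted_design` list.
#' @export
planted_design <- function(groups = default_groups(),
                           n_cells_per_group = 100,
                           n_genes = 1000,
                           n_region_genes = 50, n_time_genes = 50,
                           region_effect = 1.0, time_effect = 1.0,
                           baseline_mean = 2, nb_dispersion = 0.5,
                           seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "region", "months") %in% names(groups)),
            n_cells_per_group >= 1, n_genes >= 1,
            n_region_genes + n_time_genes <= n_genes,
            is.finite(region_effect), is.finite(time_effect),
            baseline_mean > 0)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(list(groups = groups, n_cells_per_group = n_cells_per_group,
                 n_genes = n_genes, n_region_genes = n_region_genes,
                 n_time_genes = n_time_genes,
                 region_effect = region_effect, time_effect = time_effect,
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "planted_design")
}

#' The study's five sample groups
#'
#' @return data frame with `group`, `region`, `months` for D0, PFC_2MPT,
#'   PFC_4MPT, HIP_2MPT and HIP_4MPT.
#' @export
default_groups <- function() {
  data.frame(
    group = c("D0", "PFC_2MPT", "PFC_4MPT", "HIP_2MPT", "HIP_4MPT"),
    region = c("none", "PFC", "PFC", "HIP", "HIP"),
    months = c(0, 2, 4, 2, 4),
    stringsAsFactors = FALSE
  )
}

#' Simulate grouped negative-binomial counts with planted effects
#'
#' Counts are negative binomial with shared dispersion. Gene baselines are
#' log-normal around `baseline_mean`; a planted gene's mean is
#' `baseline * 2^effect` in the groups where its program is up-shifted
#' (PFC vs HIP groups for the region axis, 4MPT vs earlier groups for the
#' time axis), baseline elsewhere. Each planted set is sign-balanced so the
#' programs leave per-cell library sizes comparable across groups.
#'
#' @param design a [planted_design()].
#' @return list with `matrix` (a [count_matrix()] carrying group labels in
#'   `cell_sample`) and `truth` (data frame: gene, axis in
#'   `{region, time}`, effect — signed so that positive means up in PFC,
#'   resp. up in 4MPT). With all effects zero, `truth` has no rows.
#' @export
simulate_grouped_counts <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  with_seed(design$seed, {
    ng <- design$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    grp <- design$groups
    n_per <- design$n_cells_per_group
    cell_group <- rep(grp$group, each = n_per)
    n_cells <- length(cell_group)

    base <- design$baseline_mean * exp(stats::rnorm(ng, 0, 0.3))
    idx_region <- seq_len(design$n_region_genes)
    idx_time <- design$n_region_genes + seq_len(design$n_time_genes)
    # alternate planted directions: +1 = up in PFC (resp. 4MPT)
    dir_region <- rep_len(c(1, -1), design$n_region_genes)
    dir_time <- rep_len(c(1, -1), design$n_time_genes)

    # per-group log2 shift matrix (genes x groups)
    shift <- matrix(0, ng, nrow(grp))
    if (design$region_effect != 0 && design$n_region_genes > 0) {
      shift[idx_region[dir_region > 0], grp$region == "PFC"] <-
        design$region_effect
      shift[idx_region[dir_region < 0], grp$region == "HIP"] <-
        design$region_effect
    }
    if (design$time_effect != 0 && design$n_time_genes > 0) {
      shift[idx_time[dir_time > 0], grp$months == 4] <- design$time_effect
      shift[idx_time[dir_time < 0], grp$months < 4] <- design$time_effect
    }

    size <- 1 / design$nb_dispersion
    cols <- vector("list", n_cells)
    gi <- match(cell_group, grp$group)
    for (i in seq_len(n_cells)) {
      mu <- base * 2^shift[, gi[i]]
      cols[[i]] <- stats::rnbinom(ng, size = size, mu = mu)
    }
    m <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    rownames(m) <- genes
    colnames(m) <- sprintf("%s_c%04d", cell_group,
                           stats::ave(seq_len(n_cells), cell_group,
                                      FUN = seq_along))
    truth <- data.frame(gene = character(), axis = character(),
                        effect = numeric(), stringsAsFactors = FALSE)
    if (design$region_effect != 0 && design$n_region_genes > 0)
      truth <- rbind(truth, data.frame(gene = genes[idx_region],
                                       axis = "region",
                                       effect = dir_region *
                                         design$region_effect))
    if (design$time_effect != 0 && design$n_time_genes > 0)
      truth <- rbind(truth, data.frame(gene = genes[idx_time],
                                       axis = "time",
                                       effect = dir_time *
                                         design$time_effect))
    list(matrix = count_matrix(m, cell_sample = cell_group), truth = truth)
  })
}

#' Simulate a reference expression panel with known best matches
#'
#' Each reference condition gets an independent log-scale expression
#' profile; each query sample is one reference column plus Gaussian noise.
#' The sample-to-reference assignment (the truth map) is returned.
#'
#' @param n_refs number of reference conditions (>= 2).
#' @param n_samples number of query samples.
#' @param n_genes genes in the panel.
#' @param noise_sd Gaussian noise added to each sample profile.
#' @param seed RNG seed.
#' @return list with `panel` (genes x refs matrix), `samples` (genes x
#'   samples matrix) and `truth` (data frame: sample, reference).
#' @export
simulate_reference_panel <- function(n_refs, n_samples, n_genes = 500,
                                     noise_sd = 0, seed = 1L) {
  if (n_refs < 2) stop("need at least 2 reference conditions")
  stopifnot(n_samples >= 1, n_genes >= 2, noise_sd >= 0)
  with_seed(as.integer(seed), {
    genes <- sprintf("G%05d", seq_len(n_genes))
    panel <- matrix(stats::rnorm(n_genes * n_refs, mean = 5, sd = 2),
                    n_genes, n_refs,
                    dimnames = list(genes, sprintf("REF%02d", seq_len(n_refs))))
    assign_to <- sample(rep_len(seq_len(n_refs), n_samples))
    samples <- panel[, assign_to, drop = FALSE] +
      stats::rnorm(n_genes * n_samples, 0, noise_sd)
    colnames(samples) <- sprintf("S%02d", seq_len(n_samples))
    list(panel = panel, samples = samples,
         truth = data.frame(sample = colnames(samples),
                            reference = colnames(panel)[assign_to],
                            stringsAsFactors = FALSE))
  })
}
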