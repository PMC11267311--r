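# Small in-code fixtures shared across tests.

# dense -> count_matrix with optional species tags / sample labels
cm_fixture <- function(mat, species = NULL, samples = NULL) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("c%02d", seq_len(ncol(mat)))
  count_matrix(Matrix::Matrix(mat, sparse = TRUE),
               gene_species = species, cell_sample = samples)
}

# random sparse count fixture
random_cm <- function(n_genes, n_cells, lambda = 1, seed = 1) {
  set.seed(seed)
  mat <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  mat[1, colSums(mat) == 0] <- 1  # avoid empty cells
  cm_fixture(mat)
}

# straight skeleton along +x: soma at origin plus nodes every `step` um
# out to `length_um`
straight_skeleton <- function(length_um, step = 10, soma_radius = 5) {
  xs <- seq(step, length_um, by = step)
  as_skeleton(data.frame(
    id = seq_len(length(xs) + 1),
    type = c(1L, rep(3L, length(xs))),
    x = c(0, xs), y = 0, z = 0,
    radius = c(soma_radius, rep(1, length(xs))),
    parent = c(-1L, seq_len(length(xs)))
  ))
}

# independent pairwise-comparison oracle for the two-sided rank-sum p:
# enumerates every assignment of nA observations to group A and scores the
# Mann-Whitney U by direct pairwise counting (ties count 1/2)
exact_ranksum_oracle <- function(values, na) {
  n <- length(values)
  u_of <- function(idx_a) {
    a <- values[idx_a]; b <- values[-idx_a]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  center <- na * (n - na) / 2
  obs <- abs(u_of(seq_len(na)) - center)
  all_u <- apply(utils::combn(n, na), 2, u_of)
  mean(abs(all_u - center) >= obs - 1e-9)
}

# dense-sampling Sholl oracle: walk each segment at fine resolution and
# count a crossing when the below/above-r state flips an odd number of
# times along the sampled distance profile (a sphere grazed and re-exited
# within one segment flips twice and is not a crossing)
sholl_dense_oracle <- function(sk, radii, step = 0.01) {
  xyz <- as.matrix(sk[, c("x", "y", "z")])
  soma <- xyz[sk$parent == -1, ]
  pidx <- match(sk$parent, sk$id)
  segs <- which(sk$parent != -1)
  profiles <- lapply(segs, function(i) {
    a <- xyz[pidx[i], ]; b <- xyz[i, ]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) return(NULL)
    t <- seq(0, 1, by = step / L)
    pts <- outer(t, b - a) + rep(a, each = length(t))
    sqrt(rowSums(sweep(pts, 2, soma)^2))
  })
  vapply(radii, function(r) {
    total <- 0L
    for (d in profiles) {
      if (is.null(d)) next
      state <- d > r
      flips <- sum(state[-1] != state[-length(state)])
      total <- total + (flips %% 2L)
    }
    total
  }, integer(1))
}
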