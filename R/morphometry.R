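# Internal geometry helpers shared by the skeleton operators.

# Node coordinates as a matrix; soma row index.
skeleton_xyz <- function(sk) as.matrix(sk[, c("x", "y", "z")])

soma_index <- function(sk) which(sk$parent == -1)

# Edge list: child row index, parent row index, length.
skeleton_edges <- function(sk) {
  pidx <- match(sk$parent, sk$id)
  child <- which(sk$parent != -1)
  xyz <- skeleton_xyz(sk)
  d <- sqrt(rowSums((xyz[child, , drop = FALSE] -
                     xyz[pidx[child], , drop = FALSE])^2))
  data.frame(child = child, parent = pidx[child], length = d)
}

# Chop every edge into sub-segments of at most `step` um; returns midpoints,
# sub-lengths and the midpoint distance to the soma center.
discretize_skeleton <- function(sk, step = 0.5) {
  stopifnot(inherits(sk, "skeleton"), step > 0)
  edges <- skeleton_edges(sk)
  if (nrow(edges) == 0)
    return(data.frame(mx = numeric(), my = numeric(), mz = numeric(),
                      len = numeric(), soma_dist = numeric()))
  xyz <- skeleton_xyz(sk)
  soma <- xyz[soma_index(sk), ]
  out <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- xyz[edges$parent[e], ]
    b <- xyz[edges$child[e], ]
    L <- edges$length[e]
    if (L == 0) next
    k <- max(1L, ceiling(L / step))
    t_mid <- (seq_len(k) - 0.5) / k
    mid <- outer(t_mid, b - a) + rep(a, each = k)
    out[[e]] <- data.frame(
      mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
      len = rep(L / k, k),
      soma_dist = sqrt(rowSums(sweep(mid, 2, soma)^2))
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mx = numeric(), my = numeric(), mz = numeric(),
                      len = numeric(), soma_dist = numeric())
  rownames(res) <- NULL
  res
}

#' Sholl profile of a skeleton
#'
#' Counts, for each concentric sphere of radius `r` around the soma center,
#' the parent-child segments whose endpoint distances from the soma straddle
#' `r` (strictly: `min(d) < r < max(d)`); each segment contributes at most
#' one crossing per sphere. The profile is zero at radii beyond the farthest
#' node.
#'
#' @param skeleton an [as_skeleton()] data frame.
#' @param radius_step sphere spacing, um (default 5).
#' @param max_radius largest radius; default the smallest multiple of
#'   `radius_step` at or beyond the farthest node.
#' @param project_xy drop the z coordinate first (2D Sholl)?
#' @return data frame (`sholl_profile`): `radius`, `crossings`.
#' @export
sholl <- function(skeleton, radius_step = 5, max_radius = NULL,
                  project_xy = FALSE) {
  stopifnot(inherits(skeleton, "skeleton"), radius_step > 0)
  sk <- skeleton
  if (project_xy) sk$z <- 0
  xyz <- skeleton_xyz(sk)
  soma <- soma_index(sk)
  dist_soma <- sqrt(rowSums(sweep(xyz, 2, xyz[soma, ])^2))
  edges <- skeleton_edges(sk)
  if (is.null(max_radius))
    max_radius <- radius_step * max(1, ceiling(max(dist_soma) / radius_step))
  radii <- seq(radius_step, max_radius, by = radius_step)
  if (nrow(edges) == 0)
    return(structure(data.frame(radius = radii, crossings = 0L),
                     class = c("sholl_profile", "data.frame")))
  lo <- pmin(dist_soma[edges$child], dist_soma[edges$parent])
  hi <- pmax(dist_soma[edges$child], dist_soma[edges$parent])
  crossings <- vapply(radii, function(r) sum(lo < r & r < hi), integer(1))
  structure(data.frame(radius = radii, crossings = crossings),
            class = c("sholl_profile", "data.frame"))
}

#' Branch statistics of a skeleton
#'
#' Total branch length (sum of parent-child Euclidean distances), number of
#' primary branches (children of the soma), number of terminal branches
#' (leaves), and effective soma area (`pi * soma_radius^2`).
#'
#' @param skeleton an [as_skeleton()] data frame.
#' @return list (`branch_stats`): `total_length` um, `n_primary`,
#'   `n_terminal`, `soma_area` um^2.
#' @export
branch_stats <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton"))
  sk <- skeleton
  soma <- soma_index(sk)
  edges <- skeleton_edges(sk)
  n_primary <- sum(sk$parent == sk$id[soma])
  has_child <- sk$id %in% sk$parent
  n_terminal <- sum(!has_child & seq_len(nrow(sk)) != soma)
  structure(list(total_length = sum(edges$length),
                 n_primary = n_primary,
                 n_terminal = n_terminal,
                 soma_area = pi * sk$radius[soma]^2),
            class = "branch_stats")
}

#' Fiber-neurite colocalization with a proximal/distal split
#'
#' Discretizes the skeleton into sub-segments of at most `step` um; a
#' sub-segment is colocalized when its midpoint lies within `eps` of any
#' neurite evidence point, and proximal when its midpoint is within
#' `boundary` (Euclidean) of the soma center. Fractions are
#' colocalized length over region length. The default 40 um boundary is the
#' conventional proximal/distal split from the soma center.
#'
#' @param skeleton an [as_skeleton()] data frame with at least one segment.
#' @param points data frame or matrix with columns/cols x, y, z (um); may
#'   be empty, giving all-zero fractions.
#' @param eps colocalization radius, um (> 0; default 1).
#' @param boundary proximal/distal split distance from soma center, um
#'   (default 40).
#' @param step discretization step, um (default 0.5).
#' @return list (`coloc_result`): `proximal_fraction`, `distal_fraction`,
#'   `total_fraction`, plus `proximal_length`, `distal_length`,
#'   `total_length`.
#' @export
colocalization <- function(skeleton, points, eps = 1, boundary = 40,
                           step = 0.5) {
  stopifnot(inherits(skeleton, "skeleton"), eps > 0, boundary > 0)
  segs <- discretize_skeleton(skeleton, step = step)
  if (nrow(segs) == 0) stop("skeleton has no segments")
  pts <- as.matrix(as.data.frame(points))
  hit <- rep(FALSE, nrow(segs))
  if (nrow(pts) > 0) {
    pts <- pts[, 1:3, drop = FALSE]
    mids <- as.matrix(segs[, c("mx", "my", "mz")])
    # chunk over sub-segments to bound the distance-matrix size
    chunk <- max(1L, floor(4e6 / max(1, nrow(pts))))
    for (s in seq(1, nrow(mids), by = chunk)) {
      idx <- s:min(nrow(mids), s + chunk - 1)
      d2 <- outer(rowSums(mids[idx, , drop = FALSE]^2), rep(1, nrow(pts))) +
        outer(rep(1, length(idx)), rowSums(pts^2)) -
        2 * mids[idx, , drop = FALSE] %*% t(pts)
      hit[idx] <- sqrt(pmax(0, apply(d2, 1, min))) <= eps
    }
  }
  prox <- segs$soma_dist < boundary
  frac <- function(sel) {
    tot <- sum(segs$len[sel])
    if (tot == 0) return(0)
    sum(segs$len[sel & hit]) / tot
  }
  structure(list(
    proximal_fraction = frac(prox),
    distal_fraction = frac(!prox),
    total_fraction = frac(rep(TRUE, nrow(segs))),
    proximal_length = sum(segs$len[prox]),
    distal_length = sum(segs$len[!prox]),
    total_length = sum(segs$len)
  ), class = "coloc_result")
}
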