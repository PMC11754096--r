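# shared fixtures and independent oracles

# a chain of particles along x at given spacings, single tomogram
chain_set <- function(spacings, state = "closed", tomo = "t1", ...) {
  x <- cumsum(c(0, spacings))
  particle_set(tomogram_id = tomo, x = x, y = 0, z = 0, state = state, ...)
}

# Haar-uniform Euler angles via uniform quaternions — independent of the
# package's own sampler
haar_euler <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  t(apply(q, 1, function(qi) {
    w <- qi[1]; x <- qi[2]; y <- qi[3]; z <- qi[4]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3)
    th <- acos(min(max(R[3, 3], -1), 1)) * 180 / pi
    if (sin(th * pi / 180) < 1e-9) {
      c(atan2(R[2, 1], R[1, 1]) * 180 / pi, th, 0)
    } else {
      c(atan2(R[2, 3], R[1, 3]) * 180 / pi, th,
        atan2(R[3, 2], -R[3, 1]) * 180 / pi)
    }
  }))
}

# uniform unit vectors on the sphere
uniform_sphere <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# brute-force union-find over all pairwise distances: the independent
# clustering oracle. Returns membership vector (component id per point),
# components of size >= 2 only are clusters.
uf_components <- function(pos, threshold) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(dist(pos))
  edges <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a >=2-membership partition for comparison:
# sorted list of sorted member-id groups
partition_groups <- function(ids, membership) {
  grp <- split(ids, membership)
  grp <- grp[lengths(grp) >= 2]
  grp <- lapply(grp, sort)
  unname(grp[order(vapply(grp, `[`, character(1), 1))])
}

cluster_partition <- function(clusters) {
  grp <- lapply(clusters, function(cl) sort(cl$members))
  unname(grp[order(vapply(grp, `[`, character(1), 1))])
}
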