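#' Relative orientations of in-cluster neighbours
#'
#' For every member of every cluster, finds its nearest neighbour within
#' the same cluster and computes the relative rotation
#' `R(member)^-1 %*% R(neighbor)`, the image of the reference pole
#' `(0, 0, 1)` under that rotation, and its stereographic hemisphere
#' projection. Identical orientations therefore land on the north pole at
#' `(0, 0)`; a uniform orientation field spreads samples uniformly over
#' the sphere.
#'
#' Each member contributes one sample against its own nearest in-cluster
#' neighbour, so a mutual pair is counted once per direction; set
#' `dedup = TRUE` to keep only one sample per unordered pair.
#'
#' @param ps the [particle_set] the clusters were traced from.
#' @param clusters a `cluster_list` from [trace_clusters()].
#' @param dedup drop the second sample of each mutual pair (default FALSE).
#' @return data.frame (class `orientation_samples`): `particle_id`,
#'   `neighbor_id`, `pole_x/y/z` (unit vector), `u`, `v`, `hemisphere`.
#' @export
neighbor_orientation_map <- function(ps, clusters, dedup = FALSE) {
  stopifnot(inherits(ps, "particle_set"), inherits(clusters, "cluster_list"))
  if (length(clusters) == 0) stop("no clusters supplied")
  lookup <- match(unlist(lapply(clusters, `[[`, "members")), ps$particle_id)
  if (anyNA(lookup)) {
    bad <- unlist(lapply(clusters, `[[`, "members"))[which(is.na(lookup))[1]]
    stop("cluster member not present in particle set: ", bad)
  }
  rows <- list()
  for (cl in clusters) {
    ids <- cl$members
    ridx <- match(ids, ps$particle_id)
    pos <- cl$positions
    Rs <- lapply(ridx, function(i) {
      euler_to_matrix(ps$phi[i], ps$theta[i], ps$psi[i])
    })
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    for (m in seq_along(ids)) {
      rel <- t(Rs[[m]]) %*% Rs[[nn[m]]]
      pole <- rotated_pole(rel)
      proj <- stereographic_project(pole)
      rows[[length(rows) + 1]] <- data.frame(
        particle_id = ids[m], neighbor_id = ids[nn[m]],
        pole_x = pole[1], pole_y = pole[2], pole_z = pole[3],
        u = proj$u, v = proj$v, hemisphere = proj$hemisphere,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (dedup) {
    key <- apply(cbind(out$particle_id, out$neighbor_id), 1, function(r) {
      paste(sort(r), collapse = "|")
    })
    out <- out[!duplicated(key), , drop = FALSE]
  }
  class(out) <- c("orientation_samples", "data.frame")
  out
}

#' Monte-Carlo uniformity test for pole directions
#'
#' Tests whether the pole vectors of an orientation sample are uniformly
#' distributed on the sphere — the signature of neighbours with no
#' preferred relative orientation. The statistic is the Rayleigh-type
#' resultant length, `Rbar = |mean pole vector|` (0 for perfectly balanced
#' directions, 1 for perfectly concentrated ones). The null distribution
#' is simulated by `n_boot` draws of the same sample size from the uniform
#' sphere; the p-value is the add-one Monte-Carlo estimate
#' `(1 + #{null >= observed}) / (n_boot + 1)`, deterministic given `seed`.
#'
#' @param samples an `orientation_samples` data.frame, or an n x 3 matrix
#'   of unit vectors.
#' @param n_boot number of null draws (default 1000).
#' @param seed integer seed for the null simulation.
#' @return list (class `uniformity_test`) with `statistic` (resultant
#'   length), `p_value`, `n`, `n_boot`.
#' @export
uniformity_test <- function(samples, n_boot = 1000, seed = 1) {
  poles <- if (is.matrix(samples)) samples else
    as.matrix(samples[, c("pole_x", "pole_y", "pole_z")])
  n <- nrow(poles)
  if (n < 10) {
    stop("insufficient data: uniformity test needs >= 10 samples, got ", n)
  }
  rbar <- sqrt(sum(colMeans(poles)^2))
  null <- null_resultants(n, n_boot, seed)
  p <- (1 + sum(null >= rbar)) / (n_boot + 1)
  structure(
    list(statistic = rbar, p_value = p, n = n, n_boot = n_boot),
    class = "uniformity_test"
  )
}

# resultant lengths of n_boot uniform-on-sphere samples of size n,
# vectorised (one rnorm call, group sums)
null_resultants <- function(n, n_boot, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  m <- matrix(stats::rnorm(3L * n * n_boot), ncol = 3)
  m <- m / sqrt(rowSums(m^2))
  grp <- rep(seq_len(n_boot), each = n)
  sums <- rowsum(m, grp)
  sqrt(rowSums(sums^2)) / n
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat(sprintf(
    "Sphere uniformity test (Monte-Carlo Rayleigh)\n  resultant length = %.4f, n = %d\n  p = %.4g (%d null draws)\n",
    x$statistic, x$n, x$p_value, x$n_boot
  ))
  invisible(x)
}

#' Bin hemisphere points into equal-area annular sectors
#'
#' Report-level binning of the stereographic disc: `n_rings` annuli of
#' equal spherical area, each split into sectors so that every cell covers
#' the same solid angle (cells per ring proportional to ring area,
#' totalling about `n_bins`). Returns per-cell counts and densities for
#' each hemisphere.
#'
#' @param samples an `orientation_samples` data.frame.
#' @param n_bins approximate total number of cells per hemisphere
#'   (default 48).
#' @param n_rings number of annuli (default 4).
#' @return data.frame with `hemisphere`, `ring`, `sector`, `count`,
#'   `density` (count per unit solid-angle fraction).
#' @export
hemisphere_bins <- function(samples, n_bins = 48, n_rings = 4) {
  stopifnot(inherits(samples, "orientation_samples"))
  # equal-area rings on the hemisphere: z-cuts uniform in |z|
  sectors <- ring_sectors(n_bins, n_rings)
  out <- list()
  for (h in c("north", "south")) {
    s <- samples[samples$hemisphere == h, , drop = FALSE]
    az <- atan2(s$v, s$u) %% (2 * pi)
    r2 <- s$u^2 + s$v^2
    # invert the projection's radial coordinate to |z| for equal-area rings
    absz <- abs((1 - r2) / (1 + r2))
    ring <- pmin(findInterval(1 - absz, seq(0, 1, length.out = n_rings + 1),
                              rightmost.closed = TRUE), n_rings)
    for (ri in seq_len(n_rings)) {
      k <- sectors[ri]
      sector <- pmin(floor(az[ring == ri] / (2 * pi / k)) + 1, k)
      cnt <- tabulate(sector, nbins = k)
      out[[length(out) + 1]] <- data.frame(
        hemisphere = h, ring = ri, sector = seq_len(k), count = cnt,
        density = cnt / (1 / sum(sectors)), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

ring_sectors <- function(n_bins, n_rings) {
  # rings have equal area, so spread sectors evenly, at least 1 per ring
  pmax(1L, round(rep(n_bins / n_rings, n_rings)))
}
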