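#' Nearest-neighbour distances within tomograms
#'
#' Computes, for every particle of the filtered state, the identity of and
#' Euclidean centre-to-centre distance to its nearest neighbour of the same
#' filtered set, within the same tomogram. Particles alone in their
#' tomogram are kept with `NA` neighbour rather than dropped.
#'
#' @param ps a [particle_set].
#' @param state_filter character vector of state labels to analyse, or
#'   `NULL` for all particles.
#' @return a data.frame (class `neighbor_table`) with columns
#'   `particle_id`, `tomogram_id`, `state`, `nn_id`, `nn_dist` (nm).
#' @export
nearest_neighbors <- function(ps, state_filter = NULL) {
  sub <- filter_state(ps, state_filter)
  if (nrow(sub) == 0) {
    stop("no particles match the state filter: ",
         paste(state_filter, collapse = ", "))
  }
  res <- lapply(split_by_tomogram(sub), function(idx) {
    n <- length(idx)
    out <- data.frame(
      particle_id = sub$particle_id[idx],
      tomogram_id = sub$tomogram_id[idx],
      state = sub$state[idx],
      nn_id = NA_character_, nn_dist = NA_real_,
      stringsAsFactors = FALSE
    )
    if (n >= 2) {
      d <- as.matrix(stats::dist(position_matrix(sub)[idx, , drop = FALSE]))
      diag(d) <- Inf
      j <- apply(d, 1, which.min)
      out$nn_id <- sub$particle_id[idx][j]
      out$nn_dist <- d[cbind(seq_len(n), j)]
    }
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("neighbor_table", "data.frame")
  out
}

# all pairs (i, j, dist) within one tomogram whose distance falls in
# [lo, hi]; indices are relative to `idx`
pairs_within <- function(pos, lo, hi) {
  n <- nrow(pos)
  if (n < 2) return(cbind(i = integer(0), j = integer(0), d = numeric(0)))
  d <- stats::dist(pos)
  m <- as.matrix(d)
  sel <- which(upper.tri(m) & m >= lo & m <= hi, arr.ind = TRUE)
  cbind(i = sel[, 1], j = sel[, 2], d = m[sel])
}

#' Trace particle clusters under a distance rule
#'
#' A cluster is a group of two or more particles, all in one tomogram,
#' connected under a centre-to-centre distance rule. With `window = NULL`
#' the rule is a simple cut-off: an edge joins any two particles at
#' distance `<= threshold`, and clusters are the single-linkage connected
#' components of size >= 2 (the default 20 nm cut-off is the headline
#' cluster definition). With `window = w` an edge instead requires the
#' distance to fall in the closed interval `[threshold - w, threshold + w]`
#' — the windowed rule used by the threshold sweep.
#'
#' Member order within each cluster follows greedy closest-unvisited
#' chaining from the lexicographically smallest member id (the "trailing
#' particle" rule), which makes consecutive-link distances meaningful for
#' pair-spacing statistics.
#'
#' @param ps a [particle_set].
#' @param threshold centre-to-centre distance cut-off in nm (default 20).
#' @param window half-width in nm of the closed distance window, or `NULL`
#'   for the plain cut-off rule.
#' @param state_filter states to cluster; default `"closed"`. `NULL` for all.
#' @return list of class `cluster_list`; each element has `members`
#'   (ordered ids), `tomogram_id`, `length`, `link_dists` (nm, consecutive
#'   pairs in traced order), `topology` (via [topology_classify()]), and
#'   the active `threshold`/`window`. Attribute `n_particles` records the
#'   size of the filtered input.
#' @export
trace_clusters <- function(ps, threshold = 20, window = NULL,
                           state_filter = "closed") {
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number of nm")
  }
  if (!is.null(window) && (!is.numeric(window) || window <= 0)) {
    stop("window must be a positive half-width in nm (or NULL)")
  }
  sub <- filter_state(ps, state_filter)
  lo <- if (is.null(window)) 0 else threshold - window
  hi <- if (is.null(window)) threshold else threshold + window
  clusters <- list()
  by_tomo <- split_by_tomogram(sub)
  for (tomo in names(by_tomo)) {
    idx <- by_tomo[[tomo]]
    pos <- position_matrix(sub)[idx, , drop = FALSE]
    pw <- pairs_within(pos, lo, hi)
    if (nrow(pw) == 0) next
    g <- igraph::graph_from_edgelist(cbind(pw[, 1], pw[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(pos) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) < 2) next
      ord <- chain_order(pos[members, , drop = FALSE],
                         sub$particle_id[idx][members])
      members <- members[ord]
      mpos <- pos[members, , drop = FALSE]
      link <- unname(sqrt(rowSums((mpos[-1, , drop = FALSE] -
                                   mpos[-nrow(mpos), , drop = FALSE])^2)))
      cl <- list(
        members = sub$particle_id[idx][members],
        tomogram_id = tomo,
        length = length(members),
        link_dists = link,
        threshold = threshold,
        window = window,
        positions = mpos
      )
      cl$topology <- topology_classify(cl)
      clusters[[length(clusters) + 1]] <- cl
    }
  }
  structure(clusters,
    class = "cluster_list",
    n_particles = nrow(sub),
    threshold = threshold, window = window
  )
}

# greedy closest-unvisited chaining, starting at the smallest id
chain_order <- function(pos, ids) {
  n <- nrow(pos)
  ord <- integer(n)
  ord[1] <- which.min(rank(ids, ties.method = "first"))
  visited <- rep(FALSE, n)
  visited[ord[1]] <- TRUE
  for (k in seq_len(n - 1)) {
    cur <- pos[ord[k], ]
    d2 <- rowSums(sweep(pos, 2, cur)^2)
    d2[visited] <- Inf
    nxt <- which.min(d2)
    ord[k + 1] <- nxt
    visited[nxt] <- TRUE
  }
  ord
}

#' @export
print.cluster_list <- function(x, ...) {
  cat(sprintf(
    "cluster_list: %d cluster(s) over %d particles (threshold %g nm%s)\n",
    length(x), attr(x, "n_particles"), attr(x, "threshold"),
    if (is.null(attr(x, "window"))) ""
    else sprintf(", window +/-%g nm", attr(x, "window"))
  ))
  if (length(x) > 0) {
    lens <- vapply(x, `[[`, integer(1), "length")
    cat("lengths:", paste(sort(unique(lens)), collapse = ", "),
        "| clustered particles:", sum(lens), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cluster_list <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(
      cluster_id = integer(0), tomogram_id = character(0),
      length = integer(0), topology = character(0),
      members = character(0), link_dists = character(0)
    ))
  }
  data.frame(
    cluster_id = seq_along(x),
    tomogram_id = vapply(x, `[[`, character(1), "tomogram_id"),
    length = vapply(x, `[[`, integer(1), "length"),
    topology = vapply(x, `[[`, character(1), "topology"),
    members = vapply(x, function(cl) paste(cl$members, collapse = ";"),
                     character(1)),
    link_dists = vapply(x, function(cl)
      paste(formatC(cl$link_dists, format = "f", digits = 3),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Sweep cluster membership across distance thresholds
#'
#' Re-traces clusters at every grid value from `t_min` to `t_max`, each
#' with a closed `+/- window` distance interval (so for 17 nm and the
#' default 0.5 nm half-width the permissible link distance ranges from
#' 16.5 to 17.5 nm). The default grid, 15 to 40 nm, spans from the
#' physical minimum centre-to-centre distance between two chaperonin
#' particles up to well past the cluster regime.
#'
#' @param ps a [particle_set].
#' @param t_min,t_max,step threshold grid in nm.
#' @param window half-width of the closed interval, nm; must be positive.
#' @param state_filter states to cluster (default `"closed"`).
#' @return data.frame (class `sweep_result`) with one row per grid value:
#'   `threshold`, `n_clusters`, `n_clustered` (particles in clusters),
#'   `frac_clustered`, plus `len_<k>` columns giving the per-length
#'   cluster counts.
#' @export
threshold_sweep <- function(ps, t_min = 15, t_max = 40, step = 1,
                            window = 0.5, state_filter = "closed") {
  stopifnot(t_min <= t_max, step > 0)
  if (!is.numeric(window) || window <= 0) {
    stop("window must be a positive half-width in nm")
  }
  grid <- seq(t_min, t_max, by = step)
  traced <- lapply(grid, function(t) {
    trace_clusters(ps, threshold = t, window = window,
                   state_filter = state_filter)
  })
  rows <- lapply(seq_along(grid), function(i) {
    cl <- traced[[i]]
    lens <- vapply(cl, `[[`, integer(1), "length")
    n_total <- attr(cl, "n_particles")
    data.frame(
      threshold = grid[i],
      n_clusters = length(cl),
      n_clustered = sum(lens),
      frac_clustered = if (n_total > 0) sum(lens) / n_total else 0
    )
  })
  out <- do.call(rbind, rows)
  # per-length histogram columns, padded across the grid
  hists <- lapply(traced, function(cl) {
    table(vapply(cl, `[[`, integer(1), "length"))
  })
  all_lens <- sort(unique(as.integer(unlist(lapply(hists, names)))))
  for (k in all_lens) {
    out[[paste0("len_", k)]] <- vapply(hists, function(h) {
      v <- h[as.character(k)]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  }
  attr(out, "window") <- window
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Summarise link spacings by cluster length
#'
#' Pools the consecutive-link distances of traced clusters, keeping only
#' links inside `[d_min, d_max]` (default 15-20 nm, the interval to which
#' pair statistics are restricted), and reports per-cluster-length counts
#' with mean and sample (n-1) standard deviation — the shape of the
#' published per-length spacing table. A single qualifying link reports
#' `sd = 0` with `n_links = 1` flagging that the spread is undefined.
#'
#' @param clusters a `cluster_list` from [trace_clusters()].
#' @param d_min,d_max link-distance window in nm.
#' @return data.frame (class `cluster_summary`) with one row per cluster
#'   length: `length`, `n_clusters`, `n_links`, `mean_dist`, `sd_dist`,
#'   plus attributes `frac_clustered`, `pooled_mean`, `pooled_sd`,
#'   `pooled_n`.
#' @export
cluster_summary <- function(clusters, d_min = 15, d_max = 20) {
  stopifnot(inherits(clusters, "cluster_list"))
  n_total <- attr(clusters, "n_particles")
  lens <- vapply(clusters, `[[`, integer(1), "length")
  empty <- data.frame(
    length = integer(0), n_clusters = integer(0), n_links = integer(0),
    mean_dist = numeric(0), sd_dist = numeric(0)
  )
  if (length(clusters) == 0) {
    attr(empty, "frac_clustered") <- 0
    attr(empty, "pooled_mean") <- NA_real_
    attr(empty, "pooled_sd") <- NA_real_
    attr(empty, "pooled_n") <- 0L
    class(empty) <- c("cluster_summary", "data.frame")
    return(empty)
  }
  qual <- lapply(clusters, function(cl) {
    d <- cl$link_dists
    d[d >= d_min & d <= d_max]
  })
  rows <- lapply(sort(unique(lens)), function(k) {
    d <- unlist(qual[lens == k])
    if (length(d) == 0) return(NULL)
    data.frame(
      length = k, n_clusters = sum(lens == k), n_links = length(d),
      mean_dist = mean(d),
      sd_dist = if (length(d) > 1) stats::sd(d) else 0
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  pooled <- unlist(qual)
  attr(out, "frac_clustered") <- sum(lens) / n_total
  attr(out, "pooled_mean") <- if (length(pooled) > 0) mean(pooled) else NA_real_
  attr(out, "pooled_sd") <- if (length(pooled) > 1) stats::sd(pooled) else 0
  attr(out, "pooled_n") <- length(pooled)
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Classify cluster topology
#'
#' Labels a traced cluster `"circular"` when its two chain endpoints lie
#' within the active link rule of each other (the ring-closing link
#' exists), `"linear"` when the chain is nearly straight — end-to-end
#' distance at least 80% of the summed link lengths — and `"other"`
#' otherwise. Pairs are linear by convention.
#'
#' @param cl one element of a `cluster_list` (needs `positions`,
#'   `link_dists`, `threshold`, `window`).
#' @return `"linear"`, `"circular"` or `"other"`.
#' @export
topology_classify <- function(cl) {
  k <- nrow(cl$positions)
  if (k <= 2) return("linear")
  ends <- sqrt(sum((cl$positions[1, ] - cl$positions[k, ])^2))
  lo <- if (is.null(cl$window)) 0 else cl$threshold - cl$window
  hi <- if (is.null(cl$window)) cl$threshold else cl$threshold + cl$window
  if (ends >= lo && ends <= hi) return("circular")
  ratio <- ends / sum(cl$link_dists)
  if (ratio >= 0.8) "linear" else "other"
}

#' Fraction of clusters near filament tracks
#'
#' A cluster counts as proximal when any member lies within `cutoff` of
#' any track point in the same tomogram (default 20 nm centre-to-centre,
#' the rule used for actin-dimer proximity).
#'
#' @param clusters a `cluster_list`.
#' @param tracks a [particle_set] of filament track points (e.g. actin
#'   dimer centres).
#' @param cutoff nm.
#' @return fraction of clusters proximal to a track, with attribute
#'   `n_proximal`.
#' @export
proximity_fraction <- function(clusters, tracks, cutoff = 20) {
  stopifnot(inherits(clusters, "cluster_list"),
            inherits(tracks, "particle_set"))
  if (length(clusters) == 0) {
    stop("no clusters to test for proximity")
  }
  tpos <- position_matrix(tracks)
  tsplit <- split(seq_len(nrow(tracks)), tracks$tomogram_id)
  prox <- vapply(clusters, function(cl) {
    ti <- tsplit[[cl$tomogram_id]]
    if (is.null(ti)) return(FALSE)
    tp <- tpos[ti, , drop = FALSE]
    for (r in seq_len(nrow(cl$positions))) {
      d2 <- rowSums(sweep(tp, 2, cl$positions[r, ])^2)
      if (any(d2 <= cutoff^2)) return(TRUE)
    }
    FALSE
  }, logical(1))
  out <- mean(prox)
  attr(out, "n_proximal") <- sum(prox)
  out
}
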