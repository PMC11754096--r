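#' Scenario configuration for the synthetic particle-field generator
#'
#' Fully parameterises a synthetic tomogram annotation field. Defaults are
#' anchored to the source study's stated conditions: a per-tomogram
#' analyzable volume of 800 x 800 x 150 nm, mean per-tomogram counts from
#' the printed particle totals (4,054 closed and 3,353 open particles over
#' 360 tomograms, i.e. about 11.3 and 9.3 per tomogram), a 15 nm hard-core
#' minimum centre-to-centre distance, injected clusters with link spacing
#' Normal(17.35, 1.18) nm truncated to [15, 20], a geometric cluster-length
#' law over 2..7 matching the printed per-length profile, uniform (Haar)
#' orientations, and an exit-tunnel-side placement probability of 0.551
#' for ribosome scenes.
#'
#' @param box 3-vector, nm: tomogram box dimensions.
#' @param n_tomograms number of tomograms to simulate.
#' @param mean_closed,mean_open mean per-tomogram particle counts (Poisson).
#' @param hard_core minimum centre-to-centre distance, nm.
#' @param clustered_fraction fraction of closed particles injected as
#'   cluster members.
#' @param length_decay geometric decay of the cluster-length law over
#'   lengths 2..7 (P(k) proportional to `length_decay^(k-2)`).
#' @param spacing_mean,spacing_sd,spacing_range link spacing law: Normal
#'   mean/sd in nm, truncated to `spacing_range`.
#' @param p_circular probability that an injected cluster of length >= 3
#'   is laid out as a ring rather than a chain.
#' @param orientation_law `"uniform"` or `"concentrated"` (small rotations
#'   about random axes, sd `concentration_sd` degrees).
#' @param concentration_sd rotation-angle sd (degrees) of the concentrated
#'   law.
#' @param mean_ribosomes mean ribosomes per tomogram for ribosome scenes.
#' @param p_ets probability that an associated chaperonin is placed on the
#'   exit-tunnel side of its ribosome.
#' @param ribo_dist_range radial distance range (nm) at which associated
#'   chaperonins are placed from their ribosome centre.
#' @param frame a [frame_config()] shared with the analysis side.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return list of class `scenario_config`.
#' @seealso [scenario_preset()] for the named study scenarios.
#' @export
scenario_config <- function(box = c(800, 800, 150),
                            n_tomograms = 360,
                            mean_closed = 4054 / 360,
                            mean_open = 3353 / 360,
                            hard_core = 15,
                            clustered_fraction = 0.30,
                            length_decay = 0.45,
                            spacing_mean = 17.35,
                            spacing_sd = 1.18,
                            spacing_range = c(15, 20),
                            p_circular = 0.2,
                            orientation_law = c("uniform", "concentrated"),
                            concentration_sd = 8,
                            mean_ribosomes = 55,
                            p_ets = 0.551,
                            ribo_dist_range = c(20, 60),
                            frame = frame_config(),
                            seed = 1) {
  orientation_law <- match.arg(orientation_law)
  stopifnot(
    length(box) == 3, all(box > 0), n_tomograms >= 1,
    hard_core > 0, hard_core <= spacing_range[1],
    clustered_fraction >= 0, clustered_fraction <= 1,
    p_circular >= 0, p_circular <= 1,
    p_ets >= 0, p_ets <= 1,
    spacing_range[1] < spacing_range[2],
    ribo_dist_range[1] > 0, ribo_dist_range[1] < ribo_dist_range[2]
  )
  structure(
    list(
      box = box, n_tomograms = n_tomograms,
      mean_closed = mean_closed, mean_open = mean_open,
      hard_core = hard_core, clustered_fraction = clustered_fraction,
      length_decay = length_decay,
      spacing_mean = spacing_mean, spacing_sd = spacing_sd,
      spacing_range = spacing_range, p_circular = p_circular,
      orientation_law = orientation_law,
      concentration_sd = concentration_sd,
      mean_ribosomes = mean_ribosomes, p_ets = p_ets,
      ribo_dist_range = ribo_dist_range, frame = frame, seed = seed
    ),
    class = "scenario_config"
  )
}

#' Named scenario presets
#'
#' `"untreated"` mirrors the untreated dataset: 360 tomograms, per-tomogram
#' means from 4,054 closed / 3,353 open, clustered fraction 0.30, ETS bias
#' 0.551. `"treated"` mirrors the translation-inhibited dataset: 352
#' tomograms, means from 3,418 closed / 3,785 open, clustered fraction
#' 0.19, no ETS bias (0.5). `"csr_null"` is the matched
#' complete-spatial-randomness control: same densities as untreated but no
#' injected clusters and no placement bias.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [scenario_config()] (e.g.
#'   `n_tomograms`, `seed`).
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name = c("untreated", "treated", "csr_null"),
                            ...) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown preset '", name[1],
         "'; available: untreated, treated, csr_null")
  })
  base <- switch(name,
    untreated = list(
      n_tomograms = 360, mean_closed = 4054 / 360, mean_open = 3353 / 360,
      clustered_fraction = 0.30, p_ets = 0.551
    ),
    treated = list(
      n_tomograms = 352, mean_closed = 3418 / 352, mean_open = 3785 / 352,
      clustered_fraction = 0.19, spacing_mean = 17.04, spacing_sd = 1.28,
      p_ets = 0.5
    ),
    csr_null = list(
      n_tomograms = 360, mean_closed = 4054 / 360, mean_open = 3353 / 360,
      clustered_fraction = 0, p_ets = 0.5
    )
  )
  over <- list(...)
  cfg <- do.call(scenario_config, utils::modifyList(base, over))
  attr(cfg, "preset") <- name
  cfg
}

# truncated-normal link spacings by rejection (support comfortably wide)
draw_spacing <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(2 * n + 10, cfg$spacing_mean, cfg$spacing_sd)
    out <- c(out, d[d >= cfg$spacing_range[1] & d <= cfg$spacing_range[2]])
  }
  out[seq_len(n)]
}

draw_cluster_length <- function(cfg) {
  k <- 2:7
  p <- cfg$length_decay^(k - 2)
  sample(k, 1, prob = p / sum(p))
}

in_box <- function(p, box) all(p >= 0) && all(p <= box)

# TRUE if candidate point keeps hard-core distance to all rows of `pts`
clears_hard_core <- function(p, pts, hc) {
  if (is.null(pts) || nrow(pts) == 0) return(TRUE)
  all(rowSums(sweep(pts, 2, p)^2) >= hc^2)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Lay out one cluster of k points; returns k x 3 matrix or NULL on failure.
place_cluster <- function(k, cfg, existing, max_tries = 50) {
  for (try in seq_len(max_tries)) {
    circular <- k >= 3 && stats::runif(1) < cfg$p_circular
    pts <- if (circular) ring_points(k, cfg) else chain_points(k, cfg)
    if (is.null(pts)) next
    # random placement of the rigid body inside the box
    Rb <- random_rotation(1)[[1]]
    pts <- pts %*% t(Rb)
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    if (any(hi - lo > cfg$box)) next
    shift <- stats::runif(3) * (cfg$box - (hi - lo)) - lo
    pts <- sweep(pts, 2, shift, `+`)
    ok <- TRUE
    placed <- existing
    for (r in seq_len(k)) {
      if (!clears_hard_core(pts[r, ], placed, cfg$hard_core)) {
        ok <- FALSE
        break
      }
      placed <- rbind(placed, pts[r, ])
    }
    if (ok) return(pts)
  }
  NULL
}

# chain with link lengths from the spacing law and free turning angles,
# self-respecting the hard core
chain_points <- function(k, cfg, max_tries = 30) {
  pts <- matrix(0, k, 3)
  for (r in 2:k) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      d <- draw_spacing(1, cfg)
      cand <- pts[r - 1, ] + d * random_unit_vector()
      if (clears_hard_core(cand, pts[seq_len(r - 1), , drop = FALSE],
                           cfg$hard_core)) {
        pts[r, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  pts
}

# regular k-gon with side length from the spacing law, in the xy-plane
ring_points <- function(k, cfg) {
  side <- draw_spacing(1, cfg)
  radius <- side / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

draw_orientations <- function(n, cfg) {
  if (n == 0) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("phi", "theta", "psi"))))
  }
  if (cfg$orientation_law == "uniform") {
    random_euler(n)
  } else {
    # small rotations: angle ~ |N(0, sd)| about a random axis
    m <- t(vapply(seq_len(n), function(i) {
      ang <- abs(stats::rnorm(1, 0, cfg$concentration_sd)) * pi / 180
      ax <- random_unit_vector()
      q <- c(cos(ang / 2), sin(ang / 2) * ax)
      matrix_to_euler(quat_to_matrix(q))
    }, numeric(3)))
    colnames(m) <- c("phi", "theta", "psi")
    m
  }
}

#' Generate a synthetic particle field with known ground truth
#'
#' Builds `n_tomograms` independent tomogram annotations: closed-state
#' clusters injected as chains or rings with link spacings from the
#' truncated-normal law, the remaining closed and all open particles
#' placed by hard-core rejection sampling (complete spatial randomness
#' with a 15 nm exclusion), and orientations drawn from the configured
#' law. Deterministic given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `particles` (a [particle_set]) and `truth` (list:
#'   `membership` data.frame of `particle_id`, `true_cluster` id or `NA`;
#'   `clustered_fraction` realised over closed particles; `spacing_mean`,
#'   `spacing_sd`, `n_links` of the generated links).
#' @export
generate_field <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  recs <- list()
  truth <- list()
  links <- numeric(0)
  cluster_counter <- 0
  for (t in seq_len(cfg$n_tomograms)) {
    tomo <- sprintf("tomo%03d", t)
    n_closed <- stats::rpois(1, cfg$mean_closed)
    n_open <- stats::rpois(1, cfg$mean_open)
    target <- round(cfg$clustered_fraction * n_closed)
    pts <- matrix(numeric(0), 0, 3)
    cl_id <- integer(0)
    remaining <- target
    fail <- 0
    while (remaining >= 2 && fail < 20) {
      k <- min(draw_cluster_length(cfg), remaining)
      if (k < 2) k <- 2
      # absorb a would-be leftover singleton into this cluster so the
      # realised clustered count tracks the configured fraction
      if (remaining - k == 1) k <- k + 1
      placed <- place_cluster(k, cfg, pts)
      if (is.null(placed)) {
        fail <- fail + 1
        next
      }
      cluster_counter <- cluster_counter + 1
      # realised consecutive-link spacings of the layout
      links <- c(links, sqrt(rowSums(
        (placed[-1, , drop = FALSE] - placed[-k, , drop = FALSE])^2
      )))
      pts <- rbind(pts, placed)
      cl_id <- c(cl_id, rep(cluster_counter, k))
      remaining <- remaining - k
    }
    n_in_clusters <- nrow(pts)
    n_bg_closed <- max(0, n_closed - n_in_clusters)
    bg <- sample_hard_core(n_bg_closed + n_open, cfg, pts)
    if (nrow(bg) < n_bg_closed + n_open) {
      stop(sprintf(
        "packing failure in %s: placed %d of %d background particles",
        tomo, nrow(bg), n_bg_closed + n_open
      ))
    }
    all_pts <- rbind(pts, bg)
    n_all <- nrow(all_pts)
    if (n_all == 0) next
    states <- c(rep("closed", n_in_clusters + n_bg_closed),
                rep("open", n_open))
    eul <- draw_orientations(n_all, cfg)
    recs[[t]] <- data.frame(
      particle_id = sprintf("%s_p%04d", tomo, seq_len(n_all)),
      tomogram_id = tomo,
      x = all_pts[, 1], y = all_pts[, 2], z = all_pts[, 3],
      phi = eul[, "phi"], theta = eul[, "theta"], psi = eul[, "psi"],
      state = states, stringsAsFactors = FALSE
    )
    truth[[t]] <- data.frame(
      particle_id = recs[[t]]$particle_id,
      true_cluster = c(cl_id, rep(NA_integer_, n_all - n_in_clusters)),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, recs)
  membership <- do.call(rbind, truth)
  rownames(df) <- rownames(membership) <- NULL
  ps <- as_particle_set(df, provenance = sprintf(
    "synthetic field (seed %s, clustered_fraction %g)",
    format(cfg$seed), cfg$clustered_fraction
  ))
  n_closed_all <- sum(ps$state == "closed")
  list(
    particles = ps,
    truth = list(
      membership = membership,
      clustered_fraction = if (n_closed_all > 0) {
        sum(!is.na(membership$true_cluster)) / n_closed_all
      } else 0,
      spacing_mean = if (length(links) > 0) mean(links) else NA_real_,
      spacing_sd = if (length(links) > 1) stats::sd(links) else NA_real_,
      n_links = length(links)
    )
  )
}

# hard-core rejection sampler for n uniform points against existing ones
sample_hard_core <- function(n, cfg, existing, max_attempts_per = 200) {
  pts <- existing
  out <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts_per)) {
      cand <- stats::runif(3) * cfg$box
      if (clears_hard_core(cand, pts, cfg$hard_core)) {
        pts <- rbind(pts, cand)
        out <- rbind(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  out
}

#' Generate a synthetic ribosome-chaperonin scene
#'
#' Ribosomes are placed by hard-core rejection sampling with Haar-uniform
#' orientations. Each chaperonin is attached to a randomly chosen ribosome
#' at a radial distance drawn uniformly from `cfg$ribo_dist_range`, on the
#' exit-tunnel side of that ribosome with probability `cfg$p_ets` — the
#' side being defined exactly as [classify_side()] defines it — and
#' otherwise on the far side. Placements are rejected unless the host is
#' the chaperonin's nearest ribosome, so the directed nearest pairing used
#' at analysis time recovers the association (and the injected bias)
#' undiluted; the rejection is symmetric with respect to the tunnel
#' direction because ribosome orientations are Haar-uniform. Ground truth
#' records the drawn side per chaperonin.
#'
#' @param cfg a [scenario_config()] with `mean_ribosomes > 0`.
#' @return list with `trics`, `ribosomes` (both [particle_set]s) and
#'   `truth` (data.frame `particle_id`, `true_side`, `ribosome_id`).
#' @export
generate_ribosome_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$mean_ribosomes > 0)
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  dir <- cfg$frame$exit_tunnel_offset /
    sqrt(sum(cfg$frame$exit_tunnel_offset^2))
  ribs <- list(); trics <- list(); truth <- list()
  for (t in seq_len(cfg$n_tomograms)) {
    tomo <- sprintf("tomo%03d", t)
    n_rib <- stats::rpois(1, cfg$mean_ribosomes)
    if (n_rib == 0) next
    rpts <- sample_hard_core(n_rib, cfg, NULL)
    n_rib <- nrow(rpts)
    reul <- random_euler(n_rib)
    rid <- sprintf("%s_r%04d", tomo, seq_len(n_rib))
    ribs[[t]] <- data.frame(
      particle_id = rid, tomogram_id = tomo,
      x = rpts[, 1], y = rpts[, 2], z = rpts[, 3],
      phi = reul[, "phi"], theta = reul[, "theta"], psi = reul[, "psi"],
      state = "ribosome", stringsAsFactors = FALSE
    )
    n_tric <- stats::rpois(1, cfg$mean_closed + cfg$mean_open)
    if (n_tric == 0) next
    tpts <- matrix(NA_real_, n_tric, 3)
    side <- character(n_tric)
    host <- character(n_tric)
    placed_t <- matrix(numeric(0), 0, 3)
    keep <- logical(n_tric)
    for (i in seq_len(n_tric)) {
      want_ets <- stats::runif(1) < cfg$p_ets
      for (a in seq_len(100)) {
        j <- sample.int(n_rib, 1)
        r <- stats::runif(1, cfg$ribo_dist_range[1], cfg$ribo_dist_range[2])
        u <- random_unit_vector()
        # flip into the wanted half-space relative to the tunnel direction
        s <- sum(u * dir)
        if ((want_ets && s <= 0) || (!want_ets && s > 0)) u <- -u
        if (!want_ets && sum(u * dir) == 0) next  # boundary is non-ETS
        Rr <- euler_to_matrix(reul[j, "phi"], reul[j, "theta"],
                              reul[j, "psi"])
        cand <- rpts[j, ] + as.numeric(Rr %*% (u * r))
        if (!in_box(cand, cfg$box)) next
        if (!clears_hard_core(cand, placed_t, cfg$hard_core)) next
        # the host must be the candidate's nearest ribosome, or directed
        # nearest pairing at analysis time would re-pair it elsewhere
        d2_all <- rowSums(sweep(rpts, 2, cand)^2)
        if (which.min(d2_all) != j) next
        tpts[i, ] <- cand
        side[i] <- if (want_ets) "ETS" else "non-ETS"
        host[i] <- rid[j]
        placed_t <- rbind(placed_t, cand)
        keep[i] <- TRUE
        break
      }
    }
    if (!any(keep)) next
    tpts <- tpts[keep, , drop = FALSE]
    n_kept <- nrow(tpts)
    teul <- draw_orientations(n_kept, cfg)
    st <- sample(c("closed", "open"), n_kept, replace = TRUE,
                 prob = c(cfg$mean_closed, cfg$mean_open))
    pid <- sprintf("%s_p%04d", tomo, seq_len(n_kept))
    trics[[t]] <- data.frame(
      particle_id = pid, tomogram_id = tomo,
      x = tpts[, 1], y = tpts[, 2], z = tpts[, 3],
      phi = teul[, "phi"], theta = teul[, "theta"], psi = teul[, "psi"],
      state = st, stringsAsFactors = FALSE
    )
    truth[[t]] <- data.frame(
      particle_id = pid, true_side = side[keep],
      ribosome_id = host[keep], stringsAsFactors = FALSE
    )
  }
  rib_df <- do.call(rbind, ribs)
  tric_df <- do.call(rbind, trics)
  truth_df <- do.call(rbind, truth)
  rownames(rib_df) <- rownames(tric_df) <- rownames(truth_df) <- NULL
  list(
    trics = as_particle_set(tric_df,
      provenance = sprintf("synthetic ribosome scene (seed %s, p_ets %g)",
                           format(cfg$seed), cfg$p_ets)),
    ribosomes = as_particle_set(rib_df,
      provenance = "synthetic ribosome scene"),
    truth = truth_df
  )
}
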