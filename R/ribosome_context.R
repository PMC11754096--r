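#' Frame configuration for ribosome-relative analysis
#'
#' Fixes where the polypeptide exit tunnel sits in a ribosome's
#' zero-rotation frame and how far a chaperonin may be from a ribosome to
#' be paired with it. The default offset, `(0, 0, -25)` nm, is a
#' documented stand-in for the 60S exit-tunnel position relative to the
#' ribosome centre and should be overridden when a refined tunnel
#' coordinate from a subtomogram average is available; only the direction
#' of the offset matters for the side classification.
#'
#' @param exit_tunnel_offset 3-vector, nm, non-zero.
#' @param pairing_max_dist maximum chaperonin-to-ribosome centre distance
#'   for pairing, nm (default 100).
#' @return list of class `frame_config`.
#' @export
frame_config <- function(exit_tunnel_offset = c(0, 0, -25),
                         pairing_max_dist = 100) {
  exit_tunnel_offset <- as.numeric(exit_tunnel_offset)
  stopifnot(length(exit_tunnel_offset) == 3,
            all(is.finite(exit_tunnel_offset)),
            sum(exit_tunnel_offset^2) > 0,
            is.numeric(pairing_max_dist), pairing_max_dist > 0)
  structure(
    list(exit_tunnel_offset = exit_tunnel_offset,
         pairing_max_dist = pairing_max_dist),
    class = "frame_config"
  )
}

#' Pair each chaperonin with its nearest ribosome
#'
#' Directed nearest-neighbour pairing from chaperonin to ribosome within
#' one tomogram: every chaperonin pairs with its closest ribosome at
#' centre distance `<= max_dist`; one ribosome may serve several
#' chaperonins (ribosomes outnumber chaperonins in cells, and the pairing
#' is directed). Chaperonins with no ribosome in range — or none in their
#' tomogram — are reported unpaired rather than dropped.
#'
#' @param trics [particle_set] of chaperonin particles.
#' @param ribosomes [particle_set] of ribosome particles.
#' @param max_dist pairing cut-off in nm.
#' @return data.frame: `particle_id`, `tomogram_id`, `state`,
#'   `ribosome_id` (`NA` if unpaired), `dist` (nm).
#' @export
pair_to_nearest_ribosome <- function(trics, ribosomes, max_dist = 100) {
  stopifnot(inherits(trics, "particle_set"),
            inherits(ribosomes, "particle_set"),
            max_dist > 0)
  tpos <- position_matrix(trics)
  rpos <- position_matrix(ribosomes)
  rsplit <- split(seq_len(nrow(ribosomes)), ribosomes$tomogram_id)
  out <- data.frame(
    particle_id = trics$particle_id,
    tomogram_id = trics$tomogram_id,
    state = trics$state,
    ribosome_id = NA_character_,
    dist = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(trics))) {
    ri <- rsplit[[trics$tomogram_id[i]]]
    if (is.null(ri)) next
    d2 <- rowSums(sweep(rpos[ri, , drop = FALSE], 2, tpos[i, ])^2)
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) {
      out$ribosome_id[i] <- ribosomes$particle_id[ri[j]]
      out$dist[i] <- sqrt(d2[j])
    }
  }
  out
}

#' Express a position in a ribosome's exit-tunnel frame
#'
#' Places the origin at the ribosome's exit tunnel and undoes the
#' ribosome's rotation, so a ribosome at zero rotation with a particle
#' sitting exactly at the tunnel maps that particle to `(0, 0, 0)`. The
#' tunnel position in the tomogram is
#' `ribosome_centre + R(ribosome) %*% offset`; the returned frame
#' coordinate is `R(ribosome)^-1 %*% (position - tunnel_position)`. This
#' transform is a rigid motion, so pairwise distances among co-transformed
#' points are preserved.
#'
#' @param position 3-vector (nm) in the tomogram frame, or an n x 3 matrix.
#' @param ribosome a single-row [particle_set] slice (or list with `x`,
#'   `y`, `z`, `phi`, `theta`, `psi`) for the paired ribosome.
#' @param cfg a [frame_config()].
#' @return 3-vector (or n x 3 matrix) in the ribosome frame, nm.
#' @export
to_ribosome_frame <- function(position, ribosome, cfg = frame_config()) {
  R <- euler_to_matrix(ribosome$phi[1], ribosome$theta[1], ribosome$psi[1])
  centre <- c(ribosome$x[1], ribosome$y[1], ribosome$z[1])
  tunnel <- centre + as.numeric(R %*% cfg$exit_tunnel_offset)
  if (is.matrix(position)) {
    t(t(position) - tunnel) %*% R   # == (pos - tunnel) %*% R, rows
  } else {
    as.numeric(t(R) %*% (as.numeric(position) - tunnel))
  }
}

#' Classify exit-tunnel side
#'
#' Splits the space around a ribosome by the plane through its centre
#' orthogonal to the centre-to-tunnel direction: positions in the open
#' half-space facing the tunnel are `"ETS"`, everything else — including
#' the dividing plane itself — is `"non-ETS"`. Input positions are in the
#' exit-tunnel frame of [to_ribosome_frame()] (origin at the tunnel), so
#' the position relative to the ribosome centre is
#' `frame_position + offset`.
#'
#' @param frame_position 3-vector or n x 3 matrix from
#'   [to_ribosome_frame()].
#' @param cfg a [frame_config()].
#' @return `"ETS"`/`"non-ETS"` (character vector for matrix input).
#' @export
classify_side <- function(frame_position, cfg = frame_config()) {
  dir <- cfg$exit_tunnel_offset / sqrt(sum(cfg$exit_tunnel_offset^2))
  if (!is.matrix(frame_position)) {
    frame_position <- matrix(frame_position, nrow = 1)
  }
  rel <- sweep(frame_position, 2, -cfg$exit_tunnel_offset)  # + offset
  proj <- as.numeric(rel %*% dir)
  ifelse(proj > 0, "ETS", "non-ETS")
}

#' Exit-tunnel-side enrichment with bootstrap uncertainty
#'
#' Pairs each chaperonin with its nearest ribosome, transforms it into
#' that ribosome's exit-tunnel frame, classifies the side, and reports the
#' ETS fraction per state label with a seeded percentile bootstrap CI over
#' chaperonin-pair resampling (the chaperonin pair, not the ribosome, is
#' the unit of analysis). A per-distance-bin breakdown of the ETS fraction
#' is included.
#'
#' @param trics,ribosomes [particle_set]s sharing tomogram ids.
#' @param cfg a [frame_config()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param dist_breaks breakpoints (nm) for the distance-bin breakdown.
#' @param conf confidence level (default 0.95).
#' @return list of class `ets_result`: `pairs` (per-chaperonin table with
#'   frame coordinates, side, distance), `by_state` (state, n, ets_fraction,
#'   ci_lo, ci_hi), `by_distance` (bin, n, ets_fraction), `n_paired`.
#' @export
ets_enrichment <- function(trics, ribosomes, cfg = frame_config(),
                           n_boot = 1000, seed = 1,
                           dist_breaks = c(0, 25, 50, 75, 100, Inf),
                           conf = 0.95) {
  pairs <- pair_to_nearest_ribosome(trics, ribosomes, cfg$pairing_max_dist)
  paired <- pairs[!is.na(pairs$ribosome_id), , drop = FALSE]
  if (nrow(paired) == 0) {
    stop("no chaperonin-ribosome pairs within ", cfg$pairing_max_dist, " nm")
  }
  tpos <- position_matrix(trics)
  fr <- matrix(NA_real_, nrow(paired), 3,
               dimnames = list(NULL, c("fx", "fy", "fz")))
  for (i in seq_len(nrow(paired))) {
    rib <- ribosomes[ribosomes$particle_id == paired$ribosome_id[i], ,
                     drop = FALSE]
    fr[i, ] <- to_ribosome_frame(
      tpos[match(paired$particle_id[i], trics$particle_id), ], rib, cfg
    )
  }
  paired <- cbind(paired, as.data.frame(fr))
  paired$side <- classify_side(fr, cfg)
  is_ets <- paired$side == "ETS"

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  alpha <- (1 - conf) / 2
  by_state <- do.call(rbind, lapply(
    sort(unique(paired$state)), function(st) {
      sel <- paired$state == st
      n <- sum(sel)
      frac <- mean(is_ets[sel])
      boots <- vapply(seq_len(n_boot), function(b) {
        mean(is_ets[sel][sample.int(n, n, replace = TRUE)])
      }, numeric(1))
      data.frame(
        state = st, n = n, ets_fraction = frac,
        ci_lo = unname(stats::quantile(boots, alpha)),
        ci_hi = unname(stats::quantile(boots, 1 - alpha)),
        stringsAsFactors = FALSE
      )
    }
  ))
  bin <- cut(paired$dist, breaks = dist_breaks, include.lowest = TRUE)
  by_distance <- do.call(rbind, lapply(levels(bin), function(lv) {
    sel <- which(bin == lv)
    data.frame(
      bin = lv, n = length(sel),
      ets_fraction = if (length(sel) > 0) mean(is_ets[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(pairs = paired, by_state = by_state, by_distance = by_distance,
         n_paired = nrow(paired), conf = conf, n_boot = n_boot, seed = seed),
    class = "ets_result"
  )
}

#' @export
print.ets_result <- function(x, ...) {
  cat(sprintf("ETS enrichment: %d paired chaperonin(s)\n", x$n_paired))
  for (i in seq_len(nrow(x$by_state))) {
    r <- x$by_state[i, ]
    cat(sprintf(
      "  %-12s n=%5d  ETS %.1f%%  [%.1f, %.1f]%% (%d%% CI)\n",
      r$state, r$n, 100 * r$ets_fraction, 100 * r$ci_lo, 100 * r$ci_hi,
      round(100 * x$conf)
    ))
  }
  invisible(x)
}
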