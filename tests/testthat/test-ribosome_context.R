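test_that("directed pairing picks the nearest ribosome within range", {
  trics <- particle_set(particle_id = "T1", tomogram_id = "t",
                        x = 0, y = 0, z = 0, state = "open")
  ribos <- particle_set(particle_id = c("R1", "R2"), tomogram_id = "t",
                        x = c(30, 60), y = 0, z = 0, state = "ribosome")
  p <- pair_to_nearest_ribosome(trics, ribos, max_dist = 100)
  expect_equal(p$ribosome_id, "R1")
  expect_equal(p$dist, 30)
  # beyond max_dist or in a ribosome-free tomogram: unpaired, kept
  expect_true(is.na(pair_to_nearest_ribosome(trics, ribos,
                                             max_dist = 20)$ribosome_id))
  lonely <- particle_set(particle_id = "T2", tomogram_id = "empty",
                         x = 0, y = 0, z = 0)
  expect_true(is.na(pair_to_nearest_ribosome(lonely, ribos,
                                             max_dist = 100)$ribosome_id))
})

test_that("pairing equals an exhaustive scan on random placements", {
  set.seed(41)
  trics <- particle_set(tomogram_id = sample(c("a", "b"), 200, TRUE),
                        x = runif(200, 0, 400), y = runif(200, 0, 400),
                        z = runif(200, 0, 150))
  rib_df <- particle_set(particle_id = sprintf("r%d", 1:300),
                         tomogram_id = sample(c("a", "b"), 300, TRUE),
                         x = runif(300, 0, 400), y = runif(300, 0, 400),
                         z = runif(300, 0, 150), state = "ribosome")
  got <- pair_to_nearest_ribosome(trics, rib_df, max_dist = 80)
  for (i in seq_len(nrow(trics))) {
    sel <- rib_df$tomogram_id == trics$tomogram_id[i]
    d <- sqrt((rib_df$x[sel] - trics$x[i])^2 +
              (rib_df$y[sel] - trics$y[i])^2 +
              (rib_df$z[sel] - trics$z[i])^2)
    if (length(d) == 0 || min(d) > 80) {
      expect_true(is.na(got$ribosome_id[i]))
    } else {
      expect_equal(got$ribosome_id[i], rib_df$particle_id[sel][which.min(d)])
      expect_equal(got$dist[i], min(d))
    }
  }
})

test_that("the exit-tunnel frame transform matches its stated anchors", {
  cfg <- frame_config(exit_tunnel_offset = c(0, 0, 10))
  rib0 <- list(x = 5, y = -3, z = 2, phi = 0, theta = 0, psi = 0)
  # a particle exactly at the tunnel maps to the origin
  expect_equal(to_ribosome_frame(c(5, -3, 12), rib0, cfg), c(0, 0, 0))
  # at the ribosome centre: minus the offset
  expect_equal(to_ribosome_frame(c(5, -3, 2), rib0, cfg), c(0, 0, -10))
})

test_that("the frame transform round-trips and preserves distances", {
  set.seed(42)
  cfg <- frame_config()
  for (i in seq_len(50)) {
    e <- haar_euler(1)[1, ]
    rib <- list(x = runif(1, 0, 500), y = runif(1, 0, 500),
                z = runif(1, 0, 150), phi = e[1], theta = e[2], psi = e[3])
    R <- euler_to_matrix(e)
    centre <- c(rib$x, rib$y, rib$z)
    frame_pts <- matrix(rnorm(30, sd = 40), 10, 3)
    # forward transform: frame -> tomogram
    tunnel <- centre + as.numeric(R %*% cfg$exit_tunnel_offset)
    tomo_pts <- t(R %*% t(frame_pts)) +
      matrix(tunnel, 10, 3, byrow = TRUE)
    back <- to_ribosome_frame(tomo_pts, rib, cfg)
    expect_lt(max(abs(back - frame_pts)), 1e-9)
    # isometry among co-transformed points
    expect_lt(max(abs(dist(back) - dist(tomo_pts))), 1e-9)
  }
})

test_that("side classification splits the sphere at the centre plane", {
  cfg <- frame_config(exit_tunnel_offset = c(0, 0, -25))
  # along the tunnel direction from the centre (frame pos = offset + more)
  expect_equal(classify_side(c(0, 0, -10), cfg), "ETS")
  # opposite side
  expect_equal(classify_side(c(0, 0, 40), cfg), "non-ETS")
  # exactly on the dividing plane: non-ETS by the boundary rule
  expect_equal(classify_side(c(3, -7, 25), cfg), "non-ETS")
  # isotropic positions around the centre split close to half
  set.seed(43)
  pos <- uniform_sphere(4000) * 50
  frame_pos <- sweep(pos, 2, cfg$exit_tunnel_offset)  # centre-rel -> frame
  frac <- mean(classify_side(frame_pos, cfg) == "ETS")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("ets_enrichment recovers extreme and calibrated fractions", {
  cfg <- frame_config(exit_tunnel_offset = c(0, 0, -25),
                      pairing_max_dist = 100)
  # all chaperonins explicitly on the tunnel side of one unrotated ribosome
  rib <- particle_set(particle_id = "R1", tomogram_id = "t",
                      x = 0, y = 0, z = 0, state = "ribosome")
  trics <- particle_set(tomogram_id = "t", x = rnorm(40, sd = 5),
                        y = rnorm(40, sd = 5), z = -40 - runif(40, 0, 20),
                        state = "open")
  res <- ets_enrichment(trics, rib, cfg, n_boot = 100, seed = 2)
  expect_equal(res$by_state$ets_fraction, 1)
  expect_equal(res$n_paired, 40)
  # empty pairing is an explicit error
  far <- particle_set(tomogram_id = "t", x = 500, y = 500, z = 500)
  expect_error(ets_enrichment(far, rib, cfg), "no chaperonin-ribosome pairs")
})

test_that("unbiased scenes are statistically indistinguishable from 0.5", {
  scene <- generate_ribosome_scene(
    scenario_preset("csr_null", n_tomograms = 12, seed = 44,
                    mean_closed = 20, mean_open = 0)
  )
  res <- ets_enrichment(scene$trics, scene$ribosomes, n_boot = 200, seed = 4)
  n <- res$by_state$n[res$by_state$state == "closed"]
  frac <- res$by_state$ets_fraction[res$by_state$state == "closed"]
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("recovered enrichment is monotone in the placement bias", {
  fracs <- vapply(c(0.3, 0.5, 0.8), function(p) {
    scene <- generate_ribosome_scene(
      scenario_preset("csr_null", n_tomograms = 10, seed = 45,
                      mean_closed = 20, mean_open = 0, p_ets = p)
    )
    res <- ets_enrichment(scene$trics, scene$ribosomes,
                          n_boot = 50, seed = 4)
    sum(res$by_state$n * res$by_state$ets_fraction) / sum(res$by_state$n)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})
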