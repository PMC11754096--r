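test_that("nearest neighbours match arithmetic and brute force", {
  ps <- chain_set(c(17, 23))  # collinear at 0, 17, 40
  nn <- nearest_neighbors(ps, "closed")
  expect_equal(nn$nn_dist, c(17, 17, 23))
  # two particles: mutual neighbours at the same distance
  nn2 <- nearest_neighbors(chain_set(17), "closed")
  expect_equal(nn2$nn_dist, c(17, 17))
  expect_equal(nn2$nn_id, rev(nn2$particle_id))
  # 500 random points vs exhaustive scan
  set.seed(21)
  ps3 <- particle_set(
    tomogram_id = "t1", x = runif(500, 0, 300),
    y = runif(500, 0, 300), z = runif(500, 0, 150)
  )
  nn3 <- nearest_neighbors(ps3, NULL)
  d <- as.matrix(dist(cbind(ps3$x, ps3$y, ps3$z)))
  diag(d) <- Inf
  expect_equal(nn3$nn_dist, unname(apply(d, 1, min)))
  expect_equal(nn3$nn_id, ps3$particle_id[apply(d, 1, which.min)])
})

test_that("singleton tomograms are kept as neighbourless, not dropped", {
  ps <- particle_set(tomogram_id = c("a", "a", "b"),
                     x = c(0, 10, 0), y = 0, z = 0, state = "closed")
  nn <- nearest_neighbors(ps, "closed")
  expect_equal(nrow(nn), 3)
  expect_true(is.na(nn$nn_dist[nn$tomogram_id == "b"]))
  expect_error(nearest_neighbors(ps, "open"), "no particles")
})

test_that("trace_clusters finds chains and respects the cut-off", {
  ps <- chain_set(c(17, 17, 17))
  cl <- trace_clusters(ps, threshold = 20)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$length, 4)
  expect_equal(cl[[1]]$link_dists, rep(17, 3))
  expect_length(trace_clusters(chain_set(25), threshold = 20), 0)
  expect_error(trace_clusters(ps, threshold = -1), "non-negative")
  expect_error(trace_clusters(ps, window = 0), "positive")
})

test_that("windowed tracing uses the closed +/- interval", {
  pair <- chain_set(17)
  hit <- function(t) length(trace_clusters(pair, threshold = t,
                                           window = 0.5)) == 1
  expect_true(hit(17))
  expect_true(hit(16.5))   # 17 is the closed upper boundary of 16.5+/-0.5
  expect_true(hit(17.5))   # and the closed lower boundary of 17.5+/-0.5
  expect_false(hit(15))
  expect_false(hit(20))
})

test_that("membership equals the union-find oracle on random instances", {
  set.seed(22)
  for (rep in seq_len(30)) {
    n <- sample(20:300, 1)
    pos <- cbind(runif(n, 0, 250), runif(n, 0, 250), runif(n, 0, 120))
    ps <- particle_set(tomogram_id = "t1",
                       x = pos[, 1], y = pos[, 2], z = pos[, 3])
    thr <- runif(1, 15, 30)
    got <- cluster_partition(trace_clusters(ps, threshold = thr,
                                            state_filter = NULL))
    want <- partition_groups(ps$particle_id, uf_components(pos, thr))
    expect_identical(got, want)
  }
})

test_that("partition is invariant to input order and rigid motion", {
  set.seed(23)
  n <- 120
  pos <- cbind(runif(n, 0, 200), runif(n, 0, 200), runif(n, 0, 100))
  ps <- particle_set(tomogram_id = "t1", particle_id = sprintf("p%03d", 1:n),
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
  base <- cluster_partition(trace_clusters(ps, 22, state_filter = NULL))
  perm <- sample(n)
  ps_perm <- as_particle_set(as.data.frame(ps)[perm, ])
  expect_identical(
    cluster_partition(trace_clusters(ps_perm, 22, state_filter = NULL)),
    base
  )
  R <- euler_to_matrix(33, 51, -70)
  moved <- pos %*% t(R) + matrix(c(10, -40, 7), n, 3, byrow = TRUE)
  ps_mov <- as_particle_set(within(as.data.frame(ps), {
    x <- moved[, 1]; y <- moved[, 2]; z <- moved[, 3]
  }))
  expect_identical(
    cluster_partition(trace_clusters(ps_mov, 22, state_filter = NULL)),
    base
  )
})

test_that("clustered count is monotone in threshold without a window", {
  set.seed(24)
  ps <- particle_set(tomogram_id = rep(c("a", "b"), each = 60),
                     x = runif(120, 0, 250), y = runif(120, 0, 250),
                     z = runif(120, 0, 100))
  counts <- vapply(seq(10, 60, by = 5), function(t) {
    sum(vapply(trace_clusters(ps, t, state_filter = NULL), `[[`,
               integer(1), "length"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("clusters never span tomograms", {
  ps <- particle_set(tomogram_id = c("a", "b"), x = c(0, 10), y = 0, z = 0)
  expect_length(trace_clusters(ps, 20, state_filter = NULL), 0)
})

test_that("threshold_sweep reproduces interval arithmetic and empty input", {
  pair <- chain_set(17)
  sw <- threshold_sweep(pair, t_min = 15, t_max = 20, step = 0.5)
  expect_s3_class(sw, "sweep_result")
  hit <- sw$threshold[sw$n_clusters > 0]
  expect_equal(hit, c(16.5, 17, 17.5))
  lone <- chain_set(100)  # nothing within any sweep window
  sw0 <- threshold_sweep(lone)
  expect_true(all(sw0$n_clusters == 0) && all(sw0$n_clustered == 0))
  expect_error(threshold_sweep(pair, window = 0), "positive")
})

test_that("cluster_summary pools link distances within [d_min, d_max]", {
  one <- cluster_summary(trace_clusters(chain_set(17)))
  expect_equal(one$n_links, 1)
  expect_equal(one$mean_dist, 17)
  expect_equal(one$sd_dist, 0)  # single link: flagged by n_links == 1
  # two pairs at 16 and 18 nm in separate tomograms
  two <- rbind(as.data.frame(chain_set(16, tomo = "a")),
               as.data.frame(chain_set(18, tomo = "b",
                                       particle_id = c("q1", "q2"))))
  cs <- cluster_summary(trace_clusters(as_particle_set(two)))
  expect_equal(cs$length, 2)
  expect_equal(cs$n_clusters, 2)
  expect_equal(cs$mean_dist, 17)
  expect_equal(cs$sd_dist, sqrt(2), tolerance = 1e-12)
  expect_equal(attr(cs, "frac_clustered"), 1)
  # out-of-window links do not contribute
  far <- cluster_summary(trace_clusters(chain_set(12), threshold = 20),
                         d_min = 15, d_max = 20)
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "pooled_n"), 0)
})

test_that("topology labels follow the closing-link and straightness rules", {
  # 4 points on a square of 17 nm edges: the closing link exists
  sq <- particle_set(tomogram_id = "t", x = c(0, 17, 17, 0),
                     y = c(0, 0, 17, 17), z = 0, state = "closed")
  cl <- trace_clusters(sq, threshold = 20)
  expect_equal(cl[[1]]$topology, "circular")
  # 4 collinear points: straightness ratio 1
  lin <- trace_clusters(chain_set(c(17, 17, 17)), threshold = 20)
  expect_equal(lin[[1]]$topology, "linear")
  # right-angle L of 5 points, arms 2x17 each: ratio computed directly
  Lpts <- rbind(c(0, 0), c(17, 0), c(34, 0), c(34, 17), c(34, 34))
  Lps <- particle_set(tomogram_id = "t", x = Lpts[, 1], y = Lpts[, 2],
                      z = 0, state = "closed")
  clL <- trace_clusters(Lps, threshold = 20)
  ratio <- sqrt(sum((Lpts[5, ] - Lpts[1, ])^2)) / (4 * 17)
  expect_equal(clL[[1]]$topology, if (ratio >= 0.8) "linear" else "other")
  expect_equal(clL[[1]]$topology, "other")  # ratio ~ 0.707
})

test_that("proximity_fraction applies the any-member 20 nm rule", {
  cl <- trace_clusters(chain_set(17))
  near <- particle_set(tomogram_id = "t1", x = -19, y = 0, z = 0,
                       state = "actin_segment")
  far <- particle_set(tomogram_id = "t1", x = -21, y = 0, z = 0,
                      state = "actin_segment")
  expect_equal(as.numeric(proximity_fraction(cl, near)), 1)
  expect_equal(as.numeric(proximity_fraction(cl, far)), 0)
  # tracks in another tomogram never count
  other <- particle_set(tomogram_id = "t2", x = 0, y = 0, z = 0)
  expect_equal(as.numeric(proximity_fraction(cl, other)), 0)
  expect_error(proximity_fraction(structure(list(), class = "cluster_list",
                                            n_particles = 0), near),
               "no clusters")
})
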