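test_that("presets encode the stated scenarios", {
  un <- scenario_preset("untreated")
  expect_equal(un$clustered_fraction, 0.30)
  expect_equal(un$n_tomograms, 360)
  expect_equal(un$mean_closed * un$n_tomograms, 4054)
  expect_equal(un$mean_open * un$n_tomograms, 3353)
  expect_equal(un$p_ets, 0.551)
  tr <- scenario_preset("treated")
  expect_equal(tr$clustered_fraction, 0.19)
  expect_equal(tr$n_tomograms, 352)
  expect_equal(tr$mean_closed * tr$n_tomograms, 3418)
  null <- scenario_preset("csr_null")
  expect_equal(null$clustered_fraction, 0)
  expect_equal(null$p_ets, 0.5)
  expect_error(scenario_preset("bogus"), "untreated, treated, csr_null")
})

test_that("identical seed and config give bit-identical fields", {
  cfg <- scenario_preset("untreated", n_tomograms = 10, seed = 77)
  f1 <- generate_field(cfg)
  f2 <- generate_field(cfg)
  expect_identical(as.data.frame(f1$particles), as.data.frame(f2$particles))
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_field(scenario_preset("untreated", n_tomograms = 10,
                                       seed = 78))
  expect_false(identical(f1$particles$x, f3$particles$x))
})

test_that("hard-core exclusion holds for every emitted tomogram", {
  f <- generate_field(scenario_preset("untreated", n_tomograms = 15,
                                      seed = 61))
  for (tomo in unique(f$particles$tomogram_id)) {
    sub <- f$particles[f$particles$tomogram_id == tomo, ]
    if (nrow(sub) < 2) next
    expect_gte(min(dist(cbind(sub$x, sub$y, sub$z))), 15)
  }
  # positions stay inside the box
  expect_true(all(f$particles$x >= 0 & f$particles$x <= 800))
  expect_true(all(f$particles$z >= 0 & f$particles$z <= 150))
})

test_that("zero clustered fraction leaves only CSR leakage", {
  f <- generate_field(scenario_preset("csr_null", n_tomograms = 60,
                                      seed = 62))
  expect_true(all(is.na(f$truth$membership$true_cluster)))
  cl <- trace_clusters(f$particles, threshold = 20)
  leak <- sum(vapply(cl, `[[`, integer(1), "length")) /
    sum(f$particles$state == "closed")
  # hard-core CSR at ~11 closed per box leaves well under 5% in clusters
  expect_lt(leak, 0.05)
})

test_that("generated spacings follow the truncated-normal law", {
  f <- generate_field(scenario_preset("untreated", n_tomograms = 170,
                                      seed = 63))
  expect_gt(f$truth$n_links, 300)
  # law-of-large-numbers check against the truncated N(17.35, 1.18) moments
  expect_lt(abs(f$truth$spacing_mean - 17.35), 0.2)
  expect_lt(abs(f$truth$spacing_sd - 1.18), 0.25)
  expect_true(all(generate_field(
    scenario_preset("untreated", n_tomograms = 5, seed = 64)
  )$truth$membership$true_cluster %in% c(NA, 1:100)))
})

test_that("ground-truth and traced partitions agree on >=95% of particles", {
  f <- generate_field(scenario_preset("untreated", n_tomograms = 80,
                                      seed = 65))
  cl <- trace_clusters(f$particles, threshold = 20)
  traced <- unlist(lapply(cl, `[[`, "members"))
  truth_members <-
    f$truth$membership$particle_id[!is.na(f$truth$membership$true_cluster)]
  closed_ids <- f$particles$particle_id[f$particles$state == "closed"]
  agree <- mean(closed_ids %in% traced == closed_ids %in% truth_members)
  expect_gte(agree, 0.95)
})

test_that("ribosome scenes respect extreme placement biases", {
  one <- generate_ribosome_scene(
    scenario_preset("csr_null", n_tomograms = 4, seed = 66,
                    mean_closed = 15, mean_open = 0, p_ets = 1)
  )
  expect_true(all(one$truth$true_side == "ETS"))
  res <- ets_enrichment(one$trics, one$ribosomes, n_boot = 50, seed = 1)
  expect_equal(res$by_state$ets_fraction, 1)
  # the analysis-side classification agrees with the drawn ground truth
  half <- generate_ribosome_scene(
    scenario_preset("csr_null", n_tomograms = 6, seed = 67,
                    mean_closed = 15, mean_open = 0)
  )
  res2 <- ets_enrichment(half$trics, half$ribosomes, n_boot = 50, seed = 1)
  sides <- setNames(res2$pairs$side, res2$pairs$particle_id)
  truth <- setNames(half$truth$true_side, half$truth$particle_id)
  common <- intersect(names(sides), names(truth))
  expect_gt(length(common), 50)
  expect_equal(unname(sides[common]), unname(truth[common]))
})
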