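# Excluded-volume geometry, crowder placement and co-translational synthesis.

test_that("sphere overlap volume handles the limiting cases", {
  expect_equal(sphere_overlap_volume(3, 4, 8), 0)
  expect_equal(sphere_overlap_volume(3, 10, 2), 4 / 3 * pi * 27)
  expect_equal(sphere_overlap_volume(5, 5, 0), 4 / 3 * pi * 125)
})

test_that("available volume matches Monte-Carlo integration", {
  scene <- make_scene()
  va <- available_volume(scene)
  set.seed(123)
  n <- 2e5
  P <- matrix(runif(3 * n, -50, 50), ncol = 3)
  inside <- rowSums(P^2) <= 50^2
  out_rib <- rowSums(sweep(P, 2, scene$ribosome_center)^2) >= 100^2
  mc <- mean(inside & out_rib) * 100^3
  expect_equal(va, mc, tolerance = 0.01)
  # no ribosome overlap: the full container ball
  scene2 <- make_scene(ribosome_radius = NA)
  expect_equal(available_volume(scene2), 4 / 3 * pi * 50^3)
  # whole-container accounting on request
  scene3 <- make_scene(volume_denominator = "container")
  expect_equal(available_volume(scene3), 4 / 3 * pi * 50^3)
})

test_that("crowder counts realise the target fraction to rounding", {
  scene <- make_scene()
  expect_equal(as.integer(crowder_count(0, scene)), 0)
  vcr <- 4 / 3 * pi * scene$crowder_radius^3
  va <- available_volume(scene)
  one <- crowder_count(vcr / va, scene)
  expect_equal(as.integer(one), 1)
  for (f in c(0.1, 0.25, 0.4)) {
    n <- crowder_count(f, scene)
    expect_lte(abs(attr(n, "realised_fraction") - f), 0.5 * vcr / va)
    # excluded-volume accounting is exact
    expect_equal(attr(n, "realised_fraction"), as.integer(n) * vcr / va)
  }
})

test_that("placed crowders satisfy all geometric constraints", {
  scene <- make_scene()
  expect_equal(nrow(place_crowders(0, scene)), 0)
  for (seed in 1:3) {
    set.seed(seed)
    n <- as.integer(crowder_count(0.25, scene))
    X <- place_crowders(n, scene)
    expect_false(attr(X, "compressed"))
    expect_true(all(sqrt(rowSums(X^2)) <=
                      scene$container_radius - scene$crowder_radius + 1e-9))
    expect_true(all(sqrt(rowSums(sweep(X, 2, scene$ribosome_center)^2)) >=
                      scene$ribosome_radius + scene$crowder_radius - 1e-9))
    if (n > 1) expect_gte(min(dist(X)), 2 * scene$crowder_radius - 1e-6)
  }
  # determinism under the seed
  set.seed(5); a <- place_crowders(5, scene)
  set.seed(5); b <- place_crowders(5, scene)
  expect_identical(a, b)
})

test_that("overdense targets fall back to a flagged compressed start", {
  scene <- make_scene()
  n50 <- as.integer(crowder_count(0.5, scene))
  set.seed(1)
  expect_warning(X <- place_crowders(n50, scene), "compressed")
  expect_equal(nrow(X), n50)
  expect_true(attr(X, "compressed"))
  set.seed(1)
  expect_error(suppressWarnings(
    place_crowders(n50, scene, allow_compressed = FALSE)), "at most")
})

test_that("the sampling plan reproduces the full-scale study bookkeeping", {
  plan <- crowding_plan()
  expect_equal(plan$samples_per_replicate, 1000)
  expect_equal(plan$samples_per_protein_level, 100000)
  expect_equal(plan$total_conformations, 1.2e6)
})

test_that("synthesis emits one residue per rate interval with one tether", {
  tseq <- make_fixture("toy_sequence", L = 8)
  chain <- build_chain(tseq$sequence, tseq$ss)
  scene <- make_scene()
  sys <- make_system(chain, scene, synthesized = 0)
  ff <- default_ff_params()
  lp <- default_langevin_params()
  rate <- 50
  set.seed(3)
  for (k in 1:8) {
    res <- crowdfold:::.engine(sys, ff, lp, n_steps = rate,
                               sample_interval = 0L,
                               it_offset = (k - 1) * rate,
                               synthesis = TRUE, synth_rate = rate)
    sys <- res$system
    expect_equal(sys$synthesized, min(k, 8))
    if (k < 8) {
      # exactly one tether, to the newest backbone particle
      expect_equal(sys$tether_to, chain$bb_id[k])
    }
    # active chain particles never sit inside the ribosome sphere
    act <- which(sys$active & sys$role %in% 1:2)
    d <- sqrt(rowSums(sweep(sys$pos[act, , drop = FALSE], 2,
                            scene$ribosome_center)^2))
    expect_true(all(d >= scene$ribosome_radius - 1e-6))
  }
  # after L*rate iterations the chain is complete and untethered
  expect_true(is.na(sys$tether_to))
  expect_equal(sys$synthesized, 8)
})

test_that("crowded synthesis keeps particles inside the container", {
  tseq <- make_fixture("toy_sequence", L = 10)
  traj <- run_crowding_simulation(tseq$sequence, tseq$ss, fraction = 0.2,
                                  seed = 11, synth_rate = 50,
                                  post_iterations = 2000,
                                  sample_interval = 200)
  expect_equal(attr(traj, "n_crowders"),
               as.integer(crowder_count(0.2, make_scene())))
  for (s in seq_len(dim(traj$samples)[1])) {
    xyz <- traj$samples[s, , ]
    xyz <- xyz[!is.na(xyz[, 1]), , drop = FALSE]
    expect_true(all(sqrt(rowSums(xyz^2)) <= 50 + 2))
  }
  # zero crowding means zero crowders
  traj0 <- run_crowding_simulation(tseq$sequence, tseq$ss, fraction = 0,
                                   seed = 1, synth_rate = 20,
                                   post_iterations = 200,
                                   sample_interval = 100)
  expect_equal(attr(traj0, "n_crowders"), 0L)
})
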