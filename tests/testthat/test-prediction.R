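# Pool generation, consensus contact-map ranking and diversity selection.

make_map <- function(conf, ss) contact_map(conf, ss)

test_that("pool bookkeeping reproduces the protocol arithmetic", {
  plan <- pool_plan(l = 75)
  expect_equal(plan$budget_per_trajectory, 6000 * 75 + 400000)
  expect_equal(plan$sampling_start, 6000 * 75)
  expect_equal(plan$pool_size, 6000)
  expect_equal(pool_plan(l = 40)$pool_size, 150 * 40)
})

test_that("a reduced pool run produces the scheduled samples", {
  tseq <- make_fixture("toy_sequence", L = 10)
  pool <- generate_pool(tseq$sequence, tseq$ss, n_traj = 2,
                        iters_per_res = 100, extra_iters = 1000,
                        n_samples = 4, synth_rate = 50, base_seed = 7)
  expect_equal(length(pool$conformations), 2 * 4)
  expect_equal(length(pool$maps), 8)
  expect_equal(unique(pool$provenance$trajectory), 1:2)
  expect_equal(unique(pool$provenance$seed), c(7, 8))
  # sampling covers (sampling_start, budget] at equal spacing
  expect_equal(pool$provenance$iteration[1:4], 1000 + 250 * 1:4)
  # reruns with the same base seed are identical
  pool2 <- generate_pool(tseq$sequence, tseq$ss, n_traj = 2,
                         iters_per_res = 100, extra_iters = 1000,
                         n_samples = 4, synth_rate = 50, base_seed = 7)
  expect_identical(pool$conformations, pool2$conformations)
})

test_that("consensus maps average member contact maps", {
  ss <- strrep("C", 8)
  A <- make_fixture("random_coil", 8, seed = 1)
  B <- make_fixture("random_coil", 8, seed = 2)
  pool_same <- list(maps = list(make_map(A, ss), make_map(A, ss)))
  cm <- consensus_map(pool_same)
  expect_equal(cm$map, make_map(A, ss)$map)
  pool_two <- list(maps = list(make_map(A, ss), make_map(B, ss)))
  cm2 <- consensus_map(pool_two)
  both <- make_map(A, ss)$map + make_map(B, ss)$map
  expect_equal(cm2$map, both / 2)
  expect_true(all(cm2$map[both == 1] == 0.5))
  # direct-averaging oracle over a random pool
  maps <- lapply(1:5, function(s)
    make_map(make_fixture("random_coil", 8, seed = s + 10), ss))
  cm3 <- consensus_map(list(maps = maps))
  expect_equal(cm3$map, Reduce(`+`, lapply(maps, `[[`, "map")) / 5)
})

test_that("the consensus score rewards and penalises by contact frequency", {
  ss <- strrep("C", 8)
  A <- make_fixture("random_coil", 8, seed = 21)
  B <- make_fixture("random_coil", 8, seed = 22)
  mean_map <- consensus_map(list(maps = list(make_map(A, ss),
                                             make_map(B, ss))))
  # hand evaluation over eligible upper-triangle pairs
  mA <- make_map(A, ss)
  ut <- upper.tri(mA$map) & mA$eligible
  hand <- sum(ifelse(mA$map[ut] > 0, mean_map$map[ut], -mean_map$map[ut]))
  expect_equal(consensus_score(mA, mean_map), hand)
  # all-zero consensus scores everything zero
  zero <- mean_map
  zero$map[] <- 0
  expect_equal(consensus_score(mA, zero), 0)
  # a member identical to a binary consensus attains the maximal score
  self <- consensus_map(list(maps = list(mA)))
  smax <- consensus_score(mA, self)
  expect_gte(smax, consensus_score(make_map(B, ss), self))
  expect_equal(smax, sum(self$map[ut]))
  expect_error(consensus_score(mA, make_map(A[1:5, ], strrep("C", 5))),
               "shape|mask")
})

test_that("diversity filtering prunes near-duplicate predictions", {
  ss <- strrep("C", 10)
  base <- make_fixture("random_coil", 10, seed = 31)
  jitter <- function(s, sd) base + matrix(rnorm(30, sd = sd), 10, 3)
  # a pool of identical structures collapses to a single prediction
  set.seed(1)
  pool_id <- list(conformations = rep(list(base), 8),
                  maps = rep(list(make_map(base, ss)), 8),
                  sequence = strrep("A", 10), ss = ss)
  class(pool_id) <- "cf_pool"
  sel <- select_predictions(pool_id)
  expect_equal(length(sel$selected), 1)
  # mutually dissimilar structures are all retained in score order
  set.seed(2)
  distinct <- lapply(1:5, function(s)
    make_fixture("random_coil", 10, seed = 40 + s) * (1 + s / 4))
  pool_d <- list(conformations = distinct,
                 maps = lapply(distinct, make_map, ss = ss),
                 sequence = strrep("A", 10), ss = ss)
  class(pool_d) <- "cf_pool"
  sel_d <- select_predictions(pool_d)
  expect_equal(length(sel_d$selected), 5)
  expect_equal(length(sel_d$eliminated), 0)
  # scores of the selection are non-increasing
  sc <- sel_d$ranking$score[match(sel_d$selected, sel_d$ranking$index)]
  expect_true(all(diff(sc) <= 1e-12))
  # one duplicated member is eliminated and a new structure promoted
  set.seed(3)
  pool_dup <- list(
    conformations = c(distinct[1], list(jitter(1, 0.01)), distinct[2:5]),
    maps = NULL, sequence = strrep("A", 10), ss = ss)
  pool_dup$conformations[[2]] <- pool_dup$conformations[[1]] +
    matrix(rnorm(30, sd = 0.01), 10, 3)
  pool_dup$maps <- lapply(pool_dup$conformations, make_map, ss = ss)
  class(pool_dup) <- "cf_pool"
  sel_dup <- select_predictions(pool_dup)
  expect_equal(length(sel_dup$selected), 5)
  expect_equal(length(sel_dup$eliminated), 1)
  # the duplicate pair cannot both survive
  expect_false(all(c(1, 2) %in% sel_dup$selected))
  # small pools are returned whole, ranked
  small <- list(conformations = distinct[1:3],
                maps = lapply(distinct[1:3], make_map, ss = ss),
                sequence = strrep("A", 10), ss = ss)
  class(small) <- "cf_pool"
  expect_equal(length(select_predictions(small)$selected), 3)
})
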