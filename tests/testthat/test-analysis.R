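# Structural observables: superposition, TM score, alignable fraction,
# radius of gyration, fixation, native-like time, contact maps, summaries.

test_that("superposition recovers rigid transforms exactly", {
  set.seed(21)
  A <- make_fixture("random_coil", 10, seed = 2)
  sp <- superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  B <- rigid_move(A)
  sp2 <- superpose(A, B)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(A[1:2, ], B[1:2, ]), "3 points")
  # collinear points are degenerate
  C <- cbind(1:5 * 2, 0, 0)
  expect_error(superpose(C, C + 1), "collinear|degenerate")
})

test_that("superposed RMSD matches a rotation-grid oracle", {
  set.seed(31)
  for (rep in 1:3) {
    A <- matrix(rnorm(18, sd = 4), 6, 3)
    B <- matrix(rnorm(18, sd = 4), 6, 3)
    expect_equal(superpose(A, B)$rmsd, rmsd_grid_oracle(A, B),
                 tolerance = 1e-3)
    # independent cross-check against bio3d's fitted RMSD
    expect_equal(superpose(A, B)$rmsd,
                 bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)),
                             fit = TRUE),
                 tolerance = 1e-4)
  }
})

test_that("TM score is 1 for self and rigid copies and uses the d0 formula", {
  hx <- ideal_helix(20)
  expect_equal(tm_score(hx, hx), 1.0)
  set.seed(5)
  expect_equal(tm_score(rigid_move(hx), hx), 1.0, tolerance = 1e-6)
  expect_equal(tm_d0(20, clamp = FALSE), 1.24 * 5^(1 / 3) - 1.8,
               tolerance = 1e-12)
  expect_equal(tm_d0(20), 0.5)  # the scoring floor engages below 0.5 A
  expect_error(tm_score(hx[1:4, ], hx[1:4, ]), "fewer than 5")
})

test_that("TM score matches a dense grid-search oracle on 8-residue toys", {
  set.seed(8)
  native <- make_fixture("random_coil", 8, seed = 3)
  decoys <- make_fixture("decoy_pool", seed = 4, native = native,
                         rmsd = c(1, 3, 6), n_per_level = 1)
  for (d in decoys) {
    expect_lt(abs(tm_score(d, native) - tm_grid_oracle(d, native)), 0.01)
  }
})

test_that("alignable fraction behaves like a largest-subset search", {
  hx <- ideal_helix(12)
  expect_equal(maxsub_fraction(hx, hx), 1.0)
  # a 10x-dilated copy shares no 4-residue alignment within the cutoff
  expect_lte(maxsub_fraction(hx * 10, hx), 4 / 12)
  # monotone in the cutoff
  set.seed(9)
  d <- make_fixture("decoy_pool", seed = 7, native = hx, rmsd = 4,
                    n_per_level = 1)[[1]]
  f <- vapply(c(7, 5, 3, 1), function(ct) maxsub_fraction(d, hx, ct),
              numeric(1))
  expect_true(all(diff(f) <= 1e-12))
})

test_that("alignable fraction is bounded by the exhaustive-subset oracle", {
  set.seed(12)
  native <- make_fixture("random_coil", 8, seed = 13)
  for (r in c(1, 4)) {
    d <- make_fixture("decoy_pool", seed = r, native = native, rmsd = r,
                      n_per_level = 1)[[1]]
    greedy <- maxsub_fraction(d, native)
    best <- maxsub_subset_oracle(d, native)
    expect_lte(greedy, best + 1e-12)
    expect_gte(greedy, best - 2 / 8)  # within two residues of optimal
  }
  # near-identical structures: greedy finds the full subset
  d1 <- make_fixture("decoy_pool", seed = 2, native = native, rmsd = 0.5,
                     n_per_level = 1)[[1]]
  expect_equal(maxsub_fraction(d1, native), 1.0)
})

test_that("radius of gyration has its closed forms", {
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)  # two points at distance d: d/2
  hx <- ideal_helix(15)
  expect_equal(relative_rg(hx, hx), 1.0)
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(radius_of_gyration(X),
               sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2))))
  expect_error(relative_rg(X, matrix(1, 4, 3)), "degenerate")
})

test_that("rigid motion leaves the structural metrics unchanged", {
  set.seed(14)
  native <- make_fixture("random_coil", 10, seed = 5)
  model <- make_fixture("decoy_pool", seed = 6, native = native, rmsd = 3,
                        n_per_level = 1)[[1]]
  t0 <- tm_score(model, native)
  m0 <- maxsub_fraction(model, native)
  g0 <- relative_rg(model, native)
  for (rep in 1:2) {
    M <- rigid_move(model)
    expect_equal(tm_score(M, native), t0, tolerance = 0.01)
    expect_equal(maxsub_fraction(M, native), m0, tolerance = 0.101)
    expect_equal(relative_rg(M, native), g0, tolerance = 1e-9)
  }
})

test_that("fixation time equals its brute-force definition", {
  hx <- ideal_helix(8)
  # constant trajectory: first sample
  expect_equal(fixation_time(rep(list(hx), 6)), 1)
  # last sample breaks similarity: last index
  far <- hx * 5
  expect_equal(fixation_time(c(rep(list(hx), 5), list(far))), 6)
  # random walks against the O(n^2) oracle
  set.seed(17)
  for (rep in 1:3) {
    base <- make_fixture("random_coil", 6, seed = rep)
    samples <- list(base)
    for (i in 2:50) {
      samples[[i]] <- samples[[i - 1]] +
        matrix(rnorm(18, sd = runif(1, 0.1, 2)), 6, 3)
    }
    expect_equal(fixation_time(samples), fixation_brute(samples))
  }
})

test_that("native-like time counts threshold crossings", {
  hx <- ideal_helix(20)
  expect_equal(native_like_time(rep(list(hx), 4), hx), 100)
  coils <- lapply(1:5, function(s) make_fixture("random_coil", 20, seed = s))
  expect_equal(native_like_time(coils, hx), 0)
  mixed <- c(rep(list(hx), 3), coils[1:2])
  expect_equal(native_like_time(mixed, hx), 100 * 3 / 5)
})

test_that("contact maps respect smoothing, cutoffs and unit eligibility", {
  # straight coil chain (no smoothing): contacts only where the
  # hand-computed distance |i-j| * 3.8 falls under the 11 A cutoff
  L <- 12
  straight <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
  cm <- contact_map(straight, strrep("C", L), window = 1)
  expect_true(isSymmetric(cm$map))
  idx <- which(cm$map == 1, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - idx[, 2]) <= 2))
  # the truncated smoothing window only draws termini inward along the
  # trace, never creating long-range contacts
  cm9 <- contact_map(straight, strrep("C", L))
  idx9 <- which(cm9$map == 1, arr.ind = TRUE)
  expect_true(all(abs(idx9[, 1] - idx9[, 2]) <= 4))
  # residues of one helix run are ineligible however close
  cmh <- contact_map(ideal_helix(L), strrep("H", L))
  expect_equal(sum(cmh$map), 0)
  expect_false(any(cmh$eligible))
  # strand-strand pairs use the tighter 8 A cutoff (window 1: no smoothing,
  # so the inter-strand spacing of 9.5 A sits between the two cutoffs)
  two <- rbind(ideal_strand(6),
               sweep(ideal_strand(6), 2, c(0, 9.5, 0), "+"))
  ssEE <- paste0(strrep("E", 6), strrep("E", 6))
  ssCC <- strrep("C", 12)
  cm_e <- contact_map(two, ssEE, window = 1)
  cm_c <- contact_map(two, ssCC, window = 1)
  expect_lt(sum(cm_e$map[1:6, 7:12]), sum(cm_c$map[1:6, 7:12]))
  # eligibility is independent of coordinates
  cm2 <- contact_map(two + 100, ssEE)
  expect_identical(cm_e$eligible, cm2$eligible)
  # short chains still smooth (truncated window)
  expect_silent(contact_map(ideal_helix(5), "HHHHH"))
})

test_that("quartile summaries use linear interpolation", {
  expect_equal(unname(summary_quartiles(c(1, 2, 3))), c(2, 1.5, 2.5))
  expect_equal(unname(summary_quartiles(rep(7, 10))), c(7, 7, 7))
  set.seed(19)
  x <- rnorm(501)
  s <- sort(x)
  # direct order-statistic interpolation oracle
  oracle <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  expect_equal(unname(summary_quartiles(x)),
               c(oracle(0.5), oracle(0.25), oracle(0.75)))
  expect_error(summary_quartiles(numeric(0)), "empty")
})

test_that("foldable-protein selection is boundary inclusive", {
  nl <- c(a = 0, b = 9.99, c = 10, d = 35)
  expect_equal(select_foldable(nl), c("c", "d"))
  expect_equal(select_foldable(c(x = 0, y = 0)), character(0))
})
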