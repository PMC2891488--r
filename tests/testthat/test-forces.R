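# Force-field terms: Hooke's law, soft-core repulsion, hydrogen bonds,
# boundaries, and the whole-system evaluation.

test_that("harmonic force obeys Hooke's law and antisymmetry", {
  # equilibrium
  f <- harmonic_force(c(0, 0, 0), c(2, 0, 0), k = 1, L0 = 2)
  expect_equal(f$f_i, c(0, 0, 0))
  # stretched to twice the rest length: magnitude k*L0, attractive
  f <- harmonic_force(c(0, 0, 0), c(4, 0, 0), k = 1, L0 = 2)
  expect_equal(f$f_i, c(2, 0, 0))
  expect_equal(f$f_i, -f$f_j)
  # coincident points: zero force, logged once
  expect_warning(f0 <- harmonic_force(c(1, 1, 1), c(1, 1, 1), 1, 2),
                 "coincident")
  expect_equal(f0$f_i, c(0, 0, 0))
})

test_that("harmonic force matches the finite-difference spring gradient", {
  set.seed(7)
  for (rep in 1:5) {
    xi <- rnorm(3, sd = 3); xj <- rnorm(3, sd = 3)
    k <- runif(1, 0.2, 2); L0 <- runif(1, 0.5, 4)
    U <- function(x) {
      d <- sqrt(sum((x[1:3] - x[4:6])^2))
      0.5 * k * (d - L0)^2
    }
    g <- fd_gradient(U, c(xi, xj))
    f <- harmonic_force(xi, xj, k, L0)
    expect_equal(f$f_i, -g[1:3], tolerance = 1e-6)
    expect_equal(f$f_j, -g[4:6], tolerance = 1e-6)
  }
})

test_that("vdw ramp is purely repulsive with an exact cutoff", {
  ff <- default_ff_params()
  contact <- 4.0  # backbone-backbone
  f <- vdw_force("backbone", "backbone", c(0, 0, 0), c(contact + 0.01, 0, 0),
                 ff$vdw_table)
  expect_equal(f$f_i, c(0, 0, 0))
  f <- vdw_force("backbone", "backbone", c(0, 0, 0), c(contact / 2, 0, 0),
                 ff$vdw_table)
  expect_equal(f$f_i, c(-0.5, 0, 0))  # half max_repulsion, pushing i away
  expect_equal(f$f_i, -f$f_j)
})

test_that("a tabulated vdw profile overrides the ramp", {
  prof <- cbind(distance = c(0, 1, 2, 3, 4), force = c(5, 4, 1, 0.5, 0))
  hand <- function(r) approx(prof[, 1], prof[, 2], r)$y
  for (r in c(0.5, 1.5, 2.2, 3.7)) {
    f <- vdw_force("backbone", "backbone", c(0, 0, 0), c(r, 0, 0),
                   profile = prof)
    expect_equal(-f$f_i[1], hand(r), tolerance = 1e-12)
  }
  f <- vdw_force("backbone", "backbone", c(0, 0, 0), c(4.5, 0, 0),
                 profile = prof)
  expect_equal(f$f_i, c(0, 0, 0))
})

test_that("missing vdw pair falls back to the type-radii sum rule", {
  ff <- default_ff_params()
  tab <- ff$vdw_table[ff$vdw_table$type_i != "crowder" &
                        ff$vdw_table$type_j != "crowder", ]
  attr(tab, "type_radii") <- attr(ff$vdw_table, "type_radii")
  expect_warning(
    f <- vdw_force("crowder", "backbone", c(0, 0, 0), c(10, 0, 0), tab),
    "sum rule")
  # contact = 15 + 2 = 17, magnitude = 1 - 10/17
  expect_equal(-f$f_i[1], 1 - 10 / 17, tolerance = 1e-12)
})

test_that("hydrogen bonds are gated by distance and sequence separation", {
  ff <- default_ff_params()
  # far-apart extended chain: no hb at all
  ch <- build_chain(strrep("A", 8), strrep("E", 8))
  bb <- ideal_strand(8)
  pos <- matrix(0, nrow(ch$particles), 3)
  pos[ch$bb_id, ] <- bb
  pos[ch$sc_id, ] <- bb + matrix(c(0, 0, 4), 8, 3, byrow = TRUE)
  hb <- hb_force(ch, pos, ff)
  expect_equal(max(abs(hb)), 0)

  # two close strands: some pair attracts; forces are antisymmetric overall
  ch2 <- build_chain(strrep("G", 10), strrep("C", 10))
  bb2 <- rbind(ideal_strand(5),
               cbind(rev(ideal_strand(5)[, 1]), ideal_strand(5)[, 2] + 4.6,
                     0))
  hb2 <- hb_force(ch2, bb2, ff)
  expect_gt(max(abs(hb2)), 0)
  expect_equal(colSums(hb2), c(0, 0, 0), tolerance = 1e-9)
  # attraction: the two strands are pulled toward each other in y
  expect_gt(sum(hb2[1:5, 2]), 0)
  expect_lt(sum(hb2[6:10, 2]), 0)

  # near neighbours below the separation gate never bond
  ch3 <- build_chain(strrep("G", 4), strrep("C", 4))
  bb3 <- cbind(c(0, 2, 2.8, 4.5), c(0, 1.5, -1, 0.5), 0)  # compact kink
  hb3 <- hb_force(ch3, bb3, ff)
  expect_equal(max(abs(hb3)), 0)  # all pairs have |i-j| < hb_min_separation
})

test_that("boundary forces follow the stated spring laws", {
  ch <- build_chain("G", "C")
  scene <- make_scene(container_radius = 20, ribosome_radius = NA)
  ff <- default_ff_params()
  r <- default_solvent_radii()[["backbone"]]
  sys <- make_system(ch, scene, bb_xyz = matrix(c(5, 0, 0), 1, 3))
  expect_equal(max(abs(boundary_forces(sys, ff))), 0)
  # centre beyond the wall by delta: inward k * (delta + solvent_radius)
  delta <- 1.5
  sys$pos[1, ] <- c(20 + delta, 0, 0)
  bf <- boundary_forces(sys, ff)
  expect_equal(bf[1, ], c(-scene$k_boundary * (delta + r), 0, 0),
               tolerance = 1e-12)
  # particle surface just clear of the ribosome: zero ribosome term
  scene2 <- make_scene(container_radius = NA, ribosome_radius = 100)
  sys2 <- make_system(ch, scene2,
                      bb_xyz = matrix(scene2$ribosome_center +
                                        c(100 + r + 0.01, 0, 0), 1, 3))
  sys2$exit_id <- NA_integer_  # isolate the ribosome term from the anchor
  expect_equal(max(abs(boundary_forces(sys2, ff)[1, ])), 0)
  # penetrating surface: outward push
  sys2$pos[1, ] <- scene2$ribosome_center + c(100 + r / 2, 0, 0)
  bf2 <- boundary_forces(sys2, ff)
  expect_equal(bf2[1, 1], scene2$k_boundary * r / 2, tolerance = 1e-12)
})

test_that("total force equals the sum of its terms and is antisymmetric", {
  set.seed(11)
  ch <- build_chain("MKVLATGE", "HHHCCEEE")
  sys <- make_system(ch, bb_xyz = make_fixture("random_coil", 8, seed = 2))
  fr <- total_force(sys)
  summed <- fr$cov + fr$bb + fr$sc + fr$vdw + fr$hb + fr$boundary
  expect_equal(fr$total, summed, tolerance = 1e-12)
  # Newton's third law: internal pairwise terms sum to zero
  for (term in c("cov", "bb", "sc", "vdw", "hb")) {
    expect_equal(colSums(fr[[term]]), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("compiled spring terms agree with the per-pair R implementation", {
  set.seed(3)
  ch <- build_chain("AKVA", "CCCC")
  sys <- make_system(ch, bb_xyz = make_fixture("random_coil", 4, seed = 5))
  ff <- default_ff_params()
  fr <- total_force(sys, ff)
  ref <- matrix(0, nrow(sys$pos), 3)
  for (s in seq_len(nrow(sys$springs))) {
    sp <- sys$springs[s, ]
    f <- harmonic_force(sys$pos[sp$i, ], sys$pos[sp$j, ], sp$stiffness,
                        sp$rest_length)
    ref[sp$i, ] <- ref[sp$i, ] + f$f_i
    ref[sp$j, ] <- ref[sp$j, ] + f$f_j
  }
  expect_equal(fr$cov + fr$bb + fr$sc, ref, tolerance = 1e-12)
})

test_that("internal forces are invariant under rigid translation", {
  ch <- build_chain("MKVLAT", "CCCCCC")
  X <- make_fixture("random_coil", 6, seed = 9)
  sys <- make_system(ch, bb_xyz = X)
  f1 <- total_force(sys)
  sys2 <- sys
  sys2$pos <- sweep(sys$pos, 2, c(13.7, -4.2, 8.8), "+")
  f2 <- total_force(sys2)
  expect_equal(f1$total, f2$total, tolerance = 1e-9)
})
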