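# Independent oracles and small construction helpers shared across tests.
# These deliberately avoid the code paths they check: energies are summed in
# plain R, superpositions are grid searches, TM objectives are optimised
# numerically.

rand_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(X, R = rand_rotation(), t = rnorm(3, sd = 5)) {
  sweep(X %*% R, 2, t, "+")
}

euler_rot <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# free single particle wrapped in a 1-residue glycine chain
free_particle_system <- function(pos = c(0, 0, 0), vel = c(0, 0, 0)) {
  chain <- build_chain("G", "C")
  sys <- make_system(chain, bb_xyz = matrix(pos, 1, 3))
  sys$vel[1, ] <- vel
  sys
}

# conservative part of the potential (springs + vdw ramp + boundaries);
# the hydrogen-bond term is gated/non-conservative and must be off
system_energy <- function(system, ff) {
  U <- 0
  X <- system$pos
  for (s in seq_len(nrow(system$springs))) {
    i <- system$springs$i[s]
    j <- system$springs$j[s]
    if (!system$active[i] || !system$active[j]) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    U <- U + 0.5 * system$springs$stiffness[s] *
      (d - system$springs$rest_length[s])^2
  }
  radii <- attr(ff$vdw_table, "type_radii")
  tname <- c("backbone", "sidechain", "crowder")
  excl <- paste(pmin(system$springs$i, system$springs$j),
                pmax(system$springs$i, system$springs$j))
  idx <- which(system$role %in% 1:3 & system$active)
  if (length(idx) > 1) {
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (paste(min(i, j), max(i, j)) %in% excl) next
        ti <- tname[system$role[i]]; tj <- tname[system$role[j]]
        row <- ff$vdw_table[(ff$vdw_table$type_i == ti &
                               ff$vdw_table$type_j == tj) |
                              (ff$vdw_table$type_i == tj &
                                 ff$vdw_table$type_j == ti), ]
        contact <- if (nrow(row)) row$contact_distance[1] else
          radii[ti] + radii[tj]
        maxrep <- if (nrow(row)) row$max_repulsion[1] else 1
        r <- sqrt(sum((X[i, ] - X[j, ])^2))
        if (r < contact) U <- U + maxrep * contact / 2 * (1 - r / contact)^2
      }
    }
  }
  sc <- system$scene
  if (!is.null(sc)) {
    for (i in which(system$active & system$role != 4L)) {
      if (!is.na(sc$container_radius)) {
        over <- sqrt(sum((X[i, ] - sc$container_center)^2)) +
          system$solvent_radius[i] - sc$container_radius
        if (over > 0) U <- U + 0.5 * sc$k_boundary * over^2
      }
      if (!is.na(sc$ribosome_radius)) {
        pen <- sc$ribosome_radius + system$solvent_radius[i] -
          sqrt(sum((X[i, ] - sc$ribosome_center)^2))
        if (pen > 0) U <- U + 0.5 * sc$k_boundary * pen^2
      }
    }
  }
  U
}

# central-difference gradient of f at x
fd_gradient <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps
    xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# least-squares RMSD by rotation-grid search + polish (never uses SVD)
rmsd_grid_oracle <- function(A, B, coarse = 12) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = coarse + 1)[-1],
                      b = seq(0, pi, length.out = coarse %/% 2 + 1),
                      g = seq(0, 2 * pi, length.out = coarse + 1)[-1])
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt$value
}

# TM objective maximised by dense rotation grid + local polish over the full
# 6-dof rigid transform (independent of the fragment-seeded search)
tm_grid_oracle <- function(model, native, coarse = 14) {
  L <- nrow(native)
  d0 <- tm_d0(L)
  Mc <- sweep(model, 2, colMeans(model))
  obj6 <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    TM <- sweep(Mc %*% R, 2, p[4:6], "+")
    -mean(1 / (1 + (rowSums((TM - native)^2)) / d0^2))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = coarse + 1)[-1],
                      b = seq(0, pi, length.out = coarse %/% 2 + 1),
                      g = seq(0, 2 * pi, length.out = coarse + 1)[-1])
  cn <- colMeans(native)
  vals <- apply(grid, 1, function(p) obj6(c(as.numeric(p), cn)))
  top <- order(vals)[seq_len(60)]
  starts <- lapply(top, function(k) c(as.numeric(grid[k, ]), cn))
  # random restarts guard against basins the grid resolution misses
  for (r in seq_len(60)) {
    starts[[length(starts) + 1]] <- c(runif(3, 0, 2 * pi),
                                      cn + rnorm(3, sd = 3))
  }
  best <- Inf
  for (s in starts) {
    opt <- optim(s, obj6, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, opt$value)
  }
  -best
}

# exhaustive-subset MaxSub oracle: superpose on every residue subset of size
# >= 3, count residues within d_cut, return the best fraction
maxsub_subset_oracle <- function(model, native, d_cut = 5) {
  L <- nrow(native)
  best <- 0
  for (mask in seq_len(2^L - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(L) - 1)) > 0)
    if (length(sel) < 3) next
    sp <- tryCatch(superpose(model, native, subset = sel),
                   error = function(e) NULL)
    if (is.null(sp)) next
    d <- sqrt(rowSums((sp$transformed - native)^2))
    best <- max(best, sum(d < d_cut))
  }
  best / L
}

# O(n^2) brute-force fixation oracle straight from the definition
fixation_brute <- function(samples, theta = 4) {
  n <- length(samples)
  D <- lapply(samples, function(s) as.numeric(dist(s)))
  for (t in seq_len(n)) {
    if (t == n) return(n)
    sim <- vapply((t + 1):n, function(u) mean(abs(D[[u]] - D[[t]])) < theta,
                  logical(1))
    if (all(sim)) return(t)
  }
  n
}
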