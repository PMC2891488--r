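# Force field: every term is pairwise and obeys Newton's third law.  The
# per-pair operations here are plain R; whole-system evaluation goes through
# the compiled core (cpp_forces), and the two routes are cross-checked in the
# test suite.

.cf_env <- new.env(parent = emptyenv())

.log_once <- function(key, msg) {
  if (is.null(.cf_env[[key]])) {
    .cf_env[[key]] <- TRUE
    warning(msg, call. = FALSE)
  }
}

#' Harmonic spring force between two points
#'
#' Restores the distance toward the rest length `L0` with magnitude
#' `k * |d - L0|`.  Coincident points with a positive rest length have no
#' defined direction: the force is zero and the degenerate geometry is
#' logged once.
#'
#' @param x_i,x_j 3-vectors, Angstrom
#' @param k stiffness
#' @param L0 rest length, Angstrom
#' @return list with `f_i` and `f_j` (`f_i == -f_j`)
#' @export
harmonic_force <- function(x_i, x_j, k, L0) {
  d <- x_j - x_i
  r <- sqrt(sum(d^2))
  if (r < 1e-12) {
    if (L0 > 0) {
      .log_once("harm_degenerate",
                "harmonic_force: coincident points with L0 > 0; zero force")
    }
    z <- c(0, 0, 0)
    return(list(f_i = z, f_j = z))
  }
  f <- k * (r - L0) * d / r
  list(f_i = f, f_j = -f)
}

#' Soft-core repulsive (van der Waals proxy) force between two particles
#'
#' Purely repulsive, zero at and beyond the pair's contact distance.  The
#' default profile ramps linearly from `max_repulsion` at zero separation to
#' zero at contact, standing in for a statistical clash-probability profile;
#' a tabulated `(distance, force)` profile can be supplied to override the
#' ramp (piecewise-linear interpolation, zero outside the table's range).
#'
#' @param type_i,type_j particle type names (`"backbone"`, `"sidechain"`,
#'   `"crowder"`)
#' @param x_i,x_j 3-vector positions, Angstrom
#' @param table pair table as in `default_ff_params()$vdw_table`; a missing
#'   pair falls back to the type-radii sum rule (logged once)
#' @param profile optional 2-column matrix/data.frame (distance, force)
#' @return list with `f_i`, `f_j`
#' @export
vdw_force <- function(type_i, type_j, x_i, x_j,
                      table = default_ff_params()$vdw_table,
                      profile = NULL) {
  d <- x_j - x_i
  r <- sqrt(sum(d^2))
  z <- c(0, 0, 0)
  if (r < 1e-12) return(list(f_i = z, f_j = z))
  if (is.null(profile)) {
    row <- table[(table$type_i == type_i & table$type_j == type_j) |
                   (table$type_i == type_j & table$type_j == type_i), ]
    if (nrow(row)) {
      contact <- row$contact_distance[1]
      maxrep <- row$max_repulsion[1]
    } else {
      radii <- attr(table, "type_radii")
      if (is.null(radii) || !all(c(type_i, type_j) %in% names(radii))) {
        stop("no vdw entry for pair (", type_i, ", ", type_j,
             ") and no type radii to fall back on")
      }
      .log_once(paste0("vdw_fallback_", type_i, type_j),
                paste0("vdw_force: no table entry for (", type_i, ", ",
                       type_j, "); using type-radii sum rule"))
      contact <- radii[[type_i]] + radii[[type_j]]
      maxrep <- max(table$max_repulsion, 1)
    }
    mag <- if (r >= contact) 0 else maxrep * (1 - r / contact)
  } else {
    profile <- as.matrix(profile)
    mag <- approx(profile[, 1], profile[, 2], xout = r, yleft = profile[1, 2],
                  yright = 0, rule = 2)$y
    if (r > max(profile[, 1])) mag <- 0
  }
  f <- -mag * d / r  # push i away from j
  list(f_i = f, f_j = -f)
}

# shared builder for calls into the compiled force kernel
.forces_cpp <- function(system, ff, terms_off = character(0)) {
  sp <- .springs_cpp(system)
  ffc <- .ff_cpp(system, ff)
  if ("vdw" %in% terms_off) ffc$vdw_maxrep[] <- 0
  if ("hb" %in% terms_off) ffc$hb_strength <- 0
  if ("springs" %in% terms_off) {
    sp <- list(i = integer(0), j = integer(0), L0 = numeric(0),
               k = numeric(0), cat = integer(0))
  }
  scn <- .scene_cpp(system, ff)
  if ("boundary" %in% terms_off) {
    scn$container_radius <- NA_real_
    scn$ribosome_radius <- NA_real_
    scn$anchor_id <- -1L
  }
  tether_to <- if ("tether" %in% terms_off || is.na(system$tether_to))
    -1L else system$tether_to - 1L
  cpp_forces(system$pos, system$solvent_radius, system$role,
             system$active, sp$i, sp$j, sp$L0, sp$k, sp$cat,
             tether_to, ff$k_tether, ff$cov_ca_ca,
             if (is.na(system$exit_id)) -1L else system$exit_id - 1L,
             as.integer(system$res_bb - 1L), scn, ffc)
}

#' Backbone hydrogen-bonding forces
#'
#' Virtual O/H sites are placed at +/- half a backbone bond length along the
#' local chain bisector of each (non-terminal) backbone particle.  Backbone
#' pairs at sequence separation of at least `hb_min_separation` whose
#' closest opposite-sense virtual sites come within `hb_threshold` are
#' pulled together along the virtual-site axis with the fixed strength
#' `hb_strength`; all other pairs feel nothing.
#'
#' @param chain a [build_chain()] result
#' @param positions n_particle x 3 coordinate matrix for the chain particles
#' @param ff force-field parameters
#' @return n x 3 matrix of hydrogen-bond forces on the chain particles
#' @export
hb_force <- function(chain, positions, ff = default_ff_params()) {
  sys <- make_system(chain, scene = NULL,
                     bb_xyz = positions[chain$bb_id, , drop = FALSE], ff = ff)
  sys$pos <- positions
  .forces_cpp(sys, ff, terms_off = c("springs", "vdw", "boundary",
                                     "tether"))$hb
}

#' Boundary and tether forces
#'
#' Container: an inward spring of stiffness `k_boundary` acts on any
#' non-ribosome particle whose solvent sphere extends past the container
#' wall, with magnitude `k_boundary * (overshoot + solvent_radius)` once the
#' centre passes the wall.  Ribosome: an outward force expels any particle
#' whose surface penetrates the ribosome sphere.  The exit particle is
#' anchored to the container centre by a spring.
#'
#' @param system a [make_system()] result
#' @param ff force-field parameters
#' @return n x 3 matrix of boundary-term forces
#' @export
boundary_forces <- function(system, ff = default_ff_params()) {
  .forces_cpp(system, ff, terms_off = c("springs", "vdw", "hb"))$boundary
}

#' Total force field with per-term breakdown
#'
#' Sum of covalent, backbone-geometry, side-chain, van der Waals,
#' hydrogen-bond and boundary terms.  Every internal term is pairwise and
#' antisymmetric, so the internal contributions sum to the zero vector.
#'
#' @param system a [make_system()] result
#' @param ff force-field parameters
#' @return object of class `cf_force_report`: list with `total` and the
#'   per-term matrices `cov`, `bb`, `sc`, `vdw`, `hb`, `boundary`
#' @export
total_force <- function(system, ff = default_ff_params()) {
  rep <- .forces_cpp(system, ff)
  class(rep) <- "cf_force_report"
  rep
}

#' @export
print.cf_force_report <- function(x, ...) {
  mag <- sqrt(rowSums(x$total^2))
  cat("cf_force_report:", nrow(x$total), "particles; |F| max",
      signif(max(mag), 4), " mean", signif(mean(mag), 4), "\n")
  invisible(x)
}
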