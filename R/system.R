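# Particle-system assembly: chain + ribosome + exit point + crowders inside
# the containing sphere.  Role codes used by the compiled core:
# 1 backbone, 2 sidechain, 3 crowder, 4 ribosome, 5 exit_point.

.role_codes <- c(backbone = 1L, sidechain = 2L, crowder = 3L,
                 ribosome = 4L, exit_point = 5L)
.cat_codes <- c(cov = 1L, bb = 2L, sc = 3L, tether = 4L, boundary = 5L)

#' Define the simulated cell
#'
#' The container sphere (default diameter 100 A) holds the protein and the
#' crowding macromolecules.  The ribosome is a heavy sphere of radius 100 A
#' from which all particles are excluded; the synthesis exit point sits on
#' its surface and is tethered to the container centre by a spring so the
#' protein is synthesized into the middle of the crowded volume.  Crowders
#' are spheres of diameter 30 A and mass 150 base masses, standing in for
#' previously synthesized ~75-residue proteins whose only modelled effect
#' is volume exclusion.
#'
#' @param container_radius containing-sphere radius, Angstrom (NA = open
#'   space, no container)
#' @param ribosome_radius ribosome-sphere radius, Angstrom (NA/0 = none)
#' @param crowder_radius,crowder_mass crowder sphere radius (A) and mass
#'   (base-particle units)
#' @param target_fraction target excluded-volume fraction in [0, 0.74)
#' @param k_boundary boundary/exclusion spring stiffness
#' @param container_center 3-vector, Angstrom
#' @param volume_denominator `"ribosome_free"` (default: the container
#'   volume not occupied by the ribosome) or `"container"` (whole container)
#'   for excluded-volume accounting
#' @return object of class `cf_scene`
#' @export
make_scene <- function(container_radius = 50, ribosome_radius = 100,
                       crowder_radius = 15, crowder_mass = 150,
                       target_fraction = 0, k_boundary = 1,
                       container_center = c(0, 0, 0),
                       volume_denominator = c("ribosome_free", "container")) {
  volume_denominator <- match.arg(volume_denominator)
  has_rib <- !is.na(ribosome_radius) && ribosome_radius > 0
  has_cont <- !is.na(container_radius) && is.finite(container_radius)
  if (has_cont && crowder_radius >= container_radius) {
    stop("crowder_radius must be smaller than container_radius")
  }
  if (target_fraction < 0 || target_fraction >= close_packing_fraction()) {
    stop("target_fraction must lie in [0, ", round(close_packing_fraction(), 4),
         ") (close-packing bound)")
  }
  sc <- list(
    container_radius = if (has_cont) container_radius else NA_real_,
    container_center = container_center,
    ribosome_radius = if (has_rib) ribosome_radius else NA_real_,
    # exit point sits at the container centre, on the ribosome surface
    ribosome_center = if (has_rib)
      container_center + c(-ribosome_radius, 0, 0) else c(NA_real_, NA, NA),
    exit_point = container_center,
    crowder_radius = crowder_radius, crowder_mass = crowder_mass,
    target_fraction = target_fraction, k_boundary = k_boundary,
    volume_denominator = volume_denominator
  )
  class(sc) <- "cf_scene"
  sc
}

#' Maximum sphere-packing fraction
#'
#' Densest packing of equal spheres (face-centred cubic), the hard upper
#' bound on any target excluded-volume fraction.
#'
#' @return pi / (3 sqrt(2)), about 0.7405
#' @export
close_packing_fraction <- function() pi / (3 * sqrt(2))

# place side-chain centroids from a backbone trace: push each centroid away
# from the local backbone axis
chain_positions <- function(chain, bb_xyz, ff = default_ff_params()) {
  L <- nchar(chain$sequence)
  stopifnot(nrow(bb_xyz) == L)
  n <- nrow(chain$particles)
  pos <- matrix(0, n, 3)
  pos[chain$bb_id, ] <- bb_xyz
  for (i in seq_len(L)) {
    si <- chain$sc_id[i]
    if (is.na(si)) next
    a <- bb_xyz[max(1, i - 1), ]
    b <- bb_xyz[min(L, i + 1), ]
    dir <- bb_xyz[i, ] - (a + b) / 2
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-6) dir <- c(0, 0, 1) else dir <- dir / nd
    d_sc <- unname(ff$cov_ca_centroid[chain$residues$aa[i]])
    pos[si, ] <- bb_xyz[i, ] + d_sc * dir
  }
  pos
}

#' Assemble a particle system
#'
#' Combines a protein chain with an optional scene (ribosome + exit point +
#' crowders + container).  For a free-folding system supply backbone
#' coordinates; for co-translational synthesis pass `synthesized = 0` and
#' the chain particles start inactive, appearing at the exit point as the
#' synthesis schedule runs.
#'
#' @param chain a [build_chain()] result
#' @param scene a [make_scene()] result, or NULL for open space
#' @param bb_xyz L x 3 backbone coordinates (required unless synthesizing)
#' @param crowder_xyz n x 3 crowder centres (see [place_crowders()])
#' @param synthesized number of residues already synthesized; use 0 to start
#'   co-translational synthesis, or `nchar(sequence)` (default) for a
#'   complete chain
#' @param ff force-field parameters
#' @return object of class `cf_system`
#' @export
make_system <- function(chain, scene = NULL, bb_xyz = NULL,
                        crowder_xyz = NULL,
                        synthesized = nchar(chain$sequence),
                        ff = default_ff_params()) {
  L <- nchar(chain$sequence)
  nc <- nrow(chain$particles)
  has_rib <- !is.null(scene) && !is.na(scene$ribosome_radius)
  ncr <- if (is.null(crowder_xyz)) 0L else nrow(crowder_xyz)
  n <- nc + (if (has_rib) 2L else 0L) + ncr

  pos <- matrix(0, n, 3)
  mass <- rep(1, n)
  srad <- rep(0, n)
  role <- integer(n)
  hydro <- logical(n)
  residue <- rep(NA_integer_, n)
  active <- logical(n)

  role[seq_len(nc)] <- .role_codes[chain$particles$role]
  hydro[seq_len(nc)] <- chain$particles$hydrophobic
  residue[seq_len(nc)] <- chain$particles$residue
  mass[seq_len(nc)] <- chain$particles$mass
  srad[seq_len(nc)] <- chain$particles$solvent_radius

  if (synthesized > 0) {
    if (is.null(bb_xyz)) stop("bb_xyz required when the chain pre-exists")
    pos[seq_len(nc), ] <- chain_positions(chain, bb_xyz, ff)
    keep <- chain$particles$residue <= synthesized
    active[seq_len(nc)][keep] <- TRUE
  } else if (has_rib) {
    pos[seq_len(nc), ] <- matrix(scene$exit_point, nc, 3, byrow = TRUE)
  } else {
    stop("synthesis requires a scene with a ribosome exit point")
  }

  exit_id <- NA_integer_
  rib_id <- NA_integer_
  if (has_rib) {
    exit_id <- nc + 1L
    rib_id <- nc + 2L
    pos[exit_id, ] <- scene$exit_point
    role[exit_id] <- .role_codes["exit_point"]
    mass[exit_id] <- 1e5  # ribosome-scale: effectively immobile
    srad[exit_id] <- 2.0
    active[exit_id] <- TRUE
    pos[rib_id, ] <- scene$ribosome_center
    role[rib_id] <- .role_codes["ribosome"]
    mass[rib_id] <- 1e9
    srad[rib_id] <- scene$ribosome_radius
    active[rib_id] <- TRUE
  }
  crowder_ids <- integer(0)
  if (ncr > 0) {
    crowder_ids <- nc + (if (has_rib) 2L else 0L) + seq_len(ncr)
    pos[crowder_ids, ] <- crowder_xyz
    role[crowder_ids] <- .role_codes["crowder"]
    mass[crowder_ids] <- scene$crowder_mass
    srad[crowder_ids] <- scene$crowder_radius
    active[crowder_ids] <- TRUE
  }

  springs <- chain$springs
  sys <- list(pos = pos, vel = matrix(0, n, 3), mass = mass,
              solvent_radius = srad, role = role, hydrophobic = hydro,
              residue = residue, active = active, springs = springs,
              res_bb = chain$bb_id, res_sc = ifelse(is.na(chain$sc_id), -1L,
                                                    chain$sc_id),
              exit_id = exit_id, ribosome_id = rib_id,
              crowder_ids = crowder_ids,
              tether_to = if (synthesized == 0 || !has_rib) NA_integer_ else
                chain$bb_id[synthesized],
              synthesized = as.integer(synthesized),
              sequence = chain$sequence, ss = chain$ss, scene = scene)
  # a freshly completed chain is no longer tethered
  if (synthesized >= L) sys$tether_to <- NA_integer_
  class(sys) <- "cf_system"
  sys
}

#' @export
print.cf_system <- function(x, ...) {
  cat("cf_system:", nrow(x$pos), "particles (",
      sum(x$role %in% 1:2), "protein,", length(x$crowder_ids), "crowders )",
      if (!is.na(x$exit_id)) "+ ribosome/exit" else "", "\n")
  invisible(x)
}

# ---- compiled-core argument builders ---------------------------------------

.scene_cpp <- function(system, ff) {
  sc <- system$scene
  if (is.null(sc)) {
    return(list(container_radius = NA_real_, container_center = c(0, 0, 0),
                ribosome_radius = NA_real_, ribosome_center = c(0, 0, 0),
                k_boundary = 0, anchor_id = -1L, anchor_point = c(0, 0, 0),
                anchor_k = 0, anchor_L0 = 0))
  }
  list(container_radius = sc$container_radius,
       container_center = sc$container_center,
       ribosome_radius = sc$ribosome_radius,
       ribosome_center = if (is.na(sc$ribosome_radius)) c(0, 0, 0) else
         sc$ribosome_center,
       k_boundary = sc$k_boundary,
       anchor_id = if (is.na(system$exit_id)) -1L else system$exit_id - 1L,
       anchor_point = sc$container_center,
       anchor_k = ff$k_tether, anchor_L0 = 0)
}

.ff_cpp <- function(system, ff) {
  radii <- attr(ff$vdw_table, "type_radii")
  tnames <- c("backbone", "sidechain", "crowder")
  contact <- matrix(0, 5, 5)
  maxrep <- matrix(0, 5, 5)
  for (a in 1:3) {
    for (b in 1:3) {
      row <- ff$vdw_table[(ff$vdw_table$type_i == tnames[a] &
                             ff$vdw_table$type_j == tnames[b]) |
                            (ff$vdw_table$type_i == tnames[b] &
                               ff$vdw_table$type_j == tnames[a]), ]
      if (nrow(row)) {
        contact[a, b] <- row$contact_distance[1]
        maxrep[a, b] <- row$max_repulsion[1]
      } else if (!is.null(radii)) {
        # fall back to the type-radii sum rule
        contact[a, b] <- radii[tnames[a]] + radii[tnames[b]]
        maxrep[a, b] <- max(ff$vdw_table$max_repulsion, 1)
      }
    }
  }
  list(vdw_contact = contact, vdw_maxrep = maxrep,
       excl_i = as.integer(system$springs$i - 1L),
       excl_j = as.integer(system$springs$j - 1L),
       hb_threshold = ff$hb_threshold, hb_strength = ff$hb_strength,
       hb_min_sep = as.integer(ff$hb_min_separation),
       hb_offset = 0.5 * ff$cov_ca_ca)
}

.lp_cpp <- function(lp) {
  list(gamma = lp$gamma, kick_rate = lp$kick_rate, kick_speed = lp$kick_speed,
       hydrophobic_multiplier = lp$hydrophobic_multiplier, dt = lp$dt,
       speed_cap = lp$speed_cap, neighbor_cutoff = lp$neighbor_cutoff,
       exposure_every = lp$exposure_every,
       rays = fibonacci_sphere(lp$exposure_rays))
}

.springs_cpp <- function(system) {
  sp <- system$springs
  list(i = as.integer(sp$i - 1L), j = as.integer(sp$j - 1L),
       L0 = as.numeric(sp$rest_length), k = as.numeric(sp$stiffness),
       cat = unname(.cat_codes[sp$category]))
}
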