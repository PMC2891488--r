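#' @useDynLib crowdfold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile runif rnorm approx setNames
#' @importFrom utils read.table write.csv head tail
NULL

# one-letter alphabet and per-residue tables ---------------------------------

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy; positive values flag hydrophobic side chains
.aa_kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
            H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
            P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
            W = -0.9, Y = -1.3)

# side-chain heavy-atom counts (used to scale solvent radii)
.aa_heavy <- c(A = 1, C = 2, D = 4, E = 5, F = 7, G = 0, H = 6, I = 4,
               K = 5, L = 4, M = 4, N = 4, P = 3, Q = 5, R = 7, S = 2,
               T = 3, V = 3, W = 10, Y = 8)

# approximate C-alpha to side-chain-centroid distances (Angstrom)
.aa_centroid <- c(A = 1.53, C = 2.07, D = 2.47, E = 3.11, F = 3.41, G = 0,
                  H = 3.16, I = 2.31, K = 3.53, L = 2.60, M = 3.19, N = 2.49,
                  P = 1.87, Q = 3.13, R = 4.12, S = 1.90, T = 1.93, V = 1.97,
                  W = 3.86, Y = 3.84)

#' Default solvent radii table
#'
#' One backbone radius plus per-residue side-chain radii that grow with the
#' cube root of the side chain's heavy-atom count (i.e. roughly with its
#' volume).  These stand in for radii that would otherwise be fitted against
#' decoy sets; they are plain configuration and can be replaced wholesale
#' with [read_radii_table()].
#'
#' @return Named numeric vector of radii in Angstrom.  The element
#'   `"backbone"` applies to all backbone particles; the one-letter elements
#'   apply to the corresponding side-chain particles.
#' @export
default_solvent_radii <- function() {
  sc <- setNames(pmax(1.6, 1.7 * .aa_heavy^(1 / 3)), names(.aa_heavy))
  sc["G"] <- 0
  c(backbone = 2.0, sc)
}

#' Read a solvent radii table from a text file
#'
#' Whitespace-delimited, two columns (particle_type, radius_A), `#` comments.
#' Particle types are `backbone` or one-letter amino-acid codes.
#'
#' @param path file path
#' @return named numeric vector usable as `lp$solvent_radii`
#' @export
read_radii_table <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("type", "radius"),
                    stringsAsFactors = FALSE)
  if (any(tab$radius < 0)) stop("solvent radii must be >= 0 in ", path)
  setNames(tab$radius, tab$type)
}

# ideal-geometry helpers used to derive spring rest lengths and fixtures ----

#' Ideal alpha-helix C-alpha trace
#'
#' Rise 1.5 A per residue and 100 degree twist; the helix radius is set so
#' that consecutive C-alpha atoms are `ca_ca` apart.
#'
#' @param L residue count
#' @param rise rise per residue, Angstrom
#' @param twist twist per residue, degrees
#' @param ca_ca consecutive C-alpha distance, Angstrom
#' @return L x 3 coordinate matrix
#' @export
ideal_helix <- function(L, rise = 1.5, twist = 100, ca_ca = 3.8) {
  th <- twist * pi / 180
  r <- sqrt(ca_ca^2 - rise^2) / (2 * sin(th / 2))
  i <- seq_len(L) - 1
  cbind(r * cos(i * th), r * sin(i * th), i * rise)
}

#' Ideal extended-strand C-alpha trace
#'
#' Planar zigzag with consecutive C-alpha distance `ca_ca` and an axial rise
#' chosen to match extended-chain geometry (~3.32 A per residue).
#'
#' @inheritParams ideal_helix
#' @param axial_rise rise per residue along the strand axis, Angstrom
#' @return L x 3 coordinate matrix
#' @export
ideal_strand <- function(L, ca_ca = 3.8, axial_rise = 3.32) {
  h <- sqrt(ca_ca^2 - axial_rise^2)
  i <- seq_len(L) - 1
  cbind(i * axial_rise, (i %% 2) * h, 0)
}

.pair_dist <- function(xyz, sep) {
  i <- seq_len(nrow(xyz) - sep)
  mean(sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[i + sep, , drop = FALSE])^2)))
}

# force-field parameter container --------------------------------------------

#' Default force-field parameters
#'
#' Stiffnesses are in force units per Angstrom, lengths in Angstrom, masses
#' in base-particle units, and time in iterations throughout the package.
#' The backbone-geometry springs (sequence separations 2 and 3) take their
#' rest lengths from ideal alpha-helix and extended-strand geometry; mixed
#' or coil pairs use intermediate coil values.  The van der Waals term is a
#' purely repulsive linear ramp from `vdw_max_repulsion` at zero distance to
#' zero at the pair's contact distance (the sum of the two particle types'
#' contact radii, or an entry from a user-supplied table).
#'
#' @param k_cov,k_bb,k_sc,k_tether,k_boundary spring stiffnesses
#' @param hb_threshold virtual O/H site distance below which the backbone
#'   hydrogen-bond attraction engages, Angstrom
#' @param hb_strength magnitude of the (constant) hydrogen-bond force
#' @param hb_min_separation minimum sequence separation for hydrogen bonds
#' @param vdw_max_repulsion repulsion magnitude at zero distance between
#'   protein particles
#' @param crowder_repulsion crowder-crowder repulsion at zero distance;
#'   much stiffer than the protein soft-core because crowders stand in for
#'   the hard excluded volume of folded proteins and must jam into
#'   effectively rigid walls
#' @param crowder_protein_repulsion crowder-protein repulsion at zero
#'   distance; firm but moderate, so wall contact does not inject
#'   unphysical agitation into the chain
#' @return object of class `cf_ff` (a named list)
#' @export
default_ff_params <- function(k_cov = 1.0, k_bb = 0.3, k_sc = 0.3,
                              k_tether = 1.0, k_boundary = 1.0,
                              hb_threshold = 3.0, hb_strength = 0.25,
                              hb_min_separation = 3,
                              vdw_max_repulsion = 1.0,
                              crowder_repulsion = 20,
                              crowder_protein_repulsion = 3) {
  hx <- ideal_helix(8)
  st <- ideal_strand(8)
  bb_rest <- list(
    HH = c(`2` = .pair_dist(hx, 2), `3` = .pair_dist(hx, 3)),
    EE = c(`2` = .pair_dist(st, 2), `3` = .pair_dist(st, 3)),
    CC = c(`2` = 6.0, `3` = 7.5)
  )
  # contact radii by particle type; pair contact distance is their sum
  type_radii <- c(backbone = 2.0, sidechain = 2.2, crowder = 15.0)
  vdw_table <- expand.grid(type_i = names(type_radii),
                           type_j = names(type_radii),
                           stringsAsFactors = FALSE)
  vdw_table <- vdw_table[as.integer(factor(vdw_table$type_i,
                                           names(type_radii))) <=
                         as.integer(factor(vdw_table$type_j,
                                           names(type_radii))), ]
  vdw_table$contact_distance <- type_radii[vdw_table$type_i] +
    type_radii[vdw_table$type_j]
  vdw_table$max_repulsion <- vdw_max_repulsion
  is_cr_i <- vdw_table$type_i == "crowder"
  is_cr_j <- vdw_table$type_j == "crowder"
  vdw_table$max_repulsion[is_cr_i & is_cr_j] <- crowder_repulsion
  vdw_table$max_repulsion[xor(is_cr_i, is_cr_j)] <- crowder_protein_repulsion
  rownames(vdw_table) <- NULL
  attr(vdw_table, "type_radii") <- type_radii
  ff <- list(k_cov = k_cov, k_bb = k_bb, k_sc = k_sc, k_tether = k_tether,
             k_boundary = k_boundary, bb_rest_lengths = bb_rest,
             cov_ca_ca = 3.8, cov_ca_centroid = .aa_centroid,
             vdw_table = vdw_table, hb_threshold = hb_threshold,
             hb_strength = hb_strength,
             hb_min_separation = as.integer(hb_min_separation))
  class(ff) <- "cf_ff"
  validate_ff(ff)
  ff
}

validate_ff <- function(ff) {
  ks <- unlist(ff[c("k_cov", "k_bb", "k_sc", "k_tether", "k_boundary")])
  if (any(ks < 0)) stop("all stiffnesses must be >= 0")
  for (p in c("HH", "EE", "CC")) {
    if (!all(c("2", "3") %in% names(ff$bb_rest_lengths[[p]]))) {
      stop("bb_rest_lengths must define separations 2 and 3 for ", p)
    }
  }
  if (any(unlist(ff$bb_rest_lengths) < 0)) stop("rest lengths must be >= 0")
  invisible(ff)
}

#' Default Langevin / solvent parameters
#'
#' Drag and kicks act per unit of solvent-exposed surface area: the drag
#' force is `-gamma * accessible_area * v` and kicks arrive as a Poisson
#' process with mean `kick_rate * accessible_area` per iteration (multiplied
#' by `hydrophobic_multiplier` for hydrophobic side-chain particles).  All
#' kicks change speed by `kick_speed / mass`.  Exposure is estimated by
#' casting a fixed quasi-uniform set of `exposure_rays` directions
#' (Fibonacci sphere), so exposure is deterministic and trajectories are
#' reproducible from the seed alone.
#'
#' @param gamma drag coefficient per Angstrom^2 of exposed area per iteration
#' @param kick_speed speed change per kick on a unit-mass particle, A/iter
#' @param kick_rate kick probability per Angstrom^2 exposed area per iteration
#' @param hydrophobic_multiplier kick-rate multiplier for hydrophobic
#'   side-chain particles (>= 1); this is the only effect of hydrophobicity
#' @param dt iteration time unit
#' @param exposure_rays number of exposure test rays (>= 1)
#' @param neighbor_cutoff occluder search distance, Angstrom
#' @param speed_cap maximum particle speed, A/iter (numerical stability
#'   device, not physics)
#' @param exposure_every recompute exposure every this many iterations
#' @param solvent_radii named radii vector, see [default_solvent_radii()]
#' @param seed optional RNG seed recorded with runs
#' @return object of class `cf_lp` (a named list)
#' @export
default_langevin_params <- function(gamma = 0.01, kick_speed = 1.0,
                                    kick_rate = 0.002,
                                    hydrophobic_multiplier = 3,
                                    dt = 1, exposure_rays = 32,
                                    neighbor_cutoff = 12, speed_cap = 1.5,
                                    exposure_every = 1,
                                    solvent_radii = default_solvent_radii(),
                                    seed = NULL) {
  lp <- list(gamma = gamma, kick_speed = kick_speed, kick_rate = kick_rate,
             hydrophobic_multiplier = hydrophobic_multiplier, dt = dt,
             exposure_rays = as.integer(exposure_rays),
             neighbor_cutoff = neighbor_cutoff, speed_cap = speed_cap,
             exposure_every = as.integer(exposure_every),
             solvent_radii = solvent_radii, seed = seed)
  class(lp) <- "cf_lp"
  validate_lp(lp)
  lp
}

validate_lp <- function(lp) {
  if (lp$gamma < 0) stop("gamma must be >= 0")
  if (lp$kick_rate < 0) stop("kick_rate must be >= 0")
  if (lp$hydrophobic_multiplier < 1) {
    stop("hydrophobic_multiplier must be >= 1")
  }
  if (lp$exposure_rays < 1) stop("exposure_rays must be >= 1")
  if (lp$exposure_every < 1) stop("exposure_every must be >= 1")
  invisible(lp)
}

#' Default parameter set
#'
#' @return list with elements `ff` ([default_ff_params()]) and `lp`
#'   ([default_langevin_params()])
#' @export
default_params <- function() {
  list(ff = default_ff_params(), lp = default_langevin_params())
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read a van der Waals pair table
#'
#' Whitespace-delimited text with columns
#' (type_i, type_j, contact_distance_A, max_repulsion); `#` comments.
#'
#' @param path file path
#' @return data.frame in the format of `default_ff_params()$vdw_table`
#' @export
read_vdw_table <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("type_i", "type_j", "contact_distance",
                                  "max_repulsion"),
                    stringsAsFactors = FALSE)
  if (any(tab$contact_distance < 0) || any(tab$max_repulsion < 0)) {
    stop("contact distances and repulsions must be >= 0 in ", path)
  }
  tab
}

# short digest of a configuration, recorded with trajectories for provenance
config_digest <- function(...) {
  obj <- list(...)
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}
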