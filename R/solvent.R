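# Hybrid implicit-explicit solvent: drag and directional kicks act only on
# solvent-exposed surface, estimated by ray casting against neighbouring
# solvent spheres.  Buried particles feel no solvent at all; hydrophobic
# side chains are kicked more often, which drives hydrophobic collapse.

#' Solvent-exposed fraction of each particle
#'
#' Casts a fixed quasi-uniform set of `lp$exposure_rays` directions from
#' each particle and reports the fraction not blocked by any neighbouring
#' particle's solvent sphere within `lp$neighbor_cutoff`.  Deterministic
#' given the ray set; an isolated particle has fraction 1.
#'
#' @param system a [make_system()] result
#' @param lp Langevin parameters, see [default_langevin_params()]
#' @return list with `fraction` (in [0,1]) and `area`
#'   (fraction x 4 pi solvent_radius^2, Angstrom^2) per particle
#' @export
exposed_fraction <- function(system, lp = default_langevin_params()) {
  cpp_exposure(system$pos, system$solvent_radius, system$role, system$active,
               fibonacci_sphere(lp$exposure_rays), lp$neighbor_cutoff)
}

#' Sample solvent kicks for one iteration
#'
#' Per particle, the kick count is Poisson with mean
#' `kick_rate x accessible_area`, multiplied by `hydrophobic_multiplier`
#' for hydrophobic side-chain particles.  Each kick has a uniformly random
#' direction; kicks arriving from a direction blocked by another particle
#' are discarded (not resampled), so crowded particles receive fewer kicks.
#' Velocity increments have magnitude `kick_speed / mass`.
#'
#' @param system a [make_system()] result
#' @param exposure result of [exposed_fraction()] (recomputed if NULL)
#' @param lp Langevin parameters
#' @return list with `dv` (n x 3 velocity increments), `attempted` and
#'   `landed` per-particle kick counts
#' @export
sample_kicks <- function(system, exposure = NULL,
                         lp = default_langevin_params()) {
  if (is.null(exposure)) exposure <- exposed_fraction(system, lp)
  cpp_sample_kicks(system$pos, system$solvent_radius, system$role,
                   system$hydrophobic, system$active, system$mass,
                   exposure$area, lp$neighbor_cutoff, lp$kick_rate,
                   lp$kick_speed, lp$hydrophobic_multiplier)
}

#' Solvent drag force
#'
#' `-gamma x accessible_area x velocity` per particle: a fully buried
#' particle (zero exposed area) feels no drag.
#'
#' @param system a [make_system()] result
#' @param exposure result of [exposed_fraction()] (recomputed if NULL)
#' @param lp Langevin parameters
#' @return n x 3 matrix of drag forces
#' @export
drag_force <- function(system, exposure = NULL,
                       lp = default_langevin_params()) {
  if (is.null(exposure)) exposure <- exposed_fraction(system, lp)
  -lp$gamma * exposure$area * system$vel
}
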