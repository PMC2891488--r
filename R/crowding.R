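# The simulated cell: excluded-volume accounting, crowder placement, and the
# co-translational crowding simulation drivers.

#' Overlap (lens) volume of two spheres
#'
#' @param R1,R2 sphere radii, Angstrom
#' @param d centre-centre distance, Angstrom
#' @return intersection volume, Angstrom^3 (closed form)
#' @export
sphere_overlap_volume <- function(R1, R2, d) {
  if (d >= R1 + R2) return(0)
  if (d <= abs(R1 - R2)) return(4 / 3 * pi * min(R1, R2)^3)
  a <- (d^2 - R2^2 + R1^2) / (2 * d)
  h1 <- R1 - a
  h2 <- R2 - (d - a)
  pi * h1^2 * (3 * R1 - h1) / 3 + pi * h2^2 * (3 * R2 - h2) / 3
}

#' Solvent-accessible cell volume
#'
#' The container volume minus the container-ribosome lens, evaluated at the
#' equilibrium tether geometry (exit point at the container centre).  With
#' `volume_denominator = "container"` the whole container volume is used
#' instead.
#'
#' @param scene a [make_scene()] result
#' @return volume in Angstrom^3
#' @export
available_volume <- function(scene) {
  if (is.na(scene$container_radius)) stop("scene has no container")
  vc <- 4 / 3 * pi * scene$container_radius^3
  if (scene$volume_denominator == "container" ||
      is.na(scene$ribosome_radius)) {
    return(vc)
  }
  d <- sqrt(sum((scene$ribosome_center - scene$container_center)^2))
  vc - sphere_overlap_volume(scene$container_radius, scene$ribosome_radius, d)
}

#' Number of crowders realising a target excluded-volume fraction
#'
#' @param target_fraction desired fraction of the available volume
#' @param scene a [make_scene()] result
#' @return integer count, with attribute `realised_fraction` (the fraction
#'   the rounded count actually occupies)
#' @export
crowder_count <- function(target_fraction, scene) {
  if (target_fraction < 0 || target_fraction > 0.74) {
    stop("target_fraction must lie in [0, 0.74]")
  }
  va <- available_volume(scene)
  vcr <- 4 / 3 * pi * scene$crowder_radius^3
  n <- round(target_fraction * va / vcr)
  structure(as.integer(n), realised_fraction = n * vcr / va)
}

.runif_ball <- function(radius, center = c(0, 0, 0)) {
  repeat {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(center + p)
  }
}

.crowder_ok <- function(p, scene, placed, rc) {
  if (sqrt(sum((p - scene$container_center)^2)) >
      scene$container_radius - rc) return(FALSE)
  if (!is.na(scene$ribosome_radius) &&
      sqrt(sum((p - scene$ribosome_center)^2)) <
      scene$ribosome_radius + rc) return(FALSE)
  if (length(placed) && any(sqrt(colSums((t(do.call(rbind, placed)) - p)^2))
                            < 2 * rc)) return(FALSE)
  TRUE
}

#' Place crowding macromolecules
#'
#' Rejection-samples crowder centres inside the container (centre within
#' `container_radius - crowder_radius`), outside the ribosome, with
#' pairwise centre distances of at least one crowder diameter.  Dense
#' targets that sequential rejection sampling cannot reach (it jams well
#' below close packing in this lens-shaped geometry) are completed by a
#' deterministic overlap-relaxation pass; if even relaxation cannot
#' separate the spheres, the start is accepted `compressed` (with a
#' warning) when `allow_compressed` is TRUE -- the soft repulsive dynamics
#' then resolves residual overlaps -- or an error names the largest
#' strictly placeable count.
#'
#' @param n number of crowders
#' @param scene a [make_scene()] result
#' @param max_attempts rejection-sampling budget
#' @param allow_compressed accept unresolved overlaps (see above)
#' @return n x 3 matrix of centres; attribute `compressed` is TRUE when
#'   residual overlaps remain
#' @export
place_crowders <- function(n, scene, max_attempts = 1e5,
                           allow_compressed = TRUE) {
  rc <- scene$crowder_radius
  if (n == 0) {
    return(structure(matrix(numeric(0), 0, 3), compressed = FALSE))
  }
  placed <- list()
  attempts <- 0
  while (length(placed) < n && attempts < max_attempts) {
    attempts <- attempts + 1
    p <- .runif_ball(scene$container_radius - rc, scene$container_center)
    if (.crowder_ok(p, scene, placed, rc)) placed[[length(placed) + 1]] <- p
  }
  n_strict <- length(placed)
  if (n_strict == n) {
    return(structure(do.call(rbind, placed), compressed = FALSE))
  }
  # relaxation fallback: drop in the remainder anywhere legal w.r.t. the
  # walls, then iteratively push overlapping pairs apart
  X <- do.call(rbind, placed)
  extra <- t(replicate(n - n_strict,
                       .runif_ball(scene$container_radius - rc,
                                   scene$container_center)))
  X <- rbind(X, matrix(extra, ncol = 3))
  for (iter in seq_len(500)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- X[j, ] - X[i, ]
        r <- sqrt(sum(d^2))
        if (r < 2 * rc) {
          if (r < 1e-9) {
            d <- rnorm(3)
            r <- sqrt(sum(d^2))
          }
          push <- (2 * rc - r) / 2 + 1e-3
          X[i, ] <- X[i, ] - push * d / r
          X[j, ] <- X[j, ] + push * d / r
          moved <- TRUE
        }
      }
    }
    for (i in seq_len(n)) { # project back inside walls
      d <- X[i, ] - scene$container_center
      r <- sqrt(sum(d^2))
      lim <- scene$container_radius - rc
      if (r > lim) X[i, ] <- scene$container_center + d * lim / r
      if (!is.na(scene$ribosome_radius)) {
        d <- X[i, ] - scene$ribosome_center
        r <- sqrt(sum(d^2))
        lim <- scene$ribosome_radius + rc
        if (r < lim) {
          X[i, ] <- scene$ribosome_center + d * lim / max(r, 1e-9)
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  dmin <- min(stats::dist(X))
  if (dmin >= 2 * rc - 1e-6) {
    return(structure(X, compressed = FALSE))
  }
  if (allow_compressed) {
    warning("place_crowders: target too dense for strict placement (",
            n_strict, " of ", n, " placed without overlap); returning a ",
            "compressed start (min separation ", round(dmin, 2), " A)",
            call. = FALSE)
    return(structure(X, compressed = TRUE))
  }
  stop("cannot place ", n, " crowders without overlap; at most ~", n_strict,
       " fit strictly -- lower the target fraction")
}

#' Sampling-plan bookkeeping for a crowding study
#'
#' The study protocol synthesizes each protein many times into the cell at
#' each crowding level, continues each simulation after synthesis, and
#' samples conformations at a fixed interval.
#'
#' @param n_proteins proteins in the study
#' @param replicates syntheses per protein per crowding level
#' @param post_iterations iterations after synthesis completes
#' @param sample_interval iterations between samples
#' @return list with `samples_per_replicate`, `samples_per_protein_level`,
#'   `total_conformations` (across all proteins at one crowding level)
#' @export
crowding_plan <- function(n_proteins = 12, replicates = 100,
                          post_iterations = 1e6, sample_interval = 1000) {
  spr <- post_iterations %/% sample_interval
  list(samples_per_replicate = spr,
       samples_per_protein_level = spr * replicates,
       total_conformations = spr * replicates * n_proteins)
}

#' Synthesize a protein into a crowded cell and simulate
#'
#' Runs co-translational synthesis (one residue per `synth_rate`
#' iterations, emerging at the ribosome exit point, the growing end
#' tethered to it) followed by `post_iterations` of free evolution among
#' the crowders, sampling conformations every `sample_interval` iterations
#' after synthesis completes.
#'
#' @param sequence,ss sequence and secondary structure strings
#' @param fraction target excluded-volume fraction
#' @param seed integer seed (all randomness: placement, kicks, synthesis
#'   jitter)
#' @param ff,lp parameter sets
#' @param scene cell geometry (crowder count is derived from `fraction`)
#' @param synth_rate iterations per residue
#' @param post_iterations iterations after synthesis
#' @param sample_interval sampling interval
#' @return `cf_trajectory` (protein particles only) with attributes
#'   `realised_fraction` and `n_crowders`
#' @export
run_crowding_simulation <- function(sequence, ss, fraction, seed,
                                    ff = default_ff_params(),
                                    lp = default_langevin_params(),
                                    scene = make_scene(),
                                    synth_rate = 1000,
                                    post_iterations = 1e6,
                                    sample_interval = 1000) {
  set.seed(seed)
  scene$target_fraction <- fraction
  n_cr <- crowder_count(fraction, scene)
  crowders <- place_crowders(n_cr, scene)
  chain <- build_chain(sequence, ss, ff, lp$solvent_radii)
  sys <- make_system(chain, scene, crowder_xyz = crowders, synthesized = 0,
                     ff = ff)
  L <- nchar(sequence)
  n_synth <- L * synth_rate
  phaseA <- .engine(sys, ff, lp, n_steps = n_synth, sample_interval = 0L,
                    synthesis = TRUE, synth_rate = synth_rate)
  traj <- run_simulation(phaseA$system, ff, lp, n_steps = post_iterations,
                         sample_interval = sample_interval,
                         it_offset = n_synth)
  traj$seed <- seed
  attr(traj, "realised_fraction") <- attr(n_cr, "realised_fraction")
  attr(traj, "n_crowders") <- as.integer(n_cr)
  attr(traj, "compressed_start") <- isTRUE(attr(crowders, "compressed"))
  traj
}

#' Crowding sweep over fractions and replicates
#'
#' Repeats [run_crowding_simulation()] over crowding levels and random
#' seeds, computing per-replicate observables against a reference (native)
#' backbone structure.
#'
#' @param sequence,ss protein definition
#' @param native L x 3 native backbone coordinates (reference for relative
#'   radius of gyration and TM score)
#' @param fractions excluded-volume fractions to test
#' @param replicates syntheses per fraction
#' @param base_seed replicate r at fraction index f uses seed
#'   `base_seed + (f-1)*replicates + (r-1)`
#' @param out_dir optional directory: per-replicate trajectories plus a JSON
#'   run manifest (fraction, replicate, seed, realised fraction) are written
#' @param native_like compute the TM-score-based native-like time (the most
#'   expensive observable); set FALSE for sweeps that only need conformation
#'   size and fixation
#' @param ... passed to [run_crowding_simulation()]
#' @return data.frame with one row per replicate: realised fraction,
#'   fixation sample index and iteration, median relative Rg, native-like
#'   time (per cent, NA when not computed)
#' @export
crowding_sweep <- function(sequence, ss, native, fractions = c(0, 0.5),
                           replicates = 10, base_seed = 1, out_dir = NULL,
                           native_like = TRUE, ...) {
  rows <- list()
  manifest <- list()
  for (f in seq_along(fractions)) {
    for (r in seq_len(replicates)) {
      seed <- base_seed + (f - 1) * replicates + (r - 1)
      traj <- run_crowding_simulation(sequence, ss, fractions[f], seed, ...)
      confs <- backbone_samples(traj)
      fx <- fixation_time(confs)
      rel <- vapply(confs, relative_rg, numeric(1), native = native)
      nlt <- if (native_like) native_like_time(confs, native) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        fraction = fractions[f],
        realised_fraction = attr(traj, "realised_fraction"),
        replicate = r, seed = seed,
        fixation_index = fx,
        fixation_iteration = traj$iterations[fx],
        median_relative_rg = stats::median(rel),
        native_like_time = nlt)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        tf <- file.path(out_dir, sprintf("traj_f%03d_r%03d.txt.gz",
                                         round(fractions[f] * 100), r))
        write_trajectory(traj, tf)
        manifest[[length(manifest) + 1]] <- list(
          fraction = fractions[f], replicate = r, seed = seed,
          realised_fraction = attr(traj, "realised_fraction"),
          trajectory = basename(tf))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Per-fraction summary of a crowding sweep
#'
#' @param sweep a [crowding_sweep()] result
#' @return data.frame keyed by fraction with median/p25/p75 columns for the
#'   fixation iteration, relative radius of gyration and native-like time
#' @export
summarize_sweep <- function(sweep) {
  do.call(rbind, lapply(split(sweep, sweep$fraction), function(d) {
    fx <- summary_quartiles(d$fixation_iteration)
    rg <- summary_quartiles(d$median_relative_rg)
    nl <- if (all(is.na(d$native_like_time))) rep(NA_real_, 3) else
      summary_quartiles(d$native_like_time)
    data.frame(fraction = d$fraction[1], n = nrow(d),
               fixation_median = fx[1], fixation_p25 = fx[2],
               fixation_p75 = fx[3],
               relative_rg_median = rg[1], relative_rg_p25 = rg[2],
               relative_rg_p75 = rg[3],
               native_like_median = nl[1], native_like_p25 = nl[2],
               native_like_p75 = nl[3])
  }))
}
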