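# Iterative solution of the Langevin equation of motion
#   a = (F - gamma_eff v + R) / m
# with a semi-implicit (velocity-then-position) update, per-iteration speed
# clamp, and strict seed determinism: all randomness flows through R's RNG.

.synth_cpp <- function(system, ff, enabled = FALSE, rate = 1000L) {
  list(enabled = enabled, rate = as.integer(rate),
       res_bb = as.integer(system$res_bb - 1L),
       res_sc = as.integer(ifelse(system$res_sc < 0, -1L,
                                  system$res_sc - 1L)),
       synthesized = as.integer(system$synthesized),
       tether_k = ff$k_tether, tether_L0 = ff$cov_ca_ca,
       exit_id = if (is.na(system$exit_id)) -1L else system$exit_id - 1L)
}

.engine <- function(system, ff, lp, n_steps, sample_interval = 0L,
                    it_offset = 0L, record_ids = NULL, synthesis = FALSE,
                    synth_rate = 1000L) {
  sp <- .springs_cpp(system)
  if (is.null(record_ids)) record_ids <- which(system$role %in% c(1L, 2L))
  res <- cpp_engine_run(system$pos, system$vel, system$mass,
                        system$solvent_radius, system$role,
                        system$hydrophobic, system$active,
                        sp$i, sp$j, sp$L0, sp$k, sp$cat,
                        .scene_cpp(system, ff), .ff_cpp(system, ff),
                        .lp_cpp(lp), .synth_cpp(system, ff, synthesis,
                                                synth_rate),
                        as.integer(n_steps), as.integer(sample_interval),
                        as.integer(it_offset),
                        as.integer(record_ids - 1L),
                        if (is.na(system$tether_to)) -1L else
                          as.integer(system$tether_to - 1L))
  system$pos <- res$pos
  system$vel <- res$vel
  system$active <- res$active
  system$synthesized <- res$synthesized
  system$tether_to <- if (res$tether_to < 0) NA_integer_ else
    res$tether_to + 1L
  list(system = system, samples = res$samples,
       sample_iterations = res$sample_iterations, kicks = res$kicks,
       exposure = res$exposure, record_ids = record_ids)
}

#' Advance the system by one iteration
#'
#' One Langevin step: forces are evaluated, velocities updated by
#' `dt (F - gamma_eff v)/m` plus any sampled solvent kicks, speeds clamped
#' at `speed_cap`, and positions advanced.  The ribosome particle is held
#' immobile.  A non-finite coordinate aborts with a diagnostic naming the
#' particle.
#'
#' @param system a [make_system()] result
#' @param ff,lp parameter sets
#' @return the updated system
#' @export
simulate_step <- function(system, ff = default_ff_params(),
                          lp = default_langevin_params()) {
  .engine(system, ff, lp, n_steps = 1L)$system
}

#' Run a simulation and collect a trajectory
#'
#' Samples are taken at iterations `k * sample_interval` for
#' `k = 1..floor(n_steps/sample_interval)`; the initial state is stored
#' separately.  Identical seed and configuration give bit-identical
#' trajectories.
#'
#' @param system a [make_system()] result
#' @param ff,lp parameter sets
#' @param n_steps number of iterations (>= 0)
#' @param sample_interval iterations between samples (>= 1)
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the run is reproducible in isolation
#' @param record which particles to record: `"protein"` (default) or
#'   `"all"`
#' @param synthesis enable the co-translational synthesis schedule
#' @param synth_rate iterations per synthesized residue
#' @param it_offset global iteration index of the step before the first
#'   (for multi-phase runs)
#' @return object of class `cf_trajectory`: `samples` (n_samples x
#'   n_recorded x 3 array, NA for not-yet-synthesized particles),
#'   `iterations`, `initial`, `final_system`, provenance fields
#' @export
run_simulation <- function(system, ff = default_ff_params(),
                           lp = default_langevin_params(), n_steps,
                           sample_interval = 1000L, seed = NULL,
                           record = c("protein", "all"), synthesis = FALSE,
                           synth_rate = 1000L, it_offset = 0L) {
  record <- match.arg(record)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (sample_interval < 1) stop("sample_interval must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  record_ids <- if (record == "protein") which(system$role %in% c(1L, 2L))
    else seq_len(nrow(system$pos))
  initial <- system$pos[record_ids, , drop = FALSE]
  res <- .engine(system, ff, lp, n_steps, sample_interval, it_offset,
                 record_ids, synthesis, synth_rate)
  traj <- list(samples = res$samples, iterations = res$sample_iterations,
               sample_interval = as.integer(sample_interval),
               seed = seed, sequence = system$sequence, ss = system$ss,
               record_ids = record_ids,
               record_role = system$role[record_ids],
               record_residue = system$residue[record_ids],
               initial = initial, final_system = res$system,
               kicks = res$kicks,
               config_digest = config_digest(ff, lp, system$scene))
  class(traj) <- "cf_trajectory"
  traj
}

#' @export
print.cf_trajectory <- function(x, ...) {
  cat("cf_trajectory:", dim(x$samples)[1], "samples x", dim(x$samples)[2],
      "particles (interval", x$sample_interval, ")\n")
  invisible(x)
}

#' Extract backbone conformations from a trajectory
#'
#' @param traj a [run_simulation()] result
#' @param complete_only drop samples in which any backbone particle is
#'   absent (not yet synthesized)
#' @return list of L x 3 backbone coordinate matrices
#' @export
backbone_samples <- function(traj, complete_only = TRUE) {
  bb <- which(traj$record_role == 1L)
  ns <- dim(traj$samples)[1]
  out <- lapply(seq_len(ns), function(s) traj$samples[s, bb, , drop = TRUE])
  if (complete_only) out <- out[!vapply(out, anyNA, logical(1))]
  out
}

# ---- trajectory file format ------------------------------------------------

#' Write a trajectory to a self-describing text file
#'
#' Header (sequence, ss, roster, interval, seed, config digest) followed by
#' one coordinate block per sample.  Pass a path ending in `.gz` for a
#' gzipped variant.
#'
#' @param traj a [run_simulation()] result
#' @param path output path
#' @export
write_trajectory <- function(traj, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# crowdfold trajectory v1")
  w("sequence ", traj$sequence)
  w("ss ", traj$ss)
  w("n_particles ", length(traj$record_ids))
  w("n_samples ", dim(traj$samples)[1])
  w("sample_interval ", traj$sample_interval)
  w("seed ", if (is.null(traj$seed)) "NA" else traj$seed)
  w("config_digest ", traj$config_digest)
  w("roster role residue")
  for (q in seq_along(traj$record_ids)) {
    w("P ", traj$record_role[q], " ",
      ifelse(is.na(traj$record_residue[q]), 0L, traj$record_residue[q]))
  }
  ns <- dim(traj$samples)[1]
  for (s in seq_len(ns)) {
    w("MODEL ", traj$iterations[s])
    m <- traj$samples[s, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    writeLines(sprintf("%.4f %.4f %.4f", m[, 1], m[, 2], m[, 3]), con)
    w("ENDMDL")
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path (plain or gzipped)
#' @return object of class `cf_trajectory` (without `final_system`)
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# crowdfold trajectory", lines[1])) {
    stop("not a crowdfold trajectory file: ", path, " (line 1)")
  }
  hv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) stop("missing header field '", key, "' in ", path)
    sub(paste0("^", key, " "), "", ln)
  }
  np <- as.integer(hv("n_particles"))
  ns <- as.integer(hv("n_samples"))
  roster <- grep("^P ", lines)
  if (length(roster) != np) {
    stop("roster length mismatch in ", path, " (line ", roster[1], ")")
  }
  rr <- do.call(rbind, strsplit(lines[roster], " "))
  starts <- grep("^MODEL ", lines)
  if (length(starts) != ns) stop("sample count mismatch in ", path)
  samples <- array(NA_real_, c(ns, np, 3))
  iters <- integer(ns)
  for (s in seq_along(starts)) {
    iters[s] <- as.integer(sub("^MODEL ", "", lines[starts[s]]))
    block <- lines[(starts[s] + 1):(starts[s] + np)]
    xyz <- do.call(rbind, lapply(strsplit(block, " +"), as.numeric))
    samples[s, , ] <- xyz
  }
  seed <- hv("seed")
  traj <- list(samples = samples, iterations = iters,
               sample_interval = as.integer(hv("sample_interval")),
               seed = if (seed == "NA") NULL else as.integer(seed),
               sequence = hv("sequence"), ss = hv("ss"),
               record_ids = seq_len(np),
               record_role = as.integer(rr[, 2]),
               record_residue = ifelse(rr[, 3] == "0", NA_integer_,
                                       as.integer(rr[, 3])),
               initial = NULL, final_system = NULL,
               config_digest = hv("config_digest"))
  class(traj) <- "cf_trajectory"
  traj
}
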