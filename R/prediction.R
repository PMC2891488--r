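# Structure-prediction protocol: many seeded co-translational folding
# trajectories produce a conformation pool; pool members are ranked by
# similarity to the pool's consensus contact map, a pluggable scorer
# rescoeres the shortlist, and a diversity filter keeps the final five from
# being near-duplicates.

#' Bookkeeping for a prediction pool
#'
#' Each trajectory runs for `iters_per_res * l + extra_iters` iterations
#' (synthesis at one residue per `synth_rate` iterations), and `n_samples`
#' structures are sampled at equal intervals from iteration
#' `iters_per_res * l` to the end.
#'
#' @param l residue count
#' @param n_traj number of random-seed trajectories
#' @param iters_per_res,extra_iters per-trajectory budget coefficients
#' @param n_samples samples per trajectory
#' @return list with `budget_per_trajectory`, `sampling_start`,
#'   `sample_spacing`, `pool_size`
#' @export
pool_plan <- function(l, n_traj = 150, iters_per_res = 6000,
                      extra_iters = 400000, n_samples = 40) {
  list(budget_per_trajectory = iters_per_res * l + extra_iters,
       sampling_start = iters_per_res * l,
       sample_spacing = extra_iters / n_samples,
       pool_size = n_traj * n_samples)
}

#' Generate a conformation pool by repeated seeded folding
#'
#' Runs `n_traj` co-translational folding simulations (ribosome and exit
#' tether, no crowders) that differ only in the random seed, sampling
#' `n_samples` structures per trajectory after the relaxation phase.
#' Defaults match the full-scale protocol; reduce `n_traj`,
#' `iters_per_res` and `extra_iters` for desk-scale runs.
#'
#' @param sequence,ss protein definition
#' @param n_traj trajectories (seed = `base_seed + trajectory index - 1`)
#' @param iters_per_res,extra_iters,n_samples see [pool_plan()]
#' @param synth_rate iterations per synthesized residue
#' @param base_seed first seed
#' @param ff,lp parameter sets
#' @return object of class `cf_pool`: conformations, provenance
#'   (trajectory, seed, iteration), contact maps, `sequence`, `ss`
#' @export
generate_pool <- function(sequence, ss, n_traj = 150, iters_per_res = 6000,
                          extra_iters = 400000, n_samples = 40,
                          synth_rate = 1000, base_seed = 1,
                          ff = default_ff_params(),
                          lp = default_langevin_params()) {
  l <- nchar(sequence)
  plan <- pool_plan(l, n_traj, iters_per_res, extra_iters, n_samples)
  spacing <- as.integer(round(plan$sample_spacing))
  if (spacing < 1) stop("extra_iters too small for n_samples")
  if (iters_per_res < synth_rate) {
    stop("iters_per_res (", iters_per_res, ") must be at least synth_rate (",
         synth_rate, ") so sampling starts after synthesis completes")
  }
  scene <- make_scene(container_radius = NA, ribosome_radius = 100)
  confs <- list()
  prov <- list()
  for (tr in seq_len(n_traj)) {
    seed <- base_seed + tr - 1
    set.seed(seed)
    chain <- build_chain(sequence, ss, ff, lp$solvent_radii)
    sys <- make_system(chain, scene, synthesized = 0, ff = ff)
    phaseA <- .engine(sys, ff, lp, n_steps = plan$sampling_start,
                      sample_interval = 0L, synthesis = TRUE,
                      synth_rate = synth_rate)
    traj <- run_simulation(phaseA$system, ff, lp,
                           n_steps = spacing * n_samples,
                           sample_interval = spacing,
                           it_offset = plan$sampling_start)
    bb <- backbone_samples(traj)
    for (s in seq_along(bb)) {
      confs[[length(confs) + 1]] <- bb[[s]]
      prov[[length(prov) + 1]] <- data.frame(trajectory = tr, seed = seed,
                                             iteration = traj$iterations[s])
    }
  }
  pool <- list(conformations = confs, provenance = do.call(rbind, prov),
               maps = lapply(confs, contact_map, ss = ss),
               sequence = sequence, ss = ss)
  class(pool) <- "cf_pool"
  pool
}

#' @export
print.cf_pool <- function(x, ...) {
  cat("cf_pool:", length(x$conformations), "conformations of",
      nchar(x$sequence), "residues\n")
  invisible(x)
}

#' Consensus (mean) contact map of a pool
#'
#' @param pool a [generate_pool()] result (or any list of `cf_contact_map`
#'   in `$maps`)
#' @return `cf_contact_map` whose `map` holds mean contact frequencies in
#'   [0, 1] over eligible pairs
#' @export
consensus_map <- function(pool) {
  if (length(pool$maps) == 0) stop("empty pool")
  m <- Reduce(`+`, lapply(pool$maps, `[[`, "map")) / length(pool$maps)
  out <- list(map = m, eligible = pool$maps[[1]]$eligible,
              ss = pool$maps[[1]]$ss)
  class(out) <- "cf_contact_map"
  out
}

#' Similarity of a conformation's contact map to the consensus
#'
#' Rewards a contact where the pool tends to have one and penalises its
#' absence: over eligible pairs i < j the score adds `mean_map[i,j]` when
#' the conformation has the contact and subtracts it otherwise.
#'
#' @param conf_map single-structure `cf_contact_map` (binary)
#' @param mean_map consensus `cf_contact_map`
#' @return numeric score
#' @export
consensus_score <- function(conf_map, mean_map) {
  if (!all(dim(conf_map$map) == dim(mean_map$map))) {
    stop("contact map shapes differ")
  }
  if (!all(conf_map$eligible == mean_map$eligible)) {
    stop("contact map eligibility masks differ")
  }
  ut <- upper.tri(conf_map$map) & conf_map$eligible
  sum(ifelse(conf_map$map[ut] > 0, mean_map$map[ut], -mean_map$map[ut]))
}

# "very similar": after optimal superposition at least `frac` of residues
# lie within `cut` Angstrom of their counterparts
.very_similar <- function(A, B, frac = 0.9, cut = 7) {
  sp <- superpose(A, B)
  d <- sqrt(rowSums((sp$transformed - B)^2))
  mean(d < cut) > frac - 1e-12
}

#' Select final structure predictions from a pool
#'
#' All pool members are ranked by [consensus_score()]; the top
#' `k_shortlist` are rescored by `scorer` (default: keep the consensus
#' score; any callable ranking, e.g. a learned model-quality assessor, can
#' be plugged in); then, while any pair among the current top `k_final` is
#' very similar (>= 90% of residues within 7 A after superposition), the
#' lower-scoring member is dropped and the next candidate promoted, until
#' the selection is diverse or candidates run out.  Ties break toward
#' earlier provenance, so selection is deterministic given the pool order.
#'
#' @param pool a [generate_pool()] result
#' @param scorer optional function(conformation) -> numeric score (higher
#'   is better) applied to the shortlist
#' @param k_shortlist,k_final shortlist and final selection sizes
#' @param similar_frac,similar_cut diversity thresholds
#' @return list with `selected` (indices into the pool, in rank order),
#'   `conformations`, `ranking` (data.frame of shortlist scores) and
#'   `eliminated` (indices dropped as near-duplicates)
#' @export
select_predictions <- function(pool, scorer = NULL, k_shortlist = 20,
                               k_final = 5, similar_frac = 0.9,
                               similar_cut = 7) {
  n <- length(pool$conformations)
  if (n == 0) stop("empty pool")
  mm <- consensus_map(pool)
  cs <- vapply(pool$maps, consensus_score, numeric(1), mean_map = mm)
  ord <- order(-cs, seq_len(n))  # stable: earlier provenance wins ties
  shortlist <- head(ord, k_shortlist)
  rs <- if (is.null(scorer)) cs[shortlist] else
    vapply(pool$conformations[shortlist], scorer, numeric(1))
  sl_ord <- shortlist[order(-rs, seq_along(shortlist))]
  rs_ord <- rs[order(-rs, seq_along(shortlist))]

  current <- head(sl_ord, k_final)
  queue <- sl_ord[-seq_len(min(k_final, length(sl_ord)))]
  eliminated <- integer(0)
  repeat {
    dup <- NULL
    if (length(current) >= 2) {
      for (a in seq_len(length(current) - 1)) {
        for (b in (a + 1):length(current)) {
          if (.very_similar(pool$conformations[[current[a]]],
                            pool$conformations[[current[b]]],
                            similar_frac, similar_cut)) {
            dup <- b  # later entry scores no higher: drop it
            break
          }
        }
        if (!is.null(dup)) break
      }
    }
    if (is.null(dup)) break
    eliminated <- c(eliminated, current[dup])
    current <- current[-dup]
    if (length(queue)) {
      current <- c(current, queue[1])
      queue <- queue[-1]
    } else if (length(current) < 1) {
      break
    }
  }
  list(selected = current,
       conformations = pool$conformations[current],
       ranking = data.frame(index = sl_ord, score = rs_ord),
       eliminated = eliminated)
}
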