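# Trajectory observables.  All structural metrics use residue-indexed
# correspondence (model residue i vs native residue i); superposition-based
# metrics are invariant under rigid motion of either argument.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `A` onto `B` with a proper rotation (no
#' reflection), via singular value decomposition of the covariance matrix.
#'
#' @param A,B L x 3 coordinate matrices, equal L >= 3
#' @param subset optional residue indices to fit on (the transform still
#'   applies to all residues)
#' @return list with `rotation` (3 x 3), `translation` (3-vector), `rmsd`
#'   over the fitted subset, and `transformed` (A after superposition).
#'   `A %*% rotation + translation` maps A onto B.
#' @export
superpose <- function(A, B, subset = NULL) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("conformations must have equal length")
  if (is.null(subset)) subset <- seq_len(nrow(A))
  if (length(subset) < 3) stop("need at least 3 points to superpose")
  As <- A[subset, , drop = FALSE]
  Bs <- B[subset, , drop = FALSE]
  ca <- colMeans(As)
  cb <- colMeans(Bs)
  H <- crossprod(sweep(As, 2, ca), sweep(Bs, 2, cb))
  sv <- svd(H)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) coordinates")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (!is.finite(d) || d == 0) stop("degenerate (collinear) coordinates")
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cb - as.numeric(ca %*% R)
  TA <- sweep(A %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((TA[subset, , drop = FALSE] - Bs)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, transformed = TA)
}

#' TM-score normalisation distance d0
#'
#' @param L native length
#' @param clamp apply the 0.5 Angstrom floor used in scoring
#' @return d0 in Angstrom
#' @export
tm_d0 <- function(L, clamp = TRUE) {
  x <- L - 15
  d0 <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  if (clamp) max(0.5, d0) else d0
}

# one seeded TM refinement: superpose on `frag`, then iterate inclusion of
# residues within a ladder of cutoffs (d0 alone is too tight to grow the
# aligned set on poor models); returns the best (score, rotation,
# translation) seen
.tm_refine <- function(model, native, frag, d0, score_fun,
                       cutoffs = unique(c(d0, 2, 5)), max_iter = 10) {
  best <- list(score = -Inf, rotation = NULL, translation = NULL)
  for (ct in cutoffs) {
    sel <- frag
    for (iter in seq_len(max_iter)) {
      sp <- tryCatch(superpose(model, native, subset = sel),
                     error = function(e) NULL)
      if (is.null(sp)) break
      d <- sqrt(rowSums((sp$transformed - native)^2))
      s <- score_fun(d)
      if (s > best$score) {
        best <- list(score = s, rotation = sp$rotation,
                     translation = sp$translation)
      }
      cut <- ct
      repeat {
        new_sel <- which(d < cut)
        if (length(new_sel) >= 3) break
        cut <- cut * 1.5
      }
      if (length(new_sel) == length(sel) && all(new_sel == sel)) break
      sel <- new_sel
    }
  }
  best
}

.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# derivative-free polish of the TM objective over the rigid transform:
# the least-squares superposition that seeds the search is not optimal for
# the distance-weighted TM objective, so the best few seed transforms are
# refined against the objective itself
.tm_polish <- function(model, native, d0, start, maxit = 600) {
  R0 <- start$rotation
  t0 <- start$translation
  obj <- function(p) {
    TM <- sweep(model %*% (R0 %*% .rodrigues(p[1:3])), 2, t0 + p[4:6], "+")
    -mean(1 / (1 + rowSums((TM - native)^2) / d0^2))
  }
  opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  -opt$value
}

.tm_seeds <- function(L, lengths, max_starts = 12) {
  seeds <- list()
  for (fl in unique(pmin(L, lengths))) {
    if (fl < 3) next
    starts <- unique(round(seq(1, L - fl + 1, length.out =
                                 min(L - fl + 1, max_starts))))
    for (s in starts) seeds[[length(seeds) + 1]] <- s:(s + fl - 1)
  }
  seeds
}

#' Template-modelling (TM) score
#'
#' `max over superpositions of mean(1 / (1 + (d_i/d0)^2))` with
#' `d0 = 1.24 (L-15)^(1/3) - 1.8` (floored at 0.5 A), normalised by the
#' native length.  The search seeds superpositions from contiguous
#' fragments of lengths L, L/2 and 4 and iterates inclusion of residues
#' within d0.  Scores above 0.3 indicate a roughly native-like topology;
#' random structure pairs average about 0.17.
#'
#' @param model,native L x 3 backbone coordinate matrices (residue-indexed
#'   correspondence)
#' @return score in (0, 1]
#' @export
tm_score <- function(model, native) {
  model <- as.matrix(model)
  native <- as.matrix(native)
  L <- nrow(native)
  if (nrow(model) != L) stop("model and native must have equal length")
  if (L < 5) stop("TM score undefined for fewer than 5 residues")
  d0 <- tm_d0(L)
  score_fun <- function(d) mean(1 / (1 + (d / d0)^2))
  cands <- list()
  for (frag in .tm_seeds(L, c(L, floor(L / 2), 4))) {
    cands[[length(cands) + 1]] <- .tm_refine(model, native, frag, d0,
                                             score_fun)
  }
  scores <- vapply(cands, `[[`, numeric(1), "score")
  best <- max(scores)
  for (k in order(-scores)[seq_len(min(3, length(cands)))]) {
    best <- max(best, .tm_polish(model, native, d0, cands[[k]]))
  }
  best
}

#' Largest fraction of residues alignable within a distance cutoff
#'
#' Greedy seed-and-extend search: every contiguous 4-residue seed is
#' superposed, residues within `d_cut` are added and the superposition
#' refitted until the aligned set is stable; the largest aligned set over
#' all seeds is reported as a fraction of the length.
#'
#' @param model,native L x 3 backbone coordinates
#' @param d_cut alignment distance cutoff, Angstrom (default 5)
#' @return fraction in [0, 1]
#' @export
maxsub_fraction <- function(model, native, d_cut = 5) {
  model <- as.matrix(model)
  native <- as.matrix(native)
  L <- nrow(native)
  if (nrow(model) != L) stop("model and native must have equal length")
  best <- 0
  for (frag in .tm_seeds(L, 4)) {
    sel <- frag
    size <- 0
    for (iter in seq_len(20)) {
      sp <- tryCatch(superpose(model, native, subset = sel),
                     error = function(e) NULL)
      if (is.null(sp)) break
      d <- sqrt(rowSums((sp$transformed - native)^2))
      new_sel <- which(d < d_cut)
      size <- max(size, length(new_sel))
      if (length(new_sel) < 3) break
      if (length(new_sel) == length(sel) && all(new_sel == sel)) break
      sel <- new_sel
    }
    best <- max(best, size)
  }
  best / L
}

#' Radius of gyration
#'
#' Root-mean-square distance of backbone particles from their centroid.
#'
#' @param conf L x 3 coordinates
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(conf) {
  conf <- as.matrix(conf)
  sqrt(mean(rowSums(sweep(conf, 2, colMeans(conf))^2)))
}

#' Radius of gyration relative to the native state
#'
#' @param conf L x 3 coordinates
#' @param native L x 3 native coordinates (non-degenerate)
#' @return Rg(conf) / Rg(native)
#' @export
relative_rg <- function(conf, native) {
  rgn <- radius_of_gyration(native)
  if (rgn <= 0) stop("degenerate native structure: Rg = 0")
  radius_of_gyration(conf) / rgn
}

# mean |pairwise-distance difference| between two conformations
.dist_vec <- function(conf) as.numeric(stats::dist(conf))

#' Conformational fixation time
#'
#' Two conformations are similar when the mean absolute difference of their
#' internal pairwise residue distances is below `theta` (superposition-free
#' metric over all residue pairs i < j).  Returns the smallest sample index
#' t such that sample t is similar to every later sample; if no earlier
#' sample qualifies, the last index is returned.
#'
#' @param samples list of L x 3 conformations (ordered in time)
#' @param theta similarity threshold, Angstrom (default 4)
#' @return sample index (1-based)
#' @export
fixation_time <- function(samples, theta = 4) {
  n <- length(samples)
  if (n < 1) stop("need at least one sample")
  if (n == 1) return(1L)
  D <- t(vapply(samples, .dist_vec, numeric(length(.dist_vec(samples[[1]])))))
  for (t in seq_len(n - 1)) {
    ok <- TRUE
    for (u in n:(t + 1)) {  # later samples first: most likely to differ
      if (mean(abs(D[u, ] - D[t, ])) >= theta) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(t)
  }
  n
}

#' Native-like time
#'
#' Percentage of sampled conformations whose TM score to the native exceeds
#' `tau`.
#'
#' @param samples list of L x 3 conformations
#' @param native L x 3 native coordinates
#' @param tau TM-score threshold (default 0.3)
#' @return percentage in [0, 100]
#' @export
native_like_time <- function(samples, native, tau = 0.3) {
  if (length(samples) < 1) stop("need at least one sample")
  100 * mean(vapply(samples, function(s) tm_score(s, native), numeric(1)) >
               tau)
}

# residues belong to the same secondary-structure unit when they sit in the
# same maximal run of identical non-coil assignment
.ss_units <- function(ss) {
  sv <- strsplit(ss, "")[[1]]
  runs <- rle(sv)
  unit <- rep(seq_along(runs$lengths), runs$lengths)
  unit[sv == "C"] <- 0L
  unit
}

#' Backbone contact map
#'
#' The backbone trace is smoothed with a centred moving average (window of
#' nine residues, truncated symmetrically at the termini).  Residue pairs
#' within the same secondary-structure unit are ineligible.  A contact is a
#' smoothed distance below 8 A when both residues are strand, 11 A
#' otherwise (strand backbones hydrogen-bond closer together).
#'
#' @param conf L x 3 backbone coordinates
#' @param ss secondary-structure string of length L
#' @param window smoothing window (residues)
#' @param cut_EE,cut_other contact cutoffs, Angstrom
#' @return object of class `cf_contact_map`: list with `map` (L x L, 0/1)
#'   and `eligible` (L x L logical mask)
#' @export
contact_map <- function(conf, ss, window = 9, cut_EE = 8, cut_other = 11) {
  conf <- as.matrix(conf)
  L <- nrow(conf)
  if (nchar(ss) != L) stop("ss length must equal residue count")
  sm <- apply(conf, 2, function(x)
    zoo::rollapply(zoo::zoo(x), window, mean, partial = TRUE))
  sm <- matrix(sm, L, 3)
  D <- as.matrix(stats::dist(sm))
  sv <- strsplit(ss, "")[[1]]
  both_E <- outer(sv == "E", sv == "E", "&")
  cut <- ifelse(both_E, cut_EE, cut_other)
  unit <- .ss_units(ss)
  eligible <- outer(unit, unit, function(a, b) a == 0 | b == 0 | a != b)
  diag(eligible) <- FALSE
  m <- (D < cut) * 1
  m[!eligible] <- 0
  out <- list(map = m, eligible = eligible, ss = ss)
  class(out) <- "cf_contact_map"
  out
}

#' Median and middle-50% percentiles
#'
#' Standard order statistics with linear interpolation.
#'
#' @param values non-empty numeric vector
#' @return numeric vector `c(median, p25, p75)`
#' @export
summary_quartiles <- function(values) {
  if (length(values) == 0) stop("empty value vector")
  q <- unname(quantile(values, c(0.5, 0.25, 0.75), type = 7))
  setNames(q, c("median", "p25", "p75"))
}

#' Select proteins that fold reliably
#'
#' Keeps proteins whose pooled native-like time reaches the threshold
#' (boundary inclusive).
#'
#' @param native_like named numeric vector of per-protein native-like times
#'   (per cent)
#' @param threshold minimum native-like time, per cent (default 10)
#' @return character vector of protein names
#' @export
select_foldable <- function(native_like, threshold = 10) {
  names(native_like)[native_like >= threshold]
}

#' Per-replicate trajectory metrics
#'
#' @param traj a `cf_trajectory`
#' @param native L x 3 native backbone coordinates
#' @return list with per-sample `relative_rg`, `fixation_index`,
#'   `native_like_time`
#' @export
analyze_trajectory <- function(traj, native) {
  confs <- backbone_samples(traj)
  list(relative_rg = vapply(confs, relative_rg, numeric(1), native = native),
       fixation_index = fixation_time(confs),
       native_like_time = native_like_time(confs, native))
}
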