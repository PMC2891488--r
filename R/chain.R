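# Coarse-grained chain topology: one backbone (C-alpha) particle per residue
# plus one side-chain centroid particle per non-glycine residue.

.bb_rest_key <- function(ss_i, ss_j) {
  if (ss_i == "H" && ss_j == "H") "HH"
  else if (ss_i == "E" && ss_j == "E") "EE"
  else "CC"
}

#' Build a protein chain topology
#'
#' Constructs the particle roster and spring network for a sequence with a
#' three-state secondary-structure assignment.  Particles: one backbone per
#' residue and one side-chain centroid per non-glycine residue (glycine's
#' centroid coincides with its C-alpha, so it carries no extra particle).
#' Springs: `cov` between consecutive backbones (rest length `cov_ca_ca`)
#' and between each backbone and its own side chain; `bb` between backbones
#' at sequence separations 2 and 3 with rest lengths keyed by the residues'
#' secondary structure; `sc` linking each side chain to the backbone
#' particles of residues i-1 and i+1 where they exist, orienting side
#' chains relative to the backbone.
#'
#' @param sequence one-letter amino-acid string
#' @param ss secondary-structure string over \{H, E, C\} (same length)
#' @param ff force-field parameters, see [default_ff_params()]
#' @param solvent_radii named radii vector, see [default_solvent_radii()]
#' @param hydrophobic_override optional character vector of one-letter codes
#'   to flag hydrophobic regardless of the Kyte-Doolittle sign
#' @return object of class `cf_chain` with elements `sequence`, `ss`,
#'   `residues`, `particles`, `springs`, `synthesized_count`
#' @export
#' @examples
#' ch <- build_chain("AAA", "HHH")
#' nrow(ch$particles)  # 6
#' nrow(ch$springs)    # 10
build_chain <- function(sequence, ss, ff = default_ff_params(),
                        solvent_radii = default_solvent_radii(),
                        hydrophobic_override = NULL) {
  sequence <- toupper(sequence)
  ss <- toupper(ss)
  if (nchar(sequence) < 1) stop("sequence must have length >= 1")
  if (nchar(sequence) != nchar(ss)) {
    stop("sequence (", nchar(sequence), ") and secondary structure (",
         nchar(ss), ") lengths differ")
  }
  aa <- strsplit(sequence, "")[[1]]
  sv <- strsplit(ss, "")[[1]]
  bad <- which(!aa %in% .aa_alphabet)
  if (length(bad)) {
    stop("unknown amino-acid letter '", aa[bad[1]], "' at position ", bad[1])
  }
  bad <- which(!sv %in% c("H", "E", "C"))
  if (length(bad)) {
    stop("secondary structure must use H/E/C; found '", sv[bad[1]],
         "' at position ", bad[1])
  }
  L <- length(aa)
  hydro <- .aa_kd[aa] > 0
  if (!is.null(hydrophobic_override)) {
    hydro[aa %in% toupper(hydrophobic_override)] <- TRUE
  }
  residues <- data.frame(index = seq_len(L), aa = aa, ss = sv,
                         hydrophobic = unname(hydro),
                         stringsAsFactors = FALSE)

  # particle roster in synthesis order: bb_i then (unless glycine) sc_i
  bb_id <- integer(L)
  sc_id <- rep(NA_integer_, L)
  id <- 0L
  rows <- vector("list", 2L * L)
  nr <- 0L
  for (i in seq_len(L)) {
    id <- id + 1L
    bb_id[i] <- id
    nr <- nr + 1L
    rows[[nr]] <- data.frame(id = id, role = "backbone", residue = i,
                             aa = aa[i], hydrophobic = FALSE, mass = 1,
                             solvent_radius = unname(solvent_radii["backbone"]),
                             stringsAsFactors = FALSE)
    if (aa[i] != "G") {
      id <- id + 1L
      sc_id[i] <- id
      nr <- nr + 1L
      rows[[nr]] <- data.frame(id = id, role = "sidechain", residue = i,
                               aa = aa[i], hydrophobic = unname(hydro[i]),
                               mass = 1,
                               solvent_radius = unname(solvent_radii[aa[i]]),
                               stringsAsFactors = FALSE)
    }
  }
  particles <- do.call(rbind, rows[seq_len(nr)])

  sp <- list()
  add <- function(i, j, L0, k, cat) {
    sp[[length(sp) + 1L]] <<- data.frame(i = i, j = j, rest_length = L0,
                                         stiffness = k, category = cat,
                                         stringsAsFactors = FALSE)
  }
  for (i in seq_len(L)) {
    if (i < L) add(bb_id[i], bb_id[i + 1], ff$cov_ca_ca, ff$k_cov, "cov")
    if (!is.na(sc_id[i])) {
      add(bb_id[i], sc_id[i], unname(ff$cov_ca_centroid[aa[i]]), ff$k_cov,
          "cov")
    }
  }
  for (sep in c(2L, 3L)) {
    for (i in seq_len(max(0L, L - sep))) {
      j <- i + sep
      key <- .bb_rest_key(sv[i], sv[j])
      add(bb_id[i], bb_id[j],
          unname(ff$bb_rest_lengths[[key]][as.character(sep)]), ff$k_bb, "bb")
    }
  }
  for (i in seq_len(L)) {
    if (is.na(sc_id[i])) next
    d_sc <- unname(ff$cov_ca_centroid[aa[i]])
    rest <- sqrt(ff$cov_ca_ca^2 + d_sc^2)
    if (i > 1) add(sc_id[i], bb_id[i - 1], rest, ff$k_sc, "sc")
    if (i < L) add(sc_id[i], bb_id[i + 1], rest, ff$k_sc, "sc")
  }
  springs <- if (length(sp)) do.call(rbind, sp) else
    data.frame(i = integer(), j = integer(), rest_length = numeric(),
               stiffness = numeric(), category = character(),
               stringsAsFactors = FALSE)

  chain <- list(sequence = sequence, ss = ss, residues = residues,
                particles = particles, springs = springs,
                bb_id = bb_id, sc_id = sc_id, synthesized_count = 0L)
  class(chain) <- "cf_chain"
  chain
}

#' @export
print.cf_chain <- function(x, ...) {
  cat("cf_chain:", nchar(x$sequence), "residues,", nrow(x$particles),
      "particles,", nrow(x$springs), "springs\n")
  cat("  sequence:", x$sequence, "\n  ss:      ", x$ss, "\n")
  invisible(x)
}
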