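# Readers, writers, configuration and the deterministic fixture generator.
# PDB parsing goes through bio3d; the coarse-grained multi-MODEL writer
# (CA + CEN pseudo-atoms) is a purpose-built formatter.

#' Read a native structure from a PDB file
#'
#' Extracts the C-alpha trace and per-residue side-chain centroids (mean of
#' side-chain heavy atoms; the C-alpha itself for glycine) of one chain.
#' Alternate locations beyond the first and HETATM records are skipped.
#'
#' @param path PDB file
#' @param chain_id chain identifier (default: first chain in the file)
#' @return object of class `cf_native`: list with `ca` (L x 3), `centroid`
#'   (L x 3), `sequence`, `ss` (NA until assigned)
#' @export
read_native <- function(path, chain_id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain == chain_id, ]
  if (nrow(at) == 0) stop("no ATOM records for chain '", chain_id, "'")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  resk <- paste(at$resno, at$insert)
  resk <- factor(resk, levels = unique(resk))
  ca <- at[at$elety == "CA", ]
  if (anyDuplicated(paste(ca$resno, ca$insert))) {
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), ]
  }
  keys <- levels(resk)
  miss <- setdiff(keys, paste(ca$resno, ca$insert))
  if (length(miss)) {
    stop("residues without C-alpha in chain ", chain_id, ": ",
         paste(miss, collapse = ", "))
  }
  L <- nrow(ca)
  seq1 <- bio3d::aa321(ca$resid)
  cent <- matrix(NA_real_, L, 3)
  bbnames <- c("N", "CA", "C", "O", "OXT")
  for (i in seq_len(L)) {
    sel <- at$resno == ca$resno[i] &
      (is.na(at$insert) | at$insert %in% c("", NA) |
         at$insert == ca$insert[i]) & !(at$elety %in% bbnames) &
      !grepl("^H", at$elety)
    sc <- at[sel & at$resno == ca$resno[i], c("x", "y", "z")]
    cent[i, ] <- if (nrow(sc)) colMeans(sc) else
      as.numeric(ca[i, c("x", "y", "z")])
  }
  out <- list(ca = unname(as.matrix(ca[, c("x", "y", "z")])),
              centroid = cent,
              sequence = paste(seq1, collapse = ""), ss = NA_character_)
  dimnames(out$ca) <- NULL
  class(out) <- "cf_native"
  out
}

#' Write conformations as a (multi-MODEL) coarse-grained PDB
#'
#' Backbone particles become CA atoms, side-chain centroids become `CEN`
#' pseudo-atoms of the same residue.  REMARK lines carry the seed and
#' configuration digest when supplied.
#'
#' @param conformations one L x 3 matrix or a list of them (backbone only),
#'   or a list with elements `ca` and `centroid`
#' @param path output path
#' @param sequence optional one-letter sequence for residue names
#' @param remarks optional character vector of REMARK payloads
#' @export
write_pdb_models <- function(conformations, path, sequence = NULL,
                             remarks = NULL) {
  if (is.matrix(conformations)) conformations <- list(conformations)
  if (length(conformations) == 0) stop("need at least one conformation")
  aa3 <- function(i) {
    if (is.null(sequence)) return("ALA")
    bio3d::aa123(substr(sequence, i, i))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in remarks) cat("REMARK 250 ", r, "\n", sep = "", file = con)
  for (m in seq_along(conformations)) {
    conf <- conformations[[m]]
    cat(sprintf("MODEL     %4d\n", m), file = con)
    serial <- 0
    if (is.list(conf) && !is.null(conf$ca)) {
      ca <- conf$ca
      cen <- conf$centroid
    } else {
      ca <- as.matrix(conf)
      cen <- NULL
    }
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1
      cat(sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00\n",
                  serial, aa3(i), i, ca[i, 1], ca[i, 2], ca[i, 3]),
          file = con)
      if (!is.null(cen) && !anyNA(cen[i, ])) {
        serial <- serial + 1
        cat(sprintf(
          "ATOM  %5d  CEN %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00\n",
          serial, aa3(i), i, cen[i, 1], cen[i, 2], cen[i, 3]), file = con)
      }
    }
    cat("ENDMDL\n", file = con)
  }
  invisible(path)
}

#' Read a three-state secondary-structure assignment
#'
#' Accepts a plain H/E/C string, a psipred `.ss2` file (six columns per
#' residue), or a psipred `.horiz` file (`Pred:` lines).  Output is an
#' uppercase H/E/C string.
#'
#' @param x string or file path
#' @param sequence optional sequence to validate the length against
#' @return secondary-structure string
#' @export
read_ss <- function(x, sequence = NULL) {
  ss <- if (!file.exists(x)) {
    toupper(gsub("\\s", "", x))
  } else if (grepl("\\.ss2$", x)) {
    lines <- readLines(x)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    fields <- strsplit(trimws(lines), "\\s+")
    nbad <- which(vapply(fields, length, integer(1)) < 3)
    if (length(nbad)) {
      stop("malformed .ss2 record at data line ", nbad[1], " of ", x)
    }
    paste(toupper(vapply(fields, `[[`, character(1), 3)), collapse = "")
  } else if (grepl("\\.horiz$", x)) {
    lines <- grep("^Pred:", readLines(x), value = TRUE)
    if (!length(lines)) stop("no 'Pred:' lines found in ", x)
    toupper(paste(gsub("^Pred:\\s*", "", lines), collapse = ""))
  } else {
    toupper(gsub("\\s", "", readLines(x, n = 1)))
  }
  ss <- chartr("-. ", "CCC", ss)
  bad <- regmatches(ss, regexpr("[^HEC]", ss))
  if (length(bad)) stop("secondary structure contains '", bad,
                        "' (expected H/E/C)")
  if (!is.null(sequence) && nchar(ss) != nchar(sequence)) {
    stop("secondary structure length ", nchar(ss),
         " does not match sequence length ", nchar(sequence))
  }
  ss
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA file
#' @return one-letter amino-acid string
#' @export
read_fasta_seq <- function(path) {
  fa <- bio3d::read.fasta(path)
  toupper(paste(fa$ali[1, fa$ali[1, ] != "-"], collapse = ""))
}

#' Geometric three-state secondary-structure assignment
#'
#' A coarse stand-in for an assignment program when none is supplied with a
#' native structure: residue i is called helix when the local i to i+3
#' C-alpha distance matches helical geometry (< 7 A), strand when extended
#' (> 9 A); short runs are flattened to coil.
#'
#' @param ca L x 3 C-alpha coordinates
#' @return H/E/C string of length L
#' @export
assign_ss <- function(ca) {
  ca <- as.matrix(ca)
  L <- nrow(ca)
  lab <- rep("C", L)
  if (L >= 4) {
    d13 <- sqrt(rowSums((ca[1:(L - 3), , drop = FALSE] -
                           ca[4:L, , drop = FALSE])^2))
    for (i in seq_len(L - 3)) {
      span <- i:(i + 3)
      if (d13[i] < 7) lab[span] <- "H"
      else if (d13[i] > 9) lab[span] <- "E"
    }
  }
  r <- rle(lab)
  r$values[r$lengths < 3 & r$values != "C"] <- "C"
  paste(inverse.rle(r), collapse = "")
}

# ---- deterministic fixtures ------------------------------------------------

.self_avoiding_walk <- function(L, step = 3.8, min_sep = 3.0) {
  X <- matrix(0, L, 3)
  i <- 2
  stuck <- 0
  while (i <= L) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    p <- X[i - 1, ] + step * u
    prev <- X[seq_len(i - 1), , drop = FALSE]
    if (all(sqrt(rowSums(sweep(prev, 2, p)^2)) >= min_sep)) {
      X[i, ] <- p
      i <- i + 1
      stuck <- 0
    } else {
      stuck <- stuck + 1
      if (stuck > 200) {  # back off and retry
        i <- max(2, i - 5)
        stuck <- 0
      }
    }
  }
  X
}

.beta_hairpin <- function(L) {
  n1 <- ceiling((L - 2) / 2)
  n2 <- L - 2 - n1
  s1 <- ideal_strand(n1)
  gap <- 4.8  # inter-strand backbone spacing
  turn <- rbind(s1[n1, ] + c(1.9, gap / 2 - 1, 1.5),
                s1[n1, ] + c(1.9, gap / 2 + 1, 1.5))
  s2 <- ideal_strand(n2)
  s2 <- cbind(rev(s2[, 1]) + s1[n1, 1] - s2[n2, 1], s2[, 2] + gap, s2[, 3])
  rbind(s1, turn, s2)
}

#' Deterministic test fixtures
#'
#' Generates idealised structures, toy sequences and decoy pools that make
#' every other module testable without external data.  All output is
#' reproducible bit-exactly from (kind, parameters, seed).
#'
#' Kinds: `ideal_helix` (C-alpha on a 1.5 A rise / 100 degree twist helix),
#' `beta_hairpin` (two antiparallel strands joined by a turn),
#' `random_coil` (self-avoiding walk, 3.8 A steps, minimum pairwise
#' distance 3 A), `toy_sequence` (sequence + secondary structure with an
#' alternating hydrophobic/hydrophilic pattern), `decoy_pool` (native plus
#' perturbed copies at given RMSD levels).
#'
#' @param kind fixture kind (see above)
#' @param L residue count (structural kinds)
#' @param seed RNG seed for the stochastic kinds
#' @param pattern for `toy_sequence`: `"alternating"` (LK repeat, helix ss)
#'   or `"mixed"` (helix-turn-strand toy)
#' @param native for `decoy_pool`: L x 3 native coordinates
#' @param rmsd for `decoy_pool`: numeric vector of perturbation sizes
#'   (Angstrom, unsuperposed RMSD of the added noise)
#' @param n_per_level decoys per RMSD level
#' @return coordinates matrix, `list(sequence, ss)`, or list of decoys
#' @export
make_fixture <- function(kind, L = 20, seed = 1, pattern = "alternating",
                         native = NULL, rmsd = c(0, 2, 5), n_per_level = 3) {
  set.seed(seed)
  switch(kind,
    ideal_helix = ideal_helix(L),
    beta_hairpin = .beta_hairpin(L),
    random_coil = .self_avoiding_walk(L),
    toy_sequence = {
      if (pattern == "alternating") {
        list(sequence = paste(rep(c("L", "K"), length.out = L),
                              collapse = ""),
             ss = strrep("C", L))
      } else {
        n1 <- L %/% 2 - 1
        n2 <- L - n1 - 2
        list(sequence = paste(rep(c("L", "K", "A", "E"), length.out = L),
                              collapse = ""),
             ss = paste0(strrep("H", n1), "CC", strrep("E", n2)))
      }
    },
    decoy_pool = {
      if (is.null(native)) stop("decoy_pool needs a native structure")
      out <- list()
      for (r in rmsd) {
        for (k in seq_len(n_per_level)) {
          E <- matrix(rnorm(length(native)), nrow(native), 3)
          sc <- sqrt(mean(rowSums(E^2)))
          E <- if (sc > 0 && r > 0) E * r / sc else E * 0
          out[[length(out) + 1]] <- structure(native + E, rmsd_level = r)
        }
      }
      out
    },
    stop("unknown fixture kind '", kind, "'")
  )
}

# ---- YAML configuration ----------------------------------------------------

.merge_cfg <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      defaults[[nm]] <- .merge_cfg(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Read a simulation configuration
#'
#' The YAML mirrors the parameter containers field for field under the top
#' level keys `ff`, `lp` and `scene`; unspecified keys keep their defaults.
#'
#' @param path YAML file, or NULL for pure defaults
#' @return list with `ff`, `lp`, `scene`
#' @export
read_config <- function(path = NULL) {
  ff <- default_ff_params()
  lp <- default_langevin_params()
  scn <- make_scene()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$ff)) {
      ff2 <- .merge_cfg(unclass(ff), cfg$ff)
      class(ff2) <- "cf_ff"
      attr(ff2$vdw_table, "type_radii") <- attr(ff$vdw_table, "type_radii")
      ff <- validate_ff(ff2)
    }
    if (!is.null(cfg$lp)) {
      lp2 <- .merge_cfg(unclass(lp), cfg$lp)
      if (!is.null(cfg$lp$solvent_radii)) {
        lp2$solvent_radii <- unlist(cfg$lp$solvent_radii)
      }
      class(lp2) <- "cf_lp"
      lp <- validate_lp(lp2)
    }
    if (!is.null(cfg$scene)) {
      args <- cfg$scene[names(cfg$scene) %in% names(formals(make_scene))]
      scn <- do.call(make_scene, args)
    }
  }
  list(ff = ff, lp = lp, scene = scn)
}

#' Write the effective configuration next to outputs
#'
#' @param config a [read_config()]-style list
#' @param path output YAML path
#' @export
write_config <- function(config, path) {
  dump <- list(ff = unclass(config$ff), lp = unclass(config$lp),
               scene = unclass(config$scene))
  dump$ff$vdw_table <- as.list(as.data.frame(dump$ff$vdw_table))
  yaml::write_yaml(dump, path)
  invisible(path)
}
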