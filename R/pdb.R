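#' Read a coarse-grained structure from a PDB file
#'
#' Bead-model files written by [write_pdb_cg()] (atom names `BB`/`BS`) are
#' read back directly.  All-atom nucleic-acid files are reduced to two beads
#' per nucleotide: the backbone bead takes the P-atom position (C4' fallback,
#' with a warning, where P is absent, e.g. at 5' ends) and the base bead the
#' glycosidic nitrogen (N9 for purines, N1 for pyrimidines; residue centroid
#' fallback).  Non-nucleic chains are skipped with a message.
#'
#' @param path PDB file.
#' @param config A [cg_config()] attached to the result.
#' @return A `cg_structure`.
#' @export
read_pdb_cg <- function(path, config = cg_config()) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("format error: no ATOM records in ", path)
  if (all(at$elety %in% c("BB", "BS"))) {
    return(beads_from_records(at, config))
  }
  nuc_res <- c("A", "U", "G", "C", "I", "DA", "DT", "DG", "DC", "RA", "RU",
               "RG", "RC", "N")
  skip <- !(at$resid %in% nuc_res)
  if (any(skip)) {
    message("skipping ", length(unique(at$chain[skip])),
            " non-nucleic chain(s)")
    at <- at[!skip, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("format error: no nucleic ATOM records")
  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  n <- length(res_keys)
  xyz <- matrix(NA_real_, 2L * n, 3)
  resid <- character(n)
  chain_lab <- character(n)
  missing_p <- 0L
  for (r in seq_len(n)) {
    rows <- at[key == res_keys[r], , drop = FALSE]
    resid[r] <- rows$resid[1]
    chain_lab[r] <- rows$chain[1]
    pxyz <- rows[rows$elety == "P", c("x", "y", "z")]
    if (nrow(pxyz) == 0) {
      pxyz <- rows[rows$elety == "C4'", c("x", "y", "z")]
      missing_p <- missing_p + 1L
    }
    if (nrow(pxyz) == 0) pxyz <- data.frame(t(colMeans(rows[, c("x", "y", "z")])))
    gly <- if (resid[r] %in% c("A", "G", "DA", "DG", "RA", "RG")) "N9" else "N1"
    bxyz <- rows[rows$elety == gly, c("x", "y", "z")]
    if (nrow(bxyz) == 0) {
      base_rows <- rows[!grepl("'|P", rows$elety), , drop = FALSE]
      if (nrow(base_rows) == 0) base_rows <- rows
      bxyz <- data.frame(t(colMeans(base_rows[, c("x", "y", "z")])))
    }
    xyz[2 * r - 1, ] <- as.numeric(pxyz[1, ])
    xyz[2 * r, ] <- as.numeric(bxyz[1, ])
  }
  if (missing_p > 0) {
    warning(missing_p, " residue(s) lack a P atom; used C4' fallback")
  }
  chain <- as.integer(factor(chain_lab, levels = unique(chain_lab)))
  nt <- seq_len(n)
  runs <- split(nt, chain)
  cg <- new_cg_structure(xyz, nt = rep(nt, each = 2),
                         chain = rep(chain, each = 2),
                         role = rep(c("BB", "BS"), n),
                         helix = rep(NA_integer_, 2 * n),
                         bonds = strand_bonds(runs), config = config)
  attr(cg, "resid") <- resid
  cg
}

beads_from_records <- function(at, config) {
  n <- nrow(at) / 2L
  ord <- order(at$eleno)
  at <- at[ord, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nt <- at$resno
  chain <- as.integer(factor(at$chain, levels = unique(at$chain)))
  role <- at$elety
  helix <- suppressWarnings(as.integer(at$b))
  helix[!is.na(helix) & helix == 0L] <- NA_integer_
  runs <- split(unique(nt), chain[match(unique(nt), nt)])
  new_cg_structure(xyz, nt, chain, role, helix,
                   bonds = strand_bonds(runs), config = config)
}

#' Write a coarse-grained structure as PDB
#'
#' Beads become ATOM records with atom names `BB`/`BS`, one residue per
#' nucleotide; helix membership is stored in the B-factor column (0 for
#' unassigned).  Coordinates round-trip through [read_pdb_cg()] to the
#' 0.001 Angstrom PDB precision.
#'
#' @param cg A `cg_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_cg <- function(cg, path) {
  n <- n_beads(cg)
  resid <- rep("N", n)
  if (!is.null(cg$ss)) {
    resid <- strsplit(cg$ss$seq, "")[[1]][cg$nt]
  } else if (!is.null(attr(cg, "resid"))) {
    resid <- attr(cg, "resid")[cg$nt]
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cg$xyz)),
                   resno = cg$nt,
                   resid = resid,
                   eleno = seq_len(n),
                   elety = cg$role,
                   chain = LETTERS[cg$chain],
                   o = rep(1, n),
                   b = ifelse(is.na(cg$helix), 0, cg$helix))
  invisible(path)
}
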