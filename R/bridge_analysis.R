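# Structure-based screen for carbamate-bridge geometry: inter-subunit
# residue-pair distances and enumeration of candidate lysine -> arginine /
# lysine bridges.

# Atoms defining the "side chain" end for the distance metric.  The
# carbamate chemically links the lysine NZ to the arginine guanidinium
# group, so LYS contributes NZ and ARG its guanidinium atoms; for other
# residue types fall back to all non-backbone atoms.
side_chain_atoms <- function(resname) {
  switch(resname,
         LYS = "NZ",
         ARG = c("NE", "CZ", "NH1", "NH2"),
         NULL)
}
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

residue_atoms <- function(full, chain, resno) {
  a <- full$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

#' Distance between two residues
#'
#' `side_chain_min` is the minimum distance over pairs of side-chain
#' terminal atoms (LYS: NZ; ARG: NE, CZ, NH1, NH2; other residues: all
#' non-backbone atoms); `calpha` is the CA-CA distance.  The atom pair that
#' realised the minimum is attached as attribute `atom_pair`.
#'
#' @param structure a `FullAtomStructure`.
#' @param resA,resB `c(chain, residue_number)` identifying the two residues.
#' @param metric `"side_chain_min"` (default) or `"calpha"`.
#' @return Distance in Angstrom, with attribute `atom_pair`.
#' @export
measure_pair_distance <- function(structure, resA, resB,
                                  metric = c("side_chain_min", "calpha")) {
  metric <- match.arg(metric)
  if (!inherits(structure, "FullAtomStructure")) {
    abort("`structure` must be a FullAtomStructure", "carbanm_parameter_error")
  }
  get_res <- function(res, label) {
    ra <- residue_atoms(structure, as.character(res[1L]), as.integer(res[2L]))
    if (!nrow(ra)) {
      abort(sprintf("%s residue %s%s not present in structure",
                    label, res[1L], res[2L]), "carbanm_lookup_error")
    }
    ra
  }
  ra <- get_res(resA, "first")
  rb <- get_res(resB, "second")
  pick <- function(ra, label) {
    if (metric == "calpha") {
      sel <- ra[ra$atom == "CA", , drop = FALSE]
      if (!nrow(sel)) {
        abort(sprintf("%s residue %s%d has no CA atom", label,
                      ra$chain[1L], ra$resno[1L]), "carbanm_lookup_error")
      }
      return(sel)
    }
    want <- side_chain_atoms(ra$resname[1L])
    sel <- if (is.null(want)) {
      ra[!(ra$atom %in% .BACKBONE), , drop = FALSE]
    } else {
      ra[ra$atom %in% want, , drop = FALSE]
    }
    if (!nrow(sel)) {
      abort(sprintf("%s residue %s%d (%s) is missing its side-chain atoms%s",
                    label, ra$chain[1L], ra$resno[1L], ra$resname[1L],
                    if (!is.null(want)) paste0(" (need ", paste(want, collapse = "/"), ")")
                    else ""),
            "carbanm_lookup_error")
    }
    sel
  }
  pa <- pick(ra, "first")
  pb <- pick(rb, "second")
  A <- as.matrix(pa[, c("x", "y", "z")])
  B <- as.matrix(pb[, c("x", "y", "z")])
  D <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
             Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  best <- which(D == min(D), arr.ind = TRUE)[1L, , drop = TRUE]
  structure(min(D), atom_pair = c(pa$atom[best[1L]], pb$atom[best[2L]]))
}

#' Enumerate candidate inter-subunit carbamate bridges
#'
#' Scans all donor residues of `donor_type` against all acceptor residues of
#' the given types on *different* chains and keeps pairs whose minimum
#' side-chain distance is at most `max_distance`.  Donors or acceptors with
#' unresolved side-chain atoms are skipped with a warning rather than
#' silently substituted.
#'
#' @param structure a multi-chain `FullAtomStructure`.
#' @param donor_type donor residue name (default `"LYS"`: only lysines can
#'   be carbamylated).
#' @param acceptor_types acceptor residue names (default `c("ARG", "LYS")`).
#' @param max_distance distance threshold in Angstrom (default 8).
#' @return data.frame of candidates sorted by distance then donor
#'   (chain, residue): columns `donor_chain`, `donor_resno`, `donor_resname`,
#'   `acceptor_chain`, `acceptor_resno`, `acceptor_resname`, `distance`,
#'   `donor_atom`, `acceptor_atom`.
#' @export
scan_candidate_bridges <- function(structure, donor_type = "LYS",
                                   acceptor_types = c("ARG", "LYS"),
                                   max_distance = 8) {
  if (!inherits(structure, "FullAtomStructure")) {
    abort("`structure` must be a FullAtomStructure", "carbanm_parameter_error")
  }
  a <- structure$atoms
  if (length(unique(a$chain)) < 2L) {
    abort("bridges are inter-subunit by definition: need a multi-chain structure",
          "carbanm_spec_error")
  }
  res <- unique(a[, c("chain", "resno", "resname")])

  # pre-extract side-chain terminal atom coordinates per residue
  terminal <- function(row) {
    ra <- a[a$chain == row$chain & a$resno == row$resno, , drop = FALSE]
    want <- side_chain_atoms(row$resname)
    sel <- if (is.null(want)) ra[!(ra$atom %in% .BACKBONE), , drop = FALSE]
           else ra[ra$atom %in% want, , drop = FALSE]
    sel
  }

  donors <- res[res$resname == donor_type, , drop = FALSE]
  acceptors <- res[res$resname %in% acceptor_types, , drop = FALSE]
  out <- list()
  for (di in seq_len(nrow(donors))) {
    drow <- donors[di, ]
    dat <- terminal(drow)
    if (!nrow(dat)) {
      warning(sprintf("donor %s%d (%s): side-chain atoms unresolved, skipped",
                      drow$chain, drow$resno, drow$resname))
      next
    }
    for (ai in seq_len(nrow(acceptors))) {
      arow <- acceptors[ai, ]
      if (arow$chain == drow$chain) next
      aat <- terminal(arow)
      if (!nrow(aat)) {
        warning(sprintf("acceptor %s%d (%s): side-chain atoms unresolved, skipped",
                        arow$chain, arow$resno, arow$resname))
        next
      }
      dmin <- Inf; pair <- c(NA_character_, NA_character_)
      for (p in seq_len(nrow(dat))) {
        dd <- sqrt((aat$x - dat$x[p])^2 + (aat$y - dat$y[p])^2 +
                   (aat$z - dat$z[p])^2)
        q <- which.min(dd)
        if (dd[q] < dmin) {
          dmin <- dd[q]
          pair <- c(dat$atom[p], aat$atom[q])
        }
      }
      if (dmin <= max_distance) {
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = drow$chain, donor_resno = drow$resno,
          donor_resname = drow$resname,
          acceptor_chain = arow$chain, acceptor_resno = arow$resno,
          acceptor_resname = arow$resname,
          distance = dmin, donor_atom = pair[1L], acceptor_atom = pair[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_resname = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_resname = character(),
                      distance = numeric(), donor_atom = character(),
                      acceptor_atom = character(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$distance, tab$donor_chain, tab$donor_resno,
                   tab$acceptor_chain, tab$acceptor_resno), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
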