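# Anisotropic elastic network model: Hookean springs between C-alpha nodes
# within a cutoff radius (default 8 A, k = 1 kcal/mol/A^2), optional
# inter-subunit carbamate-bridge springs, Hessian assembly and normal modes.

#' Build the contact spring network of a coarse-grained structure
#'
#' Every node pair separated by at most `cutoff` (inclusive comparison) is
#' joined by a Hookean spring whose rest length is the observed separation
#' and whose constant is `k`.
#'
#' @param structure a `CGStructure`.
#' @param cutoff contact cutoff radius in Angstrom (default 8).
#' @param k spring constant, kcal mol^-1 A^-2 (default 1).
#' @return An object of class `SpringNetwork`: node count, coordinate matrix
#'   and a data.frame of springs `(i, j, rest_length, k, tag)` with `i < j`.
#' @export
build_spring_network <- function(structure, cutoff = 8, k = 1) {
  if (!inherits(structure, "CGStructure")) {
    abort("`structure` must be a CGStructure", "carbanm_parameter_error")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be positive", "carbanm_parameter_error")
  }
  if (!is.numeric(k) || k <= 0) {
    abort("`k` must be positive", "carbanm_parameter_error")
  }
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 2L) abort("need at least 2 nodes", "carbanm_empty_error")
  D <- as.matrix(dist(xyz))
  sel <- upper.tri(D) & D <= cutoff
  ij <- which(sel, arr.ind = TRUE)
  if (nrow(ij) && any(D[sel] <= 0)) {
    abort("coincident atoms: zero-length spring", "carbanm_format_error")
  }
  springs <- data.frame(i = ij[, 1L], j = ij[, 2L],
                        rest_length = D[sel],
                        k = rep(k, nrow(ij)),
                        tag = rep("contact", nrow(ij)),
                        stringsAsFactors = FALSE)
  springs <- springs[order(springs$i, springs$j), , drop = FALSE]
  rownames(springs) <- NULL
  structure(list(n_nodes = n, springs = springs, coords = xyz,
                 atoms = structure$atoms, cutoff = cutoff),
            class = "SpringNetwork")
}

#' @export
print.SpringNetwork <- function(x, ...) {
  cat(sprintf("SpringNetwork: %d nodes, %d contact + %d bridge spring(s), cutoff %g A\n",
              x$n_nodes, sum(x$springs$tag == "contact"),
              sum(x$springs$tag == "bridge"), x$cutoff))
  invisible(x)
}

#' Specification of the inter-subunit carbamate bridge
#'
#' Describes the CO2-mediated bridge as one extra Hookean spring per
#' adjacent-chain interface, from the donor lysine of chain *i* to the
#' acceptor residue of chain *i+1* (cyclically, chains taken in sorted
#' label order).  For connexin 26 the donor is K125 and the acceptor R104;
#' connexin 32 substitutes K104 as the acceptor.
#'
#' @param donor_resno residue number of the donor (default 125).
#' @param acceptor_resno residue number of the acceptor (default 104).
#' @param donor_resname expected donor residue name (default LYS).
#' @param acceptor_resname expected acceptor residue name (default ARG;
#'   LYS is also chemically plausible).
#' @param bridge_k spring constant of the bridge, kcal mol^-1 A^-2
#'   (default 1, the same constant as the contact springs).
#' @return An object of class `BridgeSpec`.
#' @export
bridge_spec <- function(donor_resno = 125L, acceptor_resno = 104L,
                        donor_resname = "LYS", acceptor_resname = "ARG",
                        bridge_k = 1) {
  if (!is.numeric(bridge_k) || bridge_k <= 0) {
    abort("`bridge_k` must be positive", "carbanm_parameter_error")
  }
  structure(list(donor_resno = as.integer(donor_resno),
                 acceptor_resno = as.integer(acceptor_resno),
                 donor_resname = donor_resname,
                 acceptor_resname = acceptor_resname,
                 bridge_k = bridge_k),
            class = "BridgeSpec")
}

#' Add one carbamate-bridge spring per adjacent-chain interface
#'
#' For an n-mer this adds exactly n springs tagged `"bridge"`, each with
#' rest length equal to the current donor-acceptor C-alpha separation and
#' constant `bridge_k`.  A bridge is stored as its own spring even when a
#' contact spring already joins the same node pair (the Hessian sums
#' per-spring contributions, so this is equivalent to incrementing that
#' pair's stiffness while keeping the bridge count auditable).
#'
#' @param network a `SpringNetwork` built from `structure`.
#' @param structure the `CGStructure` the network was built from.
#' @param bridge a [bridge_spec()].
#' @return The network with `n_chains` additional bridge springs.
#' @export
add_bridge_springs <- function(network, structure, bridge) {
  if (!inherits(network, "SpringNetwork")) {
    abort("`network` must be a SpringNetwork", "carbanm_parameter_error")
  }
  if (!inherits(bridge, "BridgeSpec")) {
    abort("`bridge` must be a BridgeSpec", "carbanm_parameter_error")
  }
  a <- structure$atoms
  if (nrow(a) != network$n_nodes) {
    abort("structure and network disagree on node count", "carbanm_comparison_error")
  }
  chains <- sort(unique(a$chain))
  if (length(chains) < 2L) {
    abort("bridges are inter-subunit: need at least 2 chains", "carbanm_spec_error")
  }
  node_of <- function(chain, resno, role) {
    idx <- which(a$chain == chain & a$resno == resno)
    if (length(idx) != 1L) {
      abort(sprintf("%s residue %d not found in chain %s", role, resno, chain),
            "carbanm_spec_error")
    }
    idx
  }
  new_rows <- lapply(seq_along(chains), function(ci) {
    cj <- chains[ci %% length(chains) + 1L]
    di <- node_of(chains[ci], bridge$donor_resno, "donor")
    ai <- node_of(cj, bridge$acceptor_resno, "acceptor")
    if (a$resname[di] != bridge$donor_resname) {
      warning(sprintf("donor %s%d is %s, expected %s", chains[ci],
                      bridge$donor_resno, a$resname[di], bridge$donor_resname))
    }
    if (a$resname[ai] != bridge$acceptor_resname) {
      warning(sprintf("acceptor %s%d is %s, expected %s", cj,
                      bridge$acceptor_resno, a$resname[ai], bridge$acceptor_resname))
    }
    d <- sqrt(sum((network$coords[di, ] - network$coords[ai, ])^2))
    if (d <= 0) abort("coincident bridge endpoints", "carbanm_format_error")
    data.frame(i = min(di, ai), j = max(di, ai), rest_length = d,
               k = bridge$bridge_k, tag = "bridge", stringsAsFactors = FALSE)
  })
  network$springs <- rbind(network$springs, do.call(rbind, new_rows))
  rownames(network$springs) <- NULL
  network
}

#' Assemble the 3N x 3N anisotropic-network Hessian
#'
#' For each spring (i, j) with unit bond vector `r` the off-diagonal 3x3
#' block is `-k r r^T` and the diagonal blocks accumulate `+k r r^T`.  The
#' result is exactly symmetric and annihilates uniform translations.
#'
#' @param network a `SpringNetwork`.
#' @return A symmetric `3N x 3N` numeric matrix (kcal mol^-1 A^-2 with unit
#'   masses).
#' @export
build_hessian <- function(network) {
  if (!inherits(network, "SpringNetwork")) {
    abort("`network` must be a SpringNetwork", "carbanm_parameter_error")
  }
  n <- network$n_nodes
  H <- matrix(0, 3L * n, 3L * n)
  sp <- network$springs
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    d <- network$coords[j, ] - network$coords[i, ]
    rhat <- d / sqrt(sum(d^2))
    K <- sp$k[s] * tcrossprod(rhat)
    ii <- (3L * i - 2L):(3L * i)
    jj <- (3L * j - 2L):(3L * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  H
}

#' Solve for normal modes and flag rigid-body modes
#'
#' Eigenvalues are returned in ascending order.  Modes whose eigenvalue is
#' below `rigid_tolerance * max(eigenvalue)` are flagged rigid (solid-body
#' translations/rotations - six for a connected 3-D network) and excluded
#' from mode numbering: mode 1 is the first non-rigid eigenpair.  Each
#' eigenvector's sign is fixed so its largest-magnitude component is
#' positive, making downstream overlap maps and NMD exports reproducible.
#'
#' @param hessian symmetric Hessian from [build_hessian()].
#' @param rigid_tolerance relative eigenvalue threshold for the rigid-body
#'   subspace (default 1e-8, scale-free).
#' @return An object of class `ModeSet`: `values` (non-rigid eigenvalues,
#'   ascending), `vectors` (orthonormal columns, 3N rows), `rigid_count`,
#'   `rigid_values`, `n_nodes`.
#' @export
compute_modes <- function(hessian, rigid_tolerance = 1e-8) {
  if (!is.matrix(hessian) || nrow(hessian) != ncol(hessian)) {
    abort("`hessian` must be a square matrix", "carbanm_parameter_error")
  }
  if (nrow(hessian) %% 3L != 0L) {
    abort("Hessian dimension must be a multiple of 3", "carbanm_parameter_error")
  }
  if (max(abs(hessian - t(hessian))) > 1e-9) {
    abort("`hessian` is not symmetric", "carbanm_parameter_error")
  }
  e <- eigen(hessian, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  tol <- rigid_tolerance * max(abs(vals))
  rigid <- vals < tol
  if (sum(rigid) > 6L) {
    abort(sprintf("network is disconnected: %d near-zero modes (expected at most 6)",
                  sum(rigid)), "carbanm_disconnected_error")
  }
  keep <- !rigid
  V <- vecs[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (c in seq_len(ncol(V))) {
    top <- which.max(abs(V[, c]))
    if (V[top, c] < 0) V[, c] <- -V[, c]
  }
  structure(list(values = vals[keep], vectors = V,
                 rigid_count = sum(rigid), rigid_values = vals[rigid],
                 n_nodes = nrow(hessian) %/% 3L),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet: %d nodes, %d non-rigid modes (%d rigid), eigenvalues %.4g .. %.4g\n",
              x$n_nodes, length(x$values), x$rigid_count,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a ModeSet directly from eigenpairs
#'
#' Mainly for tests and for re-importing modes from disk.
#'
#' @param values non-rigid eigenvalues, ascending.
#' @param vectors matrix of orthonormal eigenvector columns (3N rows).
#' @param rigid_count number of rigid modes that were excluded.
#' @param rigid_values their eigenvalues (optional).
#' @return A `ModeSet`.
#' @export
mode_set <- function(values, vectors, rigid_count = 6L,
                     rigid_values = numeric(rigid_count)) {
  if (length(values) != ncol(vectors)) {
    abort("length(values) must equal ncol(vectors)", "carbanm_parameter_error")
  }
  if (nrow(vectors) %% 3L != 0L) {
    abort("vectors must have 3N rows", "carbanm_parameter_error")
  }
  if (is.unsorted(values)) {
    abort("eigenvalues must be ascending", "carbanm_parameter_error")
  }
  structure(list(values = as.numeric(values), vectors = vectors,
                 rigid_count = as.integer(rigid_count),
                 rigid_values = as.numeric(rigid_values),
                 n_nodes = nrow(vectors) %/% 3L),
            class = "ModeSet")
}

#' Fractional contribution of a mode to the total motion
#'
#' The weight of non-rigid mode m is its thermal mean-square amplitude
#' `1/lambda_m`, normalised over all non-rigid modes (the standard ENM
#' convention; the alternative `1/sqrt(lambda)` weighting is exposed for
#' sensitivity analysis).  Fractions sum to 1 over the non-rigid spectrum.
#'
#' @param modes a `ModeSet`.
#' @param m 1-based non-rigid mode index (vectorised); `NULL` returns the
#'   fractions of all non-rigid modes.
#' @param weighting `"amplitude"` (1/lambda, default) or
#'   `"inverse_frequency"` (1/sqrt(lambda)).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
mode_fraction <- function(modes, m = NULL,
                          weighting = c("amplitude", "inverse_frequency")) {
  if (!inherits(modes, "ModeSet")) {
    abort("`modes` must be a ModeSet", "carbanm_parameter_error")
  }
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              amplitude = 1 / modes$values,
              inverse_frequency = 1 / sqrt(modes$values))
  frac <- w / sum(w)
  if (is.null(m)) return(frac)
  if (!is.numeric(m) || any(m != as.integer(m)) || any(m < 1) ||
      any(m > length(frac))) {
    abort(sprintf("mode index out of the non-rigid range 1..%d (rigid modes have no fraction)",
                  length(frac)), "carbanm_domain_error")
  }
  frac[as.integer(m)]
}

#' Export a spring network as TSV
#'
#' Columns: i, j, rest_length, k, tag.
#'
#' @param network a `SpringNetwork`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_springs_tsv <- function(network, path) {
  write.table(network$springs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
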