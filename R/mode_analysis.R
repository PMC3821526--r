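# Comparison of unbound vs bridge-bound mode sets (overlap matrix,
# best-match reordering, fraction redistribution) and the pore-occlusion
# metric along a mode.

#' Overlap matrix between two ModeSets
#'
#' Entry (a, b) is `|v_a_unbound . v_b_bound|`; eigenvector signs are
#' arbitrary, so absolute values are used.  `best_match` maps each unbound
#' mode to the bound mode of maximal overlap (ties broken toward the lower
#' bound index); `one_to_one = TRUE` instead assigns greedily without reuse,
#' in order of decreasing best overlap.
#'
#' @param unbound,bound `ModeSet`s computed on the same structure (the
#'   bridge springs change the Hessian, not the coordinate space).
#' @param n_modes number of lowest non-rigid modes to compare (default 20).
#' @param one_to_one force a one-to-one assignment instead of per-row argmax.
#' @param weighting passed to [mode_fraction()].
#' @return An object of class `OverlapMap` with fields `values`,
#'   `n_modes_compared`, `best_match`, `fraction_unbound`, `fraction_bound`,
#'   `values_unbound`, `values_bound`.
#' @export
overlap_matrix <- function(unbound, bound, n_modes = 20L, one_to_one = FALSE,
                           weighting = "amplitude") {
  if (!inherits(unbound, "ModeSet") || !inherits(bound, "ModeSet")) {
    abort("`unbound` and `bound` must be ModeSets", "carbanm_parameter_error")
  }
  if (unbound$n_nodes != bound$n_nodes) {
    abort("ModeSets have different node counts", "carbanm_comparison_error")
  }
  n <- min(n_modes, length(unbound$values), length(bound$values))
  U <- unbound$vectors[, seq_len(n), drop = FALSE]
  V <- bound$vectors[, seq_len(n), drop = FALSE]
  M <- abs(crossprod(U, V))
  dimnames(M) <- list(unbound = seq_len(n), bound = seq_len(n))
  best <- if (one_to_one) {
    assigned <- integer(n)
    left <- rep(TRUE, n)
    for (r in order(apply(M, 1L, max), decreasing = TRUE)) {
      b <- which(left)[which.max(M[r, left])]
      assigned[r] <- b
      left[b] <- FALSE
    }
    assigned
  } else {
    apply(M, 1L, which.max)   # which.max resolves ties toward the lower index
  }
  structure(list(values = M, n_modes_compared = n, best_match = best,
                 fraction_unbound = mode_fraction(unbound, weighting = weighting)[seq_len(n)],
                 fraction_bound = mode_fraction(bound, weighting = weighting)[seq_len(n)],
                 values_unbound = unbound$values[seq_len(n)],
                 values_bound = bound$values[seq_len(n)]),
            class = "OverlapMap")
}

#' @export
print.OverlapMap <- function(x, ...) {
  cat(sprintf("OverlapMap: %d x %d modes, mean diagonal overlap %.3f\n",
              x$n_modes_compared, x$n_modes_compared, mean(diag(x$values))))
  invisible(x)
}

#' Mode reordering report
#'
#' One row per compared unbound mode: its best-match bound mode, the overlap
#' of that pair, the fractional contributions of the unbound mode and of its
#' bound match, and the corresponding frequencies (`sqrt(lambda)`, so a
#' scatter of `freq_unbound` vs `freq_bound` with the x = y reference
#' reproduces the mode-reordering plot: modes demoted to higher frequency
#' fall above the line).
#'
#' @param map an `OverlapMap`.
#' @return A data.frame with columns `unbound_mode`, `bound_mode`,
#'   `overlap`, `fraction_unbound`, `fraction_bound`, `freq_unbound`,
#'   `freq_bound`.
#' @export
reordering_report <- function(map) {
  if (!inherits(map, "OverlapMap")) {
    abort("`map` must be an OverlapMap", "carbanm_parameter_error")
  }
  n <- map$n_modes_compared
  bm <- map$best_match
  data.frame(
    unbound_mode = seq_len(n),
    bound_mode = bm,
    overlap = map$values[cbind(seq_len(n), bm)],
    fraction_unbound = map$fraction_unbound,
    fraction_bound = map$fraction_bound[bm],
    freq_unbound = sqrt(map$values_unbound),
    freq_bound = sqrt(map$values_bound[bm])
  )
}

#' Identify the pore-closing mode of a ModeSet
#'
#' The closing mode is the non-rigid mode with the largest absolute overlap
#' with a concerted radial-inward displacement pattern restricted to the
#' pore-lining atoms (those whose radial distance from the pore axis is in
#' the inner half of the observed range).  For an iris-like closing motion
#' this pattern lies in the totally symmetric representation of the C_n
#' group, so the returned mode is the breathing/closing mode rather than a
#' degenerate tilt pair.
#'
#' @param modes a `ModeSet`.
#' @param structure the `CGStructure` the modes were computed on.
#' @param n_consider how many lowest non-rigid modes to score (default 30).
#' @return Integer mode index; attribute `score` holds the overlap with the
#'   closing pattern.
#' @export
closing_mode_index <- function(modes, structure, n_consider = 30L) {
  if (!inherits(modes, "ModeSet")) {
    abort("`modes` must be a ModeSet", "carbanm_parameter_error")
  }
  xyz <- coords(structure)
  if (nrow(xyz) != modes$n_nodes) {
    abort("structure and modes disagree on node count", "carbanm_comparison_error")
  }
  ax <- pore_axis(xyz)
  rel <- sweep(xyz, 2L, ax$origin)
  z <- as.numeric(rel %*% ax$direction)
  perp <- rel - outer(z, ax$direction)
  rr <- sqrt(rowSums(perp^2))
  lining <- rr < (min(rr) + max(rr)) / 2
  pat <- -perp / pmax(rr, 1e-12) * lining
  pat <- as.numeric(t(pat))
  pat <- pat / sqrt(sum(pat^2))
  n <- min(n_consider, length(modes$values))
  score <- abs(as.numeric(pat %*% modes$vectors[, seq_len(n), drop = FALSE]))
  idx <- which.max(score)
  structure(idx, score = score[idx])
}

# Pore axis: the principal axis of the C-alpha cloud whose moment is most
# separated from the other two (the C_n symmetry axis of a ring is the
# distinct principal direction); sign fixed toward +z.
pore_axis <- function(xyz) {
  centred <- sweep(xyz, 2L, colMeans(xyz))
  e <- eigen(crossprod(centred) / nrow(centred), symmetric = TRUE)
  v <- e$values   # descending
  dir <- if ((v[1] - v[2]) >= (v[2] - v[3])) e$vectors[, 1L] else e$vectors[, 3L]
  top <- which.max(abs(dir))
  if (dir[top] < 0) dir <- -dir
  list(origin = colMeans(xyz), direction = dir)
}

#' Pore-occlusion profile along the channel axis
#'
#' Optionally displaces the structure along a mode (eigenvector normalised
#' to unit 3N-norm, scaled by `amplitude`), then slices the structure along
#' the pore axis and records the minimum radial distance of any C-alpha to
#' the axis per slice.  `min_radius` is the bottleneck over all slices;
#' amplitude 0 reproduces the static profile.
#'
#' @param structure a `CGStructure`.
#' @param mode optional 3N eigenvector.
#' @param amplitude displacement amplitude in Angstrom.
#' @param axis optional `list(origin, direction)`; default is the principal
#'   axis of the coordinate cloud closest to the symmetry axis.
#' @param slice_width slice thickness along the axis (default 2 A).
#' @return An object of class `PoreProfile`: `axis`, `slices` (data.frame
#'   `z_lo`, `z_hi`, `min_radius`) and scalar `min_radius`.
#' @export
pore_profile <- function(structure, mode = NULL, amplitude = 0, axis = NULL,
                         slice_width = 2) {
  xyz <- coords(structure)
  if (!is.null(mode)) {
    if (length(mode) != 3L * nrow(xyz)) {
      abort(sprintf("mode has %d components, structure needs %d",
                    length(mode), 3L * nrow(xyz)), "carbanm_comparison_error")
    }
    if (!is.finite(amplitude)) {
      abort("`amplitude` must be finite", "carbanm_parameter_error")
    }
    disp <- matrix(mode / sqrt(sum(mode^2)), ncol = 3L, byrow = TRUE)
    xyz <- xyz + amplitude * disp
  }
  ax <- axis %||% pore_axis(coords(structure))
  rel <- sweep(xyz, 2L, ax$origin)
  z <- as.numeric(rel %*% ax$direction)
  r2 <- rowSums(rel^2) - z^2
  radial <- sqrt(pmax(r2, 0))
  breaks <- seq(floor(min(z) / slice_width) * slice_width,
                ceiling(max(z) / slice_width) * slice_width + slice_width / 2,
                by = slice_width)
  bin <- cut(z, breaks, include.lowest = TRUE, labels = FALSE)
  per_slice <- tapply(radial, bin, min)
  idx <- as.integer(names(per_slice))
  slices <- data.frame(z_lo = breaks[idx], z_hi = breaks[idx + 1L],
                       min_radius = as.numeric(per_slice))
  structure(list(axis = ax, slices = slices,
                 min_radius = min(slices$min_radius)),
            class = "PoreProfile")
}

#' @export
print.PoreProfile <- function(x, ...) {
  cat(sprintf("PoreProfile: %d slices, bottleneck radius %.2f A\n",
              nrow(x$slices), x$min_radius))
  invisible(x)
}

#' Per-residue displacement vectors of a mode
#'
#' @param structure a `CGStructure` (defines N).
#' @param mode 3N eigenvector.
#' @param scale total 3N-norm of the returned displacement field; 0 gives
#'   all-zero vectors.
#' @return N x 3 matrix of displacement vectors.
#' @export
mode_displacement_vectors <- function(structure, mode, scale = 1) {
  n <- n_atoms(structure)
  if (length(mode) != 3L * n) {
    abort("mode dimension does not match structure", "carbanm_comparison_error")
  }
  if (scale == 0) return(matrix(0, n, 3L))
  matrix(mode, ncol = 3L, byrow = TRUE) * (scale / sqrt(sum(mode^2)))
}

#' Write modes in NMD (NMWiz-compatible) format
#'
#' Emits a coordinates block plus one `mode` line per eigenpair, each scaled
#' by `1/sqrt(lambda)` (thermal amplitude), so the file can be animated in
#' VMD's NMWiz or re-imported with [read_nmd()].
#'
#' @param path output path.
#' @param structure the `CGStructure` the modes belong to.
#' @param modes a `ModeSet`.
#' @param n_modes how many lowest non-rigid modes to write (default 20).
#' @param name dataset label stored in the file.
#' @return Invisibly, `path`.
#' @export
write_nmd <- function(path, structure, modes, n_modes = 20L, name = "carbanm") {
  n <- min(n_modes, length(modes$values))
  a <- structure$atoms
  num <- function(x) paste(formatC(x, format = "g", digits = 12), collapse = " ")
  lines <- c(
    "nmwiz_load carbanm.nmd",
    paste("name", name),
    paste("resnames", paste(a$resname, collapse = " ")),
    paste("chainids", paste(a$chain, collapse = " ")),
    paste("resids", paste(a$resno, collapse = " ")),
    paste("coordinates", num(as.numeric(t(coords(structure)))))
  )
  for (m in seq_len(n)) {
    lines <- c(lines, paste("mode", m,
                            formatC(1 / sqrt(modes$values[m]), format = "g", digits = 12),
                            num(modes$vectors[, m])))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an NMD file written by [write_nmd()]
#'
#' @param path NMD file path.
#' @return list with `coordinates` (N x 3 matrix), `modes` (data-frame-free
#'   list of `index`, `scale`, `vector`), and the identity blocks that were
#'   present (`resnames`, `chainids`, `resids`).
#' @export
read_nmd <- function(path) {
  if (!file.exists(path)) abort(paste("no such NMD file:", path), "carbanm_io_error")
  lines <- readLines(path, warn = FALSE)
  out <- list(modes = list())
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!length(tok)) next
    key <- tok[1L]
    if (key == "coordinates") {
      out$coordinates <- matrix(as.numeric(tok[-1L]), ncol = 3L, byrow = TRUE)
    } else if (key == "mode") {
      out$modes[[length(out$modes) + 1L]] <-
        list(index = as.integer(tok[2L]), scale = as.numeric(tok[3L]),
             vector = as.numeric(tok[-(1:3)]))
    } else if (key %in% c("resnames", "chainids")) {
      out[[key]] <- tok[-1L]
    } else if (key == "resids") {
      out$resids <- as.integer(tok[-1L])
    }
  }
  if (is.null(out$coordinates)) {
    abort("NMD file has no coordinates block", "carbanm_format_error")
  }
  out
}
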