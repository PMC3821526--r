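# Parametric C_n-symmetric toy oligomers.
#
# Each subunit has two parts, mimicking a membrane channel protomer:
# a "wall arc" that sweeps most of its sector at the outer ring radius and
# the full axial height (adjacent arcs nearly touch, giving a stiff
# extracellular scaffold), and a "funnel leg" that descends to the pore
# radius at height zero (the pore-lining tip).  The tips of adjacent
# subunits are out of contact-spring range of each other except through the
# donor-acceptor pair, so the soft low-frequency modes are the concerted
# radial flapping of the free tips - an iris-like pore closing - and a
# single bridge spring per interface selectively opposes exactly that
# motion (tip convergence scales the inter-tip chord), while concerted
# axial or tangential tip motions leave the chord unchanged to first order.

#' Specification of a synthetic C_n-symmetric oligomer
#'
#' All lengths in Angstrom.  The defaults emulate a hexameric hemichannel:
#' six subunits around a central pore, and one donor lysine / acceptor
#' arginine pair per interface whose separation is calibrated to the 6.5 A
#' inter-subunit K125-R104 gap seen in the connexin 26 hexamer.
#'
#' @param n_subunits number of chains (>= 2).
#' @param residues_per_subunit C-alpha nodes per chain (>= 3).
#' @param ring_radius outer radius of the wall arc.
#' @param pore_radius radius of the pore-lining tip residues.
#' @param axial_rise axial extent of the subunit: the wall arc sits at this
#'   height and the funnel leg descends from it to the tip at height 0.
#' @param donor_index residue index (within the subunit) of the donor lysine.
#' @param acceptor_index residue index of the acceptor arginine.
#' @param target_bridge_distance donor(chain i) to acceptor(chain i+1)
#'   C-alpha distance, hit exactly when `noise_sigma = 0`.  The default
#'   (9.5 A) sits just outside the 8 A contact cutoff, as in the real
#'   hexamer, where the 6.5 A gap is between side-chain ends while the
#'   C-alpha pair is further apart: the bridge spring must be a *new*
#'   constraint, not a duplicate of an existing contact.
#' @param noise_sigma per-coordinate Gaussian noise applied to the final
#'   structure (0 = exactly symmetric).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return An object of class `OligomerSpec` (a validated list).
#' @export
oligomer_spec <- function(n_subunits = 6L,
                          residues_per_subunit = 26L,
                          ring_radius = 18,
                          pore_radius = 10.5,
                          axial_rise = 30,
                          donor_index = residues_per_subunit,
                          acceptor_index = residues_per_subunit - 1L,
                          target_bridge_distance = 9.5,
                          noise_sigma = 0,
                          seed = 1L) {
  spec <- list(n_subunits = as.integer(n_subunits),
               residues_per_subunit = as.integer(residues_per_subunit),
               ring_radius = ring_radius, pore_radius = pore_radius,
               axial_rise = axial_rise,
               donor_index = as.integer(donor_index),
               acceptor_index = as.integer(acceptor_index),
               target_bridge_distance = target_bridge_distance,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  if (spec$n_subunits < 2L) abort("n_subunits must be >= 2", "carbanm_parameter_error")
  if (spec$n_subunits > 26L) abort("at most 26 chains (A-Z)", "carbanm_parameter_error")
  if (spec$residues_per_subunit < 3L) {
    abort("residues_per_subunit must be >= 3", "carbanm_parameter_error")
  }
  if (spec$ring_radius <= 0 || spec$pore_radius <= 0 ||
      spec$pore_radius >= spec$ring_radius) {
    abort("need 0 < pore_radius < ring_radius", "carbanm_parameter_error")
  }
  if (spec$donor_index < 1L || spec$donor_index > spec$residues_per_subunit ||
      spec$acceptor_index < 1L || spec$acceptor_index > spec$residues_per_subunit ||
      spec$donor_index == spec$acceptor_index) {
    abort("donor_index/acceptor_index out of range or equal", "carbanm_parameter_error")
  }
  if (spec$target_bridge_distance <= 1e-6) {
    abort("target_bridge_distance must be positive", "carbanm_parameter_error")
  }
  if (spec$noise_sigma < 0) abort("noise_sigma must be >= 0", "carbanm_parameter_error")
  class(spec) <- "OligomerSpec"
  spec
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}

# Template subunit (chain A) for a spec; rows are residues.
# Residues 1..w trace the wall arc (r = ring_radius, z = axial_rise,
# phi from -0.45 to +0.45 of the sector, with a small z ripple so the arc
# is not collinear); residues w+1..m descend the funnel leg from the arc
# end to the pore tip at (r = pore_radius, z = 0, phi = sector centre).
subunit_template <- function(spec) {
  m <- spec$residues_per_subunit
  sector <- 2 * pi / spec$n_subunits
  w <- max(1L, min(round(m * 0.25), (m - 5L) %/% 2L))
  n_leg <- m - 2L * w - 2L
  if (n_leg < 3L) {
    abort("residues_per_subunit too small for the wall/leg/arm layout (need >= 8)",
          "carbanm_parameter_error")
  }
  cyl <- function(r, phi, z) cbind(r * cos(phi), r * sin(phi), z)
  # wall: an out-and-back double strand at two heights, so each interface
  # is held by a 3-D cluster of springs (tangential + diagonal directions)
  # rather than a single pivot point
  j1 <- seq_len(w)
  top <- cyl(spec$ring_radius + 0.6 * cos(2.1 * j1),
             seq(-0.45, 0.45, length.out = w) * sector,
             spec$axial_rise + 0.6 * sin(2.1 * j1))
  j2 <- seq_len(w) + w
  bot <- cyl(spec$ring_radius - 1.2 + 0.6 * cos(2.1 * j2),
             seq(0.45, -0.45, length.out = w) * sector,
             spec$axial_rise - 3.5 + 0.6 * sin(2.1 * j2))
  # funnel leg: an alpha-helix-like coil (~3.6 residues/turn) descending to
  # the pore tip at the sector centre.  The coil matters: with an 8 A cutoff
  # it gives leg residues i+/-3 and i+/-4 contacts, which suppresses the
  # free-dihedral mechanisms a thinner chain would have; its amplitude
  # tapers so the tip lands at a predictable radius.
  j <- seq_len(n_leg)
  u <- j / n_leg
  omega <- 2 * pi / 3.6
  amp <- 0.3 + 1.7 * (1 - u)
  r_leg <- spec$ring_radius - (spec$ring_radius - spec$pore_radius) * u +
    amp * cos(omega * j)
  phi_leg <- (-0.45 + 0.45 * u) * sector + amp * sin(omega * j) / r_leg
  leg <- cyl(r_leg, phi_leg, (spec$axial_rise - 3.5) * (1 - u))
  # donor/acceptor arms flank the tip tangentially, reaching toward the
  # neighbouring subunits; the donor(i) -> acceptor(i+1) pair is meant to be
  # the only inter-chain contact in the tip region, so a bridge spring
  # specifically stiffens tip-convergence (pore-closing) motions
  acceptor <- cyl(spec$pore_radius, -0.2 * sector, 0.8)
  donor <- cyl(spec$pore_radius, 0.2 * sector, -0.8)
  unname(rbind(top, bot, leg, acceptor, donor))
}

#' Generate a C_n-symmetric toy oligomer
#'
#' Chains are labelled `A`, `B`, ... in ring order; "adjacent subunit" means
#' the next label cyclically.  The donor residue carries residue name LYS and
#' the acceptor ARG; the acceptor position is adjusted along the
#' donor-acceptor line so that donor(chain i) to acceptor(chain i+1) equals
#' `target_bridge_distance` exactly (before noise).  With `noise_sigma = 0`
#' the structure is exactly C_n symmetric.
#'
#' @param spec an [oligomer_spec()].
#' @return A `CGStructure` with `n_subunits` chains.
#' @export
make_cn_oligomer <- function(spec) {
  if (!inherits(spec, "OligomerSpec")) {
    abort("`spec` must be an OligomerSpec", "carbanm_parameter_error")
  }
  tmpl <- subunit_template(spec)
  sector <- 2 * pi / spec$n_subunits
  R1 <- rot_z(sector)

  # Place the acceptor so the interface distance is exact: q0 is the
  # acceptor's image on the next chain; move it along the donor->q0 line.
  p_d <- tmpl[spec$donor_index, ]
  q0 <- as.numeric(R1 %*% tmpl[spec$acceptor_index, ])
  gap <- q0 - p_d
  gap_len <- sqrt(sum(gap^2))
  if (gap_len < 1e-9) {
    abort("degenerate geometry: donor and rotated acceptor coincide",
          "carbanm_parameter_error")
  }
  q_new <- p_d + spec$target_bridge_distance * gap / gap_len
  a_new <- as.numeric(t(R1) %*% q_new)
  shift <- sqrt(sum((a_new - tmpl[spec$acceptor_index, ])^2))
  if (shift > 6) {
    abort(sprintf(paste0("target_bridge_distance %.2f not achievable for this ring ",
                         "geometry (acceptor would move %.1f A off the backbone)"),
                  spec$target_bridge_distance, shift),
          "carbanm_parameter_error")
  }
  tmpl[spec$acceptor_index, ] <- a_new

  m <- spec$residues_per_subunit
  resname <- rep("ALA", m)
  resname[spec$donor_index] <- "LYS"
  resname[spec$acceptor_index] <- "ARG"

  chains <- LETTERS[seq_len(spec$n_subunits)]
  atoms <- do.call(rbind, lapply(seq_along(chains), function(i) {
    xyz <- tmpl %*% t(rot_z((i - 1) * sector))
    data.frame(chain = chains[i], resno = seq_len(m), resname = resname,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  cg <- cg_structure(atoms,
                     source_label = sprintf("synthetic C%d oligomer", spec$n_subunits))
  if (spec$noise_sigma > 0) {
    cg <- perturb(cg, spec$noise_sigma, spec$seed)
  }
  cg
}

#' Two-atom structure for analytic oracles
#'
#' @param separation distance between the two atoms along the x-axis.
#' @return A single-chain `CGStructure` with atoms at the origin and at
#'   `(separation, 0, 0)`.
#' @export
make_dimer <- function(separation) {
  if (!is.numeric(separation) || length(separation) != 1L ||
      !is.finite(separation) || separation <= 1e-6) {
    abort("`separation` must be a positive distance", "carbanm_parameter_error")
  }
  cg_structure(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                          x = c(0, separation), y = 0, z = 0,
                          stringsAsFactors = FALSE),
               source_label = "dimer")
}

#' Add isotropic Gaussian displacement to every atom
#'
#' Each coordinate receives independent `N(0, sigma^2)` noise.  `sigma = 0`
#' returns the input unchanged; a fixed seed is fully reproducible and the
#' caller's RNG state is left untouched.
#'
#' @param structure a `CGStructure`.
#' @param sigma per-coordinate standard deviation (Angstrom, >= 0).
#' @param seed RNG seed.
#' @return A perturbed `CGStructure`.
#' @export
perturb <- function(structure, sigma, seed = 1L) {
  if (!inherits(structure, "CGStructure")) {
    abort("`structure` must be a CGStructure", "carbanm_parameter_error")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number", "carbanm_parameter_error")
  }
  if (sigma == 0) return(structure)
  n <- n_atoms(structure)
  noise <- with_seed(seed, matrix(rnorm(3L * n, sd = sigma), ncol = 3L))
  structure$atoms$x <- structure$atoms$x + noise[, 1]
  structure$atoms$y <- structure$atoms$y + noise[, 2]
  structure$atoms$z <- structure$atoms$z + noise[, 3]
  structure
}

#' Decorate a synthetic oligomer with donor/acceptor side-chain atoms
#'
#' Produces a `FullAtomStructure` in which every residue keeps its CA atom,
#' each donor lysine gains an NZ atom and each acceptor arginine gains the
#' guanidinium atoms (NE, CZ, NH1, NH2), placed so that the minimum
#' side-chain distance NZ(chain i) to NH1(chain i+1) equals
#' `side_chain_distance` exactly at every interface.  Used to exercise the
#' salt-bridge distance screen without a crystal structure.
#'
#' @param cg a `CGStructure` from [make_cn_oligomer()].
#' @param spec the [oligomer_spec()] that generated it.
#' @param side_chain_distance planted NZ-to-guanidinium distance (Angstrom).
#' @return A `FullAtomStructure`.
#' @export
decorate_side_chains <- function(cg, spec, side_chain_distance = 6) {
  if (side_chain_distance <= 0) {
    abort("side_chain_distance must be positive", "carbanm_parameter_error")
  }
  a <- cg$atoms
  chains <- sort(unique(a$chain))
  n <- length(chains)
  rows <- list()
  add <- function(chain, resno, resname, atom, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, atom = atom,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(a))) {
    add(a$chain[i], a$resno[i], a$resname[i], "CA",
        c(a$x[i], a$y[i], a$z[i]))
  }
  pos_of <- function(chain, resno) {
    k <- which(a$chain == chain & a$resno == resno)
    c(a$x[k], a$y[k], a$z[k])
  }
  for (ci in seq_len(n)) {
    cn <- chains[ci %% n + 1L]
    p_d <- pos_of(chains[ci], spec$donor_index)
    p_a <- pos_of(cn, spec$acceptor_index)
    u <- (p_a - p_d) / sqrt(sum((p_a - p_d)^2))
    nz <- p_d + 1.5 * u
    u2 <- (p_a - nz) / sqrt(sum((p_a - nz)^2))
    nh1 <- nz + side_chain_distance * u2
    # remaining guanidinium atoms strictly further from NZ than NH1
    perp <- c(-u2[2], u2[1], 0)
    if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    cz <- nh1 + 0.65 * u2
    ne <- cz + 0.65 * u2
    nh2 <- cz + 0.65 * perp
    add(chains[ci], spec$donor_index, "LYS", "NZ", nz)
    add(cn, spec$acceptor_index, "ARG", "NH1", nh1)
    add(cn, spec$acceptor_index, "ARG", "CZ", cz)
    add(cn, spec$acceptor_index, "ARG", "NE", ne)
    add(cn, spec$acceptor_index, "ARG", "NH2", nh2)
  }
  full_atom_structure(do.call(rbind, rows),
                      source_label = paste0(cg$source_label, " + side chains"))
}
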