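# End-to-end orchestration: structure -> two ENMs (unbound / bridge-bound)
# -> modes -> overlap comparison -> report bundle.  A run is fully
# determined by its RunConfig; identical configs yield byte-identical
# summaries.

#' Configuration of a comparison run
#'
#' The input is either a PDB file path or a synthetic [oligomer_spec()].
#' Defaults follow the published ENM parameterisation: 8 A cutoff, spring
#' constant 1 kcal mol^-1 A^-2, one bridge spring per interface with the
#' same constant.
#'
#' @param pdb path to a PDB file, or `NULL` to use `spec`.
#' @param spec an [oligomer_spec()] (used when `pdb` is `NULL`).
#' @param cutoff contact cutoff (Angstrom).
#' @param k contact spring constant.
#' @param bridge a [bridge_spec()].
#' @param n_modes_report modes compared/reported (default 20).
#' @param rigid_tolerance relative rigid-mode threshold.
#' @param weighting mode-fraction weighting (see [mode_fraction()]).
#' @param pore_amplitude displacement amplitude for the mode-1 pore profile.
#' @param seed seed recorded for synthetic generation.
#' @param outdir output directory for the report bundle.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(pdb = NULL, spec = NULL, cutoff = 8, k = 1,
                       bridge = bridge_spec(), n_modes_report = 20L,
                       rigid_tolerance = 1e-8, weighting = "amplitude",
                       pore_amplitude = 5, seed = 1L, outdir = tempfile("carbanm_run_")) {
  if (is.null(pdb) && is.null(spec)) {
    abort("RunConfig needs either a PDB path or an OligomerSpec", "carbanm_parameter_error")
  }
  if (!is.null(spec) && !inherits(spec, "OligomerSpec")) {
    abort("`spec` must be an OligomerSpec", "carbanm_parameter_error")
  }
  structure(list(pdb = pdb, spec = spec, cutoff = cutoff, k = k,
                 bridge = bridge, n_modes_report = as.integer(n_modes_report),
                 rigid_tolerance = rigid_tolerance, weighting = weighting,
                 pore_amplitude = pore_amplitude, seed = as.integer(seed),
                 outdir = outdir),
            class = "RunConfig")
}

#' Serialise a RunConfig to a flat key=value file
#'
#' @param config a `RunConfig`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  kv <- c(
    if (!is.null(config$pdb)) c(pdb = config$pdb),
    if (!is.null(config$spec)) {
      s <- config$spec
      c(n_subunits = s$n_subunits, residues_per_subunit = s$residues_per_subunit,
        ring_radius = s$ring_radius, pore_radius = s$pore_radius,
        axial_rise = s$axial_rise, donor_index = s$donor_index,
        acceptor_index = s$acceptor_index,
        target_bridge_distance = s$target_bridge_distance,
        noise_sigma = s$noise_sigma, spec_seed = s$seed)
    },
    cutoff = config$cutoff, k = config$k,
    donor_resno = config$bridge$donor_resno,
    acceptor_resno = config$bridge$acceptor_resno,
    donor_resname = config$bridge$donor_resname,
    acceptor_resname = config$bridge$acceptor_resname,
    bridge_k = config$bridge$bridge_k,
    n_modes_report = config$n_modes_report,
    rigid_tolerance = config$rigid_tolerance,
    weighting = config$weighting,
    pore_amplitude = config$pore_amplitude,
    seed = config$seed)
  writeLines(paste0(names(kv), "=", vapply(kv, format, "", digits = 17)), path)
  invisible(path)
}

#' Read a RunConfig from a flat key=value file
#'
#' @param path config file path.
#' @param outdir output directory for the run.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, outdir = tempfile("carbanm_run_")) {
  if (!file.exists(path)) abort(paste("no such config:", path), "carbanm_io_error")
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""),
                          vapply(kv, `[`, "", 1L))
  num <- function(key, default) if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  chr <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  spec <- if ("n_subunits" %in% names(vals)) {
    oligomer_spec(n_subunits = num("n_subunits", 6),
                  residues_per_subunit = num("residues_per_subunit", 24),
                  ring_radius = num("ring_radius", 18),
                  pore_radius = num("pore_radius", 8),
                  axial_rise = num("axial_rise", 2),
                  donor_index = num("donor_index", 24),
                  acceptor_index = num("acceptor_index", 1),
                  target_bridge_distance = num("target_bridge_distance", 6.5),
                  noise_sigma = num("noise_sigma", 0),
                  seed = num("spec_seed", 1))
  }
  run_config(pdb = chr("pdb", NULL), spec = spec,
             cutoff = num("cutoff", 8), k = num("k", 1),
             bridge = bridge_spec(donor_resno = num("donor_resno", 125),
                                  acceptor_resno = num("acceptor_resno", 104),
                                  donor_resname = chr("donor_resname", "LYS"),
                                  acceptor_resname = chr("acceptor_resname", "ARG"),
                                  bridge_k = num("bridge_k", 1)),
             n_modes_report = num("n_modes_report", 20),
             rigid_tolerance = num("rigid_tolerance", 1e-8),
             weighting = chr("weighting", "amplitude"),
             pore_amplitude = num("pore_amplitude", 5),
             seed = num("seed", 1), outdir = outdir)
}

resolve_input <- function(config) {
  if (!is.null(config$pdb)) {
    to_calpha(read_pdb(config$pdb))
  } else {
    make_cn_oligomer(config$spec)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, carbanm_error = function(e) {
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)), class(e)[1L])
  })
}

#' Run the unbound vs bridge-bound ENM comparison
#'
#' Builds both elastic networks, solves their modes, compares them, and
#' writes the full report bundle into `config$outdir`: eigenvalue CSVs,
#' a mode-fraction table, the overlap matrix CSV, the reordering report TSV,
#' NMD files for both states, mode-1 pore profiles, and `summary.json`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `summary` (also written as JSON) and
#'   the `paths` of every artifact.
#' @export
run_comparison <- function(config) {
  if (!inherits(config, "RunConfig")) {
    abort("`config` must be a RunConfig", "carbanm_parameter_error")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)

  cg <- stage("input", resolve_input(config))
  net <- stage("build", build_spring_network(cg, cutoff = config$cutoff, k = config$k))
  netb <- stage("bridge", add_bridge_springs(net, cg, config$bridge))
  mu <- stage("modes-unbound", compute_modes(build_hessian(net), config$rigid_tolerance))
  mb <- stage("modes-bound", compute_modes(build_hessian(netb), config$rigid_tolerance))
  ov <- stage("compare", overlap_matrix(mu, mb, n_modes = config$n_modes_report,
                                        weighting = config$weighting))
  rep_tab <- reordering_report(ov)

  n_show <- ov$n_modes_compared
  eig_tab <- function(m) data.frame(mode = seq_along(m$values),
                                    eigenvalue = m$values,
                                    fraction = mode_fraction(m, weighting = config$weighting))
  utils::write.csv(eig_tab(mu), p("eigenvalues_unbound.csv"), row.names = FALSE)
  utils::write.csv(eig_tab(mb), p("eigenvalues_bound.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ov$values), p("overlap.csv"), row.names = TRUE)
  write.table(rep_tab, p("reordering.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_nmd(p("unbound.nmd"), cg, mu, n_modes = n_show, name = "unbound")
  write_nmd(p("bound.nmd"), cg, mb, n_modes = n_show, name = "bound")
  write_springs_tsv(netb, p("springs.tsv"))

  prof <- function(m, file) {
    pr <- pore_profile(cg, mode = m$vectors[, 1L], amplitude = config$pore_amplitude)
    write.table(pr$slices, file, sep = "\t", quote = FALSE, row.names = FALSE)
    pr
  }
  pr_u <- stage("pore", prof(mu, p("pore_unbound.tsv")))
  pr_b <- stage("pore", prof(mb, p("pore_bound.tsv")))
  pr_static <- pore_profile(cg)

  match1 <- ov$best_match[1L]
  summary <- list(
    n_nodes = n_atoms(cg),
    n_contact_springs = sum(net$springs$tag == "contact"),
    n_bridge_springs = sum(netb$springs$tag == "bridge"),
    rigid_count_unbound = mu$rigid_count,
    rigid_count_bound = mb$rigid_count,
    unbound_mode1_fraction = mode_fraction(mu, 1L, weighting = config$weighting),
    unbound_mode1_best_match = match1,
    bound_match_fraction = mode_fraction(mb, match1, weighting = config$weighting),
    bound_match_overlap = ov$values[1L, match1],
    pore_min_radius_static = pr_static$min_radius,
    pore_min_radius_unbound_mode1 = pr_u$min_radius,
    pore_min_radius_bound_mode1 = pr_b$min_radius,
    cutoff = config$cutoff, k = config$k,
    bridge_k = config$bridge$bridge_k, weighting = config$weighting,
    pore_amplitude = config$pore_amplitude
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_run_config(config, p("config.txt"))

  invisible(list(summary = summary,
                 paths = list(outdir = config$outdir,
                              summary = p("summary.json"))))
}

#' Run the inter-subunit bridge scan and write the candidate table
#'
#' @param config a [run_config()] whose input must be a PDB path or a
#'   synthetic spec (synthetic structures are decorated with planted
#'   side-chain atoms at the spec's `target_bridge_distance`).
#' @param max_distance distance threshold (Angstrom, default 8).
#' @param donor_type,acceptor_types forwarded to [scan_candidate_bridges()].
#' @param side_chain_distance planted side-chain gap for synthetic
#'   decoration (default 6.5 A, the K125-R104 side-chain separation; the
#'   C-alpha pair sits further apart).
#' @return Invisibly, the candidate data.frame (also written to
#'   `candidates.tsv` in `config$outdir`).
#' @export
run_bridge_scan <- function(config, max_distance = 8, donor_type = "LYS",
                            acceptor_types = c("ARG", "LYS"),
                            side_chain_distance = 6.5) {
  if (!inherits(config, "RunConfig")) {
    abort("`config` must be a RunConfig", "carbanm_parameter_error")
  }
  full <- stage("input", {
    if (!is.null(config$pdb)) {
      read_pdb(config$pdb)
    } else {
      decorate_side_chains(make_cn_oligomer(config$spec), config$spec,
                           side_chain_distance = side_chain_distance)
    }
  })
  tab <- stage("scan", scan_candidate_bridges(full, donor_type = donor_type,
                                              acceptor_types = acceptor_types,
                                              max_distance = max_distance))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(tab, file.path(config$outdir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(tab)
}
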