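# End-to-end run configuration and pipeline.

#' Assemble a run configuration
#'
#' Collects ladder, network, fuzzy-ensemble and clustering parameters plus
#' output settings into one serializable object. Values given here are
#' defaults for a whole pipeline run; individual stages can still be called
#' directly with their own parameters.
#'
#' @param ladder a [make_ladder()] object.
#' @param network_params a [network_params()] object.
#' @param fuzzy_params a [fuzzy_params()] object; `n_topologies = 1` with
#'   zero jitter reduces the ensemble stage to a single deterministic run.
#' @param k pathway clusters for multi-variant runs.
#' @param seed master seed; defaults to the fuzzy-parameter seed.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return list of class `cna_config`.
#' @export
cna_config <- function(ladder = make_ladder(),
                       network_params = cnar::network_params(),
                       fuzzy_params = cnar::fuzzy_params(),
                       k = 10, seed = fuzzy_params$seed, out_dir = NULL,
                       verbose = FALSE) {
  structure(list(ladder = ladder, network_params = network_params,
                 fuzzy_params = fuzzy_params, k = as.integer(k),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "cna_config")
}

#' Run the full analysis pipeline on one structure
#'
#' Stages: read (or accept) the structure, build the constraint network,
#' run the fuzzy-constraint ensemble of thermal unfolding simulations, and
#' compute the stability indices. When `out_dir` is set, all stage outputs
#' and a manifest (package version, seeds, parameters) are written so any
#' result file can be regenerated from the manifest alone.
#'
#' @param config a [cna_config()].
#' @param input a PDB path or a `cna_structure`.
#' @return list with `structure`, `network`, `ensemble`, `indices` (single
#'   deterministic-run global series and transition), and `manifest`.
#' @export
run_pipeline <- function(config, input) {
  stopifnot(inherits(config, "cna_config"))
  say <- function(...) if (config$verbose) message(...)

  s <- if (inherits(input, "cna_structure")) input else read_pdb(input)
  say("structure: ", nrow(s$atoms), " atoms")
  net <- build_network(s, config$network_params)
  say("network: ", nrow(net$constraints), " constraints")

  traj <- run_unfolding(net, config$ladder)
  gi <- global_indices(traj)
  transition <- tryCatch(detect_transition(gi), error = function(e) NULL)
  map <- stability_map(traj)
  single <- list(global = gi, transition = transition, stability_map = map,
                 neighbor_median = neighbor_median_stability(map),
                 profile = percolation_profile(traj))

  fp <- config$fuzzy_params
  fp$seed <- config$seed
  ens <- run_ensemble(net, config$ladder, fp)
  say("ensemble: ", fp$n_topologies, " topologies")

  manifest <- list(package = "cnar",
                   version = as.character(utils::packageVersion("cnar")),
                   seed = config$seed,
                   ladder = list(start = config$ladder$e_cut[1],
                                 stop = config$ladder$e_cut[nrow(config$ladder)],
                                 n_states = nrow(config$ladder)),
                   network_params = unclass(config$network_params),
                   fuzzy_params = unclass(fp),
                   n_atoms = nrow(s$atoms),
                   n_constraints = nrow(net$constraints))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_network(net, file.path(config$out_dir, "network.tsv"))
    write_trajectory(traj, file.path(config$out_dir, "trajectory"))
    write_profile(single$profile, file.path(config$out_dir, "profile.tsv"))
    write_matrix(map$rc, file.path(config$out_dir, "stability_map.tsv"))
    summary <- list(
      rc_median = ens$rc_median_mean,
      rc_median_K = ens$rc_median_K_mean,
      rc_median_K_sem = ens$rc_median_K_sem,
      t_p_mean = ens$t_p_mean, t_p_sem = ens$t_p_sem,
      n_t_p_missing = ens$n_t_p_missing)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(structure = s, network = net, ensemble = ens, indices = single,
       manifest = manifest)
}
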