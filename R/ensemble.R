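# Ensembles of network topologies with fuzzy noncovalent constraints
# (ENT-FNC): thermal fluctuations are emulated by randomizing the
# noncovalent constraint set of a single input structure, without moving
# atoms.

#' Fuzzy-ensemble parameters
#'
#' @param n_topologies ensemble size (default 2000, the production setting;
#'   examples and tests use far fewer).
#' @param seed master seed; per-topology seeds are derived from it.
#' @param hbond_energy_jitter kcal/mol half-width of the uniform
#'   perturbation applied to each hydrogen-bond energy (default 0.3).
#' @param tether_fuzz_band A half-width of the band around the tether
#'   distance cutoff within which candidate tethers are included with a
#'   probability falling linearly from 1 to 0 across the band (default
#'   0.25).
#' @return list of class `cna_fuzzy_params`.
#' @export
fuzzy_params <- function(n_topologies = 2000, seed = 1,
                         hbond_energy_jitter = 0.3, tether_fuzz_band = 0.25) {
  stopifnot(n_topologies >= 1, hbond_energy_jitter >= 0, tether_fuzz_band >= 0)
  structure(list(n_topologies = as.integer(n_topologies),
                 seed = as.integer(seed),
                 hbond_energy_jitter = hbond_energy_jitter,
                 tether_fuzz_band = tether_fuzz_band),
            class = "cna_fuzzy_params")
}

#' Draw one fuzzy network topology
#'
#' Covalent constraints are untouched. Each hydrogen-bond energy is
#' perturbed by a uniform draw from `[-jitter, +jitter]`; bonds pushed above
#' the energy cutoff are dropped. Each candidate tether within the fuzz band
#' around its distance cutoff is included with probability falling linearly
#' across the band; tethers well inside the cutoff are always included.
#' Salt bridges keep their fixed energy. Deterministic given
#' `(network, draw_seed, params)`.
#'
#' @param net a `cna_network` built by [build_network()].
#' @param draw_seed integer seed for this topology.
#' @param params a [fuzzy_params()] object.
#' @return a `cna_network` with the randomized constraint set.
#' @export
generate_fuzzy_topology <- function(net, draw_seed, params = fuzzy_params()) {
  stopifnot(inherits(net, "cna_network"))
  set.seed(as.integer(draw_seed))
  con <- net$constraints
  cutoff <- net$params$hbond_energy_cutoff

  hb <- which(con$kind == "hbond")
  if (length(hb) > 0 && params$hbond_energy_jitter > 0) {
    con$energy[hb] <- con$energy[hb] +
      runif(length(hb), -params$hbond_energy_jitter, params$hbond_energy_jitter)
    drop <- hb[con$energy[hb] > cutoff]
    if (length(drop) > 0) con <- con[-drop, , drop = FALSE]
  }

  cand <- net$tether_candidates
  if (!is.null(cand) && nrow(cand) > 0) {
    band <- params$tether_fuzz_band
    if (band > 0) {
      p_incl <- pmin(1, pmax(0, (cand$cutoff + band - cand$dist) / (2 * band)))
      keep <- runif(nrow(cand)) < p_incl
    } else {
      keep <- cand$dist <= cand$cutoff
    }
    con <- con[con$kind != "tether", , drop = FALSE]
    if (any(keep)) {
      con <- rbind(con, data.frame(
        body_a = cand$body_a[keep], body_b = cand$body_b[keep],
        kind = "tether", bars = net$params$tether_bars, energy = NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  .new_network(net$structure, net$n_bodies, con, net$coords, net$params,
               net$tether_candidates)
}

#' Run a fuzzy-constraint ensemble
#'
#' Generates `n_topologies` fuzzy topologies, runs the thermal unfolding on
#' each, and aggregates phase transition temperatures, neighbor median
#' contact stabilities, percolation profiles, and the ensemble-averaged
#' stability map. Topologies whose entropy series admits no transition are
#' recorded as missing for `T_p` and excluded from its mean.
#'
#' @param net a `cna_network` with a structure reference.
#' @param ladder a [make_ladder()] object.
#' @param params a [fuzzy_params()] object.
#' @param neighbor_cutoff A for the stability-map neighbor mask.
#' @return object of class `cna_ensemble`: per-topology vectors (`t_p`,
#'   `rc_median`, `rc_median_K`), their means and standard errors, the
#'   ensemble-averaged stability map (`mean_stability`), the profile matrix
#'   (`profiles`, topologies x residues), seeds and parameters.
#' @examples
#' \donttest{
#' net <- build_network(make_ideal_helix(7))
#' ens <- run_ensemble(net, params = fuzzy_params(n_topologies = 5, seed = 7))
#' ens$rc_median_K_mean
#' }
#' @export
run_ensemble <- function(net, ladder = make_ladder(), params = fuzzy_params(),
                         neighbor_cutoff = 5) {
  stopifnot(inherits(net, "cna_network"))
  n <- params$n_topologies
  set.seed(params$seed)
  draw_seeds <- sample.int(.Machine$integer.max, n)

  t_p <- rc_med <- numeric(n)
  profiles <- NULL
  rc_sum <- NULL
  for (i in seq_len(n)) {
    topo <- generate_fuzzy_topology(net, draw_seeds[i], params)
    traj <- run_unfolding(topo, ladder)
    gi <- global_indices(traj)
    t_p[i] <- tryCatch(detect_transition(gi)$t_p, error = function(e) NA_real_)
    m <- stability_map(traj, neighbor_cutoff)
    rc_med[i] <- neighbor_median_stability(m)$rc_median
    prof <- percolation_profile(traj)$p_i
    if (is.null(profiles)) profiles <- matrix(NA_real_, n, length(prof))
    profiles[i, ] <- prof
    rc_sum <- if (is.null(rc_sum)) m$rc else rc_sum + m$rc
  }
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  }
  mean_map <- structure(list(rc = rc_sum / n,
                             neighbor_mask = .neighbor_mask(net$structure,
                                                            neighbor_cutoff),
                             ladder = ladder),
                        class = "cna_stability_map")
  structure(list(
    t_p = t_p, t_p_mean = mean(t_p, na.rm = TRUE), t_p_sem = sem(t_p),
    n_t_p_missing = sum(is.na(t_p)),
    rc_median = rc_med, rc_median_mean = mean(rc_med), rc_median_sem = sem(rc_med),
    rc_median_K = ecut_to_temperature(rc_med),
    rc_median_K_mean = ecut_to_temperature(mean(rc_med)),
    rc_median_K_sem = 20 * sem(rc_med),
    mean_stability = mean_map, profiles = profiles,
    draw_seeds = draw_seeds, params = params),
    class = "cna_ensemble")
}

#' @export
print.cna_ensemble <- function(x, ...) {
  cat("cna_ensemble:", length(x$rc_median), "topologies; mean rc_median",
      sprintf("%.3f kcal/mol (%.1f K +/- %.2f)", x$rc_median_mean,
              x$rc_median_K_mean, x$rc_median_K_sem), "\n")
  invisible(x)
}
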