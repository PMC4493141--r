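# Constraint-dilution thermal unfolding over the E_cut ladder.

#' Map a hydrogen-bond energy cutoff to a temperature
#'
#' Linear relation calibrated on mesophilic/thermophilic ortholog pairs:
#' \deqn{T = -20\,\mathrm{K\,mol\,kcal^{-1}} \cdot E_{cut} + 300\,\mathrm{K}}
#' so the default ladder from -0.1 to -6.0 kcal/mol spans 302 K to 420 K.
#'
#' @param e_cut energy cutoff(s), kcal/mol.
#' @return temperature(s) in K.
#' @examples
#' ecut_to_temperature(c(-0.1, -1.2, -6.0))
#' @export
ecut_to_temperature <- function(e_cut) -20 * e_cut + 300

#' Inverse of [ecut_to_temperature()]
#' @param temperature temperature(s) in K.
#' @return energy cutoff(s), kcal/mol.
#' @export
temperature_to_ecut <- function(temperature) (300 - temperature) / 20

#' Build a dilution ladder
#'
#' Ordered E_cut values from `start` down to `stop` (inclusive) in steps of
#' `step`, with the matching temperatures attached. The values are computed
#' from integer multiples of the step so state boundaries are bit-stable.
#' The default ladder has 60 states (-0.1 to -6.0, step 0.1; 302 K to 420 K
#' in 2 K steps).
#'
#' @param start,stop ladder endpoints, kcal/mol, `start > stop`.
#' @param step positive step size, kcal/mol; must divide the range.
#' @return data frame of class `cna_ladder` with columns `state`, `e_cut`,
#'   `temperature`.
#' @examples
#' nrow(make_ladder())
#' @export
make_ladder <- function(start = -0.1, stop = -6.0, step = 0.1) {
  if (start < stop) stop("ladder start must not be below stop (start >= stop)")
  if (step <= 0) stop("ladder step must be positive")
  n <- round((start - stop) / step) + 1
  e_cut <- round(start - (seq_len(n) - 1) * step, 10)
  if (abs(e_cut[n] - stop) > 1e-9)
    stop("step does not divide the ladder range")
  structure(data.frame(state = seq_len(n), e_cut = e_cut,
                       temperature = ecut_to_temperature(e_cut)),
            class = c("cna_ladder", "data.frame"))
}

#' Run a thermal unfolding simulation
#'
#' For each ladder state sigma the active constraints are all covalent
#' bonds, all tethers (the tether set is held fixed over the whole ladder:
#' hydrophobic interactions do not weaken as temperature rises), and the
#' hydrogen bonds/salt bridges with energy at or below `E_cut(sigma)`; each
#' state is decomposed into rigid clusters. Hydrogen bonds are thereby
#' removed in increasing order of strength as the ladder descends.
#' Consecutive states with identical active sets share one decomposition.
#'
#' @param net a `cna_network`.
#' @param ladder a [make_ladder()] object.
#' @return object of class `cna_trajectory`: the ladder, the network, the
#'   list of per-state `cna_decomposition`s, and a `summary` data frame
#'   (state, e_cut, temperature, n_hbonds_active, largest_cluster_size,
#'   n_clusters, dof_total).
#' @examples
#' traj <- run_unfolding(build_network(make_ideal_helix(7)))
#' head(traj$summary, 3)
#' @export
run_unfolding <- function(net, ladder = make_ladder()) {
  stopifnot(inherits(net, "cna_network"), inherits(ladder, "cna_ladder"))
  n_states <- nrow(ladder)
  decompositions <- vector("list", n_states)
  n_active <- integer(n_states)
  prev_active <- -1L
  for (i in seq_len(n_states)) {
    state <- network_state(net, ladder$e_cut[i], state_index = i)
    breakable <- net$constraints$kind %in% c("hbond", "saltbridge")
    n_active[i] <- sum(state$active & breakable)
    if (n_active[i] == prev_active) {
      decompositions[[i]] <- decompositions[[i - 1]]
    } else {
      decompositions[[i]] <- decompose(state)
    }
    prev_active <- n_active[i]
  }
  summary <- data.frame(
    state = ladder$state, e_cut = ladder$e_cut,
    temperature = ladder$temperature,
    n_hbonds_active = n_active,
    largest_cluster_size = vapply(decompositions, function(d) d$sizes[[1]], integer(1)),
    n_clusters = vapply(decompositions, function(d) length(d$clusters), integer(1)),
    dof_total = vapply(decompositions, function(d) d$dof_total, integer(1)))
  structure(list(ladder = ladder, network = net,
                 decompositions = decompositions, summary = summary),
            class = "cna_trajectory")
}

#' @export
print.cna_trajectory <- function(x, ...) {
  cat("cna_trajectory:", nrow(x$ladder), "states;",
      "largest cluster", x$summary$largest_cluster_size[1], "->",
      x$summary$largest_cluster_size[nrow(x$ladder)], "bodies\n")
  invisible(x)
}
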