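# Rigid cluster decomposition of network states via the 6-DOF body-bar
# pebble game, plus the dense rigidity-matrix oracle used to certify it.

#' A network state on the dilution ladder
#'
#' The active constraints of state sigma are all covalent bonds and
#' tethers plus the hydrogen bonds and salt bridges with energy at or below
#' `e_cut` (ties included).
#'
#' @param net a `cna_network`.
#' @param e_cut kcal/mol dilution threshold; `NULL` keeps every constraint.
#' @param state_index optional position on the ladder.
#' @return object of class `cna_state`.
#' @export
network_state <- function(net, e_cut = NULL, state_index = NA_integer_) {
  stopifnot(inherits(net, "cna_network"))
  con <- net$constraints
  if (is.null(e_cut)) {
    active <- rep(TRUE, nrow(con))
  } else {
    breakable <- con$kind %in% c("hbond", "saltbridge")
    active <- !breakable | (!is.na(con$energy) & con$energy <= e_cut)
  }
  structure(list(network = net, e_cut = e_cut, active = active,
                 state_index = state_index),
            class = "cna_state")
}

.as_state <- function(x) {
  if (inherits(x, "cna_state")) return(x)
  if (inherits(x, "cna_network")) return(network_state(x))
  stop("expected a cna_network or cna_state")
}

#' Rigid cluster decomposition
#'
#' Plays the 6-DOF body-bar pebble game: every body starts with six pebbles
#' (its free degrees of freedom); a bar is independent iff seven pebbles can
#' be gathered on its endpoints, consuming one. Rigid clusters are maximal
#' body sets with zero internal degrees of freedom, identified by post hoc
#' mutual-rigidity searches seeded from failed-search regions. Bars are
#' processed in sorted `(body_a, body_b, kind)` order, so the decomposition
#' and its labels are reproducible.
#'
#' @param x a `cna_network` or `cna_state`.
#' @return object of class `cna_decomposition`: `cluster_id` (one label per
#'   body; clusters numbered by decreasing size, ties by smallest member),
#'   `clusters` (list of body-id vectors in that order), `sizes`,
#'   `n_bodies`, `n_independent`, `redundant_bar_count`, `dof_total`.
#' @examples
#' dimer <- make_toy_network(2, data.frame(body_a = 1, body_b = 2,
#'                                         kind = "covalent", bars = 6))
#' decompose(dimer)$sizes
#' @export
decompose <- function(x) {
  state <- .as_state(x)
  edges <- .active_edges(state)
  n <- state$network$n_bodies
  res <- pebble_game_cpp(n, edges$body_a, edges$body_b, edges$bars, TRUE)
  raw <- res$cluster_raw
  # relabel deterministically: decreasing size, ties by smallest body id
  sizes <- table(raw)
  first_member <- tapply(seq_len(n), raw, min)
  ord <- order(-as.integer(sizes), as.integer(first_member))
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  cluster_id <- relabel[match(raw, as.integer(names(sizes)))]
  clusters <- split(seq_len(n), cluster_id)
  clusters <- clusters[order(as.integer(names(clusters)))]
  names(clusters) <- NULL
  structure(list(cluster_id = cluster_id,
                 clusters = clusters,
                 sizes = lengths(clusters),
                 n_bodies = n,
                 n_independent = res$independent,
                 redundant_bar_count = res$redundant,
                 dof_total = 6L * n - res$independent),
            class = "cna_decomposition")
}

#' @export
print.cna_decomposition <- function(x, ...) {
  cat("cna_decomposition:", x$n_bodies, "bodies,", length(x$clusters),
      "clusters (largest", x$sizes[1], "),", x$dof_total, "DOF,",
      x$redundant_bar_count, "redundant bars\n")
  invisible(x)
}

.active_edges <- function(state) {
  con <- state$network$constraints[state$active, , drop = FALSE]
  if (nrow(con) == 0)
    return(data.frame(body_a = integer(0), body_b = integer(0), bars = integer(0)))
  con[order(con$body_a, con$body_b, con$kind),
      c("body_a", "body_b", "bars"), drop = FALSE]
}

#' Remaining degrees of freedom of a network state
#'
#' `6 * n_bodies` minus the number of independent bars; equals the number of
#' free pebbles left after the game.
#'
#' @param x a `cna_network` or `cna_state`.
#' @return integer DOF count.
#' @export
count_dof <- function(x) {
  state <- .as_state(x)
  edges <- .active_edges(state)
  res <- pebble_game_cpp(state$network$n_bodies, edges$body_a, edges$body_b,
                         edges$bars, FALSE)
  6L * state$network$n_bodies - res$independent
}

#' Pairwise mutual rigidity from the pebble game
#'
#' After playing the game, a pair of bodies is mutually rigid iff at most
#' six pebbles can be gathered on it (an additional bar would be redundant).
#'
#' @param x a `cna_network` or `cna_state`.
#' @param pairs two-column matrix of body ids.
#' @return logical vector, one entry per pair.
#' @export
pebble_pair_rigid <- function(x, pairs) {
  state <- .as_state(x)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  edges <- .active_edges(state)
  pebble_pair_rigid_cpp(state$network$n_bodies, edges$body_a, edges$body_b,
                        edges$bars, pairs[, 1], pairs[, 2])
}

#' Brute-force rigidity-matrix rank oracle
#'
#' Independent implementation used to certify the pebble game on small
#' instances: each bar becomes one row of the 6-DOF rigidity matrix, with
#' generic (seeded random) attachment points on its endpoint bodies; the
#' matrix rank equals the number of independent bars. Dense linear algebra,
#' intended for networks of up to a few dozen bodies.
#'
#' @param x a `cna_network` or `cna_state`.
#' @param coords optional body positions (defaults to the network's).
#' @param seed seed for the generic bar placements.
#' @return integer rank (independent-bar count).
#' @export
brute_force_rank_oracle <- function(x, coords = NULL, seed = 1) {
  state <- .as_state(x)
  M <- .rigidity_matrix(state, coords, seed)
  if (nrow(M) == 0) return(0L)
  qr(M)$rank
}

.rigidity_matrix <- function(state, coords = NULL, seed = 1, extra = NULL) {
  net <- state$network
  if (is.null(coords)) coords <- net$coords
  if (is.null(coords)) stop("network has no coordinates; supply coords")
  edges <- .active_edges(state)
  if (!is.null(extra)) edges <- rbind(edges, extra)
  total_bars <- sum(edges$bars)
  M <- matrix(0, nrow = total_bars, ncol = 6 * net$n_bodies)
  set.seed(seed)
  row <- 0
  for (k in seq_len(nrow(edges))) {
    a <- edges$body_a[k]; b <- edges$body_b[k]
    for (j in seq_len(edges$bars[k])) {
      pa <- coords[a, ] + runif(3, -0.5, 0.5)
      pb <- coords[b, ] + runif(3, -0.5, 0.5)
      u <- pb - pa
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) { u <- runif(3); nu <- sqrt(sum(u^2)) }
      u <- u / nu
      row <- row + 1
      ca <- (a - 1) * 6; cb <- (b - 1) * 6
      M[row, ca + 1:3] <- u
      M[row, ca + 4:6] <- .cross3(pa, u)
      M[row, cb + 1:3] <- -u
      M[row, cb + 4:6] <- -.cross3(pb, u)
    }
  }
  M
}

#' Pairwise mutual rigidity from the rank oracle
#'
#' A pair is mutually rigid iff adding six generic bars between the two
#' bodies does not increase the rigidity-matrix rank (zero relative DOF).
#'
#' @inheritParams brute_force_rank_oracle
#' @param pairs two-column matrix of body ids.
#' @return logical vector, one entry per pair.
#' @export
oracle_pair_rigid <- function(x, pairs, coords = NULL, seed = 1) {
  state <- .as_state(x)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  base_rank <- brute_force_rank_oracle(state, coords, seed)
  vapply(seq_len(nrow(pairs)), function(i) {
    extra <- data.frame(body_a = pairs[i, 1], body_b = pairs[i, 2], bars = 6L)
    M <- .rigidity_matrix(state, coords, seed, extra = extra)
    qr(M)$rank == base_rank
  }, logical(1))
}
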