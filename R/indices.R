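# Global and local rigidity indices computed from an unfolding trajectory.

#' Cluster configuration entropy (type 2)
#'
#' Disorder of the rigid-cluster size distribution of one network state:
#' \deqn{H = -\sum_c w_c \ln w_c, \quad w_c = s_c^2 / \sum_{c'} s_{c'}^2}
#' with cluster sizes `s_c` (singletons included). Zero when a single
#' cluster holds all bodies; the index jumps when a dominant rigid cluster
#' breaks into pieces, which marks rigidity phase transitions.
#'
#' @param d a `cna_decomposition` (or an integer vector of cluster sizes).
#' @param exponent weighting exponent on the sizes (default 2, the "type 2"
#'   weighting).
#' @return entropy (dimensionless, >= 0).
#' @examples
#' cluster_configuration_entropy(c(2, 2))  # ln 2
#' @export
cluster_configuration_entropy <- function(d, exponent = 2) {
  sizes <- if (inherits(d, "cna_decomposition")) d$sizes else d
  if (length(sizes) == 0 || sum(sizes) == 0) stop("empty decomposition")
  w <- sizes^exponent / sum(sizes^exponent)
  w <- w[w > 0]
  -sum(w * log(w))
}

#' Rigidity order parameter
#'
#' Fraction of bodies belonging to the largest rigid cluster; the global
#' percolation measure of a network state.
#'
#' @param d a `cna_decomposition`.
#' @param n_bodies total bodies (defaults to the decomposition's).
#' @return fraction in `[0, 1]`.
#' @export
rigidity_order_parameter <- function(d, n_bodies = d$n_bodies) {
  stopifnot(inherits(d, "cna_decomposition"))
  max(d$sizes) / n_bodies
}

#' Per-state global index series of a trajectory
#'
#' @param traj a `cna_trajectory`.
#' @return object of class `cna_global_series`: data frame with `state`,
#'   `e_cut`, `temperature`, `h_type2`, `order_parameter`, carrying the
#'   ladder as an attribute.
#' @export
global_indices <- function(traj) {
  stopifnot(inherits(traj, "cna_trajectory"))
  h <- vapply(traj$decompositions, cluster_configuration_entropy, numeric(1))
  op <- vapply(traj$decompositions, rigidity_order_parameter, numeric(1))
  out <- data.frame(state = traj$ladder$state, e_cut = traj$ladder$e_cut,
                    temperature = traj$ladder$temperature,
                    h_type2 = h, order_parameter = op)
  structure(out, class = c("cna_global_series", "data.frame"),
            ladder = traj$ladder)
}

#' Detect the rigidity phase transition
#'
#' The phase transition temperature `T_p` is the temperature of the state
#' immediately after the most pronounced single-step jump of the cluster
#' configuration entropy. Ties are broken toward the lower temperature
#' (earlier transition); when the two largest jumps differ by less than 10
#' percent the result is flagged low-confidence, reflecting that protein
#' networks often show several comparable jumps.
#'
#' @param series a [global_indices()] result, or a numeric vector of
#'   per-state entropies (then `ladder` must be given).
#' @param ladder a `cna_ladder` (taken from `series` when omitted).
#' @return list with `t_p` (K), `t_p_ecut` (kcal/mol), `state_index`,
#'   `low_confidence`, `tied`.
#' @export
detect_transition <- function(series, ladder = NULL) {
  if (inherits(series, "cna_global_series")) {
    if (is.null(ladder)) ladder <- attr(series, "ladder")
    h <- series$h_type2
  } else {
    h <- as.numeric(series)
  }
  if (is.null(ladder)) stop("a ladder is required")
  if (length(h) != nrow(ladder)) stop("series length must match the ladder")
  if (length(h) < 2) stop("need at least two states")
  jumps <- diff(h)
  if (max(jumps) <= 0)
    stop("no entropy increase along the trajectory: transition undefined")
  best <- which.max(jumps)            # ties resolved to the earliest state
  tied <- sum(jumps == jumps[best]) > 1
  sorted <- sort(jumps, decreasing = TRUE)
  low_conf <- tied ||
    (length(sorted) > 1 && sorted[2] > 0 && (sorted[1] - sorted[2]) < 0.1 * sorted[1])
  idx <- best + 1L
  list(t_p = ladder$temperature[idx], t_p_ecut = ladder$e_cut[idx],
       state_index = idx, low_confidence = low_conf, tied = tied)
}

# largest-cluster membership as a logical matrix (bodies x states)
.giant_membership <- function(traj) {
  vapply(traj$decompositions, function(d) d$cluster_id == 1L,
         logical(traj$network$n_bodies))
}

#' Residue-wise percolation profile
#'
#' For each backbone bond (N-CA and CA-C of every residue) the percolation
#' index is the temperature of the first ladder state at which the bond's
#' two atoms no longer belong jointly to the current largest rigid cluster;
#' bonds that never segregate receive the top ladder temperature. The
#' residue value `p_i` is the lower of its two backbone-bond values. The
#' profile encodes the hierarchical breakdown of the giant cluster, i.e.
#' the unfolding pathway.
#'
#' @param traj a `cna_trajectory` whose network carries a structure.
#' @return data frame of class `cna_profile` with `residue_index`, `p_i`
#'   (K); residues with missing backbone atoms are flagged (`excluded`) and
#'   carry `NA`.
#' @export
percolation_profile <- function(traj) {
  stopifnot(inherits(traj, "cna_trajectory"))
  s <- traj$network$structure
  if (is.null(s)) stop("trajectory network carries no structure")
  giant <- .giant_membership(traj)       # bodies x states
  temps <- traj$ladder$temperature
  t_max <- max(temps)

  bond_p <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    inside <- giant[a, ] & giant[b, ]
    first_out <- which(!inside)[1]
    if (is.na(first_out)) t_max else temps[first_out]
  }
  res <- s$residues
  p_n_ca <- mapply(bond_p, res$N, res$CA)
  p_ca_c <- mapply(bond_p, res$CA, res$C)
  p_i <- pmin(p_n_ca, p_ca_c)
  excluded <- is.na(p_i)
  if (any(excluded))
    warning(sum(excluded), " residue(s) with missing backbone atoms excluded")
  structure(data.frame(residue_index = res$index, p_i = p_i,
                       excluded = excluded),
            class = c("cna_profile", "data.frame"))
}

#' Rigid-contact stability map
#'
#' Two residues have a rigid contact at a state iff at least one atom of
#' each shares a rigid cluster. `rc_ij` is the E_cut of the last state at
#' which the contact exists (so contacts surviving the whole ladder carry
#' the ladder floor, and pairs never in contact carry the ladder start as
#' sentinel). The neighbor mask marks residue pairs with any-atom distance
#' within `neighbor_cutoff`.
#'
#' @param traj a `cna_trajectory` whose network carries a structure.
#' @param neighbor_cutoff A; default 5.
#' @return object of class `cna_stability_map`: list with `rc` (residue x
#'   residue matrix, kcal/mol, diagonal `NA`), `neighbor_mask` (logical
#'   matrix), and the ladder.
#' @export
stability_map <- function(traj, neighbor_cutoff = 5) {
  stopifnot(inherits(traj, "cna_trajectory"))
  s <- traj$network$structure
  if (is.null(s)) stop("trajectory network carries no structure")
  n_res <- s$sequence_length
  res_of <- s$atoms$residue_index
  rc <- matrix(traj$ladder$e_cut[1], n_res, n_res)

  for (i in seq_len(nrow(traj$ladder))) {
    d <- traj$decompositions[[i]]
    e <- traj$ladder$e_cut[i]
    for (cl in d$clusters) {
      if (length(cl) < 2) next
      rr <- unique(res_of[cl])
      if (length(rr) < 2) next
      rc[rr, rr] <- e
    }
  }
  diag(rc) <- NA_real_
  structure(list(rc = rc, neighbor_mask = .neighbor_mask(s, neighbor_cutoff),
                 ladder = traj$ladder),
            class = "cna_stability_map")
}

# residue pairs with any-atom distance within cutoff (logical matrix)
.neighbor_mask <- function(s, neighbor_cutoff) {
  n_res <- s$sequence_length
  res_of <- s$atoms$residue_index
  mask <- matrix(FALSE, n_res, n_res)
  dmat <- as.matrix(stats::dist(.coords(s)))
  for (i in seq_len(n_res)) {
    ai <- which(res_of == i)
    for (j in seq_len(n_res)) {
      if (j <= i) next
      aj <- which(res_of == j)
      if (min(dmat[ai, aj]) <= neighbor_cutoff) {
        mask[i, j] <- TRUE; mask[j, i] <- TRUE
      }
    }
  }
  mask
}

#' Median stability of rigid contacts between residue neighbors
#'
#' The median of `rc_ij` over unordered residue pairs flagged as neighbors
#' (any-atom distance within the map's cutoff). A robust local measure of
#' thermodynamic thermostability: unlike the summed unfolding energy it is
#' insensitive to extreme values in strongly tether-stabilized regions, and
#' unlike the phase-transition temperature it does not require identifying
#' a single global jump.
#'
#' @param m a [stability_map()] result.
#' @param include_adjacent include sequence-adjacent pairs (i, i+1)
#'   (default `TRUE`).
#' @return list with `rc_median` (kcal/mol), `rc_median_K` (temperature
#'   scale) and `n_pairs`.
#' @export
neighbor_median_stability <- function(m, include_adjacent = TRUE) {
  stopifnot(inherits(m, "cna_stability_map"))
  n <- nrow(m$rc)
  sel <- m$neighbor_mask & upper.tri(m$rc)
  if (!include_adjacent && n > 1) {
    adj <- abs(row(m$rc) - col(m$rc)) == 1
    sel <- sel & !adj
  }
  vals <- m$rc[sel]
  if (length(vals) == 0) stop("no neighboring residue pairs in the map")
  med <- median(vals)
  list(rc_median = med, rc_median_K = ecut_to_temperature(med),
       n_pairs = length(vals))
}

#' Difference stability map between two variants
#'
#' Element-wise difference of two stability maps on the temperature scale
#' (`a - b`, in K; positive entries mark contacts more stable in `a`). The
#' reporting filter marks pairs stabilized by at least `stabilized_min` K or
#' destabilized by at least `destabilized_min` K; pairs within one secondary
#' structure element can be excluded when an annotation (integer element id
#' per residue, `NA` for loops) is supplied.
#'
#' @param a,b `cna_stability_map`s over the same residue count.
#' @param stabilized_min,destabilized_min display filter thresholds (K).
#' @param ss optional secondary-structure annotation.
#' @return list with `delta` (K matrix), `show` (logical filter matrix).
#' @export
diff_stability_map <- function(a, b, stabilized_min = 4, destabilized_min = 3,
                               ss = NULL) {
  stopifnot(inherits(a, "cna_stability_map"), inherits(b, "cna_stability_map"))
  if (!all(dim(a$rc) == dim(b$rc)))
    stop("stability maps have different residue counts")
  delta <- ecut_to_temperature(a$rc) - ecut_to_temperature(b$rc)
  show <- !is.na(delta) & (delta >= stabilized_min | delta <= -destabilized_min)
  if (!is.null(ss)) {
    if (length(ss) != nrow(delta)) stop("annotation length mismatch")
    same_ss <- outer(ss, ss, function(x, y) !is.na(x) & !is.na(y) & x == y)
    show <- show & !same_ss
  }
  list(delta = delta, show = show)
}
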