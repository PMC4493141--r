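# Body-and-bar constraint network construction: covalent bars, energy-
# annotated hydrogen bonds and salt bridges, and hydrophobic tethers.

#' Constraint-network parameters
#'
#' Collects the rule thresholds of the body-and-bar representation. Defaults
#' follow the FIRST conventions the constraint-network literature builds on:
#' atoms are 6-DOF bodies; a rotatable single covalent bond contributes 5
#' bars, a locked (peptide, conjugated sp2-sp2, ring, or terminal) bond 6
#' bars; a hydrogen bond or salt bridge 5 bars between donor and acceptor
#' heavy atoms; a hydrophobic tether 2 bars.
#'
#' @param hbond_energy_cutoff kcal/mol; hydrogen bonds weaker than this are
#'   not part of the base network (default -0.1).
#' @param tether_pad A added to the van der Waals radii sum for the tether
#'   distance cutoff (default 0.25).
#' @param tether_band A half-width around the tether cutoff within which
#'   candidate contacts are recorded for fuzzy ensembles (default 0.25).
#' @param tether_bars,hbond_bars,covalent_bars_single,covalent_bars_locked
#'   bar multiplicities.
#' @param saltbridge_energy kcal/mol assigned to salt bridges; at -10 they
#'   never break on the default dilution ladder (floor -6).
#' @param hbond_distance_max A, maximal donor-acceptor distance.
#' @param hbond_angle_min degrees, minimal donor-hydrogen-acceptor angle.
#' @param covalent_pad A added to the covalent radii sum when detecting
#'   covalent bonds (default 0.4).
#' @param min_bond_separation hydrogen-bond partners fewer than this many
#'   covalent bonds apart are excluded; tether partners must be more than
#'   this many bonds apart, so that 1-4 neighbors along the backbone never
#'   become tethers.
#' @return list of class `cna_params`.
#' @export
network_params <- function(hbond_energy_cutoff = -0.1,
                           tether_pad = 0.25,
                           tether_band = 0.25,
                           tether_bars = 2L,
                           hbond_bars = 5L,
                           covalent_bars_single = 5L,
                           covalent_bars_locked = 6L,
                           saltbridge_energy = -10,
                           hbond_distance_max = 3.6,
                           hbond_angle_min = 100,
                           covalent_pad = 0.4,
                           min_bond_separation = 3L) {
  stopifnot(hbond_energy_cutoff < 0, saltbridge_energy < 0,
            tether_pad >= 0, tether_band >= 0,
            hbond_distance_max > 0, hbond_angle_min > 0, covalent_pad > 0)
  structure(list(hbond_energy_cutoff = hbond_energy_cutoff,
                 tether_pad = tether_pad, tether_band = tether_band,
                 tether_bars = as.integer(tether_bars),
                 hbond_bars = as.integer(hbond_bars),
                 covalent_bars_single = as.integer(covalent_bars_single),
                 covalent_bars_locked = as.integer(covalent_bars_locked),
                 saltbridge_energy = saltbridge_energy,
                 hbond_distance_max = hbond_distance_max,
                 hbond_angle_min = hbond_angle_min,
                 covalent_pad = covalent_pad,
                 min_bond_separation = as.integer(min_bond_separation)),
            class = "cna_params")
}

.new_network <- function(structure_ref, n_bodies, constraints, coords,
                         params, tether_candidates) {
  constraints <- .normalize_constraints(constraints)
  structure(list(structure = structure_ref, n_bodies = as.integer(n_bodies),
                 constraints = constraints, coords = coords, params = params,
                 tether_candidates = tether_candidates),
            class = "cna_network")
}

# order endpoints, sort rows, and reject duplicate (pair, kind) entries
.normalize_constraints <- function(con) {
  if (nrow(con) == 0) return(con)
  swap <- con$body_a > con$body_b
  tmp <- con$body_a[swap]
  con$body_a[swap] <- con$body_b[swap]
  con$body_b[swap] <- tmp
  con <- con[order(con$body_a, con$body_b, con$kind), , drop = FALSE]
  key <- paste(con$body_a, con$body_b, con$kind)
  if (anyDuplicated(key)) stop("duplicate (pair, kind) constraint entries")
  rownames(con) <- NULL
  con
}

#' @export
print.cna_network <- function(x, ...) {
  counts <- table(factor(x$constraints$kind,
                         levels = c("covalent", "hbond", "saltbridge", "tether")))
  cat("cna_network:", x$n_bodies, "bodies;",
      paste(names(counts), as.integer(counts), collapse = ", "), "\n")
  invisible(x)
}

# covalent adjacency list from a covalent constraint table
.bond_adjacency <- function(n_atoms, covalent) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(covalent))) {
    a <- covalent$body_a[k]; b <- covalent$body_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# matrix of atom pairs within `depth` covalent bonds (bond path <= depth)
.pairs_within_bonds <- function(adj, depth) {
  n <- length(adj)
  res <- new.env(hash = TRUE, size = n * 4L)
  for (start in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    frontier <- start
    for (d in seq_len(depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- d
      frontier <- nxt
    }
    close_ids <- which(!is.na(dist) & seq_len(n) > start)
    for (j in close_ids) assign(paste(start, j), TRUE, envir = res)
  }
  res
}

.pair_close <- function(env, a, b) {
  key <- if (a < b) paste(a, b) else paste(b, a)
  !is.null(env[[key]])
}

#' Detect covalent bonds
#'
#' Bonds are detected by interatomic distance: two atoms of the same or
#' adjacent residues are bonded when their distance does not exceed the sum
#' of their covalent radii plus `covalent_pad`. A bond is locked (6 bars)
#' when both atoms belong to conjugated sp2 groups (peptide bond,
#' carboxylate, amide, guanidinium, aromatic rings) or when either atom has
#' a single covalent neighbor (terminal bonds, e.g. N-H, C=O); all other
#' bonds are rotatable single bonds (5 bars).
#'
#' @param s a `cna_structure`.
#' @param params a [network_params()] object.
#' @return constraint data frame (`body_a`, `body_b`, `kind`, `bars`,
#'   `energy`).
#' @export
detect_covalent_bonds <- function(s, params = network_params()) {
  stopifnot(inherits(s, "cna_structure"))
  xyz <- .coords(s)
  res_idx <- s$atoms$residue_index
  covr <- .cov_radius(s$atoms$element)

  pairs_a <- integer(0); pairs_b <- integer(0)
  for (r in seq_len(s$sequence_length)) {
    ids <- which(res_idx %in% c(r, r + 1L))
    own <- which(res_idx[ids] == r)
    if (length(ids) < 2 || length(own) == 0) next
    d <- as.matrix(stats::dist(xyz[ids, , drop = FALSE]))
    cut <- outer(covr[ids], covr[ids], "+") + params$covalent_pad
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    a <- ids[hit[, 1]]; b <- ids[hit[, 2]]
    # pairs internal to residue r+1 are collected when processing r+1
    keep <- res_idx[a] == r | res_idx[b] == r
    pairs_a <- c(pairs_a, a[keep]); pairs_b <- c(pairs_b, b[keep])
  }
  dup <- duplicated(paste(pmin(pairs_a, pairs_b), pmax(pairs_a, pairs_b)))
  pairs_a <- pairs_a[!dup]; pairs_b <- pairs_b[!dup]

  degree <- tabulate(c(pairs_a, pairs_b), nbins = nrow(s$atoms))
  if (any(degree == 0))
    warning(sum(degree == 0), " atom(s) with no covalent partner (isolated bodies)")
  if (length(pairs_a) == 0)
    return(data.frame(body_a = integer(0), body_b = integer(0),
                      kind = character(0), bars = integer(0),
                      energy = numeric(0), stringsAsFactors = FALSE))

  sp2 <- .is_sp2_atom(s$atoms$residue_name, s$atoms$name)
  locked <- (sp2[pairs_a] & sp2[pairs_b]) |
    degree[pairs_a] == 1L | degree[pairs_b] == 1L
  data.frame(body_a = pairs_a, body_b = pairs_b, kind = "covalent",
             bars = ifelse(locked, params$covalent_bars_locked,
                           params$covalent_bars_single),
             energy = NA_real_, stringsAsFactors = FALSE)
}

#' Hydrogen-bond energy (Mayo-type 12-10 potential)
#'
#' \deqn{E_{HB} = V_0 \{5 (d_0/d)^{12} - 6 (d_0/d)^{10}\} F(\theta, \phi)}
#' with well depth `V0` = 8 kcal/mol, equilibrium donor-acceptor distance
#' `d0` = 2.8 A, `d` the donor-acceptor distance, and `F` in `[0, 1]` the
#' hybridization-dependent angular factor of [mayo_angular_factor()]
#' (`F = 1` at ideal geometry, so the minimum energy is -8 kcal/mol at
#' 2.8 A). Geometry outside the prescreen (donor-acceptor distance above
#' `hbond_distance_max` or donor-hydrogen-acceptor angle below
#' `hbond_angle_min`) yields `NA` (no bond).
#'
#' @param donor,hydrogen,acceptor,acceptor_base coordinate 3-vectors;
#'   `acceptor_base` may be `NULL` if the acceptor has no heavy neighbor.
#' @param donor_sp,acceptor_sp hybridization, `"sp2"` or `"sp3"`.
#' @param params a [network_params()] object.
#' @return energy in kcal/mol, or `NA_real_` when the prescreen fails.
#' @examples
#' # ideal geometry: linear D-H...A at 2.8 A
#' compute_hbond_energy(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), NULL)
#' @export
compute_hbond_energy <- function(donor, hydrogen, acceptor,
                                 acceptor_base = NULL,
                                 donor_sp = "sp3", acceptor_sp = "sp3",
                                 params = network_params()) {
  d <- sqrt(sum((acceptor - donor)^2))
  if (d > params$hbond_distance_max || d < 1e-6) return(NA_real_)
  theta <- .angle_deg(donor, hydrogen, acceptor)
  if (theta < params$hbond_angle_min) return(NA_real_)
  phi <- if (is.null(acceptor_base)) NA_real_
         else .angle_deg(hydrogen, acceptor, acceptor_base)
  f <- mayo_angular_factor(theta, phi, donor_sp, acceptor_sp)
  radial <- 8 * (5 * (2.8 / d)^12 - 6 * (2.8 / d)^10)
  radial * f
}

#' Angular factor of the Mayo-type hydrogen-bond potential
#'
#' Dimensionless factor in `[0, 1]`, equal to 1 at ideal geometry. The
#' donor-hydrogen-acceptor angle `theta` (ideal 180 deg) contributes
#' `cos^2(theta) * exp(-(pi - theta)^6)`; the hydrogen-acceptor-base angle
#' `phi` contributes `cos^2(phi - phi0)` with `phi0` = 109.5 deg for sp3
#' acceptors and 120 deg for sp2 acceptors (omitted when no acceptor base
#' is available). The functional form is kept behind this single function
#' so alternative angular terms can be swapped in.
#'
#' @param theta donor-hydrogen-acceptor angle, degrees.
#' @param phi hydrogen-acceptor-base angle, degrees (`NA` to omit).
#' @param donor_sp,acceptor_sp hybridization, `"sp2"` or `"sp3"`.
#' @return numeric factor in `[0, 1]`.
#' @export
mayo_angular_factor <- function(theta, phi = NA_real_,
                                donor_sp = "sp3", acceptor_sp = "sp3") {
  th <- theta * pi / 180
  f <- cos(th)^2 * exp(-(pi - th)^6)
  if (!is.na(phi)) {
    phi0 <- if (identical(acceptor_sp, "sp2")) 120 else 109.5
    f <- f * cos((phi - phi0) * pi / 180)^2
  }
  max(0, min(1, f))
}

#' Detect hydrogen bonds and salt bridges
#'
#' All donor (N, O, S carrying a hydrogen) to acceptor (N, O, S) pairs that
#' pass the geometric prescreen and whose Mayo-type energy is at most
#' `hbond_energy_cutoff` become 5-bar constraints carrying their energy.
#' Pairs of charged groups (Asp/Glu carboxylate oxygens versus Lys/Arg and
#' doubly protonated His nitrogens) are classified as salt bridges and
#' assigned the fixed `saltbridge_energy` so they persist over the whole
#' dilution ladder. Donor-acceptor pairs separated by fewer than
#' `min_bond_separation` covalent bonds are excluded.
#'
#' @inheritParams detect_covalent_bonds
#' @param covalent optional precomputed covalent constraint table.
#' @return constraint data frame.
#' @export
detect_hydrogen_bonds <- function(s, params = network_params(),
                                  covalent = NULL) {
  stopifnot(inherits(s, "cna_structure"))
  if (is.null(covalent)) covalent <- detect_covalent_bonds(s, params)
  xyz <- .coords(s)
  adj <- .bond_adjacency(nrow(s$atoms), covalent)
  near <- .pairs_within_bonds(adj, params$min_bond_separation - 1L)

  elem <- s$atoms$element
  heavy_don_accept <- elem %in% c("N", "O", "S")
  hydrogens <- which(elem == "H")
  acceptors <- which(heavy_don_accept)
  if (length(hydrogens) == 0 || length(acceptors) == 0)
    return(covalent[0, ])

  sp2 <- .is_sp2_atom(s$atoms$residue_name, s$atoms$name)
  is_salt_donor <- .match_atom_table(s, .SALT_DONOR_ATOMS)
  is_salt_acceptor <- .match_atom_table(s, .SALT_ACCEPTOR_ATOMS, include_oxt = TRUE)

  rows <- list()
  for (h in hydrogens) {
    donors <- adj[[h]]
    donors <- donors[heavy_don_accept[donors]]
    if (length(donors) == 0) next
    d_at <- donors[1]
    # candidate acceptors within the distance prescreen of the donor
    dd <- sqrt(colSums((t(xyz[acceptors, , drop = FALSE]) - xyz[d_at, ])^2))
    cand <- acceptors[dd <= params$hbond_distance_max & dd > 1e-6]
    for (a_at in cand) {
      if (a_at == d_at || a_at %in% adj[[h]]) next
      if (.pair_close(near, d_at, a_at)) next
      base_ids <- adj[[a_at]]
      base_ids <- base_ids[elem[base_ids] != "H"]
      base <- if (length(base_ids) > 0) xyz[base_ids[1], ] else NULL
      e <- compute_hbond_energy(xyz[d_at, ], xyz[h, ], xyz[a_at, ], base,
                                donor_sp = if (sp2[d_at]) "sp2" else "sp3",
                                acceptor_sp = if (sp2[a_at]) "sp2" else "sp3",
                                params = params)
      if (is.na(e)) next
      salt <- is_salt_donor[d_at] && is_salt_acceptor[a_at]
      if (salt) {
        rows[[length(rows) + 1]] <- data.frame(
          body_a = d_at, body_b = a_at, kind = "saltbridge",
          bars = params$hbond_bars, energy = params$saltbridge_energy,
          stringsAsFactors = FALSE)
      } else if (e <= params$hbond_energy_cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          body_a = d_at, body_b = a_at, kind = "hbond",
          bars = params$hbond_bars, energy = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(covalent[0, ])
  out <- do.call(rbind, rows)
  # several hydrogens of one donor may reach the same acceptor: keep the
  # strongest realization of each (pair, kind)
  key <- paste(pmin(out$body_a, out$body_b), pmax(out$body_a, out$body_b), out$kind)
  o <- order(key, out$energy)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(key[o]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.match_atom_table <- function(s, table, include_oxt = FALSE) {
  res <- rep(FALSE, nrow(s$atoms))
  for (rn in names(table)) {
    res <- res | (s$atoms$residue_name == rn & s$atoms$name %in% table[[rn]])
  }
  # C-terminal carboxylate oxygen is a charged acceptor
  if (include_oxt) res <- res | s$atoms$name == "OXT"
  res
}

#' Detect hydrophobic tethers
#'
#' Every pair of carbon or sulfur atoms from different residues, more than
#' `min_bond_separation` covalent bonds apart, whose distance does not
#' exceed the sum of their van der Waals radii plus `tether_pad` receives a
#' single 2-bar tether. Candidate contacts up to `tether_band` beyond the
#' cutoff are additionally recorded (inactive) for fuzzy-ensemble use.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return constraint data frame with attribute `candidates`: a data frame
#'   of candidate contacts (`body_a`, `body_b`, `dist`, `cutoff`).
#' @export
detect_hydrophobic_tethers <- function(s, params = network_params(),
                                       covalent = NULL) {
  stopifnot(inherits(s, "cna_structure"))
  if (is.null(covalent)) covalent <- detect_covalent_bonds(s, params)
  xyz <- .coords(s)
  adj <- .bond_adjacency(nrow(s$atoms), covalent)
  near <- .pairs_within_bonds(adj, params$min_bond_separation)

  phobic <- which(s$atoms$element %in% c("C", "S"))
  empty <- data.frame(body_a = integer(0), body_b = integer(0),
                      kind = character(0), bars = integer(0),
                      energy = numeric(0), stringsAsFactors = FALSE)
  cand_empty <- data.frame(body_a = integer(0), body_b = integer(0),
                           dist = numeric(0), cutoff = numeric(0))
  if (length(phobic) < 2) { attr(empty, "candidates") <- cand_empty; return(empty) }

  d <- as.matrix(stats::dist(xyz[phobic, , drop = FALSE]))
  vdw <- s$atoms$vdw_radius[phobic]
  cutoff <- outer(vdw, vdw, "+") + params$tether_pad
  res_idx <- s$atoms$residue_index[phobic]
  ok <- upper.tri(d) & d <= cutoff + params$tether_band &
    outer(res_idx, res_idx, "!=")
  hit <- which(ok, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    a <- phobic[hit[, 1]]; b <- phobic[hit[, 2]]
    far <- !mapply(.pair_close, a, b, MoreArgs = list(env = near))
    hit <- hit[far, , drop = FALSE]
  }
  if (nrow(hit) == 0) { attr(empty, "candidates") <- cand_empty; return(empty) }

  cand <- data.frame(body_a = phobic[hit[, 1]], body_b = phobic[hit[, 2]],
                     dist = d[hit], cutoff = cutoff[hit])
  act <- cand[cand$dist <= cand$cutoff, , drop = FALSE]
  out <- data.frame(body_a = act$body_a, body_b = act$body_b,
                    kind = rep("tether", nrow(act)),
                    bars = rep(params$tether_bars, nrow(act)),
                    energy = rep(NA_real_, nrow(act)),
                    stringsAsFactors = FALSE)
  attr(out, "candidates") <- cand
  out
}

#' Build the full constraint network of a structure
#'
#' Union of covalent bonds, hydrogen bonds and salt bridges (at or below the
#' energy cutoff), and hydrophobic tethers. Deterministic for a fixed input
#' and parameter set.
#'
#' @inheritParams detect_covalent_bonds
#' @return A `cna_network` (structure reference, bodies, constraint table,
#'   tether candidate table, parameters).
#' @examples
#' h <- make_ideal_helix(7)
#' net <- build_network(h)
#' net
#' @export
build_network <- function(s, params = network_params()) {
  stopifnot(inherits(s, "cna_structure"))
  covalent <- detect_covalent_bonds(s, params)
  hbonds <- detect_hydrogen_bonds(s, params, covalent = covalent)
  tethers <- detect_hydrophobic_tethers(s, params, covalent = covalent)
  candidates <- attr(tethers, "candidates")
  attr(tethers, "candidates") <- NULL
  con <- rbind(covalent, hbonds, tethers)
  .new_network(structure_ref = s, n_bodies = nrow(s$atoms),
               constraints = con, coords = .coords(s), params = params,
               tether_candidates = candidates)
}

#' Per-residue counts of noncovalent interactions
#'
#' Number of hydrogen-bond/salt-bridge constraints and hydrophobic tethers
#' with at least one endpoint in each residue. Differencing the counts of
#' two variants localizes where mutations change the interaction network.
#'
#' @param net a `cna_network` built from a structure.
#' @return data frame with `residue_index`, `n_hbonds`, `n_tethers`.
#' @export
count_interactions_per_residue <- function(net) {
  stopifnot(inherits(net, "cna_network"))
  if (is.null(net$structure)) stop("network carries no structure reference")
  res_of <- net$structure$atoms$residue_index
  n_res <- net$structure$sequence_length
  con <- net$constraints
  count_kind <- function(kinds) {
    sel <- con$kind %in% kinds
    ra <- res_of[con$body_a[sel]]; rb <- res_of[con$body_b[sel]]
    # an interaction inside one residue counts once for it
    same <- ra == rb
    tabulate(c(ra, rb[!same]), nbins = n_res)
  }
  data.frame(residue_index = seq_len(n_res),
             n_hbonds = count_kind(c("hbond", "saltbridge")),
             n_tethers = count_kind("tether"))
}
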