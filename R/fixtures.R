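# Synthetic structures, toy networks, and the packaged lipase A variant
# table. Everything downstream is testable from these without downloads.

# ideal bond lengths (A) and angles (deg) for backbone construction
.HELIX_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.010, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

#' Build an ideal poly-alanine helix
#'
#' Constructs an idealized alpha-helical backbone (standard bond lengths and
#' angles, phi = -57 deg, psi = -47 deg by default) with amide hydrogens
#' positioned in the peptide plane so that the characteristic i -> i-4
#' backbone hydrogen bonds are formed. Poly-alanine (C-beta, no further side
#' chain) keeps hydrophobic tethers out of the picture, so helix rigidity is
#' attributable to covalent constraints and backbone hydrogen bonds alone.
#' The first residue carries no amide hydrogen (it has no acceptor to reach).
#'
#' @param n_residues number of residues (>= 1).
#' @param phi,psi backbone dihedrals in degrees.
#' @return A `cna_structure`.
#' @examples
#' h <- make_ideal_helix(7)
#' h$sequence_length
#' @export
make_ideal_helix <- function(n_residues, phi = -57, psi = -47) {
  stopifnot(n_residues >= 1)
  g <- .HELIX_GEOM
  N <- vector("list", n_residues); CA <- N; C <- N; O <- N; H <- N; CB <- N

  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  # first C placed in the xy-plane
  ang <- g$a_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$b_ca_c * c(-cos(ang), sin(ang), 0)

  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                            g$b_c_n, g$a_ca_c_n, psi)
      CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                             g$b_n_ca, g$a_c_n_ca, g$omega)
      C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]],
                            g$b_ca_c, g$a_n_ca_c, phi)
      # trans-amide hydrogen: in-plane, opposite the C'/CA bisector
      H[[i]] <- N[[i]] + g$b_n_h *
        .unit(.unit(N[[i]] - C[[i - 1]]) + .unit(N[[i]] - CA[[i]]))
    }
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o,
                          psi + 180)
    # C-beta on the tetrahedral corner of CA opposite the N/C bisector
    u_n <- .unit(N[[i]] - CA[[i]]); u_c <- .unit(C[[i]] - CA[[i]])
    CB[[i]] <- CA[[i]] + g$b_ca_cb *
      .unit(-(u_n + u_c) + .cross3(u_c, u_n))
  }

  rows <- list(); serial <- 0
  add <- function(rows, name, element, res, xyz) {
    serial <<- serial + 1
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = name, element = element, residue_name = "ALA",
      chain_id = "A", author_resno = res,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    rows
  }
  for (i in seq_len(n_residues)) {
    rows <- add(rows, "N", "N", i, N[[i]])
    if (i > 1) rows <- add(rows, "H", "H", i, H[[i]])
    rows <- add(rows, "CA", "C", i, CA[[i]])
    rows <- add(rows, "CB", "C", i, CB[[i]])
    rows <- add(rows, "C", "C", i, C[[i]])
    rows <- add(rows, "O", "O", i, O[[i]])
  }
  make_structure(do.call(rbind, rows))
}

#' Build a constraint network verbatim from body and bar lists
#'
#' Bypasses all geometric detection; used for oracle testing and staged
#' unfolding scenarios. If `coords` is omitted, generic body positions are
#' drawn from `seed` so the rigidity-matrix oracle can be applied.
#'
#' @param n_bodies number of bodies.
#' @param constraints data frame with columns `body_a`, `body_b`, `kind`
#'   (covalent, hbond, saltbridge or tether), `bars`, and optionally
#'   `energy` (kcal/mol, required for hbond/saltbridge).
#' @param coords optional `n_bodies` x 3 matrix of body positions.
#' @param seed seed for generic positions when `coords` is missing.
#' @param structure optional `cna_structure` whose atoms are the bodies
#'   (enables residue-level indices on toy networks).
#' @return A `cna_network`.
#' @export
make_toy_network <- function(n_bodies, constraints, coords = NULL, seed = 1,
                             structure = NULL) {
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "cna_structure"))
    if (missing(n_bodies)) n_bodies <- nrow(structure$atoms)
    if (n_bodies != nrow(structure$atoms))
      stop("n_bodies must equal the structure's atom count")
    if (is.null(coords)) coords <- .coords(structure)
  }
  stopifnot(n_bodies >= 1, is.data.frame(constraints))
  if (!"energy" %in% names(constraints)) constraints$energy <- NA_real_
  needed <- c("body_a", "body_b", "kind", "bars", "energy")
  missing_cols <- setdiff(needed, names(constraints))
  if (length(missing_cols) > 0)
    stop("constraint table lacks column(s): ", paste(missing_cols, collapse = ", "))
  constraints <- constraints[, needed]
  if (nrow(constraints) > 0) {
    if (any(constraints$body_a < 1 | constraints$body_a > n_bodies |
            constraints$body_b < 1 | constraints$body_b > n_bodies))
      stop("constraint endpoint outside 1..n_bodies")
    if (any(constraints$body_a == constraints$body_b))
      stop("self-loop constraint")
    if (!all(constraints$kind %in% c("covalent", "hbond", "saltbridge", "tether")))
      stop("unknown constraint kind")
    noncov <- constraints$kind %in% c("hbond", "saltbridge")
    if (any(noncov & !is.finite(constraints$energy)))
      stop("hbond/saltbridge constraints require a finite energy")
    if (any(noncov & constraints$energy >= 0))
      stop("hbond/saltbridge energies must be negative")
  }
  if (is.null(coords)) {
    set.seed(seed)
    coords <- matrix(runif(3 * n_bodies, 0, 10), ncol = 3)
  }
  .new_network(structure_ref = structure, n_bodies = n_bodies,
               constraints = constraints, coords = coords,
               params = network_params(), tether_candidates = NULL)
}

#' The lipase A variant table
#'
#' The 17 Bacillus subtilis lipase A variants (wild type plus 16 mutants)
#' with their structure sources, mutation lists, experimental melting
#' (`t_m`), unfolding-initiation (`t_i`) and activity-retention (`t_50`)
#' temperatures, and the published ensemble-averaged median rigid-contact
#' stabilities (`rc_median` in kcal/mol, `rc_median_K` on the temperature
#' scale). The wild-type row additionally carries the six-crystal-structure
#' average (`rc_median_avg`, `rc_median_avg_K`). Mutation lists use the
#' incremental notation `BASE + mut1, mut2`; see [expand_mutations()].
#'
#' @return data frame with one row per variant.
#' @examples
#' tab <- table1_fixture()
#' nrow(tab)
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "bslipa_variants.tsv", package = "cnar")
  if (!nzchar(path)) stop("packaged variant table not found")
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$is_xray <- !is.na(tab$resolution)
  tab$is_modeled <- !tab$is_xray
  tab
}
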