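# Shared toy constructions for the test suite.

# constraint rows in one line
con_row <- function(a, b, kind = "covalent", bars = 5L, energy = NA_real_) {
  data.frame(body_a = a, body_b = b, kind = kind, bars = as.integer(bars),
             energy = energy, stringsAsFactors = FALSE)
}

empty_con <- function() con_row(1, 2)[0, ]

# random small multigraph network for oracle sweeps (deterministic per seed)
random_toy_network <- function(seed, max_bodies = 10, max_edges = 14) {
  set.seed(seed)
  n <- sample(2:max_bodies, 1)
  m <- sample(1:max_edges, 1)
  e <- data.frame(body_a = sample(n, m, replace = TRUE),
                  body_b = sample(n, m, replace = TRUE),
                  kind = "covalent",
                  bars = sample(1:6, m, replace = TRUE),
                  energy = NA_real_, stringsAsFactors = FALSE)
  e <- e[e$body_a != e$body_b, , drop = FALSE]
  key <- paste(pmin(e$body_a, e$body_b), pmax(e$body_a, e$body_b))
  e <- e[!duplicated(key), , drop = FALSE]
  if (nrow(e) == 0) e <- con_row(1, 2, bars = 1L)
  make_toy_network(n, e, seed = seed + 500)
}

# minimal synthetic three-residue protein: residues 1-2 are one rigid block
# (all-6-bar covalent bonds), residue 3 is a rigid body attached only by two
# hydrogen bonds with chosen energies. Backbone atom names are real so
# residue-level indices work.
make_staged_protein <- function(e_hb1 = -2.0, e_hb2 = -3.0) {
  atom <- function(serial, name, element, res, x, y, z)
    data.frame(serial = serial, name = name, element = element,
               residue_name = "GLY", chain_id = "A", author_resno = res,
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms <- rbind(
    atom(1, "N", "N", 1, 0.0, 0.0, 0.0),
    atom(2, "CA", "C", 1, 1.5, 0.0, 0.0),
    atom(3, "C", "C", 1, 2.2, 1.3, 0.0),
    atom(4, "O", "O", 1, 3.4, 1.4, 0.0),
    atom(5, "N", "N", 2, 1.6, 2.5, 0.0),
    atom(6, "CA", "C", 2, 2.2, 3.8, 0.1),
    atom(7, "C", "C", 2, 1.3, 5.0, 0.0),
    atom(8, "O", "O", 2, 0.1, 4.9, 0.1),
    atom(9, "N", "N", 3, 1.9, 6.2, 3.0),
    atom(10, "CA", "C", 3, 1.1, 7.4, 3.1),
    atom(11, "C", "C", 3, 1.9, 8.7, 3.0),
    atom(12, "O", "O", 3, 3.1, 8.7, 3.1))
  s <- make_structure(atoms)
  rigid_block <- rbind(
    con_row(1, 2, bars = 6L), con_row(2, 3, bars = 6L), con_row(3, 4, bars = 6L),
    con_row(4, 5, bars = 6L), con_row(5, 6, bars = 6L), con_row(6, 7, bars = 6L),
    con_row(7, 8, bars = 6L),
    con_row(9, 10, bars = 6L), con_row(10, 11, bars = 6L), con_row(11, 12, bars = 6L))
  hbonds <- rbind(con_row(9, 4, kind = "hbond", bars = 5L, energy = e_hb1),
                  con_row(9, 8, kind = "hbond", bars = 5L, energy = e_hb2))
  net <- make_toy_network(constraints = rbind(rigid_block, hbonds),
                          structure = s)
  list(structure = s, network = net)
}

# write a PDB fixture text file with optional water/ligand records
write_fixture_pdb <- function(path, include_water = FALSE,
                              include_ligand = FALSE) {
  fmt <- function(type, serial, name, res, chain, resno, x, y, z, elem)
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, res, chain, resno, x, y, z, 1, 0, elem)
  lines <- c(
    fmt("ATOM", 1, "N", "GLY", "A", 1, 0.000, 0.000, 0.000, "N"),
    fmt("ATOM", 2, "H", "GLY", "A", 1, -0.474, -0.840, 0.000, "H"),
    fmt("ATOM", 3, "CA", "GLY", "A", 1, 1.458, 0.000, 0.000, "C"),
    fmt("ATOM", 4, "HA2", "GLY", "A", 1, 1.822, -0.500, 0.880, "H"),
    fmt("ATOM", 5, "HA3", "GLY", "A", 1, 1.822, -0.500, -0.880, "H"),
    fmt("ATOM", 6, "C", "GLY", "A", 1, 1.999, 1.420, 0.000, "C"),
    fmt("ATOM", 7, "O", "GLY", "A", 1, 3.221, 1.536, 0.120, "O"))
  if (include_water)
    lines <- c(lines, fmt("ATOM", 8, "O", "HOH", "A", 2, 8, 8, 8, "O"),
               fmt("HETATM", 9, "O", "HOH", "A", 3, 9, 9, 9, "O"))
  if (include_ligand)
    lines <- c(lines, fmt("HETATM", 10, "C1", "LIG", "A", 4, 5, 5, 5, "C"))
  writeLines(c(lines, "END"), path)
  path
}
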