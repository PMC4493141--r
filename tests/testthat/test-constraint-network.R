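test_that("covalent bonds follow the distance and bar-multiplicity rules", {
  # two interior carbons 1.5 A apart, both with >= 2 neighbors -> 5 bars
  atoms <- data.frame(
    serial = 1:4, name = c("CX1", "CX2", "CX3", "CX4"), element = "C",
    residue_name = "UNK", chain_id = "A", author_resno = 1,
    x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0, stringsAsFactors = FALSE)
  cov <- detect_covalent_bonds(make_structure(atoms))
  # chain 1-2-3-4: middle bond joins two 2-neighbor carbons
  mid <- cov[cov$body_a == 2 & cov$body_b == 3, ]
  expect_equal(mid$bars, 5)
  # terminal bonds are locked
  expect_equal(cov$bars[cov$body_a == 1], 6)

  # two carbons 3.0 A apart: no bond
  atoms2 <- atoms[1:2, ]; atoms2$x <- c(0, 3.0)
  expect_warning(cov2 <- detect_covalent_bonds(make_structure(atoms2)),
                 "no covalent partner")
  expect_equal(nrow(cov2), 0)
})

test_that("the peptide bond is locked and rigidifies the peptide unit", {
  h <- make_ideal_helix(2)
  cov <- detect_covalent_bonds(h)
  a <- h$atoms
  c1 <- which(a$residue_index == 1 & a$name == "C")
  n2 <- which(a$residue_index == 2 & a$name == "N")
  pep <- cov[cov$body_a == min(c1, n2) & cov$body_b == max(c1, n2), ]
  expect_equal(nrow(pep), 1)
  expect_equal(pep$bars, 6)
  # the isolated dipeptide's peptide unit (C1, O1, N2, H2) is one rigid cluster
  d <- decompose(build_network(h))
  o1 <- which(a$residue_index == 1 & a$name == "O")
  h2 <- which(a$residue_index == 2 & a$name == "H")
  ids <- d$cluster_id[c(c1, o1, n2, h2)]
  expect_equal(length(unique(ids)), 1)
})

test_that("the Mayo-type energy evaluates to -8 kcal/mol at ideal geometry", {
  e <- compute_hbond_energy(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), NULL)
  expect_equal(e, -8.0)
  expect_equal(mayo_angular_factor(180, 109.5, "sp3", "sp3"), 1)
  expect_equal(mayo_angular_factor(180, 120, "sp3", "sp2"), 1)
  # F = 0 at right angle -> energy 0 (rejected by the cutoff downstream)
  expect_equal(mayo_angular_factor(90), 0, tolerance = 1e-10)
  # prescreen failure -> no-bond sentinel
  expect_true(is.na(compute_hbond_energy(c(0, 0, 0), c(1, 0, 0),
                                         c(5, 0, 0), NULL)))
  expect_true(is.na(compute_hbond_energy(c(0, 0, 0), c(0, 1, 0),
                                         c(0.5, -1, 2), NULL)))  # bent < 100 deg
})

test_that("weak hydrogen bonds are excluded by the energy cutoff", {
  # helix hbonds all pass; artificially tighten the cutoff below their energy
  h <- make_ideal_helix(7)
  strict <- network_params(hbond_energy_cutoff = -4.0)
  hb <- detect_hydrogen_bonds(h, strict)
  expect_equal(sum(hb$kind == "hbond"), 0)
  loose <- detect_hydrogen_bonds(h, network_params())
  expect_equal(sum(loose$kind == "hbond"), 3)
  expect_true(all(loose$energy[loose$kind == "hbond"] <= -0.1))
})

test_that("charged side-chain contacts become -10 kcal/mol salt bridges", {
  # Lys N-zeta donating to an Asp carboxylate oxygen at 2.8 A
  atoms <- data.frame(
    serial = 1:5,
    name = c("NZ", "HZ1", "CE", "OD1", "CG"),
    element = c("N", "H", "C", "O", "C"),
    residue_name = c("LYS", "LYS", "LYS", "ASP", "ASP"),
    chain_id = "A", author_resno = c(1, 1, 1, 2, 2),
    x = c(0, 0.94, -1.0, 2.8, 3.9),
    y = c(0, 0.34, -1.0, 1.0, 1.7),
    z = 0, stringsAsFactors = FALSE)
  s <- make_structure(atoms)
  hb <- detect_hydrogen_bonds(s)
  sb <- hb[hb$kind == "saltbridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(sb$energy, -10.0)
  expect_equal(sb$bars, 5)
})

test_that("hydrophobic tethers obey the vdW-distance rule and element filter", {
  mk <- function(d, elem2 = "C") {
    atoms <- data.frame(
      serial = 1:2, name = c("CX1", ifelse(elem2 == "C", "CX2", "NX2")),
      element = c("C", elem2), residue_name = "UNK", chain_id = "A",
      author_resno = c(1, 2), x = c(0, d), y = 0, z = 0,
      stringsAsFactors = FALSE)
    suppressWarnings(make_structure(atoms))
  }
  t1 <- suppressWarnings(detect_hydrophobic_tethers(mk(3.5)))
  expect_equal(nrow(t1), 1)          # 1.70 + 1.70 + 0.25 = 3.65 >= 3.5
  expect_equal(t1$bars, 2)
  t2 <- suppressWarnings(detect_hydrophobic_tethers(mk(3.7)))
  expect_equal(nrow(t2), 0)          # beyond the cutoff
  expect_equal(nrow(attr(t2, "candidates")), 1)  # but inside the fuzz band
  t3 <- suppressWarnings(detect_hydrophobic_tethers(mk(3.0, "N")))
  expect_equal(nrow(t3), 0)          # N is not hydrophobic
})

test_that("built networks conserve sub-counts and are deterministic", {
  s <- read_pdb(system.file("extdata", "gly.pdb", package = "cnar"))
  net <- build_network(s)
  p <- net$params
  n_cov <- nrow(detect_covalent_bonds(s, p))
  n_hb <- nrow(detect_hydrogen_bonds(s, p))
  n_tet <- nrow(suppressWarnings(detect_hydrophobic_tethers(s, p)))
  expect_equal(nrow(net$constraints), n_cov + n_hb + n_tet)

  h <- make_ideal_helix(7)
  expect_identical(build_network(h), build_network(h))
})

test_that("constraint detection is symmetric in atom order", {
  h <- make_ideal_helix(5)
  rev_atoms <- h$atoms[rev(seq_len(nrow(h$atoms))), ]
  rev_atoms$serial <- seq_len(nrow(rev_atoms))
  h_rev <- make_structure(rev_atoms)
  net <- build_network(h)
  net_rev <- build_network(h_rev)
  expect_equal(nrow(net$constraints), nrow(net_rev$constraints))
  expect_equal(table(net$constraints$kind), table(net_rev$constraints$kind))
  expect_equal(sort(net$constraints$energy), sort(net_rev$constraints$energy))
})

test_that("per-residue interaction counts localize hbonds and difference to zero", {
  net <- build_network(make_ideal_helix(9))
  counts <- count_interactions_per_residue(net)
  expect_equal(nrow(counts), 9)
  # interior residue both donates (i -> i-4) and accepts (i+4 -> i)
  expect_gte(counts$n_hbonds[5], 2)
  # termini cannot both donate and accept
  expect_equal(counts$n_hbonds[1], 1)
  # identical networks differenced -> all zeros
  diff <- counts$n_hbonds - count_interactions_per_residue(net)$n_hbonds
  expect_true(all(diff == 0))
})
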