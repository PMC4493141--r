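test_that("cluster configuration entropy matches hand-evaluated values", {
  expect_equal(cluster_configuration_entropy(10), 0)       # one cluster
  expect_equal(cluster_configuration_entropy(c(3, 3)), log(2))
  # sizes {2,1,1}: w = (4,1,1)/6
  expect_equal(cluster_configuration_entropy(c(2, 1, 1)),
               -(4 / 6 * log(4 / 6) + 2 * (1 / 6 * log(1 / 6))),
               tolerance = 1e-12)
  expect_error(cluster_configuration_entropy(integer(0)), "empty")
  # invariant under relabeling; bounded by ln(number of clusters)
  sizes <- c(5, 3, 2, 1, 1)
  expect_equal(cluster_configuration_entropy(sizes),
               cluster_configuration_entropy(rev(sizes)))
  expect_lte(cluster_configuration_entropy(sizes), log(length(sizes)))
})

test_that("transition detection finds the largest entropy jump", {
  lad <- make_ladder(-0.1, -0.5, 0.1)  # 5 states
  h <- c(0, 0, 0, 2.0, 2.1)
  tr <- detect_transition(h, lad)
  expect_equal(tr$state_index, 4)
  expect_equal(tr$t_p, lad$temperature[4])
  expect_false(tr$tied)

  # two equal jumps: the earlier (cooler... lower temperature) state wins
  h2 <- c(0, 1, 1, 2, 2)
  tr2 <- detect_transition(h2, lad)
  expect_equal(tr2$state_index, 2)
  expect_true(tr2$tied)
  expect_true(tr2$low_confidence)

  expect_error(detect_transition(rep(1, 5), lad), "undefined")
})

test_that("the order parameter is the giant-cluster fraction", {
  dimer <- decompose(make_toy_network(2, con_row(1, 2, bars = 6L)))
  expect_equal(rigidity_order_parameter(dimer), 1.0)
  iso <- decompose(make_toy_network(4, empty_con()))
  expect_equal(rigidity_order_parameter(iso), 1 / 4)
  mixed <- decompose(make_toy_network(4, rbind(con_row(1, 2, bars = 6L),
                                               con_row(2, 3, bars = 6L))))
  expect_equal(rigidity_order_parameter(mixed), 3 / 4)

  net <- build_network(make_ideal_helix(8))
  gi <- global_indices(run_unfolding(net))
  expect_true(all(gi$order_parameter >= 0 & gi$order_parameter <= 1))
  expect_true(all(diff(gi$order_parameter) <= 1e-12))
})

test_that("percolation profiles read off the segregation temperature", {
  # residue 3 is bound to the rigid block by hbonds at -2.0 and -3.0:
  # both are needed for mutual rigidity, so its backbone leaves the giant
  # cluster at the first state past -2.0 (E_cut -2.1 -> 342 K)
  toy <- make_staged_protein(e_hb1 = -2.0, e_hb2 = -3.0)
  traj <- run_unfolding(toy$network)
  prof <- percolation_profile(traj)
  expect_equal(prof$p_i[3], 342)
  # the rigid block never segregates from itself: top-of-ladder sentinel
  expect_equal(prof$p_i[1], 420)
  expect_equal(prof$p_i[2], 420)

  # the residue value is the lower of its two backbone-bond values
  giant <- cnar:::.giant_membership(traj)
  temps <- traj$ladder$temperature
  res <- toy$structure$residues[3, ]
  bond_first_out <- function(a, b) {
    inside <- giant[a, ] & giant[b, ]
    if (all(inside)) max(temps) else temps[which(!inside)[1]]
  }
  expect_equal(prof$p_i[3], min(bond_first_out(res$N, res$CA),
                                bond_first_out(res$CA, res$C)))
})

test_that("stability maps record the last state a rigid contact exists", {
  toy <- make_staged_protein(e_hb1 = -2.0, e_hb2 = -3.0)
  traj <- run_unfolding(toy$network)
  m <- stability_map(traj)
  # residues 1-2 are jointly rigid through the whole ladder
  expect_equal(m$rc[1, 2], -6.0)
  # contact of residue 3 with the block is lost after the -2.0 state
  expect_equal(m$rc[2, 3], -2.0)
  expect_equal(m$rc[1, 3], -2.0)
  expect_true(all(is.na(diag(m$rc))))
  expect_equal(m$rc, t(m$rc))

  # a pair never jointly rigid keeps the ladder-start sentinel
  toy2 <- make_staged_protein(e_hb1 = -2.0, e_hb2 = -2.0)
  # duplicate energies on distinct pairs: bond 2 to a different acceptor
  net2 <- toy2$network
  traj2 <- run_unfolding(net2)
  m2 <- stability_map(traj2)
  expect_true(all(m2$rc[!is.na(m2$rc)] >= -6.0 & m2$rc[!is.na(m2$rc)] <= -0.1))
})

test_that("the neighbor median commutes with the temperature conversion", {
  toy <- make_staged_protein()
  m <- stability_map(run_unfolding(toy$network))
  nm <- neighbor_median_stability(m)
  expect_equal(nm$rc_median_K, ecut_to_temperature(nm$rc_median))
  expect_equal(nm$rc_median_K, -20 * nm$rc_median + 300)
  # even-count median rule
  vals <- c(-1.0, -2.0)
  expect_equal(median(vals), -1.5)
  expect_equal(ecut_to_temperature(median(vals)), 330)
  # median of an odd neighbor set
  expect_equal(ecut_to_temperature(median(c(-0.5, -1.0, -2.0))), 320)
})

test_that("difference maps subtract on the temperature scale and filter", {
  toy <- make_staged_protein(e_hb1 = -2.0, e_hb2 = -3.0)
  m_a <- stability_map(run_unfolding(toy$network))
  toy_b <- make_staged_protein(e_hb1 = -1.5, e_hb2 = -3.0)
  m_b <- stability_map(run_unfolding(toy_b$network))

  self_diff <- diff_stability_map(m_a, m_a)
  expect_true(all(self_diff$delta[!is.na(self_diff$delta)] == 0))
  expect_false(any(self_diff$show))

  d <- diff_stability_map(m_a, m_b)
  # contact 2-3 is 0.5 kcal/mol (10 K) more stable in a than in b
  expect_equal(d$delta[2, 3], 10)
  expect_true(d$show[2, 3])
  # +2 K is below the display threshold
  d_small <- diff_stability_map(m_a, m_b, stabilized_min = 4)
  expect_false(isTRUE(d_small$show[1, 2]))

  # same-secondary-structure pairs can be masked out
  d_ss <- diff_stability_map(m_a, m_b, ss = c(1, 1, NA))
  expect_false(d_ss$show[1, 2])
  expect_true(d_ss$show[2, 3])

  short <- stability_map(run_unfolding(build_network(make_ideal_helix(4))))
  expect_error(diff_stability_map(m_a, short), "residue counts")
})

test_that("profiles and maps respond monotonically to losing a constraint", {
  toy <- make_staged_protein(e_hb1 = -2.0, e_hb2 = -3.0)
  weaker <- toy$network
  weaker$constraints <- weaker$constraints[
    !(weaker$constraints$kind == "hbond" &
        weaker$constraints$energy == -2.0), ]
  traj_full <- run_unfolding(toy$network)
  traj_weak <- run_unfolding(weaker)
  p_full <- percolation_profile(traj_full)$p_i
  p_weak <- percolation_profile(traj_weak)$p_i
  expect_true(all(p_weak <= p_full))
  # on the temperature scale: contacts can only be lost earlier
  rc_full_K <- ecut_to_temperature(stability_map(traj_full)$rc)
  rc_weak_K <- ecut_to_temperature(stability_map(traj_weak)$rc)
  expect_true(all(rc_weak_K <= rc_full_K, na.rm = TRUE))
})
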