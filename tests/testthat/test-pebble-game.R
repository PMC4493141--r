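test_that("textbook cases decompose correctly", {
  # a single body: one cluster, 6 DOF
  lone <- make_toy_network(1, empty_con())
  d1 <- decompose(lone)
  expect_equal(length(d1$clusters), 1)
  expect_equal(d1$dof_total, 6)

  # two bodies, 6 generic bars: one rigid cluster, no redundancy
  dimer <- make_toy_network(2, con_row(1, 2, bars = 6L))
  d6 <- decompose(dimer)
  expect_equal(length(d6$clusters), 1)
  expect_equal(d6$dof_total, 6)
  expect_equal(d6$redundant_bar_count, 0)
  expect_equal(brute_force_rank_oracle(dimer), 6)

  # 5 bars leave one relative DOF: two clusters
  pair5 <- make_toy_network(2, con_row(1, 2, bars = 5L))
  d5 <- decompose(pair5)
  expect_equal(length(d5$clusters), 2)
  expect_equal(d5$dof_total, 7)
  expect_equal(brute_force_rank_oracle(pair5), 5)

  # chain of three bodies with 5-bar links: 6 + 2 internal DOF
  chain <- make_toy_network(3, rbind(con_row(1, 2, bars = 5L),
                                     con_row(2, 3, bars = 5L)))
  expect_equal(count_dof(chain), 8)
  expect_equal(brute_force_rank_oracle(chain), 10)

  # isolated bodies keep all their DOF
  iso <- make_toy_network(4, empty_con())
  expect_equal(count_dof(iso), 24)
  expect_equal(brute_force_rank_oracle(iso), 0)
})

test_that("pebble-game counts equal rigidity-matrix ranks on random networks", {
  for (seed in 1:110) {
    net <- random_toy_network(seed)
    d <- decompose(net)
    rank <- brute_force_rank_oracle(net, seed = seed + 3000)
    expect_equal(d$n_independent, rank,
                 info = paste("independent bars vs rank, seed", seed))
    # DOF conservation: 6 * bodies = dof_total + independent bars
    expect_equal(6 * net$n_bodies, d$dof_total + d$n_independent)
    expect_equal(sum(d$sizes), net$n_bodies)
  }
})

test_that("pairwise mutual rigidity agrees between game and oracle", {
  for (seed in c(7, 21, 48, 77, 93)) {
    net <- random_toy_network(seed)
    n <- net$n_bodies
    pairs <- t(combn(n, 2))
    game <- pebble_pair_rigid(net, pairs)
    oracle <- oracle_pair_rigid(net, pairs, seed = seed + 4000)
    expect_equal(game, oracle, info = paste("seed", seed))

    # cluster partition equals the transitive closure of oracle-rigid
    # adjacent pairs
    d <- decompose(net)
    same_cluster <- d$cluster_id[pairs[, 1]] == d$cluster_id[pairs[, 2]]
    con <- net$constraints
    adjacent <- paste(pairs[, 1], pairs[, 2]) %in%
      paste(pmin(con$body_a, con$body_b), pmax(con$body_a, con$body_b))
    uf <- seq_len(n)
    find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
    for (k in which(adjacent & oracle))
      uf[find(pairs[k, 1])] <- find(pairs[k, 2])
    closure <- vapply(seq_len(nrow(pairs)), function(k)
      find(pairs[k, 1]) == find(pairs[k, 2]), logical(1))
    expect_equal(same_cluster, closure, info = paste("clusters, seed", seed))
  }
})

test_that("removing a bar never lowers DOF nor merges clusters", {
  for (seed in c(3, 12, 31)) {
    net <- random_toy_network(seed)
    d_full <- decompose(net)
    for (drop in seq_len(nrow(net$constraints))) {
      sub <- make_toy_network(net$n_bodies,
                              net$constraints[-drop, , drop = FALSE],
                              coords = net$coords)
      d_sub <- decompose(sub)
      expect_gte(d_sub$dof_total, d_full$dof_total)
      # every cluster of the reduced network is inside one full-network cluster
      for (cl in d_sub$clusters) {
        if (length(cl) > 1)
          expect_equal(length(unique(d_full$cluster_id[cl])), 1)
      }
    }
  }
})

test_that("cluster labels are invariant under body re-ordering", {
  net <- random_toy_network(64)
  n <- net$n_bodies
  set.seed(99)
  perm <- sample(n)
  con <- net$constraints
  con$body_a <- perm[con$body_a]
  con$body_b <- perm[con$body_b]
  permuted <- make_toy_network(n, con, coords = net$coords[order(perm), ])
  d1 <- decompose(net)
  d2 <- decompose(permuted)
  # partitions match up to label permutation
  relabeled <- d2$cluster_id[perm]
  tab <- table(d1$cluster_id, relabeled)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_equal(sort(d1$sizes), sort(d2$sizes))
})
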