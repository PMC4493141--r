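test_that("Manhattan distance matches hand values and the triangle rule", {
  expect_equal(manhattan_distance(c(1, 2), c(2, 4)), 3)
  expect_equal(manhattan_distance(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_error(manhattan_distance(1:3, 1:4), "length")
  set.seed(11)
  for (i in 1:50) {
    a <- runif(6); b <- runif(6); c <- runif(6)
    expect_lte(manhattan_distance(a, c),
               manhattan_distance(a, b) + manhattan_distance(b, c) + 1e-12)
  }
})

test_that("PAM recovers two planted profile groups", {
  set.seed(21)
  g1 <- matrix(rep(c(330, 345, 360, 330), each = 20), nrow = 20) +
    matrix(runif(80, -2, 2), nrow = 20)
  g2 <- matrix(rep(c(410, 305, 310, 415), each = 20), nrow = 20) +
    matrix(runif(80, -2, 2), nrow = 20)
  ps <- profile_set(rbind(g1, g2), rep(c("a", "b"), each = 20))
  fit <- pam_cluster(ps, k = 2)
  expect_equal(length(unique(fit$assignment[1:20])), 1)
  expect_equal(length(unique(fit$assignment[21:40])), 1)
  expect_false(fit$assignment[1] == fit$assignment[40])
  expect_gt(fit$objective, 0)
  # k = n: every profile its own medoid, objective zero
  fit_n <- pam_cluster(ps, k = 40)
  expect_equal(fit_n$objective, 0)
  expect_equal(sort(fit_n$medoids), 1:40)
  expect_error(pam_cluster(ps, k = 41), "exceed")
})

test_that("duplicated profiles give zero within-cluster dissimilarity", {
  prof <- matrix(rep(c(300, 320, 340), each = 6), nrow = 6)
  ps <- profile_set(rbind(prof, prof + 100), rep(c("u", "v"), each = 6))
  fit <- pam_cluster(ps, k = 2)
  expect_equal(fit$objective, 0)
})

test_that("the objective is non-increasing in k with an elbow at the truth", {
  set.seed(33)
  centers <- rbind(c(300, 400, 300), c(400, 300, 400), c(350, 350, 250))
  profs <- do.call(rbind, lapply(1:3, function(g)
    matrix(rep(centers[g, ], each = 12), nrow = 12) +
      matrix(runif(36, -1, 1), nrow = 12)))
  ps <- profile_set(profs, rep(c("a", "b", "c"), each = 12))
  scan <- objective_vs_k(ps, 1:6)
  expect_true(all(diff(scan$objective) <= 1e-9))
  # elbow: big drop up to k = 3, little after
  drop_to_truth <- scan$objective[1] - scan$objective[3]
  drop_after <- scan$objective[3] - scan$objective[6]
  expect_gt(drop_to_truth, 10 * drop_after)
  expect_equal(objective_vs_k(ps, 36)$objective, 0)
})

test_that("cluster distributions count topologies and conserve totals", {
  assignment <- c(1, 1, 1, 2, 2, 3)
  labels <- c("wt", "wt", "wt", "wt", "mut", "mut")
  counts <- cluster_distribution(assignment, labels, k = 3)
  expect_equal(counts["wt", ], c(`1` = 3L, `2` = 1L, `3` = 0L))
  expect_equal(rowSums(counts), c(wt = 4L, mut = 2L))
  # all topologies in one cluster
  one <- cluster_distribution(rep(1, 5), rep("x", 5), k = 4)
  expect_equal(unname(one[1, ]), c(5L, 0L, 0L, 0L))
  # identical assignment multisets -> identical distributions
  c2 <- cluster_distribution(c(2, 1, 1, 1, 2, 3), labels, k = 3)
  expect_equal(unname(c2["wt", ]), unname(counts["wt", ]))
})

test_that("distribution correlations reproduce the analytic Pearson r", {
  counts <- rbind(a = c(10L, 0L), b = c(0L, 10L))
  r <- distribution_correlation_matrix(counts)
  expect_equal(r["a", "b"], -1)
  expect_equal(diag(r), c(a = 1, b = 1))

  set.seed(44)
  counts2 <- matrix(rpois(40, 5), nrow = 4,
                    dimnames = list(letters[1:4], NULL))
  r2 <- distribution_correlation_matrix(counts2)
  expect_equal(r2, t(r2))
  expect_true(all(r2 >= -1 - 1e-12 & r2 <= 1 + 1e-12))
  # hand recomputation of one entry
  x <- counts2[1, ]; y <- counts2[3, ]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2[1, 3], manual)

  flat <- rbind(a = rep(3L, 5), b = c(1L, 2L, 3L, 4L, 5L))
  expect_warning(r3 <- distribution_correlation_matrix(flat), "zero-variance")
  expect_true(is.na(r3["a", "b"]))

  rel <- pathway_reliability(r2, threshold = 0.16)
  expect_equal(nrow(rel), 4)
  expect_type(rel$low_confidence, "logical")
})

test_that("clustering is invariant under permutation of profile order", {
  set.seed(55)
  profs <- rbind(matrix(runif(40, 300, 320), nrow = 10),
                 matrix(runif(40, 400, 420), nrow = 10))
  labels <- rep(c("a", "b"), each = 10)
  perm <- sample(20)
  ps1 <- profile_set(profs, labels)
  ps2 <- profile_set(profs[perm, ], labels[perm])
  f1 <- pam_cluster(ps1, 2)
  f2 <- pam_cluster(ps2, 2)
  # same partition up to label swap
  back <- integer(20); back[perm] <- seq_len(20)
  agree <- outer(f1$assignment, f1$assignment, "==")
  agree2 <- outer(f2$assignment[back], f2$assignment[back], "==")
  expect_equal(agree, agree2)
  expect_equal(f1$objective, f2$objective)
})
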