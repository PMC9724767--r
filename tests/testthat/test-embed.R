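test_that("Euclidean distances match a brute-force double loop", {
  m <- random_beta(10, 6, seed = 31)
  D <- euclidean_distances(m)
  expect_equal(D, dist_oracle(m), tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))

  dup <- cbind(m, dupcol = m[, 1])
  expect_equal(euclidean_distances(dup)["s001", "dupcol"], 0)

  two <- matrix(c(0, 0, 3, 4), 2, 2,
                dimnames = list(c("p1", "p2"), c("a", "b")))
  two <- two / 10                       # keep in [0,1]; distance scales by 1/10
  expect_equal(euclidean_distances(two)["a", "b"], 0.5)

  m[1, 1] <- NA
  expect_error(euclidean_distances(m), "impute")
})

test_that("classical MDS reproduces hand-computed embeddings and the sign rule", {
  D2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  e <- classical_mds(D2, k = 1)
  expect_equal(unname(e$coordinates[, 1]), c(2, -2))

  # three collinear points with unit gaps
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  e3 <- classical_mds(D3, k = 1)
  expect_equal(sort(unname(e3$coordinates[, 1])), c(-1, 0, 1))
  i <- which.max(abs(e3$coordinates[, 1]))
  expect_gt(e3$coordinates[i, 1], 0)

  expect_error(classical_mds(D3, k = 3), "maximum usable k")
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2), k = 1), "symmetric")
})

test_that("classical MDS matches the eigendecomposition oracle and recovers distances", {
  set.seed(17)
  X <- matrix(stats::rnorm(8 * 3), 8, 3)   # true coordinates, rank 3
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
  e <- classical_mds(D, k = 3)
  expect_equal(unname(e$coordinates), mds_oracle(D, 3), tolerance = 1e-8)
  expect_equal(as.matrix(stats::dist(e$coordinates)), D,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(e$eigenvalues) <= 1e-8))
  expect_lt(max(abs(colMeans(e$coordinates))), 1e-8)
})

test_that("the embedding is stable under sample reordering", {
  m <- random_beta(30, 10, seed = 41)
  e1 <- classical_mds(euclidean_distances(m), k = 2)
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  e2 <- classical_mds(euclidean_distances(m[, perm]), k = 2)
  # permuting input columns permutes coordinate rows identically (sign rule
  # pins the axis orientation), so each sample keeps its coordinates
  expect_equal(e2$coordinates[colnames(m), ], e1$coordinates,
               tolerance = 1e-8)
})

test_that("separation metrics distinguish separated from confounded labelings", {
  set.seed(23)
  co <- rbind(matrix(stats::rnorm(40, 0, 0.05), 20, 2),
              matrix(stats::rnorm(40, 5, 0.05), 20, 2))
  D <- as.matrix(stats::dist(co))
  dimnames(D) <- list(sprintf("s%d", 1:40), sprintf("s%d", 1:40))
  emb <- classical_mds(D, k = 2)
  labels <- rep(c("g1", "g2"), each = 20)
  met <- separation_metrics(emb, labels)
  expect_gt(met$mean_silhouette, 0.9)
  expect_gt(met$centroid_spread_ratio, 10)

  # identical points split into two labels: maximal confusion
  co2 <- matrix(rep(c(0, 0), each = 10), 10, 2)
  co2 <- co2 + stats::rnorm(20, 0, 1e-9)
  D2 <- as.matrix(stats::dist(co2))
  dimnames(D2) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  emb2 <- classical_mds(D2, k = 1)
  met2 <- separation_metrics(emb2, rep(c("a", "b"), 5))
  expect_lte(met2$mean_silhouette, 0)

  expect_error(separation_metrics(emb, rep("one", 40)), "2 groups")
  met3 <- separation_metrics(emb, c("solo", labels[-1]))
  expect_identical(met3$singleton_groups, "solo")
})
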