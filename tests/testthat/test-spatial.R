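test_that("the connection network is symmetric, standardized, and sane", {
  # 3 collinear equidistant points, k = 1: symmetrisation connects the
  # middle point to both ends
  net <- build_network(cbind(c(0, 1, 2), c(0, 0, 0)), k_neighbors = 1)
  expect_equal(net$A[2, ], c(1, 0, 1))
  expect_true(isSymmetric(net$A))
  expect_equal(rowSums(net$W), rep(1, 3))

  # interior nodes of a grid of cell centres have >= 8 neighbours
  gr <- expand.grid(x = 1:7, y = 1:7)
  net2 <- build_network(as.matrix(gr), k_neighbors = 8)
  interior <- which(gr$x %in% 2:6 & gr$y %in% 2:6)
  expect_true(all(rowSums(net2$A)[interior] >= 8))

  # random point sets give a connected graph at k = 8 (igraph oracle)
  for (seed in c(80, 81)) {
    set.seed(seed)
    pts <- cbind(runif(150), runif(150))
    net3 <- build_network(pts, k_neighbors = 8)
    g <- igraph::graph_from_adjacency_matrix(net3$A, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
  expect_error(build_network(cbind(1:3, 1:3), k_neighbors = 5), "k \\+ 1")
})

test_that("Moran's I is positive on gradients and negative on alternation", {
  line <- build_network(cbind(1:20, rep(0, 20)), k_neighbors = 2)
  expect_gt(morans_I(1:20, line), 0)
  expect_lt(morans_I(rep(c(1, -1), 10), line), 0)
  expect_error(morans_I(rep(1, 20), line), "zero-variance")
  # permutation null mean is -1/(n-1)
  set.seed(82)
  vals <- rnorm(20)
  perms <- replicate(3000, morans_I(sample(vals), line))
  expect_lt(abs(mean(perms) - (-1 / 19)), 0.02)
})

test_that("sPCA reduces to ordinary PCA under identity weights", {
  set.seed(83)
  G <- hwe_sample(rep(list(c(.5, .3, .2)), 4), 40)
  smp <- make_sample(G, cell = sample.int(625, 40, TRUE))
  n <- 40
  eye <- structure(list(W = diag(n), A = diag(n),
                        coords = cbind(1:n, 1:n), k = 0),
                   class = "tort_network")
  res <- spca(smp, eye)
  X <- tortsim:::allele_freq_matrix(smp)
  pca_var <- prcomp(X)$sdev^2 * (n - 1) / n
  expect_equal(sort(res$eigenvalues, decreasing = TRUE)[1:5],
               pca_var[1:5], tolerance = 1e-8)
})

test_that("every sPCA axis satisfies lambda = var(scores) x I(scores)", {
  set.seed(84)
  G <- hwe_sample(rep(list(c(.4, .3, .3)), 6), 60)
  cells <- sample.int(625, 60, TRUE)
  smp <- make_sample(G, cell = cells)
  net <- build_network(sample_coords(smp, seed = 85), k_neighbors = 8)
  res <- spca(smp, net)
  expect_equal(res$eigenvalues, res$var * res$moran, tolerance = 1e-8)
  expect_gt(max(res$eigenvalues), 0)
  expect_lt(min(res$eigenvalues), 0)
})

test_that("segregated clusters produce a dominant global axis", {
  # two spatial blocks fixed for different alleles at five loci
  n_half <- 25
  G <- rbind(matrix(1L, n_half, 10), matrix(2L, n_half, 10))
  cells <- c(sample(tortsim:::cell_id(rep(1:5, 5), rep(1:5, each = 5), 25L), n_half, TRUE),
             sample(tortsim:::cell_id(rep(21:25, 5), rep(21:25, each = 5), 25L), n_half, TRUE))
  smp <- make_sample(G, cell = cells)
  net <- build_network(sample_coords(smp, seed = 86), k_neighbors = 8)
  res <- spca(smp, net)
  top <- res$scores[, which.max(res$eigenvalues)]
  expect_gt(max(res$eigenvalues), 0)
  expect_true(all(sign(top[1:n_half]) == sign(top[1])))
  expect_true(all(sign(top[(n_half + 1):(2 * n_half)]) == -sign(top[1])))
  gt <- global_local_test(smp, net, n_perm = 999, seed = 87)
  expect_equal(gt$p[gt$test == "global"], 1 / 1000)
})

test_that("the global test is calibrated under spatial randomness", {
  set.seed(88)
  ps <- vapply(1:15, function(i) {
    G <- hwe_sample(rep(list(c(.5, .5)), 5), 30)
    smp <- make_sample(G, cell = sample.int(625, 30, TRUE))
    net <- build_network(sample_coords(smp), k_neighbors = 4)
    gt <- global_local_test(smp, net, n_perm = 49)
    gt$p[gt$test == "global"]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.6)   # no systematic rejection under the null
  expect_gt(stats::sd(ps), 0.05)    # and the p-values are not degenerate
  expect_error(global_local_test(make_sample(hwe_sample(list(c(.5, .5)), 10)),
                                 build_network(cbind(1:10, 1:10), 2),
                                 n_perm = 0), "n_perm")
})

test_that("the Mantel statistic equals Pearson on off-diagonal pairs", {
  # 4x4 hand-checkable matrices
  A <- matrix(0, 4, 4); A[lower.tri(A)] <- c(1, 2, 3, 4, 5, 6)
  A <- A + t(A)
  B <- matrix(0, 4, 4); B[lower.tri(B)] <- c(2, 1, 4, 3, 6, 5)
  B <- B + t(B)
  got <- mantel(A, B, n_perm = 99, seed = 89)
  expect_equal(got$r, stats::cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)))

  expect_equal(mantel(A, A, n_perm = 19, seed = 90)$r, 1)

  # independent oracle: vegan's implementation on a random pair
  set.seed(91)
  X <- dist(matrix(rnorm(60), 20))
  Y <- dist(matrix(rnorm(60), 20))
  ours <- mantel(X, Y, n_perm = 199, seed = 92)
  ref <- vegan::mantel(X, Y, permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel(dist(1:4), dist(1:5)), "size")
  expect_error(mantel(X, Y, n_perm = 0), "n_perm")
})

test_that("jittered coordinates stay inside their cell", {
  smp <- make_sample(hwe_sample(list(c(.5, .5)), 30, seed = 93),
                     cell = rep(313L, 30))
  xy <- sample_coords(smp, seed = 94)
  expect_true(all(abs(xy[, 1] - (tortsim:::cell_col(313L, 25L) - 0.5)) < 0.5))
  expect_true(all(abs(xy[, 2] - (tortsim:::cell_row(313L, 25L) - 0.5)) < 0.5))
  expect_gt(stats::sd(xy[, 1]), 0)
})

test_that("genetic distance is a metric-zero only for identical genotypes", {
  G <- rbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L))
  D <- as.matrix(genetic_dist(make_sample(G)))
  expect_equal(D[1, 2], 0)
  expect_gt(D[1, 3], 0)
  expect_equal(D, t(D))
})
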