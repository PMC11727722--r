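test_that("radius graph follows the strict-distance rule with self-loops", {
  two <- rbind(c(0, 0), c(1, 0))
  g <- build_radius_graph(two, 2)
  expect_equal(as.matrix(g$adjacency), matrix(1, 2, 2), ignore_attr = TRUE)
  g0 <- build_radius_graph(two, 0.5)
  expect_equal(as.matrix(g0$adjacency), diag(2), ignore_attr = TRUE)
  # boundary: distance exactly r is NOT an edge
  gb <- build_radius_graph(two, 1)
  expect_equal(as.matrix(gb$adjacency), diag(2), ignore_attr = TRUE)

  three <- cbind(0:2, 0)
  g3 <- build_radius_graph(three, 1.5)
  A <- as.matrix(g3$adjacency)
  expect_equal(A[1, 2], 1); expect_equal(A[2, 3], 1); expect_equal(A[1, 3], 0)
})

test_that("radius graph equals the O(n^2) pairwise-distance oracle", {
  set.seed(3)
  pts <- cbind(runif(100, 0, 10), runif(100, 0, 10))
  r <- 1.7
  g <- build_radius_graph(pts, r)
  D <- as.matrix(dist(pts))
  oracle <- (D < r) * 1; diag(oracle) <- 1
  expect_equal(as.matrix(g$adjacency), oracle, ignore_attr = TRUE)
  expect_true(isSymmetric(as.matrix(g$adjacency)))
  # r -> infinity gives the complete graph
  gi <- build_radius_graph(pts[1:10, ], 1e9)
  expect_equal(as.matrix(gi$adjacency), matrix(1, 10, 10), ignore_attr = TRUE)
})

test_that("knn graph symmetrizes by union and respects lattice geometry", {
  three <- cbind(0:2, 0)
  g <- build_knn_graph(three, 1)
  A <- as.matrix(g$adjacency)
  # endpoints pick the middle; middle's distance tie broken by lower index
  expect_equal(A[1, 2], 1); expect_equal(A[2, 3], 1); expect_equal(A[1, 3], 0)
  expect_equal(diag(A), rep(1, 3), ignore_attr = TRUE)

  # interior spot of a hex lattice has exactly its 6 lattice neighbors
  spec <- synthetic_spec(rows = 9, cols = 9, k_domains = 2, lattice = "hex",
                         n_genes = 10, markers_per_domain = 2, seed = 1)
  ds <- generate_layered_tissue(spec)
  gh <- build_knn_graph(ds$coords, 6)
  center <- which.min(rowSums(sweep(ds$coords, 2, colMeans(ds$coords))^2))
  nb <- setdiff(which(as.matrix(gh$adjacency)[center, ] == 1), center)
  d <- sqrt(rowSums(sweep(ds$coords[nb, , drop = FALSE], 2,
                          ds$coords[center, ])^2))
  expect_length(nb, 6)
  expect_equal(unname(d), rep(1, 6), tolerance = 1e-9)

  # k = n - 1 yields the complete graph + loops
  gc <- build_knn_graph(three, 2)
  expect_equal(as.matrix(gc$adjacency), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_error(build_knn_graph(three, 3), "k must")
})

test_that("expression preclustering separates disjoint gene programs", {
  set.seed(2)
  n <- 60
  X <- rbind(matrix(rpois(30 * 20, c(rep(8, 10), rep(0.2, 10))), 30, 20, byrow = TRUE),
             matrix(rpois(30 * 20, c(rep(0.2, 10), rep(8, 10))), 30, 20, byrow = TRUE))
  ds <- normalize_log1p(spot_dataset(X, cbind(runif(n), runif(n))))
  suppressWarnings(labels <- precluster_expression(ds, seed = 4))
  expect_equal(adjusted_rand_index(labels, rep(0:1, each = 30)), 1)
  # determinism under a fixed seed
  suppressWarnings(labels2 <- precluster_expression(ds, seed = 4))
  expect_identical(labels, labels2)
  # identical expression for all spots collapses to one cluster
  Xf <- matrix(5, 20, 6)
  dsf <- spot_dataset(Xf, cbind(runif(20), runif(20)), normalized = TRUE)
  suppressWarnings(lf <- precluster_expression(dsf, seed = 1))
  expect_length(unique(lf), 1)
})

test_that("pruning removes exactly the cross-cluster edges", {
  # 4-cycle: 1-2, 2-3, 3-4, 4-1, labels split 1,2 vs 3,4
  A <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 1, 2, 3, 4),
                            j = c(2, 3, 4, 1, 1, 2, 3, 4), x = 1,
                            dims = c(4, 4), symmetric = FALSE)
  A <- methods::as((A + Matrix::t(A) + Matrix::Diagonal(4)) > 0, "dMatrix")
  g <- spadom:::neighbor_graph(A, "radius", 1)
  pruned <- prune_to_ctasnn(g, c(0, 0, 1, 1))
  Ap <- as.matrix(pruned$adjacency)
  expect_equal(sum(Ap) - 4, 2 * 2)          # 2 undirected within edges remain
  expect_equal(Ap[1, 2], 1); expect_equal(Ap[2, 3], 0)
  expect_equal(Ap[3, 4], 1); expect_equal(Ap[4, 1], 0)
  expect_equal(diag(Ap), rep(1, 4), ignore_attr = TRUE)

  # all labels equal: unchanged; all distinct: loops only
  same <- prune_to_ctasnn(g, rep(0, 4))
  expect_equal(as.matrix(same$adjacency), as.matrix(g$adjacency))
  loops <- prune_to_ctasnn(g, 0:3)
  expect_equal(as.matrix(loops$adjacency), diag(4), ignore_attr = TRUE)
  expect_error(prune_to_ctasnn(g, c(0, 1)), "length")
})

test_that("edge lists round-trip through TSV export", {
  set.seed(12)
  pts <- cbind(runif(15, 0, 4), runif(15, 0, 4))
  g <- build_knn_graph(pts, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_equal(as.matrix(g2$adjacency), as.matrix(g$adjacency))
  expect_true(g2$has_self_loops)
})

test_that("pruned graphs never retain cross-precluster edges (random draws)", {
  set.seed(8)
  for (rep_i in 1:50) {
    n <- sample(10:40, 1)
    pts <- cbind(runif(n, 0, 5), runif(n, 0, 5))
    g <- build_knn_graph(pts, sample(2:5, 1))
    labels <- sample(0:3, n, replace = TRUE)
    pg <- prune_to_ctasnn(g, labels)
    tr <- methods::as(pg$adjacency, "TsparseMatrix")
    i <- tr@i + 1L; j <- tr@j + 1L
    off <- i != j
    expect_equal(sum(labels[i[off]] != labels[j[off]]), 0)
    expect_true(Matrix::isSymmetric(pg$adjacency))
    expect_equal(unname(Matrix::diag(pg$adjacency)), rep(1, n))
  }
})
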