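test_that("dense loader round-trips and aligns matrix with coordinates", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  write.table(data.frame(spot = rownames(X), X, check.names = FALSE),
              file.path(dir, "m.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(spot = c("s1", "s2", "s3"), x = 0:2, y = c(0, 0, 1)),
              file.path(dir, "c.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  ds <- load_spot_dataset(file.path(dir, "m.csv"), file.path(dir, "c.csv"))
  expect_s3_class(ds, "spot_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_identical(unname(ds$X), unname(X))
  expect_identical(ds$spot_ids, c("s1", "s2", "s3"))

  # archive round-trip preserves integer counts exactly
  out <- file.path(dir, "arch")
  write_spot_dataset(ds, out)
  ds2 <- read_spot_dataset(out)
  expect_identical(ds2$X, ds$X)
  expect_identical(ds2$coords, ds$coords)

  # a coord table missing one spot drops it with a message
  write.table(data.frame(spot = c("s1", "s3"), x = c(0, 2), y = c(0, 1)),
              file.path(dir, "c2.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  expect_message(ds3 <- load_spot_dataset(file.path(dir, "m.csv"),
                                          file.path(dir, "c2.csv")),
                 "dropped 1")
  expect_identical(ds3$spot_ids, c("s1", "s3"))
})

test_that("MatrixMarket triplets with duplicate entries are summed", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 5",
               "1 1 2", "1 1 3",   # duplicate (1,1): should sum to 5
               "2 2 7", "3 1 1", "3 2 4"), mtx)
  write.table(data.frame(spot = paste0("s", 1:3), x = 0:2, y = rep(0, 3)),
              file.path(dir, "c.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  ds <- load_spot_dataset(mtx, file.path(dir, "c.csv"), dialect = "mtx")
  dense <- matrix(c(5, 0, 1, 0, 7, 4), 3, 2)   # explicit summation oracle
  expect_equal(unname(ds$X), dense)
})

test_that("loader rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  write.table(data.frame(spot = c("s1", "s2"), x = c(0, "oops"), y = c(0, 1)),
              file.path(dir, "bad.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(spot = c("s1", "s2"), g = c(1, 2)),
              file.path(dir, "m.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_spot_dataset(file.path(dir, "m.csv"), file.path(dir, "bad.csv")),
               "s2")
  expect_error(load_spot_dataset(file.path(dir, "nope.csv"), file.path(dir, "bad.csv")),
               "not found")
  expect_error(spot_dataset(matrix(1, 2, 2), matrix(0, 2, 2),
                            spot_ids = c("a", "a")), "duplicate")
})

test_that("filter_spots subsets all fields consistently", {
  ds <- spot_dataset(matrix(1:6, 3, 2), cbind(0:2, 0:2),
                     spot_ids = c("s1", "s2", "s3"),
                     truth_labels = c(0L, 1L, 1L))
  expect_identical(filter_spots(ds, c(TRUE, TRUE, TRUE))$X, ds$X)
  sub <- filter_spots(ds, c(TRUE, FALSE, TRUE))
  expect_identical(sub$spot_ids, c("s1", "s3"))
  expect_identical(sub$truth_labels, c(0L, 1L))
  expect_identical(unname(sub$coords[, 1]), c(0, 2))
  expect_error(filter_spots(ds, rep(FALSE, 3)), "no spots remain")
  expect_error(filter_spots(ds, c(TRUE, FALSE)), "length")
})

test_that("normalize_log1p matches closed forms and a two-step oracle", {
  ds <- spot_dataset(matrix(c(10, 0), 1, 2), cbind(0, 0), spot_ids = "s1")
  dn <- normalize_log1p(ds, target_sum = 10)
  expect_equal(unname(dn$X), matrix(c(log(11), 0), 1, 2))

  # equal library sizes imply a uniform scale factor
  X <- matrix(c(2, 3, 5, 1, 4, 5), 3, 2)  # rows sum to... make equal
  X <- rbind(c(3, 7), c(6, 4), c(9, 1))   # all rows sum to 10
  ds2 <- spot_dataset(X, cbind(0:2, 0:2))
  dn2 <- normalize_log1p(ds2, target_sum = 100)
  expect_equal(unname(dn2$X), log1p(X * 10))

  # random counts vs an independently coded two-step oracle
  set.seed(7)
  Xr <- matrix(rpois(100, 3), 20, 5)
  Xr[1, ] <- Xr[1, ] + 1   # guard against zero rows
  dsr <- spot_dataset(Xr, cbind(runif(20), runif(20)))
  dsr <- drop_empty_spots(dsr)
  got <- normalize_log1p(dsr, 1e4)$X
  oracle <- t(apply(dsr$X, 1, function(r) log(1 + r / sum(r) * 1e4)))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)

  # idempotence guard and zero-library error
  expect_error(normalize_log1p(dn), "already normalized")
  ds0 <- spot_dataset(matrix(c(1, 0, 2, 0), 2, 2), cbind(0:1, 0:1),
                      spot_ids = c("ok", "empty"))
  expect_error(normalize_log1p(ds0), "empty")
})

test_that("filtering and normalization commute on nonzero-library spots", {
  set.seed(11)
  X <- matrix(rpois(60, 5) + 1, 12, 5)
  ds <- spot_dataset(X, cbind(runif(12), runif(12)))
  mask <- rep(c(TRUE, TRUE, FALSE), 4)
  a <- normalize_log1p(filter_spots(ds, mask))
  b <- filter_spots(normalize_log1p(ds), mask)
  expect_equal(a$X, b$X, tolerance = 1e-12)
})

test_that("select_hvg keeps the highest-dispersion genes", {
  ds <- make_tissue(rows = 6, cols = 6, k = 2, n_genes = 10, markers = 2, seed = 5)
  expect_identical(select_hvg(ds, ncol(ds$X))$gene_ids, ds$gene_ids)

  # constant gene has zero dispersion and is dropped first
  Xc <- ds$X; Xc[, 3] <- 1.0
  dsc <- spot_dataset(Xc, ds$coords, spot_ids = ds$spot_ids,
                      gene_ids = ds$gene_ids, normalized = TRUE)
  kept <- select_hvg(dsc, ncol(Xc) - 1L)$gene_ids
  expect_false("gene_3" %in% kept)

  # planted high-variance genes are recovered exactly, by brute force
  set.seed(9)
  n <- 40; g <- 50
  Xh <- matrix(rnorm(n * g, mean = 5, sd = 0.1), n, g)
  planted <- c(4, 17, 23, 38, 50)
  Xh[, planted] <- rnorm(n * length(planted), mean = 5, sd = 3)
  dsh <- spot_dataset(abs(Xh), cbind(runif(n), runif(n)), normalized = TRUE)
  top <- select_hvg(dsh, 5)$gene_ids
  disp <- apply(dsh$X, 2, var) / colMeans(dsh$X)
  expect_setequal(top, dsh$gene_ids[order(-disp)[1:5]])
  expect_setequal(top, paste0("gene_", planted))
  expect_error(select_hvg(dsh, 51), "n_top")
})
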