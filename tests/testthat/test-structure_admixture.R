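test_that("quantile distance matrices reduce pair distributions correctly", {
  vals <- cbind(rep(0.3, 101), seq(0, 1, length.out = 101), rep(0.1, 101))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  dm <- quantile_distance_matrices(vals, pairs = pairs)
  expect_length(dm, 5L)
  # constant pair: every quantile matrix carries that constant
  expect_true(all(vapply(dm, function(m) m[1, 2] == 0.3, logical(1))))
  # uniform 0..1 grid: median entry 0.5
  expect_equal(dm[["0.5"]][1, 3], 0.5)
  expect_true(all(vapply(dm, function(m) all(diag(m) == 0) && isSymmetric(m),
                         logical(1))))
})

test_that("DISTATIS reduces to classical MDS for identical matrices", {
  D <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3)
  ds <- distatis(list(D, D, D), n_boot = 0)
  expect_equal(ds$alpha, rep(1 / 3, 3), tolerance = 1e-10)
  # oracle: direct eigendecomposition of the double-centered matrix
  J <- diag(3) - 1 / 3
  S <- -0.5 * J %*% D %*% J
  e <- eigen(S, symmetric = TRUE)
  oracle <- e$vectors[, 1]
  got <- ds$scores[, 1] / sqrt(ds$eigenvalues[1])
  expect_equal(abs(got), abs(oracle), tolerance = 1e-8)
  expect_equal(abs(sum(got * oracle)), 1, tolerance = 1e-8)
  # compromise equals the common normalized cross-product
  expect_equal(ds$compromise, S / e$values[1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(distatis(list(matrix(0, 3, 3), D)), "degenerate")
})

test_that("compromise eigenvalues are non-negative for Euclidean input", {
  set.seed(4)
  for (i in 1:5) {
    pts <- matrix(rnorm(12), 6, 2)
    D1 <- as.matrix(dist(pts))^2
    D2 <- as.matrix(dist(pts + rnorm(12, 0, 0.1)))^2
    ds <- distatis(list(D1, D2), n_boot = 0)
    expect_true(all(ds$eigenvalues > -1e-10))
  }
})

test_that("admixed population sits between the clusters on axis 1", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 40L), seed = 7)
  ft <- pairwise_fst_table(dat$counts)
  dm <- quantile_distance_matrices(ft)
  dm <- Filter(function(m) any(m > 0), dm)
  ds <- distatis(dm, fst_values = ft$fst, pairs = ft$pairs,
                 levels = as.numeric(names(dm)), n_boot = 50, seed = 8)
  ax1 <- ds$scores[, 1]
  lo <- mean(ax1[1:4]); hi <- ax1[6]; adm <- ax1[5]
  expect_true(adm > min(lo, hi) && adm < max(lo, hi))
  expect_equal(sum(ds$alpha), 1)
  expect_length(ds$ellipses, 6L)
})

test_that("NJ solves the three-point formulas and recovers additive trees", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2; d[1, 3] <- d[3, 1] <- 0.3; d[2, 3] <- d[3, 2] <- 0.4
  rownames(d) <- colnames(d) <- c("A", "B", "C")
  tr <- attr(nj_tree(d), "phylo")
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
  # additive 4-taxon distances: exact recovery of patristic distances
  tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.05);")
  dd <- ape::cophenetic.phylo(tree)
  tr4 <- attr(nj_tree(dd), "phylo")
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(dd), colnames(dd)], dd,
               tolerance = 1e-10)
  expect_true(all(tr4$edge.length >= 0))
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("Mantel statistic is scale invariant with a permutation floor", {
  set.seed(2)
  m1 <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_equal(mantel_test(m1, m1, 99, 1)$r, 1)
  expect_equal(mantel_test(m1, 2 * m1 + 3, 99, 1)$r, 1)
  res <- mantel_test(m1, 2 * m1, 999, 5)
  expect_equal(res$p, 0.001)
  expect_warning(out <- mantel_test(matrix(1, 6, 6), m1), "constant")
  expect_true(is.na(out$r))
})

test_that("f3/f4 match hand arithmetic and the exchange identities", {
  # two loci: pA = (0.5, 0.5), pB = (0.2, 0.9), pC = (0.8, 0.1)
  freq <- cbind(c(0.5, 0.5), c(0.2, 0.9), c(0.8, 0.1))
  f3 <- f_statistic(freq, c(1, 2, 3), "f3", block_size = 1L, correction = FALSE)
  expect_equal(f3$estimate, -0.125)
  # equal target/source frequencies: zero before correction
  freq0 <- cbind(c(0.4, 0.6), c(0.4, 0.6), c(0.1, 0.9))
  expect_equal(f_statistic(freq0, c(1, 2, 3), "f3", block_size = 1L,
                           correction = FALSE)$estimate, 0)
  set.seed(9)
  fr <- matrix(runif(4 * 600), ncol = 4)
  f4 <- function(cfg) f_statistic(fr, cfg, "f4", block_size = 100L)$estimate
  expect_equal(f4(c(1, 2, 3, 4)), -f4(c(2, 1, 3, 4)))
  expect_equal(f4(c(1, 2, 3, 4)), f4(c(3, 4, 1, 2)))
  expect_error(f_statistic(fr[1:50, ], c(1, 2, 3, 4), "f4", block_size = 100L),
               "2 blocks")
})

test_that("configuration enumerators cover all triplets and tetraplets", {
  expect_equal(nrow(f3_configurations(6)), 6 * choose(5, 2))
  expect_equal(nrow(f4_configurations(6)), 3 * choose(6, 4))
  expect_equal(nrow(f4_configurations(6)), 45L)
  expect_equal(anyDuplicated(f3_configurations(6)), 0L)
})

test_that("block jackknife SE approaches the classical SE for iid SNPs", {
  set.seed(10)
  freq <- matrix(runif(3 * 5000), ncol = 3)
  fs <- f_statistic(freq, c(1, 2, 3), "f3", block_size = 500L,
                    correction = FALSE)
  v <- (freq[, 1] - freq[, 2]) * (freq[, 1] - freq[, 3])
  se_classic <- stats::sd(v) / sqrt(length(v))
  expect_gt(fs$se / se_classic, 0.8)
  expect_lt(fs$se / se_classic, 1.2)
})

test_that("admixture scenario yields strongly negative f3 for the mixed pool", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 60L), seed = 31)
  pf <- pool_frequencies(dat$counts)
  f3 <- f_statistic(pf$freq, c(5, 1, 6), "f3", pf$depth, pool_size = 100L)
  expect_lt(f3$z, -3)
  # a non-admixed target should not be negative
  f3b <- f_statistic(pf$freq, c(2, 1, 6), "f3", pf$depth, pool_size = 100L)
  expect_gt(f3b$z, -3)
})
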