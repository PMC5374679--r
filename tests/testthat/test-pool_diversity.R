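test_that("correction factors match direct summation", {
  expect_equal(correction_factors(30, 1)$f_pi, 1)
  cf <- correction_factors(30, 2)
  expect_equal(cf$f_pi, 810 / 870)
  expect_equal(cf$a_w, sum(1 / (1:28)) - 1)
  cf4 <- correction_factors(4, 2)
  expect_equal(cf4$f_pi, 1 / 3)
  expect_equal(cf4$a_w, 0.5)
  expect_error(correction_factors(4, 2.5), "undefined")
  expect_error(diversity_params(target_coverage = 4, min_count = 2))
})

test_that("coverage subsampling is hypergeometric with the boundary rules", {
  expect_equal(subsample_coverage(c(20, 10, 0, 0, 0, 0), 30),
               c(20, 10, 0, 0, 0, 0))
  expect_null(subsample_coverage(c(10, 10, 0, 0, 0, 0), 30))
  set.seed(7)
  m <- matrix(rep(c(60, 30, 0, 0, 0, 0), each = 10000), ncol = 6)
  res <- subsample_coverage(m, 30)
  expect_true(all(rowSums(res$counts) == 30))
  expect_lt(abs(mean(res$counts[, 1]) / 20 - 1), 0.01)
  expect_lt(abs(mean(res$counts[, 2]) / 10 - 1), 0.01)
  expect_error(subsample_coverage(c(1, 0, 0, 0, 0, 0), 0), "positive")
})

test_that("window estimates reproduce hand-evaluated formulas", {
  # single site (15, 15) at M = 30, b = 2 on a length-1 scaffold
  x <- make_sites("s", 1L, list(c(15, 15, 0, 0, 0, 0)))
  wd <- window_diversity(x, diversity_params(window_length = 10L), seed = 1,
                         scaffold_lengths = c(s = 1L))
  h <- (30 / 29) * 0.5
  expect_equal(wd$pi, h / (810 / 870), tolerance = 1e-12)
  expect_equal(wd$S, 1L)
  # monomorphic window
  x0 <- make_sites("s", 5L, list(c(30, 0, 0, 0, 0, 0)))
  wd0 <- window_diversity(x0, diversity_params(window_length = 10L), seed = 1)
  expect_equal(wd0$pi, 0)
  expect_equal(wd0$theta, 0)
  expect_true(is.na(wd0$D))
})

test_that("Tajima's D follows its sign convention and hand example", {
  # two sites at M = 4, b = 1: counts (2,2) and (3,1)
  D <- tajima_d(7 / 6, 2 / (11 / 6), 2, 4, 1)
  expect_equal(D, 0.59, tolerance = 0.01)
  expect_equal(tajima_d(1.5, 1.5, 3, 30, 2), 0)
  expect_true(is.na(tajima_d(1, 1, 1, 30, 2)))
  # sign(D) = sign(pi - theta) over random windows
  set.seed(1)
  for (i in 1:50) {
    p <- runif(1, 0.5, 3); th <- runif(1, 0.5, 3); S <- sample(2:50, 1)
    d <- tajima_d(p, th, S, 30, 2)
    expect_equal(sign(d), sign(p - th))
  }
})

test_that("estimates are invariant under nucleotide relabeling", {
  # totals exactly at target coverage so no subsampling randomness intervenes
  set.seed(2)
  n <- 60L
  cnt <- t(vapply(seq_len(n), function(i)
    c(rmultinom(1, 30, c(0.6, 0.3, 0.07, 0.03))[, 1], 0, 0), numeric(6)))
  x <- site_counts(rep("s", n), seq_len(n), rep("A", n), array(cnt, c(n, 6, 1)))
  perm <- c(3L, 1L, 4L, 2L, 5L, 6L)  # permute A,T,C,G among themselves
  y <- site_counts(x$scaffold, x$pos, x$ref, x$counts[, perm, , drop = FALSE])
  a <- window_diversity(x, seed = 5, scaffold_lengths = c(s = n))
  b <- window_diversity(y, seed = 5, scaffold_lengths = c(s = n))
  expect_equal(a$pi, b$pi)
  expect_equal(a$theta, b$theta)
  expect_equal(a$D, b$D)
})

test_that("with b = 1 and no subsampling loss the classical formulas hold", {
  set.seed(11)
  M <- 30L
  n_sites <- 100L
  cnt <- t(vapply(seq_len(n_sites), function(i) {
    a <- sample(0:M, 1); c(a, M - a, 0, 0, 0, 0)
  }, numeric(6)))
  x <- site_counts(rep("s", n_sites), seq_len(n_sites), rep("A", n_sites),
                   array(cnt, c(n_sites, 6, 1)))
  wd <- window_diversity(x, diversity_params(window_length = n_sites,
                                             min_count = 1L,
                                             target_coverage = M),
                         seed = 1, scaffold_lengths = c(s = n_sites))
  h_oracle <- apply(cnt, 1, function(v) {
    f <- v / sum(v); (M / (M - 1)) * (1 - sum(f^2))
  })
  seg <- apply(cnt, 1, function(v) sum(v >= 1) >= 2)
  expect_equal(wd$pi, sum(h_oracle) / n_sites, tolerance = 1e-12)
  expect_equal(wd$theta, sum(seg) / sum(1 / (1:(M - 1))) / n_sites,
               tolerance = 1e-12)
})

test_that("estimators recover theta on neutral coalescent windows", {
  sim <- simulate_neutral_windows(0.005, 120, 10000, 100, sim_config(), seed = 21)
  wd <- window_diversity(sim$counts, diversity_params(), seed = 22,
                         scaffold_lengths = stats::setNames(
                           rep(10000L, 120), sprintf("win_%04d", 1:120)))
  # unbiasedness: t-test of the window-mean errors against zero at alpha 0.01
  expect_gt(stats::t.test(wd$pi - 0.005)$p.value, 0.01)
  expect_gt(stats::t.test(wd$theta - 0.005)$p.value, 0.01)
})
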