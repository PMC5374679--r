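test_that("snp_fst matches hand values and basic identities", {
  expect_equal(snp_fst(c(15, 15), c(15, 15)), 0)
  expect_equal(snp_fst(c(30, 0), c(0, 30)), 1)
  expect_equal(snp_fst(c(20, 10), c(10, 20)), 0.09578544, tolerance = 1e-7)
  # symmetry and self-comparison
  set.seed(3)
  for (i in 1:20) {
    a <- rmultinom(1, 30, c(0.5, 0.3, 0.1, 0.1))[, 1]
    b <- rmultinom(1, 30, c(0.2, 0.4, 0.2, 0.2))[, 1]
    expect_equal(snp_fst(a, b), snp_fst(b, a))
    expect_equal(snp_fst(a, a), 0, tolerance = 1e-12)
  }
  expect_error(snp_fst(c(0, 0), c(1, 1)), "all-zero")
})

test_that("snp_fst agrees with a brute-force oracle on random tables", {
  oracle <- function(c1, c2) {
    het <- function(v) {
      M <- sum(v)
      (M / (M - 1)) * (1 - sum((v / M)^2))
    }
    ht <- het(c1 + c2)
    if (ht == 0) return(0)
    min(max((ht - (het(c1) + het(c2)) / 2) / ht, 0), 1)
  }
  set.seed(17)
  for (i in 1:1000) {
    c1 <- rmultinom(1, sample(20:120, 1), runif(4))[, 1]
    c2 <- rmultinom(1, sample(20:120, 1), runif(4))[, 1]
    if (sum(c1) == 0 || sum(c2) == 0) next
    expect_equal(snp_fst(c1, c2), oracle(c1, c2), tolerance = 1e-12)
  }
})

test_that("pairwise table filters SNPs and reproduces the cluster ordering", {
  # monomorphic input -> empty SNP set
  x0 <- make_sites("s", 1:2, list(rep(c(30, 0, 0, 0, 0, 0), 2),
                                  rep(c(30, 0, 0, 0, 0, 0), 2)))
  expect_equal(nrow(pairwise_fst_table(x0)$snps), 0L)
  # min-count filter: summed minor count 3 < 4 is not a SNP
  x1 <- make_sites("s", 1L, list(c(c(28, 2, 0, 0, 0, 0), c(29, 1, 0, 0, 0, 0))))
  expect_equal(nrow(pairwise_fst_table(x1)$snps), 0L)
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 30L), seed = 7)
  ft <- pairwise_fst_table(dat$counts)
  pm <- colMeans(ft$fst, na.rm = TRUE)
  within_A <- mean(pm[c("1_2", "1_3", "1_4", "2_3", "2_4", "3_4")])
  a_adm <- mean(pm[c("1_5", "2_5", "3_5", "4_5")])
  a_c <- mean(pm[c("1_6", "2_6", "3_6", "4_6")])
  expect_gt(a_c, a_adm)
  expect_gt(a_adm, within_A)
})

test_that("Fisher allele test is exact with the zero-margin convention", {
  expect_equal(fisher_allele_test(matrix(c(4, 0, 0, 4), 2)), 2 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_allele_test(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_warning(p <- fisher_allele_test(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_equal(p, 1)
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
})

test_that("empirical outliers use type-7 quantiles with inclusive ties", {
  res <- empirical_outliers(1:200, 0.975)
  expect_equal(res$indices, 196:200)
  all_eq <- empirical_outliers(rep(2.5, 40), 0.995)
  expect_equal(all_eq$threshold, 2.5)
  expect_equal(length(all_eq$indices), 40L)
  # saturated distribution: threshold 1.0 and every tie flagged
  v <- c(runif(900, 0, 0.5), rep(1, 100))
  sat <- empirical_outliers(v, 0.995)
  expect_equal(sat$threshold, 1)
  expect_equal(length(sat$indices), 100L)
})

test_that("gene scores average SNP F_ST and report SNP-level recovery", {
  gm <- tiny_gene_models()
  # 2 SNPs in gA with pair-1_2 F_ST 0.2 and 0.4; one intergenic SNP
  x <- make_sites("sc1", c(1100L, 1700L, 3000L),
                  list(c(c(20, 10, 0, 0, 0, 0), c(10, 20, 0, 0, 0, 0)),
                       c(c(25, 5, 0, 0, 0, 0), c(5, 25, 0, 0, 0, 0)),
                       c(c(15, 15, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0))))
  ft <- pairwise_fst_table(x)
  gs <- gene_fst_summary(ft, gm, fst_params(gene_quantile = 0.5),
                         snp_outlier_flags = c(FALSE, TRUE, FALSE))
  expect_equal(gs$gene_table$gene_id, "gA")
  expect_equal(gs$gene_table$score, mean(ft$fst[1:2, "1_2"]))
  expect_true(gs$gene_table$outlier)
  expect_equal(gs$recovery_pct, 100)
})

test_that("SNP classification partitions and respects strand-aware promoters", {
  gm <- tiny_gene_models()
  snps <- data.frame(
    scaffold = "sc1",
    pos = c(1200L,  # exon of gA, not CDS -> exonic
            1700L,  # CDS of gA -> coding
            1500L,  # inside gA between exons -> intronic
            500L,   # 500 bp upstream of gA (+) -> promoter
            250L,   # 750 bp upstream -> intergenic
            6300L,  # 300 bp past gB end; gB is '-' -> promoter
            4500L)) # 500 bp before gB start on '-' strand -> intergenic
  cl <- classify_snps(snps, gm, 600L)
  expect_equal(cl$classes,
               c("exonic", "coding", "intronic", "promoter", "intergenic",
                 "promoter", "intergenic"))
  expect_equal(unname(cl$summary["genic"] + cl$summary["intergenic"]),
               unname(cl$summary["total"]))
  # partition holds on simulated data too
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 10L), seed = 3)
  ft <- pairwise_fst_table(dat$counts)
  cs <- classify_snps(ft$snps, dat$genes)
  expect_equal(unname(cs$summary["genic"] + cs$summary["intergenic"]),
               nrow(ft$snps))
})

test_that("cluster-fixed differences honor the min-count filter and symmetry", {
  fixed_site <- c(c(30, 0, 0, 0, 0, 0), c(28, 0, 0, 0, 0, 0),
                  c(31, 0, 0, 0, 0, 0), c(29, 0, 0, 0, 0, 0),
                  c(15, 15, 0, 0, 0, 0), c(0, 30, 0, 0, 0, 0))
  noisy_fixed <- fixed_site; noisy_fixed[2] <- 1  # one sub-threshold T read in pool 1
  not_fixed <- fixed_site; not_fixed[1:2] <- c(20, 10)
  x <- make_sites("s", 1:3, list(fixed_site, noisy_fixed, not_fixed))
  got <- fixed_between_clusters(x, 1:4, 6L, 4L)
  expect_equal(got, c(1L, 2L))
  expect_equal(fixed_between_clusters(x, 6L, 1:4, 4L), got)
  expect_error(fixed_between_clusters(x, 1:4, 4:6), "disjoint|intersect")
})

test_that("selected loci are enriched among top F_ST outliers", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 60L), seed = 13)
  ft <- pairwise_fst_table(dat$counts)
  so <- snp_outliers(ft, 0.995)
  sel <- dat$truth$selected[match(paste(ft$snps$scaffold, ft$snps$pos),
                                  paste(dat$truth$scaffold, dat$truth$pos))]
  enrich <- mean(sel[so$flag]) / mean(sel)
  expect_gte(enrich, 5)
})

test_that("haplotype locus extraction applies the region and coverage rules", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 12L), seed = 2)
  hr <- simulate_haplotype_reads(dat, n_clusters = 6L, seed = 3)
  hl <- extract_haplotype_loci(hr$reads, hr$snps, seed = 4)
  expect_gt(hl$manifest$n_loci, 0L)
  expect_equal(hl$manifest$n_sequences, hl$manifest$n_loci * 6L * 20L)
  expect_true(all(hl$regions$n_snps >= 3L))
  span <- hl$regions$end - hl$regions$start
  expect_true(all(span < 90L & span >= 20L))
  expect_true(all(table(sapply(hl$loci, `[[`, "scaffold")) == 120L))
  # every emitted sequence spans the full region
  expect_true(all(nchar(sapply(hl$loci, `[[`, "seq")) == rep(span, each = 120L)))
  # 2 SNPs only, or an over-long span, never qualifies
  two_snp <- data.frame(scaffold = "zz", pos = c(100L, 140L))
  expect_equal(extract_haplotype_loci(hr$reads, two_snp, seed = 1)$manifest$n_loci, 0L)
  wide <- data.frame(scaffold = "zz", pos = c(100L, 140L, 194L))
  expect_equal(extract_haplotype_loci(hr$reads, wide, seed = 1)$manifest$n_loci, 0L)
})
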