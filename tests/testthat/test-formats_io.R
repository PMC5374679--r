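test_that("sync parsing maps fields and preserves order", {
  tmp <- withr::local_tempfile()
  writeLines(c("sc1\t10\tA\t10:20:0:0:0:0\t30:0:0:0:0:0",
               "sc2\t5\tC\t0:0:15:15:0:0\t1:2:3:4:5:6"), tmp)
  x <- parse_sync(tmp, 2)
  expect_equal(length(x), 2L)
  expect_equal(x$scaffold, c("sc1", "sc2"))
  expect_equal(x$pos, c(10L, 5L))
  expect_equal(unname(x$counts[1, , 1]), c(10, 20, 0, 0, 0, 0))
  expect_equal(unname(x$counts[1, , 2]), c(30, 0, 0, 0, 0, 0))
  expect_equal(unname(x$counts[2, , 2]), c(1, 2, 3, 4, 5, 6))
})

test_that("sync parser rejects malformed input with a line number", {
  tmp <- withr::local_tempfile()
  writeLines(c("sc1\t10\tA\t1:1:0:0:0:0", "sc1\tnotanumber\tA\t1:1:0:0:0:0"), tmp)
  expect_error(parse_sync(tmp, 1), "line 2")
  writeLines("sc1\t10\tA\t1:1:0:0:0", tmp)
  expect_error(parse_sync(tmp, 1), "sextet")
  writeLines("sc1\t10\tA\t1:1:0:0:0:0\t2:0:0:0:0:0", tmp)
  expect_error(parse_sync(tmp, 3), "pool count mismatch")
})

test_that("empty sync file yields an empty table", {
  tmp <- withr::local_tempfile()
  writeLines(character(0), tmp)
  x <- parse_sync(tmp, 4)
  expect_equal(length(x), 0L)
  expect_equal(x$n_pools, 4L)
})

test_that("write/parse round-trip is the identity on generator output", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 5L), seed = 42)
  tmp <- withr::local_tempfile()
  write_sync(dat$counts, tmp)
  back <- parse_sync(tmp, dat$counts$n_pools)
  expect_equal(back$scaffold, dat$counts$scaffold)
  expect_equal(back$pos, dat$counts$pos)
  expect_equal(back$counts, dat$counts$counts, ignore_attr = TRUE)
  tmp2 <- withr::local_tempfile()
  write_sync(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("region mask removes covered sites, is idempotent, empty mask is identity", {
  x <- make_sites("sc1", c(4L, 10L, 20L),
                  list(c(5, 0, 0, 0, 0, 0), c(5, 0, 0, 0, 0, 0),
                       c(5, 0, 0, 0, 0, 0)))
  m <- region_mask("sc1", 5, 15)  # covers 0-based 5..14 = 1-based 6..15
  y <- apply_region_mask(x, m)
  expect_equal(y$pos, c(4L, 20L))
  expect_equal(apply_region_mask(y, m)$pos, y$pos)
  expect_equal(apply_region_mask(x, region_mask())$pos, x$pos)
  # whole-scaffold mask empties the scaffold
  all_m <- region_mask("sc1", 0, 100)
  expect_equal(length(apply_region_mask(x, all_m)), 0L)
  expect_error(region_mask("sc1", 10, 10), "start < end")
})

test_that("masking commutes with scaffold-wise partitioning", {
  dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 6L), seed = 9)
  x <- dat$counts
  m <- region_mask(rep(unique(x$scaffold)[1:3], each = 2),
                   rep(c(0, 4000), 3), rep(c(2000, 7000), 3))
  whole <- apply_region_mask(x, m)
  parts <- lapply(unique(x$scaffold), function(sc)
    suppressWarnings(apply_region_mask(subset_sites(x, x$scaffold == sc), m)))
  expect_equal(whole$pos, unlist(lapply(parts, `[[`, "pos")))
})

test_that("GFF3 gene models load with exon/CDS containment", {
  gff <- withr::local_tempfile()
  writeLines(c("##gff-version 3",
               "sc1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=g1",
               "sc1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=t1;Parent=g1",
               "sc1\ttest\texon\t1000\t2000\t.\t+\t.\tParent=t1",
               "sc1\ttest\tCDS\t1100\t1900\t.\t+\t0\tParent=t1"), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$genes$gene_id, "g1")
  expect_equal(gm$exons$gene_id, "g1")
  expect_equal(gm$exons$start, 1000L)
  expect_equal(gm$cds$end, 1900L)
})

test_that("OBO parsing builds the is_a graph and rejects cycles", {
  obo <- withr::local_tempfile()
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root", "namespace: bp", "",
               "[Term]", "id: GO:2", "name: child", "namespace: bp",
               "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:9", "name: gone", "is_obsolete: true"), obo)
  expect_message(ont <- read_obo(obo), "obsolete")
  expect_setequal(ont$terms$id, c("GO:1", "GO:2"))
  expect_equal(ont$parents[["GO:2"]], "GO:1")
  writeLines(c("[Term]", "id: GO:1", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "is_a: GO:1"), obo)
  expect_error(read_obo(obo), "cyclic")
})

test_that("load_annotation drops unknown terms and reports unplaced genes", {
  gff <- withr::local_tempfile(); obo <- withr::local_tempfile()
  g2g <- withr::local_tempfile()
  writeLines(c("##gff-version 3",
               "sc1\tt\tgene\t100\t200\t.\t+\t.\tID=g1"), gff)
  writeLines(c("[Term]", "id: GO:1", "name: root", "namespace: bp"), obo)
  writeLines(c("g1\tGO:1", "g1\tGO:999", "ghost\tGO:1"), g2g)
  expect_warning(
    expect_message(res <- load_annotation(gff, obo, g2g), "absent from the GFF"),
    "unknown terms")
  expect_equal(nrow(res$annotation), 2L)
  expect_true("ghost" %in% res$annotation$gene)
})
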