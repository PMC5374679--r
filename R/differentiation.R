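#' Parameters for the F_ST differentiation scan
#'
#' @param min_count minimum summed-across-pools minor-allele count for a site
#'   to count as a SNP (alleles below it are treated as absent).
#' @param snp_quantile empirical quantile defining per-SNP outliers.
#' @param gene_quantile empirical quantile defining per-gene outliers.
#' @param alpha family-wise error rate for the Bonferroni-corrected Fisher
#'   tests over population pairs.
#' @param promoter_length length (bp) of the 5'-flanking region counted as
#'   promoter, strand-aware.
#' @param gene_score how a gene's score aggregates its per-pair mean F_ST:
#'   maximum over pairs, mean over pairs, or one specific pair.
#' @param pair pair column name (e.g. "1_6") when `gene_score = "pair"`.
#' @return an `fst_params` list.
#' @export
fst_params <- function(min_count = 4L, snp_quantile = 0.995,
                       gene_quantile = 0.95, alpha = 0.05,
                       promoter_length = 600L,
                       gene_score = c("max", "mean", "pair"), pair = NULL) {
  gene_score <- match.arg(gene_score)
  stopifnot(min_count >= 1L, snp_quantile > 0, snp_quantile < 1,
            gene_quantile > 0, gene_quantile < 1)
  structure(list(min_count = as.integer(min_count), snp_quantile = snp_quantile,
                 gene_quantile = gene_quantile, alpha = alpha,
                 promoter_length = as.integer(promoter_length),
                 gene_score = gene_score, pair = pair),
            class = "fst_params")
}

unbiased_het <- function(counts) {
  # counts: vector or matrix (sites x alleles); (M/(M-1)) * (1 - sum f^2)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  M <- rowSums(counts)
  f2 <- rowSums(counts^2) / M^2
  h <- M / (M - 1) * (1 - f2)
  h[M <= 1] <- 0
  h
}

#' Per-SNP pairwise F_ST from pooled counts
#'
#' The heterozygosity-based estimator used by sliding-window Pool-seq scans:
#' `F_ST = (pi_total - pi_within) / pi_total` with
#' `pi_within = (h1 + h2)/2`, `pi_total` the unbiased heterozygosity
#' `(M/(M-1)) (1 - sum f^2)` of the summed counts. Returns 0 when
#' `pi_total = 0`; negative finite-sample values are clamped to 0 and values
#' above 1 to 1.
#'
#' @param counts_pop1,counts_pop2 count vectors (any allele dimension) for the
#'   two pools at one site, or matrices (sites x alleles) for vectorized use.
#' @return F_ST value(s) in `[0, 1]`.
#' @export
snp_fst <- function(counts_pop1, counts_pop2) {
  if (is.null(dim(counts_pop1))) counts_pop1 <- matrix(counts_pop1, nrow = 1L)
  if (is.null(dim(counts_pop2))) counts_pop2 <- matrix(counts_pop2, nrow = 1L)
  if (any(rowSums(counts_pop1) == 0) || any(rowSums(counts_pop2) == 0))
    stop("all-zero counts: F_ST undefined")
  h1 <- unbiased_het(counts_pop1)
  h2 <- unbiased_het(counts_pop2)
  ht <- unbiased_het(counts_pop1 + counts_pop2)
  fst <- ifelse(ht == 0, 0, (ht - (h1 + h2) / 2) / ht)
  out <- pmin(pmax(fst, 0), 1)
  if (length(out) == 1L) out[[1L]] else out
}

# keep A/C/G/T alleles whose summed-across-pools count reaches min_count;
# returns list(mat = sites x 4 x pools array of filtered counts,
#              is_snp = >= 2 surviving alleles)
filter_alleles <- function(x, min_count) {
  acgt <- x$counts[, c("A", "T", "C", "G"), , drop = FALSE]
  tot <- apply(acgt, c(1L, 2L), sum)
  if (is.null(dim(tot))) tot <- matrix(tot, nrow = 1L)
  keep <- tot >= min_count
  arr <- acgt
  for (k in seq_len(dim(acgt)[3L]))
    arr[, , k] <- acgt[, , k] * keep
  list(counts = arr, n_alleles = rowSums(keep),
       allele_order = t(apply(tot, 1L, order, decreasing = TRUE)))
}

#' Pairwise F_ST table over all SNPs
#'
#' SNPs are sites with at least two A/C/G/T alleles whose summed-across-pools
#' counts reach `params$min_count`; [snp_fst()] is evaluated for every pool
#' pair on the filtered counts.
#'
#' @param x a [site_counts] object.
#' @param params an [fst_params].
#' @return an `fst_table`: list with `snps` (data.frame scaffold, pos, major,
#'   minor), `fst` (SNPs x pairs matrix, columns `i_j`), `pairs` (2-column
#'   matrix of pool indices), and `n_clamped` (negative estimates set to 0).
#' @export
pairwise_fst_table <- function(x, params = fst_params()) {
  stopifnot(inherits(x, "site_counts"))
  flt <- filter_alleles(x, params$min_count)
  is_snp <- flt$n_alleles >= 2L
  P <- x$n_pools
  pairs <- t(utils::combn(P, 2L))
  snp_idx <- which(is_snp)
  n <- length(snp_idx)
  fst <- matrix(NA_real_, n, nrow(pairs),
                dimnames = list(NULL, paste(pairs[, 1L], pairs[, 2L], sep = "_")))
  n_clamped <- 0L
  if (n > 0L) {
    cnt <- flt$counts[snp_idx, , , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      c1 <- cnt[, , pairs[j, 1L], drop = FALSE]; dim(c1) <- dim(c1)[1:2]
      c2 <- cnt[, , pairs[j, 2L], drop = FALSE]; dim(c2) <- dim(c2)[1:2]
      ok <- rowSums(c1) > 0 & rowSums(c2) > 0
      h1 <- unbiased_het(c1); h2 <- unbiased_het(c2); ht <- unbiased_het(c1 + c2)
      v <- ifelse(ht == 0, 0, (ht - (h1 + h2) / 2) / ht)
      n_clamped <- n_clamped + sum(v < 0, na.rm = TRUE)
      v <- pmin(pmax(v, 0), 1)
      v[!ok] <- NA_real_
      fst[, j] <- v
    }
  }
  base4 <- c("A", "T", "C", "G")
  structure(list(
    snps = data.frame(scaffold = x$scaffold[snp_idx], pos = x$pos[snp_idx],
                      major = base4[flt$allele_order[snp_idx, 1L]],
                      minor = base4[flt$allele_order[snp_idx, 2L]],
                      stringsAsFactors = FALSE),
    fst = fst, pairs = pairs, n_clamped = n_clamped),
    class = "fst_table")
}

#' @export
print.fst_table <- function(x, ...) {
  cat(sprintf("fst_table: %d SNPs, %d pool pairs (mean F_ST %.4g)\n",
              nrow(x$snps), nrow(x$pairs), mean(x$fst, na.rm = TRUE)))
  invisible(x)
}

#' Fisher's exact test of allele-frequency difference
#'
#' Exact two-sided p for a 2x2 allele-count table by summing hypergeometric
#' probabilities no larger than the observed table's.
#'
#' @param tab 2x2 matrix of allele counts (pools x alleles).
#' @return two-sided p-value; a zero margin yields `p = 1` with a warning.
#' @export
fisher_allele_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(round(tab))$p.value
}

#' Bonferroni-corrected per-test threshold
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return per-test significance threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) alpha / n_tests

#' Empirical outlier detection by quantile tail
#'
#' @param values numeric vector.
#' @param q quantile level (type-7 sample quantile); values greater than or
#'   equal to the threshold (ties included) are flagged.
#' @return list with `threshold` and `indices`.
#' @export
empirical_outliers <- function(values, q) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values")
  thr <- stats::quantile(v, q, type = 7, names = FALSE)
  list(threshold = thr, indices = which(values >= thr))
}

#' Per-SNP outlier flags from the pooled F_ST distribution
#'
#' The empirical threshold is taken on the pooled distribution over all
#' pairwise values; a SNP is flagged when any of its pair values reaches it.
#'
#' @param fst_tab an `fst_table`.
#' @param q quantile level.
#' @return list with `threshold` and logical `flag` over the table's SNPs.
#' @export
snp_outliers <- function(fst_tab, q = 0.995) {
  pooled <- as.numeric(fst_tab$fst)
  res <- empirical_outliers(pooled, q)
  flag <- apply(fst_tab$fst >= res$threshold, 1L, any, na.rm = TRUE)
  list(threshold = res$threshold, flag = flag)
}

snp_gene_map <- function(snps, genes) {
  g <- genes$genes
  sites <- GenomicRanges::GRanges(snps$scaffold, IRanges::IRanges(snps$pos, width = 1L))
  gr <- GenomicRanges::GRanges(g$scaffold, IRanges::IRanges(g$start, g$end))
  hits <- GenomicRanges::findOverlaps(sites, gr)
  data.frame(snp = S4Vectors::queryHits(hits),
             gene = g$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Per-gene F_ST summary and outlier tail
#'
#' For each gene and pool pair, the mean F_ST over the SNPs it contains; the
#' gene score aggregates pairs per `params$gene_score` (maximum by default)
#' and the upper tail at `params$gene_quantile` is flagged. When SNP-level
#' outlier flags are supplied, the fraction of gene-level outliers recovered
#' by the SNP-level gene list is reported.
#'
#' @param fst_tab an `fst_table` from [pairwise_fst_table()].
#' @param genes a `gene_models` object.
#' @param params an [fst_params].
#' @param snp_outlier_flags optional logical vector over the table's SNPs.
#' @return list with `gene_table` (gene_id, n_snps, score, outlier) and
#'   `recovery_pct` (`NA` without SNP flags).
#' @export
gene_fst_summary <- function(fst_tab, genes, params = fst_params(),
                             snp_outlier_flags = NULL) {
  map <- snp_gene_map(fst_tab$snps, genes)
  if (nrow(map) == 0L)
    return(list(gene_table = data.frame(gene_id = character(), n_snps = integer(),
                                        score = numeric(), outlier = logical()),
                recovery_pct = NA_real_))
  per_gene <- split(map$snp, map$gene)
  score_one <- function(idx) {
    m <- colMeans(fst_tab$fst[idx, , drop = FALSE], na.rm = TRUE)
    switch(params$gene_score,
           max = max(m, na.rm = TRUE),
           mean = mean(m, na.rm = TRUE),
           pair = m[[params$pair]])
  }
  score <- vapply(per_gene, score_one, numeric(1))
  res <- empirical_outliers(score, params$gene_quantile)
  gene_table <- data.frame(gene_id = names(per_gene),
                           n_snps = lengths(per_gene),
                           score = unname(score),
                           outlier = seq_along(score) %in% res$indices,
                           stringsAsFactors = FALSE)
  recovery <- NA_real_
  if (!is.null(snp_outlier_flags)) {
    snp_genes <- unique(map$gene[map$snp %in% which(snp_outlier_flags)])
    out_genes <- gene_table$gene_id[gene_table$outlier]
    if (length(out_genes))
      recovery <- 100 * length(intersect(out_genes, snp_genes)) / length(out_genes)
  }
  list(gene_table = gene_table, recovery_pct = recovery,
       threshold = res$threshold)
}

#' Classify SNPs by genomic feature
#'
#' Each SNP gets exactly one top-level class (genic or intergenic). Genic SNPs
#' are subclassified coding (in a CDS), exonic (in an exon but no CDS) or
#' intronic; intergenic SNPs within `promoter_length` bp upstream of a gene
#' start (strand-aware) are flagged as promoter SNPs. A SNP overlapping any
#' gene is genic regardless of promoter proximity.
#'
#' @param snps data.frame with columns scaffold, pos.
#' @param genes a `gene_models` object.
#' @param promoter_length promoter window in bp.
#' @return list with `classes` (character vector: "coding", "exonic",
#'   "intronic", "promoter", "intergenic") and `summary` (named counts with
#'   `genic + intergenic == total`).
#' @export
classify_snps <- function(snps, genes, promoter_length = 600L) {
  g <- genes$genes
  sites <- GenomicRanges::GRanges(snps$scaffold, IRanges::IRanges(snps$pos, width = 1L))
  ov <- function(df, scaffold) {
    if (is.null(df) || nrow(df) == 0L) return(rep(FALSE, length(sites)))
    IRanges::overlapsAny(sites, GenomicRanges::GRanges(
      scaffold, IRanges::IRanges(df$start, df$end)))
  }
  genic <- ov(g, g$scaffold)
  ex_sc <- g$scaffold[match(genes$exons$gene_id, g$gene_id)]
  cd_sc <- g$scaffold[match(genes$cds$gene_id, g$gene_id)]
  in_exon <- ov(genes$exons, ex_sc)
  in_cds <- ov(genes$cds, cd_sc)
  prom_start <- ifelse(g$strand == "+", pmax(1L, g$start - promoter_length), g$end + 1L)
  prom_end <- ifelse(g$strand == "+", g$start - 1L, g$end + promoter_length)
  okp <- prom_end >= prom_start
  in_prom <- IRanges::overlapsAny(sites, GenomicRanges::GRanges(
    g$scaffold[okp], IRanges::IRanges(prom_start[okp], prom_end[okp])))
  cls <- ifelse(genic,
                ifelse(in_cds, "coding", ifelse(in_exon, "exonic", "intronic")),
                ifelse(in_prom, "promoter", "intergenic"))
  summary <- c(total = length(cls),
               genic = sum(genic),
               coding = sum(cls == "coding"),
               exonic = sum(cls %in% c("coding", "exonic")),
               intronic = sum(cls == "intronic"),
               intergenic = sum(!genic),
               promoter = sum(cls == "promoter"))
  list(classes = cls, summary = summary)
}

#' SNPs differentially fixed between two pool clusters
#'
#' Within each cluster, alleles whose cluster-summed read count is below
#' `min_count` are treated as sequencing noise and zeroed (so a stray
#' singleton read does not break fixation). A SNP is differentially fixed
#' when one allele is then the only one present in every pool of cluster A
#' and a different allele is the only one in every pool of cluster B;
#' equivalently all A x B pairwise F_ST values equal 1.
#'
#' @param x a [site_counts] object.
#' @param pools_a,pools_b disjoint pool index vectors.
#' @param min_count within-cluster minor-allele count filter.
#' @return integer vector of site indices.
#' @export
fixed_between_clusters <- function(x, pools_a, pools_b, min_count = 4L) {
  stopifnot(length(intersect(pools_a, pools_b)) == 0L,
            length(pools_a) > 0L, length(pools_b) > 0L)
  acgt <- x$counts[, c("A", "T", "C", "G"), , drop = FALSE]
  n <- length(x$pos)
  fixed_allele <- function(pools) {
    # cluster-level noise filter, then require a single shared allele
    tot <- matrix(0, n, 4L)
    for (k in pools) {
      m <- acgt[, , k, drop = FALSE]; dim(m) <- dim(m)[1:2]
      tot <- tot + m
    }
    keep <- tot >= min_count
    res <- matrix(TRUE, n, 4L)
    for (k in pools) {
      m <- acgt[, , k, drop = FALSE]; dim(m) <- dim(m)[1:2]
      m <- m * keep
      s <- rowSums(m)
      res <- res & (m == s) & (s > 0)
    }
    res
  }
  fixA <- fixed_allele(pools_a)
  fixB <- fixed_allele(pools_b)
  fixed <- rowSums(fixA) == 1L & rowSums(fixB) == 1L &
    rowSums(fixA & fixB) == 0L
  which(fixed)
}

#' Extract short multi-SNP haplotype loci from a read table
#'
#' Scans each scaffold for the leftmost maximal run of SNPs spanning fewer
#' than `max_span` bp with at least `min_snps` SNPs and span at least
#' `min_len` bp; collects the reads fully spanning that region per
#' population, requires spanning coverage within `[min_cov, max_cov]` in
#' every population, and samples `n_hap` read-backed haplotypes per
#' population (seeded).
#'
#' @param reads data.frame: scaffold, start (0-based), seq, pop.
#' @param snps data.frame: scaffold, pos (1-based).
#' @param n_hap haplotypes sampled per population per locus.
#' @param min_snps,max_span,min_len,min_cov,max_cov region filters.
#' @param seed integer seed for the haplotype sampling.
#' @return a `haplotype_loci` object: list of per-sequence records plus a
#'   `manifest` (n_loci, total_bp, n_sequences) and `dropped` log.
#' @export
extract_haplotype_loci <- function(reads, snps, n_hap = 20L, min_snps = 3L,
                                   max_span = 90L, min_len = 20L,
                                   min_cov = 15L, max_cov = 100L, seed = 1L) {
  set.seed(seed)
  pops <- sort(unique(reads$pop))
  loci <- list(); dropped <- character(0)
  region_meta <- list()
  li <- 0L
  for (sc in unique(snps$scaffold)) {
    p <- sort(snps$pos[snps$scaffold == sc])
    region <- NULL
    i <- 1L
    while (i <= length(p)) {
      j <- i
      while (j < length(p) && p[j + 1L] - p[i] + 1L < max_span) j <- j + 1L
      span <- p[j] - p[i] + 1L
      if (j - i + 1L >= min_snps && span < max_span && span >= min_len) {
        region <- c(p[i], p[j])
        break  # leftmost qualifying region only
      }
      i <- i + 1L
    }
    if (is.null(region)) next
    r_start0 <- region[1L] - 1L; r_end0 <- region[2L]  # 0-based half-open
    rr <- reads[reads$scaffold == sc, , drop = FALSE]
    span_read <- rr$start <= r_start0 & rr$start + nchar(rr$seq) >= r_end0
    rr <- rr[span_read, , drop = FALSE]
    cov <- table(factor(rr$pop, levels = pops))
    if (any(cov < min_cov) || any(cov > max_cov)) {
      dropped <- c(dropped, sprintf("%s: spanning coverage outside [%d, %d]",
                                    sc, min_cov, max_cov))
      next
    }
    if (any(cov < n_hap)) {
      dropped <- c(dropped, sprintf("%s: fewer than %d spanning reads", sc, n_hap))
      next
    }
    li <- li + 1L
    locus_id <- sprintf("locus_%03d", li)
    region_meta[[li]] <- data.frame(locus_id = locus_id, scaffold = sc,
                                    start = r_start0, end = r_end0,
                                    n_snps = sum(p >= region[1L] & p <= region[2L]),
                                    stringsAsFactors = FALSE)
    for (pp in pops) {
      sel <- rr[rr$pop == pp, , drop = FALSE]
      sel <- sel[sample.int(nrow(sel), n_hap), , drop = FALSE]
      for (r in seq_len(n_hap)) {
        off <- r_start0 - sel$start[r] + 1L
        loci[[length(loci) + 1L]] <- list(
          locus_id = locus_id, scaffold = sc, start = r_start0, end = r_end0,
          pop = pp, replicate = r,
          seq = substr(sel$seq[r], off, off + (r_end0 - r_start0) - 1L))
      }
    }
  }
  regions <- if (li > 0L) do.call(rbind, region_meta) else
    data.frame(locus_id = character(), scaffold = character(), start = integer(),
               end = integer(), n_snps = integer())
  structure(list(
    loci = loci, regions = regions, dropped = dropped,
    manifest = list(n_loci = li,
                    total_bp = sum(regions$end - regions$start),
                    n_sequences = li * length(pops) * n_hap)),
    class = "haplotype_loci")
}
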