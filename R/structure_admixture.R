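#' Quantile distance matrices from per-SNP pairwise F_ST
#'
#' Reduces the full per-SNP distribution of pairwise F_ST values to a small
#' set of symmetric population-by-population distance matrices, one per sample
#' quantile level (type-7), zero on the diagonal.
#'
#' @param fst_tab an `fst_table` from [pairwise_fst_table()], or a numeric
#'   SNPs x pairs matrix with a matching `pairs` argument.
#' @param levels quantile levels.
#' @param pairs 2-column matrix of pool indices (taken from `fst_tab` when it
#'   is an `fst_table`).
#' @return list of P x P matrices, one per level, named by level.
#' @export
quantile_distance_matrices <- function(fst_tab,
                                       levels = c(0.975, 0.75, 0.5, 0.25, 0.025),
                                       pairs = NULL) {
  if (inherits(fst_tab, "fst_table")) {
    vals <- fst_tab$fst
    pairs <- fst_tab$pairs
  } else vals <- fst_tab
  stopifnot(!is.null(pairs), ncol(vals) == nrow(pairs))
  P <- max(pairs)
  out <- lapply(levels, function(q) {
    m <- matrix(0, P, P)
    for (j in seq_len(nrow(pairs))) {
      v <- vals[, j]
      v <- v[is.finite(v)]
      if (!length(v)) stop("pair with no SNPs: ", paste(pairs[j, ], collapse = "-"))
      d <- stats::quantile(v, q, type = 7, names = FALSE)
      m[pairs[j, 1L], pairs[j, 2L]] <- m[pairs[j, 2L], pairs[j, 1L]] <- d
    }
    m
  })
  names(out) <- as.character(levels)
  out
}

# double-centered cross-product of a dissimilarity matrix, normalized by its
# first eigenvalue
cross_product <- function(D, normalize = TRUE) {
  P <- nrow(D)
  J <- diag(P) - matrix(1 / P, P, P)
  S <- -0.5 * J %*% D %*% J
  if (normalize) {
    l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1L]
    if (l1 <= 0) stop("degenerate (non-informative) distance matrix")
    S <- S / l1
  }
  (S + t(S)) / 2
}

rv_coefficient <- function(S1, S2) {
  sum(S1 * S2) / sqrt(sum(S1 * S1) * sum(S2 * S2))
}

#' DISTATIS: compromise ordination of several distance matrices
#'
#' Each matrix is double-centered (`S_k = -1/2 J D_k J`) and normalized by its
#' first eigenvalue; matrix weights are the first eigenvector of the
#' RV-coefficient similarity matrix rescaled to sum one; the compromise
#' `S+ = sum alpha_k S_k` is eigendecomposed and factor scores are the
#' eigenvectors scaled by the square roots of the eigenvalues. When the
#' SNP-level F_ST values are supplied, SNPs are bootstrap-resampled, the
#' quantile matrices rebuilt, projected into the compromise space, and 95%
#' normal-approximation ellipses fitted per population on the first two axes.
#'
#' @param dmats list of symmetric zero-diagonal distance matrices (the
#'   quantile set).
#' @param fst_values optional SNPs x pairs matrix for the bootstrap.
#' @param pairs pool-index pairs matching `fst_values` columns.
#' @param levels quantile levels used to rebuild matrices in the bootstrap.
#' @param n_boot bootstrap resamples (0 disables).
#' @param seed integer seed.
#' @return a `distatis` object: `alpha` (weights), `compromise`, `eigenvalues`,
#'   `scores` (populations x axes), `rv` (matrix), and optionally `boot`
#'   (list of bootstrap score arrays) and `ellipses` (per population: center,
#'   covariance, 95% radius scale).
#' @export
distatis <- function(dmats, fst_values = NULL, pairs = NULL,
                     levels = c(0.975, 0.75, 0.5, 0.25, 0.025),
                     n_boot = 1000L, seed = 1L) {
  stopifnot(length(dmats) >= 2L)
  S <- lapply(dmats, cross_product)
  K <- length(S)
  C <- matrix(1, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    C[i, j] <- rv_coefficient(S[[i]], S[[j]])
  ev <- eigen(C, symmetric = TRUE)
  a <- ev$vectors[, 1L]
  if (sum(a) < 0) a <- -a
  alpha <- a / sum(a)
  Sp <- Reduce(`+`, Map(`*`, S, alpha))
  dec <- eigen(Sp, symmetric = TRUE)
  keep <- dec$values > 1e-12
  scores <- dec$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(dec$values[keep]), sum(keep))
  rownames(scores) <- rownames(dmats[[1L]])
  out <- list(alpha = alpha, compromise = Sp, eigenvalues = dec$values,
              scores = scores, rv = C)
  if (!is.null(fst_values) && n_boot > 0L) {
    set.seed(seed)
    proj <- dec$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(dec$values[keep]), sum(keep))
    P <- nrow(Sp)
    n_snp <- nrow(fst_values)
    boot <- array(NA_real_, c(P, 2L, n_boot))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n_snp, n_snp, replace = TRUE)
      dm_b <- quantile_distance_matrices(fst_values[idx, , drop = FALSE],
                                         levels = levels, pairs = pairs)
      # an all-zero resampled matrix carries no information; leave unnormalized
      S_b <- lapply(dm_b, function(D)
        tryCatch(cross_product(D), error = function(e) cross_product(D, FALSE)))
      Sp_b <- Reduce(`+`, Map(`*`, S_b, alpha))
      boot[, , bi] <- (Sp_b %*% proj)[, 1:2]
    }
    r2 <- sqrt(stats::qchisq(0.95, df = 2L))
    ellipses <- lapply(seq_len(P), function(i) {
      pts <- t(boot[i, , ])
      list(center = colMeans(pts), cov = stats::cov(pts), radius = r2)
    })
    names(ellipses) <- rownames(scores)
    out$boot <- boot
    out$ellipses <- ellipses
  }
  class(out) <- "distatis"
  out
}

#' @export
print.distatis <- function(x, ...) {
  cat(sprintf("DISTATIS compromise of %d matrices; axis-1 inertia %.1f%%\n",
              length(x$alpha),
              100 * x$eigenvalues[1L] / sum(pmax(x$eigenvalues, 0))))
  cat("weights:", sprintf("%.3f", x$alpha), "\n")
  invisible(x)
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard NJ agglomeration (via \pkg{ape}); any negative branch length is
#' set to zero and its magnitude transferred to the adjacent (sister) edge,
#' preserving patristic distances where possible.
#'
#' @param d symmetric zero-diagonal distance matrix (P >= 3).
#' @param labels tip labels (defaults to rownames).
#' @return Newick string (also returns the `phylo` object as attribute
#'   `"phylo"`).
#' @export
nj_tree <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  P <- nrow(d)
  if (P < 3L) stop("need at least 3 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(P))
  rownames(d) <- colnames(d) <- labels
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    excess <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sisters <- which(tr$edge[, 1L] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters))
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] + excess
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles with a permutation p-value
#' `(count + 1) / (n_perm + 1)` over row/column permutations.
#'
#' @param m1,m2 symmetric matrices of equal dimension.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r` and `p` (`r = NA` for a constant matrix).
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = 1L) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  stopifnot(all(dim(m1) == dim(m2)))
  v1 <- m1[upper.tri(m1)]; v2 <- m2[upper.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  set.seed(seed)
  r_obs <- stats::cor(v1, v2)
  P <- nrow(m1)
  count <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(P)
    while (all(perm == seq_len(P))) perm <- sample.int(P)  # observed added via +1
    mp <- m2[perm, perm]
    if (stats::cor(v1, mp[upper.tri(mp)]) >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (count + 1) / (n_perm + 1))
}

#' Per-SNP pool frequencies of the minor allele
#'
#' Applies the summed-across-pools allele-count filter and returns, for every
#' SNP, the per-pool frequency of the globally minor allele together with the
#' per-pool read depths.
#'
#' @param x a [site_counts] object.
#' @param min_count summed minor-allele count filter.
#' @return list with `freq` and `depth` (SNPs x pools matrices), `snp_index`
#'   (row indices into `x`), and `snps` (scaffold/pos data.frame).
#' @export
pool_frequencies <- function(x, min_count = 4L) {
  flt <- filter_alleles(x, min_count)
  is_snp <- flt$n_alleles >= 2L
  idx <- which(is_snp)
  P <- x$n_pools
  freq <- depth <- matrix(NA_real_, length(idx), P)
  for (k in seq_len(P)) {
    cnt <- flt$counts[idx, , k, drop = FALSE]; dim(cnt) <- dim(cnt)[1:2]
    tot <- rowSums(cnt)
    minor_col <- flt$allele_order[idx, 2L]
    focal <- cnt[cbind(seq_along(idx), minor_col)]
    freq[, k] <- ifelse(tot > 0, focal / tot, NA_real_)
    depth[, k] <- tot
  }
  list(freq = freq, depth = depth, snp_index = idx,
       snps = data.frame(scaffold = x$scaffold[idx], pos = x$pos[idx]))
}

# delete-one block jackknife over consecutive blocks
block_jackknife <- function(values, block_size) {
  n <- length(values)
  g <- ceiling(n / block_size)
  if (g < 2L) stop("need at least 2 blocks")
  blocks <- split(values, ceiling(seq_len(n) / block_size))
  total <- sum(values)
  est_minus <- vapply(blocks, function(bl) (total - sum(bl)) / (n - length(bl)),
                      numeric(1))
  theta_bar <- mean(est_minus)
  se <- sqrt((g - 1) / g * sum((est_minus - theta_bar)^2))
  list(estimate = total / n, se = se, n_blocks = g)
}

#' f3 and f4 admixture statistics with block jackknife
#'
#' `f3(A; B, C)` is the mean over SNPs of `(pA - pB)(pA - pC)` minus a
#' finite-sampling correction for the variance of the estimated target
#' frequency: `pA(1-pA)/(M_A - 1)` from read sampling, plus
#' `pA(1-pA)(1 - 1/M_A)/n` from pool sampling when the pool size `n` is given.
#' `f4(A, B; C, D)` is the mean of `(pA - pB)(pC - pD)` (no correction).
#' Standard errors come from a delete-one block jackknife over consecutive
#' SNP blocks; a significantly negative f3 z-score indicates the target is
#' admixed between sources related to B and C.
#'
#' @param freq SNPs x pools matrix of allele frequencies.
#' @param config for "f3": `c(target, source1, source2)` pool indices; for
#'   "f4": `c(A, B, C, D)`.
#' @param type "f3" or "f4".
#' @param depth optional SNPs x pools read-depth matrix (enables the read
#'   correction).
#' @param pool_size optional haploid pool size (enables the pool-sampling
#'   correction term).
#' @param block_size SNPs per jackknife block.
#' @param correction apply the finite-sampling correction to f3.
#' @return an `f_stat` list: type, config, estimate, se, z, n_blocks.
#' @export
f_statistic <- function(freq, config, type = c("f3", "f4"), depth = NULL,
                        pool_size = NULL, block_size = 500L, correction = TRUE) {
  type <- match.arg(type)
  keep <- stats::complete.cases(freq[, config, drop = FALSE])
  freq <- freq[keep, , drop = FALSE]
  if (!is.null(depth)) depth <- depth[keep, , drop = FALSE]
  if (type == "f3") {
    a <- freq[, config[1L]]; b <- freq[, config[2L]]; c_ <- freq[, config[3L]]
    v <- (a - b) * (a - c_)
    if (correction && !is.null(depth)) {
      M <- depth[, config[1L]]
      corr <- a * (1 - a) / (M - 1)
      if (!is.null(pool_size))
        corr <- corr + a * (1 - a) * (1 - 1 / M) / pool_size
      v <- v - corr
    }
  } else {
    stopifnot(length(config) == 4L)
    v <- (freq[, config[1L]] - freq[, config[2L]]) *
      (freq[, config[3L]] - freq[, config[4L]])
  }
  jk <- block_jackknife(v, block_size)
  structure(list(type = type, config = config, estimate = jk$estimate,
                 se = jk$se, z = jk$estimate / jk$se, n_blocks = jk$n_blocks),
            class = "f_stat")
}

#' @export
print.f_stat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.5g  SE %.3g  z %.2f\n", x$type,
              paste(x$config, collapse = ","), x$estimate, x$se, x$z))
  invisible(x)
}

#' All f3 population configurations
#'
#' Every choice of a target pool and an unordered pair of sources:
#' `P * choose(P-1, 2)` tests.
#'
#' @param P number of pools.
#' @return matrix with columns target, source1, source2.
#' @export
f3_configurations <- function(P) {
  out <- list()
  for (a in seq_len(P)) {
    rest <- setdiff(seq_len(P), a)
    cmb <- utils::combn(rest, 2L)
    out[[a]] <- cbind(a, t(cmb))
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("target", "source1", "source2")
  m
}

#' All f4 population configurations
#'
#' The three distinct pairings of each 4-pool subset: `3 * choose(P, 4)`
#' tests.
#'
#' @param P number of pools.
#' @return matrix with columns A, B, C, D.
#' @export
f4_configurations <- function(P) {
  quads <- utils::combn(P, 4L)
  out <- list()
  for (j in seq_len(ncol(quads))) {
    q <- quads[, j]
    out[[j]] <- rbind(q[c(1, 2, 3, 4)], q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)])
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("A", "B", "C", "D")
  m
}

#' Run every f3 and f4 test on a frequency matrix
#'
#' @inheritParams f_statistic
#' @return data.frame: type, populations, estimate, se, z.
#' @export
f_statistics_all <- function(freq, depth = NULL, pool_size = NULL,
                             block_size = 500L, correction = TRUE) {
  P <- ncol(freq)
  rows <- list()
  cfg3 <- f3_configurations(P)
  for (i in seq_len(nrow(cfg3))) {
    fs <- f_statistic(freq, cfg3[i, ], "f3", depth, pool_size, block_size,
                      correction)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "f3", populations = paste(cfg3[i, ], collapse = ";"),
      estimate = fs$estimate, se = fs$se, z = fs$z, stringsAsFactors = FALSE)
  }
  cfg4 <- f4_configurations(P)
  for (i in seq_len(nrow(cfg4))) {
    fs <- f_statistic(freq, cfg4[i, ], "f4", block_size = block_size)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "f4", populations = paste(cfg4[i, ], collapse = ";"),
      estimate = fs$estimate, se = fs$se, z = fs$z, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
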