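#' Parameters for window-based pooled diversity estimation
#'
#' @param window_length non-overlapping window length L in bp.
#' @param min_count minimum allele count b after subsampling; an allele with
#'   fewer reads is treated as absent.
#' @param target_coverage uniform coverage M* each site is subsampled to
#'   (without replacement); sites below it are excluded.
#' @param min_usable_fraction windows with fewer usable sites than this
#'   fraction of L are reported with `NA` estimates.
#' @return a `diversity_params` list.
#' @export
diversity_params <- function(window_length = 10000L, min_count = 2L,
                             target_coverage = 30L, min_usable_fraction = 0.5) {
  stopifnot(min_count >= 1L, target_coverage > 2L * min_count, window_length > 0L)
  structure(list(window_length = as.integer(window_length),
                 min_count = as.integer(min_count),
                 target_coverage = as.integer(target_coverage),
                 min_usable_fraction = min_usable_fraction),
            class = "diversity_params")
}

#' Truncation correction factors for pooled estimators
#'
#' With reads subsampled to uniform coverage `M` and alleles below count `b`
#' discarded, the usable part of the neutral site-frequency spectrum is the
#' range `[b, M - b]`. The heterozygosity correction is
#' `f_pi(M, b) = 2/(M(M-1)) * sum_{i=b}^{M-b} (M - i)` and the Watterson
#' denominator is the truncated harmonic sum `a_W(M, b) = sum_{i=b}^{M-b} 1/i`;
#' `f_pi(M, 1) = 1` recovers the classical estimator.
#'
#' @param M uniform coverage (> 2b).
#' @param b minimum allele count.
#' @return list with `f_pi` and `a_w`.
#' @export
correction_factors <- function(M, b) {
  stopifnot(b >= 1)
  if (M < 2 * b) stop("correction factors undefined for M < 2b")
  i <- b:(M - b)
  list(f_pi = 2 / (M * (M - 1)) * sum(M - i), a_w = sum(1 / i))
}

#' Subsample one pool's counts to a target coverage
#'
#' Draws `M` reads without replacement (multivariate hypergeometric over the
#' six base categories). Counts at exactly `M` are returned unchanged; sites
#' below `M` are reported as excluded.
#'
#' @param counts sextet of counts (A,T,C,G,N,del) or a sites x 6 matrix.
#' @param M target coverage.
#' @return for a vector input, the subsampled sextet or `NULL` when excluded;
#'   for a matrix, a list with `counts` (matrix) and `excluded` (logical).
#' @export
subsample_coverage <- function(counts, M) {
  if (M <= 0) stop("target coverage must be positive")
  vec <- is.null(dim(counts))
  if (vec) counts <- matrix(counts, nrow = 1L)
  tot <- rowSums(counts)
  excluded <- tot < M
  out <- counts
  over <- which(tot > M)
  if (length(over)) {
    sub <- counts[over, , drop = FALSE]
    res <- matrix(0, nrow(sub), 6L)
    remaining_k <- rep(M, nrow(sub))
    remaining_n <- rowSums(sub)
    for (j in 1:6) {
      x <- stats::rhyper(nrow(sub), sub[, j], remaining_n - sub[, j], remaining_k)
      res[, j] <- x
      remaining_k <- remaining_k - x
      remaining_n <- remaining_n - sub[, j]
    }
    out[over, ] <- res
  }
  out[excluded, ] <- NA_real_
  if (vec) {
    if (excluded[1L]) return(NULL)
    return(out[1L, ])
  }
  list(counts = out, excluded = excluded)
}

# Tajima's D for one window from corrected totals.
# pi_w and theta_w are window totals (sum of corrected per-site values),
# S the segregating-site count, M the uniform coverage, b the min count.
# Variance uses the classical Tajima constants at sample size M with a1
# replaced by the truncated harmonic sum a_W(M, b).

#' Tajima's D with truncation-adjusted constants
#'
#' @param pi_w corrected window total of heterozygosity (pi * usable length).
#' @param theta_w corrected window total of Watterson's theta.
#' @param S number of segregating sites.
#' @param M uniform coverage.
#' @param b minimum allele count.
#' @return D, or `NA` when `S < 2`.
#' @export
tajima_d <- function(pi_w, theta_w, S, M, b = 1L) {
  if (is.na(S) || S < 2) return(NA_real_)
  n <- M
  a1 <- correction_factors(M, b)$a_w
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_w - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site heterozygosity over alleles passing the min count, on subsampled
# counts; frequencies renormalized over passing alleles
site_het <- function(counts, b) {
  pass <- counts >= b
  pass[is.na(pass)] <- FALSE
  tot <- rowSums(counts * pass)
  M <- rowSums(counts)
  f2 <- rowSums((counts * pass)^2) / tot^2
  h <- M / (M - 1) * (1 - f2)
  h[tot == 0] <- 0
  h
}

#' Window-based pooled diversity estimates
#'
#' Per non-overlapping window and population: each listed site is subsampled to
#' the target coverage `M*`; a site is segregating when at least two alleles
#' each reach the min count `b` after subsampling; the corrected estimates are
#' `pi = sum(h) / (f_pi(M*, b) * L_usable)` and
#' `theta_W = S / (a_W(M*, b) * L_usable)`, with Tajima's D from [tajima_d()].
#'
#' Sites absent from the table are treated as covered invariant sites, so
#' `L_usable` is the window length minus listed sites excluded by the coverage
#' rule (the table is assumed to list every variant site).
#'
#' @param x a [site_counts] object.
#' @param params a [diversity_params].
#' @param seed seed for the subsampling draws.
#' @param scaffold_lengths optional named vector of scaffold lengths; when
#'   missing, each scaffold extends to its last listed site.
#' @return data.frame: scaffold, start, end, pop, pi, theta, D, S,
#'   usable_sites. Windows under the usable fraction carry `NA` estimates.
#' @export
window_diversity <- function(x, params = diversity_params(), seed = 1L,
                             scaffold_lengths = NULL) {
  stopifnot(inherits(x, "site_counts"), inherits(params, "diversity_params"))
  set.seed(seed)
  L <- params$window_length
  b <- params$min_count
  M <- params$target_coverage
  cf <- correction_factors(M, b)
  scaffs <- unique(x$scaffold)
  out <- list(); oi <- 0L
  for (k in seq_len(x$n_pools)) {
    mat <- x$counts[, , k, drop = FALSE]
    dim(mat) <- dim(mat)[1:2]
    sub <- subsample_coverage(mat, M)
    h <- site_het(sub$counts, b)
    pass_cnt <- sub$counts >= b
    pass_cnt[is.na(pass_cnt)] <- FALSE
    seg <- rowSums(pass_cnt) >= 2L
    for (sc in scaffs) {
      in_sc <- x$scaffold == sc
      sc_len <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
        scaffold_lengths[[sc]] else max(x$pos[in_sc])
      n_win <- ceiling(sc_len / L)
      wi <- (x$pos[in_sc] - 1L) %/% L
      for (w in seq_len(n_win) - 1L) {
        sel <- which(in_sc)[wi == w]
        win_len <- min(L, sc_len - w * L)
        excl <- sum(sub$excluded[sel])
        usable <- win_len - excl
        S <- sum(seg[sel] & !sub$excluded[sel])
        pi_tot <- sum(h[sel][!sub$excluded[sel]]) / cf$f_pi
        th_tot <- S / cf$a_w
        oi <- oi + 1L
        if (usable < params$min_usable_fraction * win_len) {
          out[[oi]] <- data.frame(scaffold = sc, start = w * L + 1L,
                                  end = w * L + win_len, pop = k,
                                  pi = NA_real_, theta = NA_real_, D = NA_real_,
                                  S = NA_integer_, usable_sites = usable,
                                  stringsAsFactors = FALSE)
          next
        }
        out[[oi]] <- data.frame(scaffold = sc, start = w * L + 1L,
                                end = w * L + win_len, pop = k,
                                pi = pi_tot / usable, theta = th_tot / usable,
                                D = tajima_d(pi_tot, th_tot, S, M, b),
                                S = S, usable_sites = usable,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
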