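#' Composite environmental axis by PCA
#'
#' Standardizes the variables (dropping constant ones with a warning), reports
#' their correlation matrix, and returns the first principal component scores
#' as the composite axis (`env1`) together with the fraction of variance it
#' explains. The sign is fixed so that env1 correlates positively with the
#' first retained variable (altitude, when present as the first column).
#'
#' @param env populations x variables numeric matrix.
#' @return an `env_composite` list: `scores` (env1, zero mean), `loadings`,
#'   `var_fraction`, `correlations`.
#' @export
env_pca <- function(env) {
  stopifnot(is.matrix(env), nrow(env) >= 3L, ncol(env) >= 2L)
  sds <- apply(env, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant variable(s) dropped")
    env <- env[, sds > 0, drop = FALSE]
  }
  z <- scale(env)
  cors <- stats::cor(z)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  if (stats::cor(scores, z[, 1L]) < 0) {
    scores <- -scores; loadings <- -loadings
  }
  structure(list(scores = scores, loadings = loadings,
                 var_fraction = pc$sdev[1L]^2 / sum(pc$sdev^2),
                 correlations = cors),
            class = "env_composite")
}

#' @export
print.env_composite <- function(x, ...) {
  cat(sprintf("env1: first PC explaining %.1f%% of variance over %d variables\n",
              100 * x$var_fraction, length(x$loadings)))
  invisible(x)
}

# standardized deviation vectors for a set of SNP frequencies:
# x_k = (p_k - pbar) / sqrt(pbar (1 - pbar))
standardized_deviations <- function(freq) {
  pbar <- rowMeans(freq)
  sweep(freq - pbar, 1L, sqrt(pbar * (1 - pbar)), "/")
}

project_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
}

#' Neutral among-population covariance matrix
#'
#' Method-of-moments analogue of the Bayenv reference matrix: for each of
#' `n_snps` randomly subsampled polymorphic SNPs, the standardized deviation
#' vector `x = (p - pbar) / sqrt(pbar(1-pbar))` contributes `x x'`; the
#' average is projected to the nearest positive semi-definite matrix. The
#' binomial read-sampling variance `phat(1-phat)/(depth-1)` is subtracted from
#' the diagonal contribution so the matrix reflects among-population structure
#' rather than sequencing noise. A second seeded subsample yields a
#' convergence metric (max absolute difference of the two correlation forms).
#'
#' @param x a [site_counts] object, or a list with `freq` and `depth` matrices
#'   as returned by [pool_frequencies()].
#' @param n_snps SNPs per subsample.
#' @param seed integer seed.
#' @param min_count SNP allele-count filter (when `x` is a [site_counts]).
#' @return a `covariance_model` list: `omega`, `omega_repl`, `convergence`,
#'   `n_snps`.
#' @export
estimate_covariance <- function(x, n_snps = 10000L, seed = 1L, min_count = 4L) {
  pf <- if (inherits(x, "site_counts")) pool_frequencies(x, min_count) else x
  freq <- pf$freq; depth <- pf$depth
  poly <- which(stats::complete.cases(freq) &
                  apply(freq, 1L, function(p) any(p > 0) && any(p < 1)))
  if (length(poly) < 50L) stop("fewer than 50 polymorphic SNPs")
  set.seed(seed)
  one <- function(idx) {
    f <- freq[idx, , drop = FALSE]
    d <- depth[idx, , drop = FALSE]
    pbar <- rowMeans(f)
    xs <- standardized_deviations(f)
    om <- crossprod(xs) / nrow(xs)
    # remove the expected read-noise contribution (diagonal, standardized)
    noise <- colMeans(f * (1 - f) / ((d - 1) * pbar * (1 - pbar)))
    project_psd(om - diag(noise) * (1 - 1 / ncol(f)))
  }
  pick <- function() {
    if (length(poly) <= n_snps) {
      if (length(poly) < n_snps)
        warning("fewer polymorphic SNPs than requested; using all")
      poly
    } else sample(poly, n_snps)
  }
  om1 <- one(pick())
  om2 <- one(pick())
  corr <- function(m) {
    d <- sqrt(pmax(diag(m), 1e-12))
    m / tcrossprod(d)
  }
  structure(list(omega = om1, omega_repl = om2,
                 convergence = max(abs(corr(om1) - corr(om2))),
                 n_snps = min(n_snps, length(poly))),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("covariance_model over %d pools (%d SNPs; convergence %.4f)\n",
              nrow(x$omega), x$n_snps, x$convergence))
  invisible(x)
}

#' Covariance-controlled environmental association scores
#'
#' For each SNP, observed pool frequencies are modeled as
#' `p = alpha 1 + beta env1 + eps` with
#' `eps ~ N(0, sigma2 Omega + diag(read noise))`, `sigma2 = pbar(1-pbar)`.
#' The intercept is integrated out analytically (flat prior) and the
#' posterior over `beta` is computed on a symmetric grid under a zero-centered
#' normal prior whose +-3 SD span the frequency range implied by the
#' environmental spread. The support statistic is
#' `Z = |P(beta > 0 | data) - 0.5|`, bounded by 0.5, and the Bayes factor is
#' the marginal likelihood ratio of the free-beta model against `beta = 0`.
#'
#' @param freq SNPs x pools frequency matrix.
#' @param depth SNPs x pools read depth matrix.
#' @param model a `covariance_model` (or a P x P matrix).
#' @param env an `env_composite` (or a numeric vector of env1 scores).
#' @param grid_points grid size (odd; default 401).
#' @param ridge diagonal regularization added when Omega is singular.
#' @return data.frame per SNP: `beta_hat` (posterior mean), `z_support`
#'   (the bounded Z statistic), `bf`, `post_pos` (`P(beta > 0 | data)`),
#'   `rank` (by `z_support * bf`, 1 = strongest).
#' @export
env_score <- function(freq, depth, model, env, grid_points = 401L,
                      ridge = 1e-6) {
  omega <- if (inherits(model, "covariance_model")) model$omega else model
  e <- if (inherits(env, "env_composite")) env$scores else env
  e <- e - mean(e)
  P <- length(e)
  stopifnot(ncol(freq) == P, all(dim(omega) == P))
  if (rcond(omega) < 1e-10) omega <- omega + diag(ridge, P)
  n <- nrow(freq)
  # prior scale: +-3 SD of beta spans the full frequency range over the env span
  env_span <- diff(range(e))
  prior_sd <- 1 / (3 * env_span)
  beta_grid <- seq(-4 * prior_sd, 4 * prior_sd, length.out = grid_points)
  zero_j <- which.min(abs(beta_grid))
  beta_grid[zero_j] <- 0   # guard against floating-point drift of the midpoint
  log_prior <- stats::dnorm(beta_grid, 0, prior_sd, log = TRUE)

  pbar <- rowMeans(freq)
  sigma2 <- pbar * (1 - pbar)
  ones <- rep(1, P)
  a <- b <- cc <- d <- f <- g <- ldet <- numeric(n)
  for (i in seq_len(n)) {
    noise <- freq[i, ] * (1 - freq[i, ]) / pmax(depth[i, ], 2)
    Sig <- sigma2[i] * omega + diag(noise + ridge, P)
    ch <- chol(Sig)
    Si1 <- backsolve(ch, forwardsolve(t(ch), ones))
    Sie <- backsolve(ch, forwardsolve(t(ch), e))
    Sip <- backsolve(ch, forwardsolve(t(ch), freq[i, ]))
    a[i] <- sum(ones * Si1); b[i] <- sum(ones * Sie); cc[i] <- sum(e * Sie)
    d[i] <- sum(ones * Sip); f[i] <- sum(e * Sip); g[i] <- sum(freq[i, ] * Sip)
    ldet[i] <- 2 * sum(log(diag(ch)))
  }
  # marginal log-likelihood over alpha (flat prior) at each grid beta:
  # -1/2 [ log|Sig| + log(a) + r'Si r - (1'Si r)^2 / a ],  r = p - beta e
  # r'Si r = g - 2 beta f + beta^2 c ;  1'Si r = d - beta b
  ll <- matrix(NA_real_, n, grid_points)
  for (j in seq_len(grid_points)) {
    bt <- beta_grid[j]
    q <- g - 2 * bt * f + bt^2 * cc - (d - bt * b)^2 / a
    ll[, j] <- -0.5 * (ldet + log(a) + q)
  }
  lp <- sweep(ll, 2L, log_prior, `+`)
  lmax <- apply(lp, 1L, max)
  w <- exp(lp - lmax)
  wsum <- rowSums(w)
  post <- w / wsum
  pos <- beta_grid > 0
  post_pos <- rowSums(post[, pos, drop = FALSE]) +
    0.5 * post[, zero_j]
  z_support <- abs(post_pos - 0.5)
  beta_hat <- as.numeric(post %*% beta_grid)
  # BF: prior-weighted mean likelihood / likelihood at beta = 0
  prior_w <- exp(log_prior - max(log_prior))
  prior_w <- prior_w / sum(prior_w)
  log_marg <- lmax + log(rowSums(exp(ll - lmax) %*% diag(prior_w)))
  bf <- exp(log_marg - ll[, zero_j])
  score <- z_support * bf
  data.frame(beta_hat = beta_hat, z_support = z_support, bf = bf,
             post_pos = post_pos,
             rank = rank(-score, ties.method = "first"))
}

#' Overlap between two candidate SNP sets
#'
#' @param env_top identifiers of the environmental-association candidates.
#' @param fst_top identifiers of the F_ST outlier candidates.
#' @return list: `n_overlap`, `pct` (100 * overlap / |env_top|, 2 decimals).
#' @export
overlap_report <- function(env_top, fst_top) {
  if (!length(env_top)) {
    warning("empty candidate set: percentage undefined")
    return(list(n_overlap = 0L, pct = NA_real_))
  }
  n <- length(intersect(env_top, fst_top))
  list(n_overlap = n, pct = round(100 * n / length(env_top), 2))
}
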