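#' Exact Mann-Whitney U test
#'
#' U is the number of (x, y) pairs with `x > y` (ties count one half). Without
#' ties and with `n_x * n_y <= 10000`, the two-sided p-value is exact: twice
#' the smaller one-sided tail of the U distribution, capped at 1. With ties
#' (or larger samples) a normal approximation with tie correction is used,
#' with a warning.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p`.
#' @export
mann_whitney_exact <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # pairs with x > y (+ half-ties)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx * ny <= 10000) {
    lower <- stats::pwilcox(U, nx, ny)
    upper <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  } else {
    if (ties) warning("ties present: normal approximation with tie correction")
    n <- nx + ny
    tie_tab <- table(c(x, y))
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Welch's unequal-variance t-test
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return list with `t`, `df`, `p`; all `NA` (flagged) when both samples have
#'   zero variance.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("zero variance in both groups: t undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Polynomial response curve of net photosynthesis against water content
#'
#' Least-squares polynomial fit of a gas-exchange trait (e.g. net
#' photosynthesis, NP) against thallus water content (WC), with the optimum
#' (WC at maximum fitted NP over the observed range) and the WC interval where
#' the fitted curve stays at or above 90% of its maximum — the
#' optimal-water-saturation criterion.
#'
#' @param wc water content values (mm precipitation equivalent).
#' @param np trait values (e.g. CO2 exchange).
#' @param degree polynomial degree (default 3); reduced with a warning when
#'   the design is ill-conditioned.
#' @param level fraction of the maximum defining the optimum interval.
#' @return a `response_curve` list: `coefficients`, `degree`, `r_squared`,
#'   `wc_opt`, `np_max`, `interval` (WC range with NP >= level * max),
#'   `fitted` function.
#' @export
fit_response_curve <- function(wc, np, degree = 3L, level = 0.9) {
  stopifnot(length(wc) == length(np), length(wc) >= degree + 2L)
  deg <- degree
  fit <- NULL
  while (deg >= 2L) {
    fit <- stats::lm(np ~ stats::poly(wc, deg, raw = TRUE))
    if (!anyNA(stats::coef(fit))) break
    warning("ill-conditioned fit: degree reduced to ", deg - 1L)
    deg <- deg - 1L
  }
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  pred <- function(x) {
    X <- outer(x, 0:deg, `^`)
    as.numeric(X %*% cf)
  }
  grid <- seq(min(wc), max(wc), length.out = 2001L)
  fx <- pred(grid)
  i_max <- which.max(fx)
  np_max <- fx[i_max]
  wc_opt <- grid[i_max]
  above <- fx >= level * np_max
  interval <- range(grid[above])
  structure(list(coefficients = cf, degree = deg, r_squared = r2,
                 wc_opt = wc_opt, np_max = np_max, interval = interval,
                 level = level, fitted = pred),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(paste0("degree-%d response curve: r^2 = %.3f, max %.3g at WC ",
                     "%.3g, %.0f%%-of-max WC range [%.3g, %.3g]\n"),
              x$degree, x$r_squared, x$np_max, x$wc_opt, 100 * x$level,
              x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Compare response-curve optima between two groups
#'
#' Fits per-sample curves and summarizes each group's optimum water content
#' (mean +- SD), the highland-versus-lowland style contrast.
#'
#' @param data data.frame with columns sample, group, wc, np.
#' @param degree polynomial degree passed to [fit_response_curve()].
#' @return data.frame per group: n, mean_wc_opt, sd_wc_opt, mean_np_max.
#' @export
compare_response_curves <- function(data, degree = 3L) {
  per_sample <- lapply(split(data, data$sample), function(d)
    data.frame(group = d$group[1L],
               t(unlist(fit_response_curve(d$wc, d$np, degree)[
                 c("wc_opt", "np_max")]))))
  df <- do.call(rbind, per_sample)
  agg <- lapply(split(df, df$group), function(d)
    data.frame(group = d$group[1L], n = nrow(d),
               mean_wc_opt = mean(d$wc_opt), sd_wc_opt = stats::sd(d$wc_opt),
               mean_np_max = mean(d$np_max), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Per-population trait summaries (mean +- SD)
#'
#' @param data tidy data.frame with columns population, trait, value.
#' @return data.frame: population, trait, n, mean, sd.
#' @export
trait_summary <- function(data) {
  sp <- split(data, list(data$population, data$trait), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(population = d$population[1L], trait = d$trait[1L],
               n = nrow(d), mean = mean(d$value), sd = stats::sd(d$value),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$trait, out$population), ]
}
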