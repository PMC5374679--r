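#' Simulation configuration for the clinal Pool-seq design
#'
#' Defaults emulate the sampled study design: six population pools of 100
#' haploid individuals each, sequenced at ~90x mean coverage, arranged along an
#' altitudinal gradient with two diverged genetic clusters (pools 1-4 versus
#' pool 6) and one admixed pool (5), plus a minority of loci whose frequencies
#' track the gradient.
#'
#' @param n_pools number of population pools.
#' @param pool_size haploid individuals per pool.
#' @param coverage mean sequencing depth per pool (Poisson).
#' @param error_rate per-base sequencing error rate; an erroneous read reports
#'   a uniformly chosen other base.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_mean_length mean scaffold length in bp (log-normal lengths).
#' @param cluster character vector of length `n_pools` with values "A", "C" or
#'   "admixed" assigning each pool to a genetic cluster.
#' @param f_div Balding-Nichols drift between the ancestral population and each
#'   cluster.
#' @param f_pop Balding-Nichols drift of each pool around its cluster frequency
#'   (for the admixed pool: around the mixture frequency, i.e. drift since
#'   admixture).
#' @param lambda_mix admixture proportion of cluster A in the admixed pool.
#' @param snp_density expected SNPs per bp.
#' @param frac_selected fraction of loci under clinal selection.
#' @param beta_env logit-scale environmental effect size at selected loci, per
#'   unit of standardized altitude.
#' @param altitude altitudes (m) of the pools, low to high along the cline.
#' @param n_env_covariates number of bioclimatic covariates generated as linear
#'   functions of altitude plus noise.
#' @param env_noise_sd standard deviation of that noise on the standardized
#'   scale (0.15 keeps the first principal component above 95% of variance).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pools = 6L, pool_size = 100L, coverage = 90,
                       error_rate = 0.002, n_scaffolds = 200L,
                       scaffold_mean_length = 10000,
                       cluster = c("A", "A", "A", "A", "admixed", "C"),
                       f_div = 0.1, f_pop = 0.01, lambda_mix = 0.5,
                       snp_density = 0.02, frac_selected = 0.01,
                       beta_env = 2, altitude = c(176, 297, 588, 842, 1125, 1303),
                       n_env_covariates = 19L, env_noise_sd = 0.15) {
  stopifnot(length(cluster) == n_pools, length(altitude) == n_pools,
            coverage > 0, f_div > 0, f_div < 1, f_pop >= 0, f_pop < 1,
            lambda_mix >= 0, lambda_mix <= 1,
            error_rate >= 0, error_rate <= 1,
            frac_selected >= 0, frac_selected <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols draw: Beta with mean p and variance F*p*(1-p)
rbn <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Turn per-pool allele frequencies into pooled read-count sextets
#'
#' Two-stage sampling: the allele count among the `pool_size` pooled haploid
#' individuals is Binomial(n, p); reads are then drawn Binomial(coverage,
#' count/n), and each read is substituted by a uniformly chosen other base with
#' probability `error_rate`.
#'
#' @param freqs numeric vector (one frequency per pool) or matrix
#'   (sites x pools) of focal-allele frequencies.
#' @param config a [sim_config].
#' @param ref,alt base identities of the non-focal and focal allele; vectors
#'   recycled over sites.
#' @param coverage optional matrix of per-site, per-pool depths; drawn
#'   Poisson(`config$coverage`) when `NULL`.
#' @return numeric array sites x 6 x pools of base counts (A,T,C,G,N,del).
#' @export
pool_reads_from_frequencies <- function(freqs, config, ref = "A", alt = "T",
                                        coverage = NULL) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)
  stopifnot(all(freqs >= 0 & freqs <= 1))
  n_sites <- nrow(freqs); P <- ncol(freqs)
  n <- config$pool_size; e <- config$error_rate
  ref <- rep_len(match(toupper(ref), BASES), n_sites)
  alt <- rep_len(match(toupper(alt), BASES), n_sites)
  if (is.null(coverage))
    coverage <- matrix(stats::rpois(n_sites * P, config$coverage), n_sites, P)
  counts <- array(0, c(n_sites, 6L, P), dimnames = list(NULL, BASES, NULL))
  for (k in seq_len(P)) {
    pool_cnt <- stats::rbinom(n_sites, n, freqs[, k])
    alt_reads <- stats::rbinom(n_sites, coverage[, k], pool_cnt / n)
    ref_reads <- coverage[, k] - alt_reads
    for (src in list(list(base = alt, n = alt_reads),
                     list(base = ref, n = ref_reads))) {
      err <- if (e > 0) stats::rbinom(n_sites, src$n, e) else 0L
      keep <- src$n - err
      idx <- cbind(seq_len(n_sites), src$base, k)
      counts[idx] <- counts[idx] + keep
      if (any(err > 0)) {
        # split errors uniformly over the three other A/C/G/T bases
        OTHERS <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
        others <- t(OTHERS[src$base, , drop = FALSE])
        b1 <- stats::rbinom(n_sites, err, 1 / 3)
        b2 <- stats::rbinom(n_sites, err - b1, 1 / 2)
        b3 <- err - b1 - b2
        for (j in 1:3) {
          bj <- list(b1, b2, b3)[[j]]
          idx2 <- cbind(seq_len(n_sites), others[j, ], k)
          counts[idx2] <- counts[idx2] + bj
        }
      }
    }
  }
  counts
}

#' Simulate a clinal Pool-seq experiment
#'
#' Hierarchical Balding-Nichols frequency model: an ancestral frequency
#' p0 ~ Uniform(0.05, 0.95) per SNP; cluster frequencies drawn around p0 with
#' drift `f_div`; per-pool frequencies drawn around the cluster frequency with
#' drift `f_pop`; the admixed pool mixes the two cluster frequencies with
#' proportion `lambda_mix` before its own drift. Selected loci receive an
#' additive logit shift `beta_env * env_k`. Pooled counts follow
#' [pool_reads_from_frequencies()]. Deterministic under a fixed seed.
#'
#' @param config a [sim_config].
#' @param seed integer seed.
#' @return a list with elements `counts` ([site_counts]), `genes`
#'   (`gene_models`), `ontology`, `annotation` (gene->term data.frame), `env`
#'   (populations x variables matrix, first column altitude), `truth`
#'   (per-SNP data.frame: scaffold, pos, ref, alt, p0, selected, plus the true
#'   per-pool frequency matrix `freq`), `scaffold_lengths`, and `config`.
#' @export
simulate_gradient_experiment <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  P <- config$n_pools
  if (config$f_pop <= 0 && config$frac_selected > 0)
    warning("f_pop = 0 with selected loci requested; proceeding")

  # genome
  sl <- pmax(2000L, round(stats::rlnorm(config$n_scaffolds,
                                        log(config$scaffold_mean_length) - 0.125,
                                        0.5)))
  scaff <- sprintf("scaffold_%03d", seq_len(config$n_scaffolds))
  n_snp_per <- stats::rpois(config$n_scaffolds, sl * config$snp_density)
  n_snp_per <- pmin(n_snp_per, sl)
  scaffold <- rep(scaff, n_snp_per)
  pos <- unlist(lapply(seq_len(config$n_scaffolds), function(i)
    sort(sample.int(sl[i], n_snp_per[i]))), use.names = FALSE)
  L <- length(pos)

  # environment: standardized altitude drives everything
  env_std <- as.numeric(scale(config$altitude))
  env <- synthetic_env_table(config, env_std)

  # frequencies
  p0 <- stats::runif(L, 0.05, 0.95)
  pA <- rbn(p0, config$f_div)
  pC <- rbn(p0, config$f_div)
  freq <- matrix(NA_real_, L, P)
  for (k in seq_len(P)) {
    base <- switch(config$cluster[k],
                   A = pA, C = pC,
                   admixed = config$lambda_mix * pA + (1 - config$lambda_mix) * pC)
    freq[, k] <- rbn(base, config$f_pop)
  }
  selected <- stats::runif(L) < config$frac_selected
  if (any(selected)) {
    shift <- outer(rep(config$beta_env, sum(selected)), env_std)
    freq[selected, ] <- inv_logit(logit(pmin(pmax(freq[selected, , drop = FALSE],
                                                  1e-6), 1 - 1e-6)) + shift)
  }

  # alleles and counts
  ref_i <- sample.int(4L, L, replace = TRUE)
  alt_i <- vapply(ref_i, function(r) sample(setdiff(1:4, r), 1L), integer(1))
  counts <- pool_reads_from_frequencies(freq, config,
                                        ref = BASES[ref_i], alt = BASES[alt_i])
  x <- site_counts(scaffold, pos, BASES[ref_i], counts)

  genes <- synthetic_gene_models(scaff, sl)
  ann <- synthetic_ontology(genes$genes$gene_id)
  truth <- data.frame(scaffold = scaffold, pos = pos,
                      ref = BASES[ref_i], alt = BASES[alt_i],
                      p0 = p0, selected = selected, stringsAsFactors = FALSE)
  truth$freq <- freq
  list(counts = x, genes = genes, ontology = ann$ontology,
       annotation = ann$annotation, env = env, truth = truth,
       scaffold_lengths = stats::setNames(sl, scaff), config = config)
}

# altitude plus n correlated bioclim-like covariates (linear in altitude with
# standardized noise sd env_noise_sd)
synthetic_env_table <- function(config, env_std = NULL) {
  if (is.null(env_std)) env_std <- as.numeric(scale(config$altitude))
  P <- config$n_pools
  m <- matrix(NA_real_, P, config$n_env_covariates)
  for (j in seq_len(config$n_env_covariates)) {
    slope <- sample(c(-1, 1), 1L) * stats::runif(1, 0.8, 1.2)
    m[, j] <- slope * env_std + stats::rnorm(P, 0, config$env_noise_sd)
  }
  out <- cbind(altitude = config$altitude, m)
  colnames(out) <- c("altitude", sprintf("bio%02d", seq_len(config$n_env_covariates)))
  rownames(out) <- sprintf("pool%d", seq_len(P))
  out
}

# uniform synthetic gene models: one gene per 5 kb, 2 exons, CDS inside exons
synthetic_gene_models <- function(scaffolds, lengths) {
  genes <- exons <- cds <- list()
  gi <- 0L
  for (i in seq_along(scaffolds)) {
    n_genes <- max(0L, floor(lengths[i] / 5000))
    for (g in seq_len(n_genes)) {
      gi <- gi + 1L
      start <- (g - 1L) * 5000L + 1001L
      end <- start + 1999L
      id <- sprintf("gene_%05d", gi)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      genes[[gi]] <- data.frame(gene_id = id, scaffold = scaffolds[i],
                                strand = strand, start = start, end = end,
                                stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(gene_id = id,
                                start = c(start, start + 1200L),
                                end = c(start + 799L, end),
                                stringsAsFactors = FALSE)
      cds[[gi]] <- data.frame(gene_id = id,
                              start = c(start + 100L, start + 1200L),
                              end = c(start + 799L, end - 200L),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(genes = do.call(rbind, genes),
                 exons = do.call(rbind, exons),
                 cds = do.call(rbind, cds)),
            class = "gene_models")
}

# 3-level synthetic DAG: 1 root, 5 mid terms, 20 leaves; genes annotate leaves
synthetic_ontology <- function(gene_ids, n_mid = 5L, n_leaf = 20L) {
  root <- "SYN:0000001"
  mid <- sprintf("SYN:00001%02d", seq_len(n_mid))
  leaf <- sprintf("SYN:00002%02d", seq_len(n_leaf))
  parents <- c(stats::setNames(list(character(0)), root),
               stats::setNames(lapply(mid, function(m) root), mid),
               stats::setNames(lapply(seq_len(n_leaf), function(i)
                 mid[1L + (i - 1L) %% n_mid]), leaf))
  ont <- structure(list(
    terms = data.frame(id = c(root, mid, leaf),
                       name = paste("synthetic term", seq_len(1L + n_mid + n_leaf)),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = parents), class = "ontology")
  n_ann <- pmin(2L, n_leaf)
  annotation <- do.call(rbind, lapply(gene_ids, function(g)
    data.frame(gene = g, term = sample(leaf, n_ann), stringsAsFactors = FALSE)))
  list(ontology = ont, annotation = annotation)
}

#' Simulate neutral coalescent windows for one pool
#'
#' Each window is an independent standard-coalescent genealogy of
#' `sample_size` haploid lineages with infinite-sites mutations at rate
#' `theta_per_site` (no intra-window recombination). The resulting sample
#' frequencies feed the pooled read model of [pool_reads_from_frequencies()].
#' Windows are emitted as scaffolds `win_001 ...` of length `window_length`.
#'
#' @param theta_per_site scaled mutation rate per site.
#' @param n_windows number of windows.
#' @param window_length window length in bp.
#' @param sample_size number of sampled lineages (at most the pool size).
#' @param config a [sim_config] supplying pool size, coverage and error rate.
#' @param seed integer seed.
#' @return list with `counts` (a [site_counts] with one pool), `true_theta`,
#'   and `window_length`.
#' @export
simulate_neutral_windows <- function(theta_per_site, n_windows, window_length,
                                     sample_size = 100L, config = sim_config(),
                                     seed = 1L) {
  stopifnot(theta_per_site >= 0, sample_size >= 2L,
            sample_size <= config$pool_size)
  set.seed(seed)
  n <- sample_size
  scaffold <- character(0); pos <- integer(0); dcount <- integer(0)
  for (w in seq_len(n_windows)) {
    # coalescent: per-branch (subtree size, exposure)
    size <- rep(1L, n); expo <- rep(0, n)
    done_size <- integer(2L * n - 2L); done_expo <- numeric(2L * n - 2L); di <- 0L
    k <- n
    while (k > 1L) {
      t_k <- stats::rexp(1L, rate = k * (k - 1L) / 2)
      expo <- expo + t_k
      pair <- sample.int(k, 2L)
      di <- di + 1L; done_size[di] <- size[pair[1L]]; done_expo[di] <- expo[pair[1L]]
      di <- di + 1L; done_size[di] <- size[pair[2L]]; done_expo[di] <- expo[pair[2L]]
      size[pair[1L]] <- size[pair[1L]] + size[pair[2L]]
      expo[pair[1L]] <- 0
      size <- size[-pair[2L]]; expo <- expo[-pair[2L]]
      k <- k - 1L
    }
    t_total <- sum(done_expo)
    n_mut <- stats::rpois(1L, theta_per_site / 2 * window_length * t_total)
    if (n_mut > 0L) {
      n_mut <- min(n_mut, window_length)
      branch <- sample.int(di, n_mut, replace = TRUE, prob = done_expo)
      p <- sort(sample.int(window_length, n_mut))
      scaffold <- c(scaffold, rep(sprintf("win_%04d", w), n_mut))
      pos <- c(pos, p)
      dcount <- c(dcount, done_size[branch])
    }
  }
  if (length(pos)) {
    freq <- matrix(dcount / n, ncol = 1L)
    counts <- pool_reads_from_frequencies(freq, config, ref = "A", alt = "T")
    x <- site_counts(scaffold, pos, rep("A", length(pos)), counts)
  } else {
    x <- site_counts(character(), integer(), character(), array(0, c(0L, 6L, 1L)))
  }
  list(counts = x, true_theta = theta_per_site, window_length = window_length)
}

#' Simulate a read table over dense SNP clusters
#'
#' Plants `n_clusters` tight SNP clusters (3-5 SNPs inside < 90 bp) on distinct
#' scaffolds of an existing simulated dataset and emits spanning reads per
#' population, for exercising [extract_haplotype_loci()].
#'
#' @param dataset result of [simulate_gradient_experiment()].
#' @param n_clusters number of clusters to plant.
#' @param read_length read length in bp.
#' @param depth expected spanning reads per population per cluster.
#' @param seed integer seed.
#' @return list with `reads` (data.frame: scaffold, start (0-based), seq, pop)
#'   and `snps` (data.frame: scaffold, pos) including the planted cluster SNPs.
#' @export
simulate_haplotype_reads <- function(dataset, n_clusters = 10L,
                                     read_length = 100L, depth = 40,
                                     seed = 1L) {
  set.seed(seed)
  config <- dataset$config
  P <- config$n_pools
  scaffs <- names(dataset$scaffold_lengths)[seq_len(n_clusters)]
  reads <- list(); snps <- list(); ri <- 0L
  for (i in seq_along(scaffs)) {
    sc <- scaffs[i]
    n_snp <- sample(3:5, 1L)
    region_start <- 200L
    span <- sample(30:80, 1L)
    spos <- region_start + sort(sample.int(span, n_snp)) - 1L
    snps[[i]] <- data.frame(scaffold = sc, pos = spos, stringsAsFactors = FALSE)
    # two haplotypes per cluster, frequency follows the cline
    hap_freq <- inv_logit(logit(0.5) + as.numeric(scale(config$altitude)))
    for (k in seq_len(P)) {
      n_reads <- stats::rpois(1L, depth)
      for (r in seq_len(n_reads)) {
        ri <- ri + 1L
        start0 <- sample(max(0L, min(spos) - 1L - (read_length - span - 5L)):
                           (min(spos) - 1L), 1L)
        hap <- stats::runif(1) < hap_freq[k]
        base <- rep("A", read_length)
        off <- spos - start0   # 1-based offset of SNPs in read
        base[off] <- if (hap) "T" else "C"
        reads[[ri]] <- data.frame(scaffold = sc, start = start0,
                                  seq = paste(base, collapse = ""),
                                  pop = sprintf("pool%d", k),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = do.call(rbind, reads), snps = do.call(rbind, snps))
}
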