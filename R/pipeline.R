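#' Configuration for a full pipeline run
#'
#' Either a simulation block or a set of input paths must be supplied.
#'
#' @param simulate a [sim_config] (simulated inputs), or `NULL`.
#' @param inputs named list of file paths (`sync`, `n_pools`, `gff`, `obo`,
#'   `gene2go`, `env`, optional `mask`), or `NULL`.
#' @param stages character vector of stage names among `diversity`, `fst`,
#'   `classify`, `fixeddiff`, `structure`, `fstats`, `envassoc`, `overlap`,
#'   `goenrich`.
#' @param out_dir output directory (created if needed); `NULL` disables file
#'   output.
#' @param seed master seed; per-stage streams are derived by fixed offsets.
#' @param diversity a [diversity_params].
#' @param fst an [fst_params].
#' @param clusters list with `a` and `b` pool index vectors for the
#'   fixed-difference scan.
#' @param n_cov_snps SNP subsample size for the covariance matrix.
#' @param top_fraction fraction of SNPs called environmental candidates.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            stages = c("diversity", "fst", "classify",
                                       "fixeddiff", "structure", "fstats",
                                       "envassoc", "overlap", "goenrich"),
                            out_dir = NULL, seed = 1L,
                            diversity = diversity_params(),
                            fst = fst_params(),
                            clusters = list(a = 1:4, b = 6L),
                            n_cov_snps = 10000L, top_fraction = 0.01) {
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or input paths must be given")
  deps <- list(overlap = c("fst", "envassoc"), goenrich = "fst",
               structure = "fst", fstats = "fst", classify = "fst",
               fixeddiff = "fst")
  for (s in intersect(names(deps), stages)) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stop(sprintf("stage '%s' requires stage(s): %s", s,
                   paste(miss, collapse = ", ")))
  }
  structure(as.list(environment())[c("simulate", "inputs", "stages", "out_dir",
                                     "seed", "diversity", "fst", "clusters",
                                     "n_cov_snps", "top_fraction")],
            class = "pipeline_config")
}

stage_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, diversity = 23L, fst = 37L, structure = 53L,
               fstats = 67L, envassoc = 83L, goenrich = 97L)
  (as.integer(master) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the clinal Pool-seq analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated or loaded
#' inputs and returns (and optionally writes) a machine-readable summary:
#' per-window diversity, the pairwise F_ST table with SNP and gene outlier
#' tails, SNP functional classification counts, cluster-fixed differences,
#' DISTATIS/NJ/Mantel structure summaries, f3/f4 tables, environmental
#' association scores and candidate overlap, and GO enrichment of the
#' outlier genes.
#'
#' @param config a [pipeline_config].
#' @return list of per-stage results plus `summary` (plain-list digest).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  if (!is.null(config$simulate)) {
    dat <- simulate_gradient_experiment(config$simulate,
                                        seed = stage_seed(config$seed, "simulate"))
  } else {
    inp <- config$inputs
    counts <- parse_sync(inp$sync, inp$n_pools)
    if (!is.null(inp$mask))
      counts <- apply_region_mask(counts, read_bed_mask(inp$mask))
    ann <- load_annotation(inp$gff, inp$obo, inp$gene2go)
    dat <- list(counts = counts, genes = ann$genes, ontology = ann$ontology,
                annotation = ann$annotation, env = read_env_table(inp$env),
                scaffold_lengths = NULL, config = NULL)
  }
  res$data <- dat
  summary <- list(seed = config$seed, n_sites = length(dat$counts$pos),
                  n_pools = dat$counts$n_pools)

  if ("diversity" %in% config$stages) {
    res$diversity <- window_diversity(dat$counts, config$diversity,
                                      seed = stage_seed(config$seed, "diversity"),
                                      scaffold_lengths = dat$scaffold_lengths)
    ok <- !is.na(res$diversity$pi)
    summary$diversity <- lapply(split(res$diversity[ok, ], res$diversity$pop[ok]),
                                function(d) list(mean_pi = mean(d$pi),
                                                 mean_theta = mean(d$theta),
                                                 mean_D = mean(d$D, na.rm = TRUE)))
  }

  if ("fst" %in% config$stages) {
    ft <- pairwise_fst_table(dat$counts, config$fst)
    so <- snp_outliers(ft, config$fst$snp_quantile)
    res$fst <- ft
    res$snp_outliers <- so
    pair_mean <- colMeans(ft$fst, na.rm = TRUE)
    summary$fst <- list(n_snps = nrow(ft$snps), mean_fst = mean(ft$fst, na.rm = TRUE),
                        pair_mean = as.list(pair_mean),
                        outlier_threshold = so$threshold,
                        n_outlier_snps = sum(so$flag))
  }

  if ("classify" %in% config$stages) {
    cl <- classify_snps(res$fst$snps, dat$genes, config$fst$promoter_length)
    res$classification <- cl
    summary$classification <- as.list(cl$summary)
  }

  if ("fixeddiff" %in% config$stages) {
    fx <- fixed_between_clusters(dat$counts, config$clusters$a,
                                 config$clusters$b, config$fst$min_count)
    res$fixed <- fx
    summary$fixed_snps <- length(fx)
  }

  if ("structure" %in% config$stages) {
    dm <- quantile_distance_matrices(res$fst)
    keep_lvl <- vapply(dm, function(m) any(m > 0), logical(1))
    if (!all(keep_lvl))
      message("dropping all-zero quantile level(s): ",
              paste(names(dm)[!keep_lvl], collapse = ", "))
    dm <- dm[keep_lvl]
    ds <- distatis(dm, fst_values = res$fst$fst, pairs = res$fst$pairs,
                   levels = as.numeric(names(dm)),
                   n_boot = 200L, seed = stage_seed(config$seed, "structure"))
    med <- dm[["0.5"]]
    rownames(med) <- colnames(med) <- sprintf("pool%d", seq_len(nrow(med)))
    res$structure <- list(quantile_matrices = dm, distatis = ds,
                          nj = nj_tree(med))
    summary$structure <- list(alpha = ds$alpha,
                              axis1 = as.numeric(ds$scores[, 1L]))
  }

  if ("fstats" %in% config$stages) {
    pf <- pool_frequencies(dat$counts, config$fst$min_count)
    fs <- f_statistics_all(pf$freq, pf$depth,
                           pool_size = if (!is.null(dat$config))
                             dat$config$pool_size else NULL)
    res$fstats <- fs
    summary$fstats <- list(n_f3 = sum(fs$type == "f3"),
                           n_f4 = sum(fs$type == "f4"),
                           n_f4_significant = sum(fs$type == "f4" & abs(fs$z) > 3))
  }

  if ("envassoc" %in% config$stages) {
    comp <- env_pca(dat$env)
    pf <- pool_frequencies(dat$counts, config$fst$min_count)
    cov <- estimate_covariance(pf, n_snps = config$n_cov_snps,
                               seed = stage_seed(config$seed, "envassoc"))
    sc <- env_score(pf$freq, pf$depth, cov, comp)
    res$env <- list(composite = comp, covariance = cov, scores = sc,
                    snps = pf$snps)
    n_top <- max(1L, round(config$top_fraction * nrow(sc)))
    res$env$top <- which(sc$rank <= n_top)
    summary$env <- list(var_fraction = comp$var_fraction,
                        convergence = cov$convergence,
                        n_top = length(res$env$top))
  }

  if ("overlap" %in% config$stages) {
    pf_idx <- pool_frequencies(dat$counts, config$fst$min_count)$snp_index
    env_ids <- pf_idx[res$env$top]
    fst_ids <- which(res$snp_outliers$flag)
    # map fst table rows back to site indices
    flt_idx <- which(filter_alleles(dat$counts, config$fst$min_count)$n_alleles >= 2L)
    fst_ids <- flt_idx[fst_ids]
    ov <- overlap_report(env_ids, fst_ids)
    res$overlap <- ov
    summary$overlap <- ov
  }

  if ("goenrich" %in% config$stages) {
    map <- snp_gene_map(res$fst$snps, dat$genes)
    study <- unique(map$gene[map$snp %in% which(res$snp_outliers$flag)])
    ann_genes <- unique(dat$annotation$gene)
    study <- intersect(study, ann_genes)
    if (length(study)) {
      enr <- elim_enrichment(dat$ontology, dat$annotation, study)
      res$enrichment <- enr
      summary$enrichment <- list(n_tested = nrow(enr),
                                 n_significant = sum(enr$p_elim < 0.05))
    } else summary$enrichment <- list(n_tested = 0L, n_significant = 0L)
  }

  res$summary <- summary
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  tsv <- function(df, name)
    utils::write.table(df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$diversity)) tsv(res$diversity, "diversity.tsv")
  if (!is.null(res$fst))
    tsv(cbind(res$fst$snps, res$fst$fst), "fst.tsv")
  if (!is.null(res$fstats)) tsv(res$fstats, "fstats.tsv")
  if (!is.null(res$env))
    tsv(cbind(res$env$snps, res$env$scores), "env_scores.tsv")
  if (!is.null(res$enrichment)) tsv(res$enrichment, "enrichment.tsv")
  if (!is.null(res$structure))
    writeLines(res$structure$nj, out("nj_median_fst.nwk"))
  jsonlite::write_json(res$summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
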