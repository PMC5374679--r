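# shared fixtures built in code

# two-level ontology with a sibling root, used for the elim worked example:
# universe of 20 genes, term T1 (5 genes, all in the study set) below R
# (10 genes incl. T1's), 10 further genes under the sibling root O
worked_ontology <- function() {
  ont <- structure(list(
    terms = data.frame(id = c("R", "T1", "O"),
                       name = c("rootA", "child", "rootB"),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = list(R = character(0), T1 = "R", O = character(0))),
    class = "ontology")
  genes <- sprintf("g%02d", 1:20)
  ann <- rbind(data.frame(gene = genes[1:5], term = "T1", stringsAsFactors = FALSE),
               data.frame(gene = genes[6:10], term = "R", stringsAsFactors = FALSE),
               data.frame(gene = genes[11:20], term = "O", stringsAsFactors = FALSE))
  list(ontology = ont, annotation = ann, genes = genes, study = genes[1:5])
}

# one '+' and one '-' strand gene on one scaffold
tiny_gene_models <- function() {
  structure(list(
    genes = data.frame(gene_id = c("gA", "gB"), scaffold = "sc1",
                       strand = c("+", "-"), start = c(1000L, 5000L),
                       end = c(2000L, 6000L), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA", "gB"),
                       start = c(1000L, 1600L, 5000L),
                       end = c(1400L, 2000L, 6000L)),
    cds = data.frame(gene_id = c("gA", "gB"),
                     start = c(1600L, 5200L), end = c(1900L, 5800L))),
    class = "gene_models")
}

# a site_counts table with given per-pool count sextets (list of matrices)
make_sites <- function(scaffold, pos, pools) {
  n <- length(pos)
  scaffold <- rep_len(scaffold, n)
  P <- length(pools[[1]]) / 6L
  counts <- array(0, c(n, 6L, P))
  for (i in seq_len(n))
    counts[i, , ] <- matrix(pools[[i]], nrow = 6L)
  site_counts(scaffold, pos, rep("A", n), counts)
}

# brute-force two-sided exact Mann-Whitney by enumeration of all splits
mw_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  U_obs <- sum(rank(vals)[seq_len(nx)]) - nx * (nx + 1) / 2
  Us <- apply(idx, 2L, function(i)
    sum(rank(vals)[i]) - nx * (nx + 1) / 2)
  lower <- mean(Us <= U_obs); upper <- mean(Us >= U_obs)
  min(1, 2 * min(lower, upper))
}
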