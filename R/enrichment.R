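#' Propagate annotations up the ontology (true-path rule)
#'
#' Each gene becomes annotated to every ancestor of its directly annotated
#' terms. Idempotent.
#'
#' @param annotation data.frame with columns gene, term (direct annotations).
#' @param ontology an `ontology` object from [read_obo()].
#' @return named list mapping each term to its annotated gene set.
#' @export
propagate_annotations <- function(annotation, ontology) {
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    ps <- ontology$parents[[term]]
    res <- term
    for (p in ps) res <- union(res, ancestors(p))
    anc_cache[[term]] <- res
    res
  }
  term2genes <- list()
  for (i in seq_len(nrow(annotation))) {
    tms <- ancestors(annotation$term[i])
    for (t in tms)
      term2genes[[t]] <- c(term2genes[[t]], annotation$gene[i])
  }
  lapply(term2genes, unique)
}

# one-sided hypergeometric tails for a term's contingency:
# k in-term study genes, K term genes, n study genes, N universe genes
term_fisher <- function(k, K, n, N, alternative = "departure") {
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  if (alternative == "greater") return(upper)
  lower <- stats::phyper(k, K, N - K, n)
  min(upper, lower)
}

#' GO-term enrichment with the elim algorithm
#'
#' Terms are processed from most specific to most general (decreasing
#' longest-path depth, ties by identifier). Each term with more than
#' `min_genes - 1` annotated genes is tested by Fisher's exact test on its
#' current (possibly pruned) annotation against the study set; when the elim
#' p-value falls below `alpha`, the term's current genes are removed from all
#' of its ancestors' annotation sets before those are tested. The classic
#' p-value (no elimination) is reported alongside. The gene universe is the
#' set of genes with at least one annotation.
#'
#' The default p-value is the smaller one-sided hypergeometric tail, with the
#' direction of departure reported; `alternative = "greater"` restricts to
#' over-representation.
#'
#' @param ontology an `ontology` object.
#' @param annotation data.frame gene/term of direct annotations (propagated
#'   internally), or a pre-propagated named term -> genes list.
#' @param study character vector of study genes (subset of the universe).
#' @param alpha elimination significance level.
#' @param min_genes a term must have at least this many annotated genes to be
#'   tested (default 4, i.e. more than three).
#' @param alternative "departure" (smaller tail) or "greater".
#' @return data.frame: term, name, annotated, in_study, p_elim, p_classic,
#'   direction, sorted by `p_elim`.
#' @export
elim_enrichment <- function(ontology, annotation, study, alpha = 0.05,
                            min_genes = 4L,
                            alternative = c("departure", "greater")) {
  alternative <- match.arg(alternative)
  full <- if (is.data.frame(annotation))
    propagate_annotations(annotation, ontology) else annotation
  universe <- unique(unlist(full, use.names = FALSE))
  study <- unique(study)
  if (!length(study)) stop("empty study set")
  if (!all(study %in% universe))
    stop("study set contains genes outside the annotated universe")
  N <- length(universe)
  n <- length(study)
  depth <- term_depth(ontology)
  terms <- names(full)
  ord <- terms[order(-depth[terms], terms)]
  current <- full
  rows <- list()
  for (t in ord) {
    genes_t <- current[[t]]
    K <- length(genes_t)
    if (K < min_genes) next
    k <- length(intersect(genes_t, study))
    p_elim <- term_fisher(k, K, n, N, alternative)
    k0 <- length(intersect(full[[t]], study))
    p_classic <- term_fisher(k0, length(full[[t]]), n, N, alternative)
    dir <- if (k / K >= n / N) "over" else "under"
    rows[[t]] <- data.frame(term = t,
                            name = ontology$terms$name[match(t, ontology$terms$id)],
                            annotated = K, in_study = k,
                            p_elim = p_elim, p_classic = p_classic,
                            direction = dir, stringsAsFactors = FALSE)
    if (p_elim < alpha) {
      # prune this term's genes from all ancestors
      anc <- setdiff(term_ancestors(ontology, t), t)
      for (a in anc)
        if (!is.null(current[[a]]))
          current[[a]] <- setdiff(current[[a]], genes_t)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[order(out$p_elim, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

term_ancestors <- function(ontology, term) {
  res <- term
  queue <- ontology$parents[[term]]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v %in% res) next
    res <- c(res, v)
    queue <- c(queue, ontology$parents[[v]])
  }
  res
}
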