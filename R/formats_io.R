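#' @keywords internal
"_PACKAGE"

BASES <- c("A", "T", "C", "G", "N", "del")

#' Site count tables
#'
#' A `site_counts` object holds per-site, per-pool nucleotide read counts as
#' parsed from a PoPoolation2-style "sync" file: for every site a scaffold, a
#' 1-based position, a reference base, and one sextet of counts per pool in the
#' fixed order A, T, C, G, N, deletion.
#'
#' @param scaffold character vector of scaffold identifiers.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (A/C/G/T/N).
#' @param counts numeric array of dimension `c(n_sites, 6, n_pools)`;
#'   `counts[i, , k]` is the A,T,C,G,N,del sextet of pool `k` at site `i`.
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(scaffold, pos, ref, counts) {
  n <- length(scaffold)
  if (length(pos) != n || length(ref) != n)
    stop("scaffold, pos and ref must have equal length")
  if (is.matrix(counts)) counts <- array(counts, dim = c(dim(counts), 1L))
  if (length(dim(counts)) != 3L || dim(counts)[1L] != n || dim(counts)[2L] != 6L)
    stop("counts must be an n_sites x 6 x n_pools array")
  if (any(counts < 0)) stop("all counts must be non-negative")
  dimnames(counts) <- list(NULL, BASES, NULL)
  structure(
    list(scaffold = as.character(scaffold), pos = as.integer(pos),
         ref = toupper(as.character(ref)), counts = counts,
         n_pools = dim(counts)[3L]),
    class = "site_counts"
  )
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d sites, %d pools, %d scaffolds\n",
              length(x$pos), x$n_pools, length(unique(x$scaffold))))
  invisible(x)
}

#' @export
length.site_counts <- function(x) length(x$pos)

#' Subset a site_counts table by site index
#' @param x a `site_counts` object.
#' @param i integer or logical site index.
#' @return the subset `site_counts`.
#' @export
subset_sites <- function(x, i) {
  site_counts(x$scaffold[i], x$pos[i], x$ref[i], x$counts[i, , , drop = FALSE])
}

#' Parse a PoPoolation2 sync file
#'
#' Reads a whitespace-separated sync file with one line per site:
#' scaffold, position, reference base, then one `A:T:C:G:N:del` count sextet
#' per pool. Line order is preserved.
#'
#' @param path path to the sync file.
#' @param n_pools expected number of pools (count columns).
#' @return a [site_counts] object.
#' @export
parse_sync <- function(path, n_pools) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_pools <- as.integer(n_pools)
  if (is.na(n_pools) || n_pools < 1L) stop("n_pools must be a positive integer")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0L)
    return(site_counts(character(), integer(), character(),
                       array(0, c(0L, 6L, n_pools))))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("sync parse error at line %d: expected %d fields, found %d",
                 bad, nf[1L], nf[bad]))
  }
  if (nf[1L] - 3L != n_pools)
    stop(sprintf("pool count mismatch: file has %d count columns, n_pools = %d",
                 nf[1L] - 3L, n_pools))
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos) || any(pos <= 0L)) {
    bad <- which(is.na(pos) | pos <= 0L)[1L]
    stop(sprintf("sync parse error at line %d: bad position '%s'", bad, m[bad, 2L]))
  }
  counts <- array(NA_real_, c(n, 6L, n_pools))
  for (k in seq_len(n_pools)) {
    parts <- strsplit(m[, 3L + k], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      bad <- which(lengths(parts) != 6L)[1L]
      stop(sprintf("sync parse error at line %d: count field '%s' is not a sextet",
                   bad, m[bad, 3L + k]))
    }
    v <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(v) || any(v < 0)) {
      bad <- ceiling(which(is.na(v) | v < 0)[1L] / 6L)
      stop(sprintf("sync parse error at line %d: non-integer or negative count", bad))
    }
    counts[, , k] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  site_counts(m[, 1L], pos, m[, 3L], counts)
}

#' Write a sync file
#'
#' Inverse of [parse_sync()]: tab-separated, counts joined with colons.
#'
#' @param x a [site_counts] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "site_counts"))
  n <- length(x$pos)
  cols <- character(0)
  if (n > 0L) {
    pools <- vapply(seq_len(x$n_pools), function(k) {
      cnt <- format(x$counts[, , k, drop = FALSE], trim = TRUE, scientific = FALSE)
      dim(cnt) <- c(n, 6L)
      apply(cnt, 1L, paste, collapse = ":")
    }, character(n))
    if (n == 1L) pools <- matrix(pools, nrow = 1L)
    lines <- paste(x$scaffold, x$pos, x$ref,
                   apply(pools, 1L, paste, collapse = "\t"), sep = "\t")
  } else lines <- character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a BED interval mask
#'
#' @param path BED file (0-based, half-open; first three columns used).
#' @return a `region_mask` data.frame with columns scaffold, start, end.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end"),
                          colClasses = c("character", "integer", "integer"))[1:3]
  region_mask(df$scaffold, df$start, df$end)
}

#' Build a region mask
#' @param scaffold,start,end vectors defining 0-based half-open intervals.
#' @return a `region_mask` data.frame.
#' @export
region_mask <- function(scaffold = character(), start = integer(), end = integer()) {
  if (any(start >= end)) stop("mask intervals must satisfy start < end")
  structure(data.frame(scaffold = as.character(scaffold),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("region_mask", "data.frame"))
}

#' Remove masked sites from a count table
#'
#' Drops sites whose 0-based position falls in any mask interval
#' (typically indel-adjacent regions). Site order is preserved; an empty mask
#' is the identity.
#'
#' @param x a [site_counts] object.
#' @param mask a [region_mask].
#' @return the filtered [site_counts].
#' @export
apply_region_mask <- function(x, mask) {
  stopifnot(inherits(x, "site_counts"))
  if (nrow(mask) == 0L || length(x$pos) == 0L) return(x)
  sites <- GenomicRanges::GRanges(x$scaffold, IRanges::IRanges(x$pos, width = 1L))
  # BED 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
  m <- GenomicRanges::GRanges(mask$scaffold,
                              IRanges::IRanges(mask$start + 1L, mask$end))
  hit <- IRanges::overlapsAny(sites, m)
  if (!any(hit)) return(x)
  subset_sites(x, !hit)
}

#' Read gene models from a GFF3 file
#'
#' Extracts gene, exon and CDS features and checks containment invariants.
#' Features with '.' strand are treated as '+' with a warning.
#'
#' @param path GFF3 file.
#' @return a `gene_models` list with data.frames `genes` (gene_id, scaffold,
#'   strand, start, end), `exons` and `cds` (gene_id, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  df <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  g <- type == "gene"
  genes <- data.frame(gene_id = ids[g], scaffold = df$scaffold[g],
                      strand = df$strand[g], start = df$start[g], end = df$end[g],
                      stringsAsFactors = FALSE)
  if (any(genes$strand %in% c(".", "*"))) {
    warning("genes with '.' strand treated as '+'")
    genes$strand[genes$strand %in% c(".", "*")] <- "+"
  }
  # exon/CDS Parent may be an mRNA; map transcript ids to their gene
  tx <- type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(parent[tx], ids[tx])
  resolve <- function(p) ifelse(p %in% genes$gene_id, p,
                                unname(tx2gene[p]))
  sub <- function(what) {
    s <- type == what
    data.frame(gene_id = resolve(parent[s]), start = df$start[s], end = df$end[s],
               stringsAsFactors = FALSE)
  }
  gm <- structure(list(genes = genes, exons = sub("exon"), cds = sub("CDS")),
                  class = "gene_models")
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  g <- gm$genes
  if (any(g$start > g$end)) stop("gene with start > end")
  idx <- match(gm$exons$gene_id, g$gene_id)
  if (anyNA(idx)) stop("exon with unknown parent gene")
  if (any(gm$exons$start < g$start[idx] | gm$exons$end > g$end[idx]))
    stop("exon outside gene span")
  ic <- match(gm$cds$gene_id, g$gene_id)
  if (anyNA(ic)) stop("CDS with unknown parent gene")
  invisible(gm)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, `is_a` parents); obsolete terms
#' are dropped with a message. The `is_a` graph must be acyclic.
#'
#' @param path OBO flat file.
#' @return an `ontology` list: `terms` data.frame (id, name, namespace),
#'   `parents` named list mapping each term to its `is_a` parents.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas in OBO file")
  term_starts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1L] - 1L, length(lines))
  id <- name <- ns <- character(0); parents <- list(); n_obs <- 0L
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    blk <- lines[(starts[i] + 1L):ends[i]]
    val <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), blk, value = TRUE))
      if (length(v)) v else character(0)
    }
    if (length(val("is_obsolete")) && val("is_obsolete")[1L] == "true") {
      n_obs <- n_obs + 1L
      next
    }
    tid <- val("id")[1L]
    id <- c(id, tid)
    name <- c(name, if (length(val("name"))) val("name")[1L] else NA_character_)
    ns <- c(ns, if (length(val("namespace"))) val("namespace")[1L] else NA_character_)
    isa <- sub(" *!.*$", "", val("is_a"))
    parents[[tid]] <- isa
  }
  if (n_obs > 0L) message(n_obs, " obsolete term(s) dropped")
  # drop dangling parent links, then check acyclicity
  parents <- lapply(parents, function(p) p[p %in% id])
  ont <- structure(list(terms = data.frame(id = id, name = name, namespace = ns,
                                           stringsAsFactors = FALSE),
                        parents = parents),
                   class = "ontology")
  topo_order(ont)  # errors on a cycle
  ont
}

# Kahn topological order over is_a edges, children before parents.
# Errors on a cyclic graph.
topo_order <- function(ont) {
  ids <- ont$terms$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (p in unlist(ont$parents[ids], use.names = FALSE))
    indeg[p] <- indeg[p] + 1L
  # indeg = number of children edges pointing at term; leaves have indeg 0
  queue <- ids[indeg[ids] == 0L]
  seen <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- c(seen, v)
    for (p in ont$parents[[v]]) {
      indeg2[p] <- indeg2[p] - 1L
      if (indeg2[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(seen) != length(ids)) stop("cyclic is_a graph in ontology")
  seen  # children before parents
}

# longest-path depth from each term down to a root (term with no parents)
term_depth <- function(ont) {
  ord <- topo_order(ont)          # children first
  depth <- stats::setNames(integer(length(ord)), ord)
  for (v in rev(ord)) {           # parents first
    ps <- ont$parents[[v]]
    depth[v] <- if (length(ps)) max(depth[ps]) + 1L else 0L
  }
  depth
}

#' Read a gene-to-term annotation table
#'
#' @param path two-column TSV (gene, term), no header.
#' @return data.frame with columns gene, term.
#' @export
read_gene2go <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "term"),
                          colClasses = "character")
  df
}

#' Load gene models plus ontology annotation
#'
#' Convenience loader combining [read_gene_models()], [read_obo()] and
#' [read_gene2go()]. Annotations to terms missing from the ontology are dropped
#' with a warning; genes annotated but absent from the GFF are kept in the
#' mapping and reported.
#'
#' @param gff_path,obo_path,gene2go_path input files.
#' @return list with elements `genes`, `ontology`, `annotation`.
#' @export
load_annotation <- function(gff_path, obo_path, gene2go_path) {
  genes <- read_gene_models(gff_path)
  ont <- read_obo(obo_path)
  ann <- read_gene2go(gene2go_path)
  unknown <- !(ann$term %in% ont$terms$id)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) to unknown terms dropped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  missing_genes <- setdiff(unique(ann$gene), genes$genes$gene_id)
  if (length(missing_genes))
    message(length(missing_genes),
            " annotated gene(s) absent from the GFF retained in the mapping")
  list(genes = genes, ontology = ont, annotation = ann)
}

#' Write haplotype loci to FASTA
#'
#' @param loci a `haplotype_loci` object from [extract_haplotype_loci()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(loci, path) {
  seqs <- character(0)
  for (l in loci$loci) {
    hdr <- sprintf("%s|%s|%d-%d|%s|%d", l$locus_id, l$scaffold, l$start, l$end,
                   l$pop, l$replicate)
    seqs <- c(seqs, stats::setNames(l$seq, hdr))
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a populations-by-environment table
#'
#' @param path TSV with a header row; first column = population label,
#'   remaining columns numeric environmental variables. No missing values.
#' @return numeric matrix, rownames = populations.
#' @export
read_env_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("environment table contains missing values")
  m
}

#' Write a populations-by-environment table
#' @param env numeric matrix (rownames = populations).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(population = rownames(env), env, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
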