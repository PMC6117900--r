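#' Reciprocal best hits between two genomes
#'
#' Runs the protein search in both directions and returns gene pairs that
#' are each other's best hit. Ties on raw score are broken by the larger
#' identity count, then the lexicographically smallest subject gene id, so
#' the result is deterministic.
#'
#' @param genome_a,genome_b `genome` objects (complete CDS records are used).
#' @param e_cutoff Protein search e-value cut-off (default `1e-4`).
#' @param ... Passed to [pairwise_protein_search()].
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(genome_a, genome_b, e_cutoff = 1e-4, ...) {
  rbh_cds(extract_cds(genome_a), extract_cds(genome_b),
          e_cutoff = e_cutoff, ...)
}

rbh_cds <- function(ga, gb, e_cutoff = 1e-4, k = 4L, min_seeds = 4L) {
  sr <- protein_search_raw(ga, gb, e_cutoff, k, min_seeds)
  ab <- sr$ab
  ba <- sr$ba
  best <- function(h) {
    if (nrow(h) == 0L) return(h)
    h %>%
      dplyr::arrange(.data$query_id, dplyr::desc(.data$raw_score),
                     dplyr::desc(.data$identities), .data$subject_id) %>%
      dplyr::distinct(.data$query_id, .keep_all = TRUE)
  }
  ab <- best(ab); ba <- best(ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  m <- dplyr::inner_join(
    dplyr::select(ab, gene_a = "query_id", gene_b = "subject_id"),
    dplyr::select(ba, gene_b = "query_id", gene_a = "subject_id"),
    by = c("gene_a", "gene_b"))
  dplyr::arrange(m, .data$gene_a)
}

#' Cluster genes of several genomes into orthologous groups
#'
#' Computes reciprocal best hits for every genome pair and takes the
#' transitive closure of the resulting edges (union-find) as clusters of
#' orthologous genes. A cluster is flagged core when it contains exactly one
#' gene from every input genome; all other clusters -- including singleton
#' genes and clusters with in-paralogs -- belong to the accessory genome.
#' Every complete CDS of every genome appears in exactly one cluster.
#'
#' @param genomes List of `genome` objects (at least 2 for a meaningful
#'   core/accessory split).
#' @param e_cutoff Protein search e-value cut-off.
#' @param ... Passed to [pairwise_protein_search()].
#' @return A `cog_set`: list with `clusters` (tibble `cog_id`, `genome_id`,
#'   `gene_id`, `is_core`) and `genomes` (character vector of genome ids).
#' @export
cluster_cogs <- function(genomes, e_cutoff = 1e-4, ...) {
  stopifnot(length(genomes) >= 1L)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  if (length(genomes) == 1L) {
    warning("single genome: all genes classified accessory")
  }
  cds <- lapply(genomes, extract_cds)
  all_genes <- dplyr::bind_rows(
    lapply(seq_along(genomes), function(i) {
      tibble::tibble(genome_id = ids[i], gene_id = cds[[i]]$gene_id)
    }))
  edges <- list()
  if (length(genomes) >= 2L) {
    for (i in seq_len(length(genomes) - 1L)) {
      for (j in (i + 1L):length(genomes)) {
        edges[[length(edges) + 1L]] <-
          rbh_cds(cds[[i]], cds[[j]], e_cutoff = e_cutoff, ...)
      }
    }
  }
  edges <- dplyr::bind_rows(edges)
  comp <- union_find_components(all_genes$gene_id, edges)
  cl <- dplyr::mutate(all_genes, component = comp[all_genes$gene_id])
  # deterministic cluster ids: order components by their smallest gene id
  key <- tapply(cl$gene_id, cl$component, min)
  ord <- rank(key, ties.method = "first")
  cl$cog_id <- sprintf("COG%05d", ord[as.character(cl$component)])
  core_flag <- cl %>%
    dplyr::group_by(.data$cog_id) %>%
    dplyr::summarise(
      is_core = dplyr::n() == length(ids) &&
        dplyr::n_distinct(.data$genome_id) == length(ids),
      .groups = "drop")
  clusters <- cl %>%
    dplyr::left_join(core_flag, by = "cog_id") %>%
    dplyr::select("cog_id", "genome_id", "gene_id", "is_core") %>%
    dplyr::arrange(.data$cog_id, .data$genome_id)
  if (length(genomes) == 1L) clusters$is_core <- FALSE
  structure(list(clusters = clusters, genomes = ids), class = "cog_set")
}

union_find_components <- function(node_ids, edges) {
  idx <- stats::setNames(seq_along(node_ids), node_ids)
  par <- seq_along(node_ids)
  findi <- function(i) {
    root <- i
    while (par[root] != root) root <- par[root]
    while (par[i] != root) { nxt <- par[i]; par[i] <<- root; i <- nxt }
    root
  }
  if (nrow(edges) > 0L) {
    ia <- idx[edges$gene_a]; ib <- idx[edges$gene_b]
    for (e in seq_along(ia)) {
      ra <- findi(ia[e]); rb <- findi(ib[e])
      if (ra != rb) par[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(node_ids), findi, integer(1))
  stats::setNames(roots, node_ids)
}

#' @export
print.cog_set <- function(x, ...) {
  n_core <- length(unique(x$clusters$cog_id[x$clusters$is_core]))
  n_acc <- length(unique(x$clusters$cog_id[!x$clusters$is_core]))
  cat("<cog_set> ", length(x$genomes), " genomes: ", n_core,
      " core and ", n_acc, " accessory clusters over ",
      nrow(x$clusters), " genes\n", sep = "")
  invisible(x)
}

#' Core clusters of a cog_set
#' @param cogs A `cog_set`.
#' @return Tibble of core cluster memberships.
#' @export
core_cogs <- function(cogs) {
  dplyr::filter(cogs$clusters, .data$is_core)
}

#' Accessory clusters of a cog_set
#' @param cogs A `cog_set`.
#' @return Tibble of accessory cluster memberships.
#' @export
accessory_cogs <- function(cogs) {
  dplyr::filter(cogs$clusters, !.data$is_core)
}
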