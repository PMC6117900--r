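# Divergence axes and the barcoding suitability score of core orthologous
# clusters. For every genome pair of a codon alignment three quantities are
# measured over the fully aligned (ungapped, non-stop) codon columns:
#   X -- sense (non-synonymous) nucleotide substitutions over all nucleotide
#        substitutions; a substitution is "sense" when its codon's
#        translation differs between the two rows (every differing
#        nucleotide of such a codon is counted),
#   Y -- 1 - protein identity over aligned residue pairs,
#   Z -- (positives - identities) / identities, positives being residue
#        pairs with a positive BLOSUM62 score (identities included).
# The per-cluster statistics are unweighted means over genome pairs, and the
# suitability score is X * (1 - X) * (1 - Y) / (Z + 1): it peaks for
# moderately variable genes under positive selection (mid X, low Y, low Z)
# and vanishes for fully conserved (X = 0) or saturated (Y -> 1) genes.

#' Divergence statistics for one genome pair of a codon alignment
#'
#' @param aln A `codon_alignment`.
#' @param genome_i,genome_j Row (genome) names to compare.
#' @param table Genetic code table for codon translation.
#' @return List with `x_pair`, `y_pair`, `z_pair`, `n_subs`, `n_pairs` and
#'   `degenerate` (TRUE when no identical residue pair exists and Z was
#'   defined as 0).
#' @export
pairwise_divergence_stats <- function(aln, genome_i, genome_j, table = "11") {
  gc <- Biostrings::getGeneticCode(table)
  bm <- blosum62()
  a <- aln$rows[[genome_i]]; b <- aln$rows[[genome_j]]
  stopifnot(nchar(a) == nchar(b))
  n <- nchar(a)
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]; cb <- cb[keep]
  aa_a <- unname(gc[ca]); aa_a[is.na(aa_a)] <- "X"
  aa_b <- unname(gc[cb]); aa_b[is.na(aa_b)] <- "X"
  ok <- aa_a != "*" & aa_b != "*"
  ca <- ca[ok]; cb <- cb[ok]; aa_a <- aa_a[ok]; aa_b <- aa_b[ok]
  if (length(ca) == 0L) {
    stop("no aligned codon columns between ", genome_i, " and ", genome_j)
  }
  # nucleotide substitutions per codon
  d1 <- substr(ca, 1, 1) != substr(cb, 1, 1)
  d2 <- substr(ca, 2, 2) != substr(cb, 2, 2)
  d3 <- substr(ca, 3, 3) != substr(cb, 3, 3)
  nsub <- d1 + d2 + d3
  sense <- aa_a != aa_b
  total_subs <- sum(nsub)
  x_pair <- if (total_subs == 0L) 0 else sum(nsub[sense]) / total_subs
  ident <- sum(aa_a == aa_b)
  y_pair <- 1 - ident / length(aa_a)
  pos <- sum(bm[cbind(aa_a, aa_b)] > 0)
  degenerate <- ident == 0L
  z_pair <- if (degenerate) 0 else (pos - ident) / ident
  list(x_pair = x_pair, y_pair = y_pair, z_pair = z_pair,
       n_subs = total_subs, n_pairs = length(aa_a), degenerate = degenerate)
}

#' Suitability score of one codon-aligned cluster
#'
#' Averages the pairwise divergence axes over all genome pairs and applies
#' the suitability formula `X * (1 - X) * (1 - Y) / (Z + 1)`.
#'
#' @param aln A `codon_alignment` with at least two rows.
#' @param table Genetic code table.
#' @return One-row tibble: `cog_id`, `X`, `Y`, `Z`, `score`, `n_pairs`,
#'   `degenerate` (any pair had no identical residues).
#' @export
score_cog <- function(aln, table = "11") {
  g <- names(aln$rows)
  stopifnot(length(g) >= 2L)
  pairs <- utils::combn(g, 2L)
  st <- lapply(seq_len(ncol(pairs)), function(k) {
    pairwise_divergence_stats(aln, pairs[1, k], pairs[2, k], table)
  })
  X <- mean(vapply(st, `[[`, numeric(1), "x_pair"))
  Y <- mean(vapply(st, `[[`, numeric(1), "y_pair"))
  Z <- mean(vapply(st, `[[`, numeric(1), "z_pair"))
  tibble::tibble(
    cog_id = aln$cog_id, X = X, Y = Y, Z = Z,
    score = cog_score_formula(X, Y, Z),
    n_pairs = ncol(pairs),
    degenerate = any(vapply(st, `[[`, logical(1), "degenerate")))
}

#' The suitability score formula
#' @param x,y,z Divergence axes (fractions; `z >= 0`).
#' @return `x * (1 - x) * (1 - y) / (z + 1)`.
#' @export
cog_score_formula <- function(x, y, z) x * (1 - x) * (1 - y) / (z + 1)

#' Codon-align and score every core cluster of a cog_set
#'
#' Clusters whose members fail the frame check are skipped with a warning.
#'
#' @param cogs A `cog_set` from [cluster_cogs()].
#' @param genomes The list of `genome` objects the set was built from.
#' @param table Genetic code table.
#' @return Tibble of per-cluster statistics (one row per scorable core
#'   cluster), sorted by descending score; the codon alignments are attached
#'   as the `"alignments"` attribute (named list).
#' @export
score_core_cogs <- function(cogs, genomes, table = "11") {
  lookup <- dplyr::bind_rows(lapply(genomes, extract_cds))
  core <- core_cogs(cogs)
  ids <- unique(core$cog_id)
  stats <- list(); alns <- list()
  for (cid in ids) {
    members <- core[core$cog_id == cid, ]
    res <- tryCatch({
      aln <- codon_align_cog(members, lookup, cog_id = cid)
      list(aln = aln, st = score_cog(aln, table))
    }, error = function(e) {
      warning("skipping cluster ", cid, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      alns[[cid]] <- res$aln
      stats[[cid]] <- res$st
    }
  }
  out <- dplyr::bind_rows(stats)
  if (nrow(out) > 0L) {
    # products: most common annotation among members
    prod <- lookup$product[match(core$gene_id, lookup$gene_id)]
    ptab <- tibble::tibble(cog_id = core$cog_id, product = prod) %>%
      dplyr::group_by(.data$cog_id) %>%
      dplyr::summarise(product = names(sort(table(.data$product),
                                            decreasing = TRUE))[1] %||% NA_character_,
                       .groups = "drop")
    out <- dplyr::left_join(out, ptab, by = "cog_id")
    out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$cog_id)
  }
  attr(out, "alignments") <- alns
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-cluster statistics table
#'
#' @param stats Tibble from [score_core_cogs()].
#' @param path Output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_cog_stats <- function(stats, path) {
  readr::write_tsv(dplyr::select(stats, -dplyr::any_of("degenerate")), path)
  invisible(path)
}
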