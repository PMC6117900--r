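new_barcode_set <- function(barcodes, segments, requested_length,
                            accessory_fraction) {
  structure(list(barcodes = barcodes, segments = segments,
                 requested_length = requested_length,
                 accessory_fraction = accessory_fraction),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  lens <- nchar(x$barcodes)
  cat("<barcode_set> ", length(x$barcodes), " barcodes, ",
      min(lens), "-", max(lens), " bp (requested ", x$requested_length,
      ", accessory fraction ", x$accessory_fraction, ")\n", sep = "")
  invisible(x)
}

#' Barcode lengths of a barcode set
#' @param bs A `barcode_set`.
#' @return Named integer vector of barcode lengths (bp).
#' @export
barcode_lengths <- function(bs) {
  vapply(bs$barcodes, nchar, integer(1))
}

#' Concatenate top-scoring core clusters into per-genome barcodes
#'
#' Clusters are taken in descending suitability score (ties broken by
#' cluster id); for each one, every genome's member sequence is appended to
#' that genome's barcode. Selection stops at the first cluster whose
#' inclusion brings the minimum per-genome core length to at least
#' `target_core_length`, so selection is identical for all genomes and every
#' barcode reaches the target (genes differ in length across genomes, so
#' realized lengths differ; the final gene is never trimmed).
#'
#' @param stats Scored core clusters from [score_core_cogs()].
#' @param cogs The `cog_set` the statistics came from.
#' @param gene_lookup Tibble of gene records covering all members.
#' @param target_core_length Requested core length per barcode (bp).
#' @return A `barcode_set` holding the core part only.
#' @export
assemble_core_barcode <- function(stats, cogs, gene_lookup,
                                  target_core_length) {
  genomes <- cogs$genomes
  seqs <- stats::setNames(rep("", length(genomes)), genomes)
  segs <- list()
  core <- core_cogs(cogs)
  ord <- stats[order(-stats$score, stats$cog_id), ]
  selected <- character(0)
  for (cid in ord$cog_id) {
    if (target_core_length <= 0) break
    members <- core[core$cog_id == cid, ]
    idx <- match(members$gene_id, gene_lookup$gene_id)
    for (k in seq_len(nrow(members))) {
      g <- members$genome_id[k]
      nt <- gene_lookup$nt[idx[k]]
      segs[[length(segs) + 1L]] <- tibble::tibble(
        barcode_id = g, gene_id = members$gene_id[k], cog_id = cid,
        start = nchar(seqs[[g]]), end = nchar(seqs[[g]]) + nchar(nt),
        origin = "core",
        product = gene_lookup$product[idx[k]])
      seqs[[g]] <- paste0(seqs[[g]], nt)
    }
    selected <- c(selected, cid)
    if (min(nchar(seqs)) >= target_core_length) break
  }
  if (target_core_length > 0 && min(nchar(seqs)) < target_core_length) {
    warning("requested length unreachable: all ", length(selected),
            " core clusters used, minimum core length ", min(nchar(seqs)),
            " < ", target_core_length)
  }
  segments <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(barcode_id = character(), gene_id = character(),
                   cog_id = character(), start = integer(), end = integer(),
                   origin = character(), product = character())
  bs <- new_barcode_set(seqs, segments, requested_length = target_core_length,
                        accessory_fraction = 0)
  attr(bs, "selected_cogs") <- selected
  bs
}

#' Select accessory clusters to cover per-genome accessory budgets
#'
#' Greedy cover: repeatedly pick the accessory cluster present in the
#' largest number of genomes still below their accessory length budget
#' (ties broken by the longer maximum member gene, then the smaller cluster
#' id); each selected cluster contributes its member gene to every genome
#' that has one. Stops when every genome meets its budget or clusters are
#' exhausted.
#'
#' @param accessory Tibble of accessory cluster memberships
#'   (from [accessory_cogs()]).
#' @param gene_lookup Tibble of gene records.
#' @param budget Accessory length budget per genome (bp); either a scalar or
#'   a named vector over genomes.
#' @param genomes Character vector of genome ids to cover.
#' @return Named list (by genome) of tibbles `cog_id`, `gene_id` in
#'   selection order; selected cluster ids as attribute `"selected_cogs"`.
#' @export
select_accessory_genes <- function(accessory, gene_lookup, budget, genomes) {
  if (length(budget) == 1L) {
    budget <- stats::setNames(rep(budget, length(genomes)), genomes)
  }
  filled <- stats::setNames(rep(0, length(genomes)), genomes)
  picks <- stats::setNames(vector("list", length(genomes)), genomes)
  if (nrow(accessory) == 0L) {
    if (any(budget > 0)) warning("no accessory genes available")
    out <- lapply(picks, function(x)
      tibble::tibble(cog_id = character(), gene_id = character()))
    attr(out, "selected_cogs") <- character(0)
    return(out)
  }
  acc <- dplyr::left_join(
    accessory, dplyr::select(gene_lookup, "gene_id", "nt"), by = "gene_id")
  acc$len <- nchar(acc$nt)
  maxlen <- tapply(acc$len, acc$cog_id, max)
  remaining <- unique(acc$cog_id)
  selected <- character(0)
  repeat {
    below <- names(filled)[filled < budget[names(filled)]]
    if (length(below) == 0L || length(remaining) == 0L) break
    cover <- acc[acc$cog_id %in% remaining & acc$genome_id %in% below, ] %>%
      dplyr::distinct(.data$cog_id, .data$genome_id) %>%
      dplyr::count(.data$cog_id)
    if (nrow(cover) == 0L) break
    cover$maxlen <- as.numeric(maxlen[cover$cog_id])
    cover <- cover[order(-cover$n, -cover$maxlen, cover$cog_id), ]
    cid <- cover$cog_id[1]
    members <- acc[acc$cog_id == cid, ]
    # one gene per genome: keep the longest, deterministic on ties
    members <- members[order(-members$len, members$gene_id), ]
    members <- members[!duplicated(members$genome_id), ]
    for (k in seq_len(nrow(members))) {
      g <- members$genome_id[k]
      picks[[g]] <- dplyr::bind_rows(
        picks[[g]], tibble::tibble(cog_id = cid,
                                   gene_id = members$gene_id[k]))
      filled[[g]] <- filled[[g]] + members$len[k]
    }
    selected <- c(selected, cid)
    remaining <- setdiff(remaining, cid)
  }
  uncovered <- names(filled)[filled < budget[names(filled)]]
  if (length(uncovered) > 0L && any(budget > 0)) {
    warning("accessory budget not met for: ",
            paste(uncovered, collapse = ", "))
  }
  out <- lapply(picks, function(x) {
    x %||% tibble::tibble(cog_id = character(), gene_id = character())
  })
  attr(out, "selected_cogs") <- selected
  out
}

#' Build a complete barcode set from genomes
#'
#' End-to-end barcode construction: clusters the genomes' genes (unless a
#' `cog_set` and scored statistics are supplied), assembles the core part to
#' `(1 - accessory_fraction) * requested_length` and appends accessory genes
#' toward the remaining per-genome budget.
#'
#' @param genomes List of `genome` objects.
#' @param requested_length Requested barcode length (bp).
#' @param accessory_fraction Requested accessory proportion in `[0, 1)`;
#'   the default 0.3 gives the 70/30 core/accessory split.
#' @param cogs Optional precomputed `cog_set`.
#' @param stats Optional precomputed statistics from [score_core_cogs()].
#' @param e_cutoff Protein search e-value cut-off when clustering here.
#' @return A `barcode_set`.
#' @export
build_barcode_set <- function(genomes, requested_length,
                              accessory_fraction = 0.3, cogs = NULL,
                              stats = NULL, e_cutoff = 1e-4) {
  stopifnot(accessory_fraction >= 0, accessory_fraction < 1)
  if (is.null(cogs)) cogs <- cluster_cogs(genomes, e_cutoff = e_cutoff)
  if (is.null(stats)) stats <- score_core_cogs(cogs, genomes)
  lookup <- dplyr::bind_rows(lapply(genomes, extract_cds))
  target_core <- (1 - accessory_fraction) * requested_length
  bs <- assemble_core_barcode(stats, cogs, lookup, target_core)
  core_cog_ids <- attr(bs, "selected_cogs")
  seqs <- bs$barcodes
  segs <- bs$segments
  target_acc <- stats::setNames(
    pmax(0, requested_length - nchar(seqs)), names(seqs))
  if (accessory_fraction > 0) {
    picks <- select_accessory_genes(accessory_cogs(cogs), lookup,
                                    budget = target_acc,
                                    genomes = cogs$genomes)
    for (g in names(picks)) {
      p <- picks[[g]]
      for (k in seq_len(nrow(p))) {
        i <- match(p$gene_id[k], lookup$gene_id)
        nt <- lookup$nt[i]
        segs <- dplyr::bind_rows(segs, tibble::tibble(
          barcode_id = g, gene_id = p$gene_id[k], cog_id = p$cog_id[k],
          start = nchar(seqs[[g]]), end = nchar(seqs[[g]]) + nchar(nt),
          origin = "accessory", product = lookup$product[i]))
        seqs[[g]] <- paste0(seqs[[g]], nt)
      }
    }
  }
  segs <- segs %>%
    dplyr::group_by(.data$barcode_id) %>%
    dplyr::mutate(segment_index = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("barcode_id", "segment_index", dplyr::everything())
  out <- new_barcode_set(seqs, segs, requested_length, accessory_fraction)
  attr(out, "selected_cogs") <- core_cog_ids
  out
}

#' Write barcode FASTA and per-barcode info files
#'
#' Writes one multi-FASTA with a record per genome barcode (60-character
#' line wrap) and one tab-separated info file per barcode listing its
#' segments with 1-based inclusive coordinates.
#'
#' @param bs A non-empty `barcode_set`.
#' @param out_dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Named list of written paths (`fasta`, `info`).
#' @export
write_barcode_outputs <- function(bs, out_dir, prefix = "barcodes") {
  if (length(bs$barcodes) == 0L || all(nchar(bs$barcodes) == 0L)) {
    stop("empty barcode set: nothing to write")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, paste0(prefix, ".fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(bs$barcodes)), fasta, width = 60L)
  info_paths <- character(0)
  for (g in names(bs$barcodes)) {
    seg <- bs$segments[bs$segments$barcode_id == g, ]
    tab <- tibble::tibble(
      barcode_id = seg$barcode_id, segment_index = seg$segment_index,
      gene_id = seg$gene_id, start = seg$start + 1L, end = seg$end,
      origin = seg$origin, product = seg$product)
    p <- file.path(out_dir, paste0(prefix, "_", gsub("[^A-Za-z0-9_.-]", "_", g),
                                   ".info"))
    readr::write_tsv(tab, p)
    info_paths <- c(info_paths, p)
  }
  list(fasta = fasta, info = info_paths)
}

#' Read a barcode FASTA back into a barcode_set
#'
#' Segment information is not recovered; the result is sufficient for read
#' binning.
#'
#' @param path Barcode FASTA file.
#' @return A `barcode_set` with empty segment table.
#' @export
read_barcode_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- stats::setNames(
    vapply(as.character(seqs), normalize_dna, character(1),
           USE.NAMES = FALSE),
    names(seqs))
  new_barcode_set(
    chr,
    tibble::tibble(barcode_id = character(), segment_index = integer(),
                   gene_id = character(), cog_id = character(),
                   start = integer(), end = integer(), origin = character(),
                   product = character()),
    requested_length = max(nchar(chr)), accessory_fraction = NA_real_)
}
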