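# Read binning against barcode sequences: seeded local alignment, the
# adaptive S' score filter, alignment/read specificity, the vicinity
# correction, read scores and per-barcode detection scores.

load_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    first <- readLines(reads, n = 1L)
    fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(reads, format = fmt)
    stats::setNames(vapply(as.character(x), normalize_dna, character(1),
                           USE.NAMES = FALSE),
                    sub("\\s.*$", "", names(x)))
  } else if (inherits(reads, "DNAStringSet")) {
    stats::setNames(vapply(as.character(reads), normalize_dna, character(1),
                           USE.NAMES = FALSE),
                    sub("\\s.*$", "", names(reads)))
  } else if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    vapply(reads, normalize_dna, character(1))
  } else stop("unreadable reads input")
}

#' Align metagenomic reads to barcode sequences
#'
#' The built-in seeded aligner: exact nucleotide k-mer matches between read
#' and barcode nominate candidate (read, strand, barcode) triples; the read
#' is then aligned by affine-gap Smith-Waterman (match +1, mismatch -2, gap
#' of length g costing `gap_open + g * gap_extend`) against the barcode
#' window spanned by the seed diagonals. At most one hit is kept per
#' (read, barcode) pair -- the best-scoring local alignment over both
#' strands -- and hits below the reporting threshold `min_score` are
#' dropped.
#'
#' @param reads Reads as a FASTA/FASTQ path (qualities ignored), a
#'   `DNAStringSet`, or a named character vector.
#' @param barcodes A `barcode_set` (or object with `$barcodes` named
#'   character vector).
#' @param k Seed k-mer length.
#' @param stride Distance between sampled seed start positions on the read.
#' @param window_pad Barcode window padding around the seed diagonals (bp).
#' @param min_score Reporting threshold on the raw alignment score.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring scheme.
#' @return Tibble of hits: `read_id`, `barcode_id`, `raw_score`,
#'   `read_length`, `e_value`; the number of input reads is attached as
#'   attribute `"n_total_reads"`.
#' @export
align_reads_to_barcodes <- function(reads, barcodes, k = 12L, stride = 13L,
                                    window_pad = 25L, min_score = 30,
                                    match = 1, mismatch = -2,
                                    gap_open = 5, gap_extend = 2) {
  bseqs <- barcodes$barcodes
  if (length(bseqs) == 0L) stop("empty barcode set")
  rseqs <- load_reads(reads)
  if (length(rseqs) == 0L) stop("no reads found")
  empty <- tibble::tibble(read_id = character(), barcode_id = character(),
                          raw_score = numeric(), read_length = integer(),
                          e_value = numeric())
  attr(empty, "n_total_reads") <- length(rseqs)

  bcodes <- lapply(bseqs, encode_dna)
  bindex <- data.table::rbindlist(lapply(seq_along(bcodes), function(b) {
    kc <- kmer_codes(bcodes[[b]], k)
    if (length(kc$starts) == 0L) return(NULL)
    data.table::data.table(kmer = kc$codes, barcode = b, bpos = kc$starts)
  }))
  if (nrow(bindex) == 0L) return(empty)

  fwd <- lapply(rseqs, encode_dna)
  rc <- lapply(fwd, function(co) {
    x <- rev(co)
    y <- 3L - x
    y[x > 3L] <- 4L
    y
  })
  # sampled seed k-mers over all reads at once
  lens <- lengths(fwd)
  n_start <- pmax(0L, (lens - k) %/% stride + 1L)
  rel <- sequence(n_start, from = 1L, by = stride)
  ridx <- rep(seq_along(fwd), n_start)
  seed_table <- function(codes_list, strand) {
    big <- unlist(codes_list, use.names = FALSE)
    goff <- c(0L, cumsum(lens))
    gs <- goff[ridx] + rel
    v <- numeric(length(gs)); bad <- logical(length(gs))
    for (o in 0:(k - 1L)) {
      cc <- big[gs + o]
      bad <- bad | cc > 3L
      v <- v * 4 + cc
    }
    data.table::data.table(kmer = v[!bad], read = ridx[!bad],
                           strand = strand, rpos = rel[!bad])
  }
  seeds <- data.table::rbindlist(list(seed_table(fwd, 1L),
                                      seed_table(rc, 2L)))
  if (nrow(seeds) == 0L) return(empty)
  data.table::setkey(bindex, kmer)
  hits <- bindex[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits[, `:=`(diag = bpos - rpos)]
  # a read seeding at several distant places on one barcode (similar genes,
  # chance repeats) gets one banded alignment per diagonal group
  data.table::setorderv(hits, c("read", "strand", "barcode", "diag"))
  hits[, grp := cumsum(c(TRUE, diff(diag) > 60L)),
       by = c("read", "strand", "barcode")]
  cand <- hits[, list(dmin = min(diag), dmax = max(diag)),
               by = c("read", "strand", "barcode", "grp")]

  rlen <- nchar(rseqs)
  blen <- nchar(bseqs)
  scores <- cpp_candidate_scores(
    fwd, rc, bcodes, cand$read, cand$strand, cand$barcode,
    cand$dmin - window_pad, cand$dmax + k + window_pad,
    nt_submat(match, mismatch), gap_open, gap_extend)
  cand[, score := scores]
  best <- cand[, list(raw_score = max(score)), by = c("read", "barcode")]
  best <- best[best$raw_score >= min_score, ]
  if (nrow(best) == 0L) return(empty)
  out <- tibble::tibble(
    read_id = names(rseqs)[best$read],
    barcode_id = names(bseqs)[best$barcode],
    raw_score = best$raw_score,
    read_length = unname(rlen[best$read]),
    e_value = unname(ka_evalue(best$raw_score, rlen[best$read],
                               blen[best$barcode], "nt")))
  out <- dplyr::arrange(out, .data$read_id, dplyr::desc(.data$raw_score))
  attr(out, "n_total_reads") <- length(rseqs)
  out
}

#' The adaptive alignment-score cut-off S'
#'
#' `S' = S + (L - S) / (1 + exp(3 (L - S) / (S log10 N)))
#'        - 10 (ln((2 S + 100) / (L + 100)) - 1)`,
#' where `S` is the average alignment score of the aligned reads, `L` their
#' average length and `N` their number.
#'
#' @param S Average alignment score (must be positive).
#' @param L Average read length.
#' @param N Number of aligned reads.
#' @return The cut-off value S'.
#' @examples
#' compute_sprime(100, 250, 1000)  # ~138.9
#' @export
compute_sprime <- function(S, L, N) {
  if (S <= 0) stop("S' undefined: average alignment score must be positive")
  S + (L - S) / (1 + exp(3 * (L - S) / (S * log10(N)))) -
    10 * (log((2 * S + 100) / (L + 100)) - 1)
}

#' Filter read hits by the S' cut-off
#'
#' Computes the pre-filter pool statistics (per-read best score, read
#' length, read count), evaluates [compute_sprime()] once and removes hits
#' scoring below it. With fewer than 2 aligned reads the filter is skipped
#' (the formula's `log10 N` denominator vanishes).
#'
#' @param hits Hit tibble from [align_reads_to_barcodes()].
#' @return The filtered hit tibble; the statistics (`S`, `L`, `N`,
#'   `sprime`, `filtered`) are attached as attribute `"sprime_stats"`.
#' @export
sprime_filter <- function(hits) {
  per_read <- hits %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(best = max(.data$raw_score),
                     len = .data$read_length[1], .groups = "drop")
  N <- nrow(per_read)
  if (N < 2L) {
    warning("fewer than 2 aligned reads: S' filtering skipped")
    attr(hits, "sprime_stats") <- list(S = NA_real_, L = NA_real_, N = N,
                                       sprime = NA_real_, filtered = 0L)
    return(hits)
  }
  S <- mean(per_read$best)
  L <- mean(per_read$len)
  sp <- compute_sprime(S, L, N)
  keep <- hits$raw_score >= sp
  out <- hits[keep, ]
  attr(out, "sprime_stats") <- list(S = S, L = L, N = N, sprime = sp,
                                    filtered = sum(!keep))
  attr(out, "n_total_reads") <- attr(hits, "n_total_reads")
  out
}

#' Alignment specificity of a hit pool
#'
#' `1 - (N_matches - N_aligned_reads) / (N_aligned_reads (N_barcodes - 1))`:
#' 1 when every aligned read matches exactly one barcode, 0 when every
#' aligned read matches every barcode.
#'
#' @param n_matches Total number of hits.
#' @param n_aligned_reads Number of distinct aligned reads.
#' @param n_barcodes Number of barcodes in the set.
#' @return Specificity in `[0, 1]`.
#' @export
alignment_specificity <- function(n_matches, n_aligned_reads, n_barcodes) {
  stopifnot(n_aligned_reads >= 1, n_matches >= n_aligned_reads)
  if (n_barcodes < 2L) {
    warning("single barcode: alignment specificity defined as 1")
    return(1)
  }
  val <- 1 - (n_matches - n_aligned_reads) /
    (n_aligned_reads * (n_barcodes - 1))
  min(1, max(0, val))
}

#' Specificity of a single read
#'
#' Linear between the endpoints: 1 for a read aligned to one barcode, 0 for
#' a read aligned to all barcodes.
#'
#' @param n_hit Number of barcodes the read aligns to.
#' @param n_barcodes Number of barcodes in the set.
#' @return `(n_barcodes - n_hit) / (n_barcodes - 1)`.
#' @export
read_specificity <- function(n_hit, n_barcodes) {
  stopifnot(all(n_hit >= 1), all(n_hit <= n_barcodes))
  if (n_barcodes < 2L) {
    warning("single barcode: read specificity defined as 1")
    return(rep(1, length(n_hit)))
  }
  (n_barcodes - n_hit) / (n_barcodes - 1)
}

#' Vicinity coefficients of reads aligned to several barcodes
#'
#' A Jaccard distance matrix over barcodes is computed from their
#' (post-filter) read sets: `d(a, b) = 1 - |reads(a) & reads(b)| /
#' |reads(a) | reads(b)|`. A read aligned to two or more barcodes gets
#' `r_vicinity = 10 * max(d among its barcodes) / max(d over the matrix)`;
#' reads aligned to a single barcode get 0, and when the matrix maximum is
#' 0 every read gets 0. Values therefore lie in `[0, 10]`: small when a
#' read's barcodes share most of their reads (closely related organisms),
#' large when the read hits unrelated barcodes.
#'
#' @param hits Post-filter hit tibble (`read_id`, `barcode_id`).
#' @return List: `per_read` tibble (`read_id`, `n_hit`, `r_vicinity`) and
#'   the `distance` matrix.
#' @export
compute_vicinity <- function(hits) {
  barcodes <- sort(unique(hits$barcode_id))
  nb <- length(barcodes)
  sets <- lapply(barcodes, function(b) unique(hits$read_id[hits$barcode_id == b]))
  names(sets) <- barcodes
  D <- matrix(0, nb, nb, dimnames = list(barcodes, barcodes))
  if (nb >= 2L) {
    for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
      u <- length(union(sets[[i]], sets[[j]]))
      d <- if (u == 0L) 0 else 1 - length(intersect(sets[[i]], sets[[j]])) / u
      D[i, j] <- D[j, i] <- d
    }
  }
  maxd <- if (nb >= 2L) max(D) else 0
  per_read <- hits %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(n_hit = dplyr::n_distinct(.data$barcode_id),
                     barcodes = list(unique(.data$barcode_id)),
                     .groups = "drop")
  rv <- vapply(seq_len(nrow(per_read)), function(i) {
    bs <- per_read$barcodes[[i]]
    if (length(bs) < 2L || maxd == 0) return(0)
    min(10, 10 * max(D[bs, bs]) / maxd)   # guard rounding at the maximum
  }, numeric(1))
  list(per_read = tibble::tibble(read_id = per_read$read_id,
                                 n_hit = per_read$n_hit,
                                 r_vicinity = rv),
       distance = D)
}

# correction factor shared by the two read scores; base exp() for
# ReadScore1, base 1.5 for ReadScore2
score_correction <- function(r_spec, r_vic, base = exp(1)) {
  (r_spec + base^(r_spec * r_vic) + 1) / (r_spec + base^(r_vic) + 1)
}

#' Per-read and per-barcode detection scores
#'
#' Implements the read scores
#' `ReadScore1 = (score / read_length) * (r_spec + e^(r_spec r_vic) + 1) /
#'   (r_spec + e^(r_vic) + 1)` (one value per read, computed from its best
#' hit) and
#' `ReadScore2 = a_spec * (N_reads|barcode / N_reads) * (score /
#'   read_length) * (r_spec + 1.5^(r_spec r_vic) + 1) / (r_spec +
#'   1.5^(r_vic) + 1)` (barcode-specific), then aggregates them per barcode
#' as `BarcodeScore_i = (1 + sum ReadScore) / (1 + 3 L_i T / (4 sum L_j))
#' - 1`.
#'
#' The scope of `T` (the equation's unsubscripted "sum of alignment
#' scores") and the meaning of `N_reads` are configurable:
#' `eq6_score_sum = "per_barcode"` (default) sums length-normalized scores
#' over the reads aligned to barcode i, `"global"` over all aligned reads,
#' `"raw"` uses un-normalized scores; `nreads_mode = "aligned"` (default)
#' takes `N_reads` as the number of aligned reads, `"total"` as all input
#' reads. See the package vignette for the rationale of the defaults.
#'
#' @param hits Post-filter hit tibble.
#' @param barcode_lengths Named vector of barcode lengths (bp).
#' @param n_total_reads Total reads in the metagenome (for
#'   `nreads_mode = "total"`).
#' @param cutoff1,cutoff2 Present/absent cut-offs on BarcodeScore1/2.
#' @param eq6_score_sum,nreads_mode Interpretation switches (above).
#' @return A `binning_result`: tibble with `barcode_id`, `barcode_length`,
#'   `n_reads`, `score1`, `score2`, `present`; pool statistics and the
#'   per-read assessments are attached as attributes.
#' @export
compute_barcode_scores <- function(hits, barcode_lengths,
                                   n_total_reads = NULL,
                                   cutoff1 = 2.3, cutoff2 = 0.5,
                                   eq6_score_sum = c("per_barcode", "global",
                                                     "raw"),
                                   nreads_mode = c("aligned", "total")) {
  eq6_score_sum <- match.arg(eq6_score_sum)
  nreads_mode <- match.arg(nreads_mode)
  nb <- length(barcode_lengths)
  if (nb == 0L) stop("empty barcode set")
  bl_sum <- sum(barcode_lengths)
  all_ids <- names(barcode_lengths)

  if (nrow(hits) == 0L) {
    res <- tibble::tibble(barcode_id = all_ids,
                          barcode_length = as.numeric(barcode_lengths),
                          n_reads = 0L, score1 = 0, score2 = 0,
                          present = FALSE)
    return(new_binning_result(res, cutoff1, cutoff2, eq6_score_sum,
                              nreads_mode,
                              pool = list(n_aligned_reads = 0L,
                                          n_matches = 0L,
                                          n_barcodes = nb,
                                          a_specificity = NA_real_,
                                          n_total_reads = n_total_reads),
                              assessments = NULL))
  }

  n_aligned <- dplyr::n_distinct(hits$read_id)
  n_matches <- nrow(hits)
  a_spec <- alignment_specificity(n_matches, n_aligned, nb)
  n_reads_denom <- switch(nreads_mode,
    aligned = n_aligned,
    total = if (is.null(n_total_reads)) {
      stop("nreads_mode = 'total' requires n_total_reads")
    } else n_total_reads)

  vic <- compute_vicinity(hits)
  per_read <- vic$per_read
  per_read$r_specificity <- read_specificity(per_read$n_hit, nb)
  per_barcode_reads <- hits %>%
    dplyr::group_by(.data$barcode_id) %>%
    dplyr::summarise(n_reads = dplyr::n_distinct(.data$read_id),
                     .groups = "drop")
  nb_reads <- stats::setNames(rep(0L, nb), all_ids)
  nb_reads[per_barcode_reads$barcode_id] <- per_barcode_reads$n_reads

  h <- dplyr::left_join(hits, per_read, by = "read_id")
  h$norm <- h$raw_score / h$read_length
  best_norm <- h %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(best_norm = max(.data$norm),
                     r_specificity = .data$r_specificity[1],
                     r_vicinity = .data$r_vicinity[1], .groups = "drop")
  best_norm$read_score1 <- best_norm$best_norm *
    score_correction(best_norm$r_specificity, best_norm$r_vicinity)
  h <- dplyr::left_join(
    h, dplyr::select(best_norm, "read_id", "read_score1"), by = "read_id")
  h$read_score2 <- a_spec * (nb_reads[h$barcode_id] / n_reads_denom) *
    h$norm * score_correction(h$r_specificity, h$r_vicinity, base = 1.5)

  sums <- h %>%
    dplyr::group_by(.data$barcode_id) %>%
    dplyr::summarise(sum_rs1 = sum(.data$read_score1),
                     sum_rs2 = sum(.data$read_score2),
                     t_i = sum(.data$norm),
                     t_raw_i = sum(.data$raw_score),
                     .groups = "drop")
  full <- tibble::tibble(barcode_id = all_ids,
                         barcode_length = as.numeric(barcode_lengths)) %>%
    dplyr::left_join(sums, by = "barcode_id") %>%
    dplyr::mutate(dplyr::across(c("sum_rs1", "sum_rs2", "t_i", "t_raw_i"),
                                ~ dplyr::coalesce(.x, 0)))
  T_global <- sum(best_norm$best_norm)
  T_raw_global <- sum(h %>% dplyr::group_by(.data$read_id) %>%
                        dplyr::summarise(m = max(.data$raw_score),
                                         .groups = "drop") %>%
                        dplyr::pull("m"))
  Tvals <- switch(eq6_score_sum,
                  per_barcode = full$t_i,
                  global = rep(T_global, nrow(full)),
                  raw = rep(T_raw_global, nrow(full)))
  denom <- 1 + 3 * full$barcode_length * Tvals / (4 * bl_sum)
  res <- tibble::tibble(
    barcode_id = full$barcode_id,
    barcode_length = full$barcode_length,
    n_reads = as.integer(nb_reads[full$barcode_id]),
    score1 = (1 + full$sum_rs1) / denom - 1,
    score2 = (1 + full$sum_rs2) / denom - 1)
  res$present <- res$score1 >= cutoff1 & res$score2 >= cutoff2
  assessments <- dplyr::select(best_norm, "read_id", "r_specificity",
                               "r_vicinity", "read_score1")
  new_binning_result(res, cutoff1, cutoff2, eq6_score_sum, nreads_mode,
                     pool = list(n_aligned_reads = n_aligned,
                                 n_matches = n_matches, n_barcodes = nb,
                                 a_specificity = a_spec,
                                 n_total_reads = n_total_reads),
                     assessments = assessments,
                     read_scores = dplyr::select(h, "read_id", "barcode_id",
                                                 "raw_score", "read_length",
                                                 "read_score1",
                                                 "read_score2"))
}

new_binning_result <- function(res, cutoff1, cutoff2, eq6_score_sum,
                               nreads_mode, pool, assessments,
                               read_scores = NULL) {
  structure(res, class = c("binning_result", class(res)),
            cutoffs = c(cutoff1 = cutoff1, cutoff2 = cutoff2),
            eq6_score_sum = eq6_score_sum, nreads_mode = nreads_mode,
            pool = pool, assessments = assessments,
            read_scores = read_scores)
}

#' Re-apply present/absent cut-offs to a binning result
#'
#' A barcode is called present when `score1 >= cutoff1` **and**
#' `score2 >= cutoff2` (boundary values count as present). The defaults
#' 2.3 / 0.5 favour sensitivity.
#'
#' @param result A `binning_result`.
#' @param cutoff1,cutoff2 Cut-offs on BarcodeScore1 and BarcodeScore2.
#' @return The result with its `present` column and cut-off attribute
#'   updated.
#' @export
classify_barcodes <- function(result, cutoff1 = 2.3, cutoff2 = 0.5) {
  result$present <- result$score1 >= cutoff1 & result$score2 >= cutoff2
  attr(result, "cutoffs") <- c(cutoff1 = cutoff1, cutoff2 = cutoff2)
  result
}

#' Bin metagenomic reads against a barcode set
#'
#' The full detection cascade: seeded alignment, S' filtering, specificity
#' and vicinity corrections, read scores, barcode scores and present/absent
#' calls.
#'
#' @inheritParams align_reads_to_barcodes
#' @inheritParams compute_barcode_scores
#' @param ... Passed to [align_reads_to_barcodes()].
#' @return A `binning_result` (see [compute_barcode_scores()]); the S'
#'   statistics are attached as attribute `"sprime_stats"`.
#' @export
bin_reads <- function(reads, barcodes, cutoff1 = 2.3, cutoff2 = 0.5,
                      eq6_score_sum = c("per_barcode", "global", "raw"),
                      nreads_mode = c("aligned", "total"), ...) {
  hits <- align_reads_to_barcodes(reads, barcodes, ...)
  n_total <- attr(hits, "n_total_reads")
  filtered <- if (nrow(hits) > 0L) sprime_filter(hits) else hits
  res <- compute_barcode_scores(
    filtered, barcode_lengths(barcodes), n_total_reads = n_total,
    cutoff1 = cutoff1, cutoff2 = cutoff2,
    eq6_score_sum = eq6_score_sum, nreads_mode = nreads_mode)
  attr(res, "sprime_stats") <- attr(filtered, "sprime_stats")
  res
}

#' @export
print.binning_result <- function(x, ...) {
  co <- attr(x, "cutoffs")
  pool <- attr(x, "pool")
  cat("<binning_result> ", nrow(x), " barcodes, ",
      pool$n_aligned_reads %||% 0L, " aligned reads, cut-offs ",
      co[1], "/", co[2], ", ", sum(x$present), " present\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
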