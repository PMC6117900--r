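# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# hand-build a genome object from coding sequences laid head-to-tail on the
# plus strand with fixed 20 bp spacers
toy_genome <- function(genome_id, genes, spacer = strrep("ACGT", 5)) {
  chrom <- spacer
  start <- integer(length(genes)); end <- integer(length(genes))
  for (i in seq_along(genes)) {
    start[i] <- nchar(chrom)
    chrom <- paste0(chrom, genes[[i]])
    end[i] <- nchar(chrom)
    chrom <- paste0(chrom, spacer)
  }
  repl <- stats::setNames(chrom, paste0(genome_id, "_chr"))
  gt <- metabarcoder:::gene_tibble(
    genome_id, rep(paste0(genome_id, "_chr"), length(genes)), start, end,
    rep("+", length(genes)), unlist(genes), names(genes),
    rep(NA_character_, length(genes)))
  metabarcoder:::new_genome(genome_id, repl, gt)
}

# random complete CDS (ATG + sense codons + stop), fixed RNG state assumed
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ct <- metabarcoder:::codon_tables()
  paste(c("ATG", sample(setdiff(ct$sense, "ATG"), n_codons - 2L, TRUE),
          sample(ct$stops, 1L)), collapse = "")
}

# small three-genome family reused across unit tests
small_family <- function() {
  cached("small_family", simulate_genome_family(
    n_genomes = 3, n_core = 10, n_accessory = 5, gene_length_mean = 450,
    gene_length_sd = 60, seed = 42))
}

small_cogs <- function() {
  cached("small_cogs", cluster_cogs(small_family()$genomes))
}

small_stats <- function() {
  cached("small_stats", score_core_cogs(small_cogs(), small_family()$genomes))
}

# --- independent oracles -------------------------------------------------

# exhaustive local protein alignment via Biostrings (same gap convention:
# a gap of length g costs gapOpening + g * gapExtension)
oracle_protein_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = BLOSUM62, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & pb != "-"
  list(score = Biostrings::score(al),
       identities = sum(pa[both] == pb[both]),
       positives = sum(BLOSUM62[cbind(pa[both], pb[both])] > 0))
}

# second, table-driven codon translation (independent of the package path)
oracle_translate <- function(nt) {
  x <- Biostrings::translate(Biostrings::DNAStringSet(nt),
                             genetic.code = Biostrings::getGeneticCode("11"),
                             if.fuzzy.codon = "solve")
  x <- as.character(x)
  sub("\\*$", "", x)
}

# term-by-term evaluation of the adaptive score cut-off
oracle_sprime <- function(S, L, N) {
  term2 <- (L - S) / (1 + exp((3 * (L - S)) / (S * log(N, base = 10))))
  term3 <- 10 * (log((2 * S + 100) / (L + 100)) - 1)
  S + term2 - term3
}

hit_row <- function(read_id, barcode_id, raw, len) {
  tibble::tibble(read_id = read_id, barcode_id = barcode_id,
                 raw_score = raw, read_length = len,
                 e_value = 1e-30)
}

# independent spreadsheet-style evaluation of the score cascade on a fixed
# six-read, three-barcode micro-pool
eq6_micro_fixture <- function() {
  list(hits = dplyr::bind_rows(
         hit_row("r1", "X", 240, 250L),
         hit_row("r2", "X", 200, 250L),
         hit_row("r3", "X", 230, 250L), hit_row("r3", "Y", 210, 250L),
         hit_row("r4", "Y", 250, 250L),
         hit_row("r5", "Z", 100, 200L),
         hit_row("r6", "X", 150, 300L), hit_row("r6", "Y", 140, 300L),
         hit_row("r6", "Z", 130, 300L)),
       bl = c(X = 1000, Y = 1000, Z = 2000))
}

oracle_eq6 <- function(hits, bl, score_sum, nreads_mode, n_total = NULL) {
  nb <- length(bl)
  reads <- split(hits, hits$read_id)
  n_aligned <- length(reads)
  n_matches <- nrow(hits)
  a_spec <- 1 - (n_matches - n_aligned) / (n_aligned * (nb - 1))
  sets <- lapply(names(bl), function(b) hits$read_id[hits$barcode_id == b])
  names(sets) <- names(bl)
  D <- matrix(0, nb, nb, dimnames = list(names(bl), names(bl)))
  for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
    u <- union(sets[[i]], sets[[j]])
    D[i, j] <- D[j, i] <- if (length(u) == 0) 0 else
      1 - length(intersect(sets[[i]], sets[[j]])) / length(u)
  }
  maxd <- max(D)
  per_read <- lapply(reads, function(h) {
    bs <- h$barcode_id
    rspec <- (nb - length(bs)) / (nb - 1)
    rvic <- if (length(bs) < 2 || maxd == 0) 0 else
      10 * max(D[bs, bs]) / maxd
    best <- max(h$raw_score / h$read_length)
    rs1 <- best * (rspec + exp(rspec * rvic) + 1) / (rspec + exp(rvic) + 1)
    list(rspec = rspec, rvic = rvic, rs1 = rs1, best = best, h = h)
  })
  n_denom <- if (nreads_mode == "aligned") n_aligned else n_total
  nb_reads <- vapply(names(bl), function(b)
    length(unique(hits$read_id[hits$barcode_id == b])), numeric(1))
  out <- numeric(0)
  for (b in names(bl)) {
    s1 <- 0; s2 <- 0; t_i <- 0; t_raw_i <- 0
    for (pr in per_read) {
      hb <- pr$h[pr$h$barcode_id == b, ]
      if (nrow(hb) == 0) next
      s1 <- s1 + pr$rs1
      norm <- hb$raw_score / hb$read_length
      s2 <- s2 + a_spec * (nb_reads[[b]] / n_denom) * norm *
        (pr$rspec + 1.5^(pr$rspec * pr$rvic) + 1) /
        (pr$rspec + 1.5^(pr$rvic) + 1)
      t_i <- t_i + norm
    }
    Tv <- switch(score_sum,
                 per_barcode = t_i,
                 global = sum(vapply(per_read, `[[`, numeric(1), "best")),
                 raw = sum(vapply(per_read, function(p)
                   max(p$h$raw_score), numeric(1))))
    den <- 1 + 3 * bl[[b]] * Tv / (4 * sum(bl))
    out <- c(out, stats::setNames(c((1 + s1) / den - 1, (1 + s2) / den - 1),
                                  paste0(b, c("_s1", "_s2"))))
  }
  out
}

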