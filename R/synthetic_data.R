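# Simulation of genome families with controlled divergence and of shotgun
# metagenomes with known composition. These stand in for curated genome
# panels and an external read simulator: families of single-copy core genes
# shared by all genomes at a controlled protein divergence, genome-specific
# accessory genes, and reads with truncated-normally distributed lengths at
# specified per-genome abundances.

.codon_cache <- new.env(parent = emptyenv())

codon_tables <- function(table = "11") {
  key <- paste0("t", table)
  if (is.null(.codon_cache[[key]])) {
    gc <- Biostrings::getGeneticCode(table)
    codons <- names(gc)
    sense <- codons[gc != "*"]
    stops <- codons[gc == "*"]
    nts <- c("A", "C", "G", "T")
    neighbors <- lapply(codons, function(co) {
      out <- character(0)
      for (p in 1:3) for (b in nts) {
        if (substr(co, p, p) != b) {
          x <- co
          substr(x, p, p) <- b
          out <- c(out, x)
        }
      }
      out
    })
    names(neighbors) <- codons
    syn <- lapply(codons, function(co) {
      nb <- neighbors[[co]]
      nb[gc[nb] == gc[co] & gc[nb] != "*"]
    })
    nonsyn <- lapply(codons, function(co) {
      nb <- neighbors[[co]]
      nb[gc[nb] != gc[co] & gc[nb] != "*"]
    })
    names(syn) <- names(nonsyn) <- codons
    .codon_cache[[key]] <- list(gc = gc, sense = sense, stops = stops,
                                syn = syn, nonsyn = nonsyn)
  }
  .codon_cache[[key]]
}

random_gene <- function(n_codons, ct) {
  stopifnot(n_codons >= 3L)
  body <- sample(setdiff(ct$sense, "ATG"), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(ct$stops, 1L)), collapse = "")
}

mutate_gene_copy <- function(gene, d_aa, nonsyn_fraction, ct) {
  n <- nchar(gene) / 3L
  codons <- substring(gene, seq(1L, nchar(gene), 3L), seq(3L, nchar(gene), 3L))
  internal <- 2:(n - 1L)
  m <- length(internal)
  n_ns <- stats::rbinom(1L, m, d_aa)
  d_syn <- d_aa * (1 - nonsyn_fraction) / nonsyn_fraction
  n_sy <- stats::rbinom(1L, m, min(1, d_syn))
  pos <- sample(internal, min(m, n_ns + n_sy))
  ns_pos <- pos[seq_len(min(n_ns, length(pos)))]
  sy_pos <- setdiff(pos, ns_pos)
  for (p in ns_pos) {
    alt <- ct$nonsyn[[codons[p]]]
    if (length(alt)) codons[p] <- sample(alt, 1L)
  }
  for (p in sy_pos) {
    alt <- ct$syn[[codons[p]]]
    if (length(alt)) codons[p] <- sample(alt, 1L)
  }
  paste(codons, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a family of related genomes with known orthology
#'
#' Generates ancestral single-copy genes (uniform sense-codon usage, ATG
#' start, single terminal stop) for `n_core` core families shared by every
#' genome and `n_accessory` accessory families carried by random genome
#' subsets. Each genome's copy is mutated by placing synonymous and
#' non-synonymous single-nucleotide codon substitutions so that the expected
#' pairwise protein identity equals `protein_identity` and the expected
#' fraction of non-synonymous among all substitutions equals
#' `nonsyn_fraction`. Gene copies are embedded in shuffled order in random
#' intergenic background.
#'
#' @param n_genomes Number of genomes.
#' @param n_core,n_accessory Number of core / accessory gene families.
#' @param gene_length_mean,gene_length_sd Gene length distribution (bp;
#'   rounded to codons, minimum 300 bp).
#' @param protein_identity Target mean pairwise protein identity within a
#'   family, in `(0, 1]`.
#' @param nonsyn_fraction Target fraction of non-synonymous substitutions
#'   among all nucleotide substitutions, in `(0, 1]`.
#' @param accessory_presence Probability that a genome carries an accessory
#'   family (at least one carrier is enforced).
#' @param spacer_range Intergenic spacer length range (bp, uniform).
#' @param genome_prefix Genome id prefix.
#' @param seed Seed fixing all randomness.
#' @return List: `genomes` (list of `genome` objects), `truth` (tibble
#'   `family_id`, `type`, `genome_id`, `gene_id`).
#' @export
simulate_genome_family <- function(n_genomes = 8L, n_core = 50L,
                                   n_accessory = 20L,
                                   gene_length_mean = 900,
                                   gene_length_sd = 150,
                                   protein_identity = 0.8,
                                   nonsyn_fraction = 0.5,
                                   accessory_presence = 0.5,
                                   spacer_range = c(50L, 150L),
                                   genome_prefix = "G",
                                   seed = 1L) {
  stopifnot(protein_identity > 0, protein_identity <= 1,
            nonsyn_fraction > 0, nonsyn_fraction <= 1)
  d_aa <- 1 - sqrt(protein_identity)
  if (d_aa * (1 - nonsyn_fraction) / nonsyn_fraction > 1) {
    stop("infeasible divergence target: implied synonymous rate exceeds 1")
  }
  set.seed(seed)
  ct <- codon_tables()
  gids <- sprintf("%s%02d", genome_prefix, seq_len(n_genomes))
  fam_ids <- c(sprintf("CORE%03d", seq_len(n_core)),
               sprintf("ACC%03d", seq_len(n_accessory)))
  fam_type <- c(rep("core", n_core), rep("accessory", n_accessory))
  genes_by_genome <- stats::setNames(
    replicate(n_genomes, list(), simplify = FALSE), gids)
  truth <- list()
  for (f in seq_along(fam_ids)) {
    len <- max(300, round(stats::rnorm(1, gene_length_mean, gene_length_sd)))
    n_codons <- max(100L, as.integer(round(len / 3)))
    anc <- random_gene(n_codons, ct)
    carriers <- if (fam_type[f] == "core") gids else {
      ca <- gids[stats::runif(n_genomes) < accessory_presence]
      if (length(ca) == 0L) ca <- sample(gids, 1L)
      ca
    }
    for (g in carriers) {
      copy <- if (d_aa == 0) anc else
        mutate_gene_copy(anc, d_aa, nonsyn_fraction, ct)
      tag <- fam_ids[f]
      genes_by_genome[[g]][[tag]] <- copy
      truth[[length(truth) + 1L]] <- tibble::tibble(
        family_id = fam_ids[f], type = fam_type[f], genome_id = g,
        gene_id = paste0(g, "|", tag))
    }
  }
  genomes <- lapply(gids, function(g) {
    tags <- sample(names(genes_by_genome[[g]]))
    seqs <- unlist(genes_by_genome[[g]][tags])
    spacers <- vapply(seq_len(length(tags) + 1L), function(i) {
      random_dna(sample(spacer_range[1]:spacer_range[2], 1L))
    }, character(1))
    chrom <- spacers[1]
    start <- integer(length(tags)); end <- integer(length(tags))
    for (i in seq_along(tags)) {
      start[i] <- nchar(chrom)
      chrom <- paste0(chrom, seqs[i])
      end[i] <- nchar(chrom)
      chrom <- paste0(chrom, spacers[i + 1L])
    }
    repl_id <- paste0(g, "_chr")
    gt <- gene_tibble(g, rep(repl_id, length(tags)), start, end,
                      rep("+", length(tags)), unname(seqs), tags,
                      paste0("simulated ", tags, " protein"))
    new_genome(g, stats::setNames(chrom, repl_id), gt)
  })
  names(genomes) <- gids
  list(genomes = genomes, truth = dplyr::bind_rows(truth))
}

#' Write a genome as a GenBank flat file
#'
#' Minimal LOCUS/FEATURES/ORIGIN records, one per replicon, readable by
#' [read_genome_file()].
#'
#' @param genome A `genome` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (repl_id in names(genome$replicons)) {
    seq <- genome$replicons[[repl_id]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                       repl_id, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s simulated replicon.", repl_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    g <- genome$genes[genome$genes$replicon_id == repl_id, ]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      tag <- sub("^.*\\|", "", g$gene_id[i])
      writeLines(sprintf("                     /locus_tag=\"%s\"", tag), con)
      if (!is.na(g$product[i])) {
        writeLines(sprintf("                     /product=\"%s\"",
                           g$product[i]), con)
      }
    }
    writeLines("ORIGIN", con)
    n <- nchar(seq)
    for (off in seq(1L, n, 60L)) {
      chunk <- substr(seq, off, min(n, off + 59L))
      blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, 10L)))
      writeLines(sprintf("%9d %s", off, tolower(paste(blocks, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Simulate a shotgun metagenome with known composition
#'
#' Draws each read's source genome by abundance, its start uniformly, its
#' length from a normal distribution truncated to a range, and its strand
#' at random. The unassigned abundance mass (`1 - sum(abundances)`) is
#' drawn from a background genome that is never barcoded: by default a
#' random sequence, or a supplied `genome` object. An optional uniform
#' substitution error rate can be applied.
#'
#' @param genomes Named list of `genome` objects (the panel).
#' @param abundances Named abundance fractions over (a subset of) the panel;
#'   must sum to at most 1.
#' @param n_reads Number of reads.
#' @param length_mean,length_sd,length_range Read length distribution
#'   (truncated normal, defaults 275 / 25 within 200-350 bp).
#' @param error_rate Per-base substitution error probability.
#' @param background `"random"` (default), `NULL` (renormalize abundances to
#'   sum to 1) or a `genome` object supplying off-target reads.
#' @param seed Seed fixing all randomness.
#' @param out Optional FASTA output path.
#' @return List: `reads` (named character vector; headers encode source
#'   genome, position and strand), `truth` (tibble `genome_id`,
#'   `abundance`, `n_reads`), `seed`.
#' @export
simulate_metagenome <- function(genomes, abundances, n_reads,
                                length_mean = 275, length_sd = 25,
                                length_range = c(200L, 350L),
                                error_rate = 0, background = "random",
                                seed = 1L, out = NULL) {
  stopifnot(sum(abundances) <= 1 + 1e-9, n_reads > 0)
  stopifnot(all(names(abundances) %in% names(genomes)))
  set.seed(seed)
  probs <- abundances
  rest <- 1 - sum(abundances)
  if (rest > 1e-9) {
    if (identical(background, "random")) {
      mean_len <- mean(vapply(genomes, function(g) sum(nchar(g$replicons)),
                              numeric(1)))
      bg <- new_genome("background",
                       stats::setNames(random_dna(round(mean_len)),
                                       "background_chr"),
                       gene_tibble("background", character(), integer(),
                                   integer(), character(), character(),
                                   character(), character()))
    } else if (inherits(background, "genome")) {
      bg <- background
    } else if (is.null(background)) {
      probs <- abundances / sum(abundances)
      bg <- NULL
    } else stop("invalid `background`")
    if (!is.null(bg)) {
      genomes <- c(genomes, stats::setNames(list(bg), bg$genome_id))
      probs <- c(probs, stats::setNames(rest, bg$genome_id))
    }
  }
  counts <- as.vector(stats::rmultinom(1L, n_reads, probs))
  names(counts) <- names(probs)
  reads <- character(0)
  for (g in names(counts)) {
    ng <- counts[[g]]
    if (ng == 0L) next
    repl <- genomes[[g]]$replicons
    rl <- nchar(repl)
    ridx <- sample.int(length(repl), ng, replace = TRUE, prob = rl)
    lens <- round(stats::rnorm(ng, length_mean, length_sd))
    bad <- lens < length_range[1] | lens > length_range[2] | lens > rl[ridx]
    while (any(bad)) {
      lens[bad] <- round(stats::rnorm(sum(bad), length_mean, length_sd))
      bad <- lens < length_range[1] | lens > length_range[2] |
        lens > rl[ridx]
    }
    starts <- floor(stats::runif(ng, 1, rl[ridx] - lens + 2))
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    seqs <- substring(repl[ridx], starts, starts + lens - 1L)
    rc <- strands == "-"
    if (any(rc)) seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        nerr <- stats::rbinom(1L, nchar(s), error_rate)
        if (nerr == 0L) return(s)
        pos <- sample.int(nchar(s), nerr)
        for (p in pos) {
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, p, p)), 1L)
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_read%06d|%s|%s|%d|%s", g, seq_len(ng), g,
                   names(repl)[ridx], starts, strands)
    reads <- c(reads, stats::setNames(seqs, ids))
  }
  reads <- reads[sample.int(length(reads))]
  truth <- tibble::tibble(genome_id = names(counts),
                          abundance = as.numeric(probs),
                          n_reads = as.integer(counts))
  if (!is.null(out)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), out,
                                width = 80L)
  }
  list(reads = reads, truth = truth, seed = seed)
}
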