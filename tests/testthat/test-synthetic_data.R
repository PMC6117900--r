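test_that("a zero-divergence family yields identical gene copies", {
  fam <- simulate_genome_family(n_genomes = 3, n_core = 4, n_accessory = 0,
                                gene_length_mean = 450, gene_length_sd = 0,
                                protein_identity = 1, seed = 5)
  truth <- fam$truth
  lookup <- dplyr::bind_rows(lapply(fam$genomes, function(g) g$genes))
  for (f in unique(truth$family_id)) {
    nts <- lookup$nt[match(truth$gene_id[truth$family_id == f],
                           lookup$gene_id)]
    expect_equal(length(unique(nts)), 1L)
  }
})

test_that("realized protein identity tracks the divergence target", {
  fam <- cached("family_id_check", simulate_genome_family(
    n_genomes = 3, n_core = 100, n_accessory = 0, gene_length_mean = 600,
    gene_length_sd = 60, protein_identity = 0.8, seed = 13))
  lookup <- dplyr::bind_rows(lapply(fam$genomes, function(g) g$genes))
  tr <- fam$truth
  ids <- vapply(unique(tr$family_id), function(f) {
    aa <- lookup$aa[match(tr$gene_id[tr$family_id == f], lookup$gene_id)]
    pairs <- utils::combn(length(aa), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      a <- strsplit(aa[pairs[1, k]], "")[[1]]
      b <- strsplit(aa[pairs[2, k]], "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.8), 0.03)
})

test_that("the non-synonymous substitution fraction is controlled", {
  fam <- cached("family_id_check", simulate_genome_family(
    n_genomes = 3, n_core = 100, n_accessory = 0, gene_length_mean = 600,
    gene_length_sd = 60, protein_identity = 0.8, seed = 13))
  lookup <- dplyr::bind_rows(lapply(fam$genomes, function(g) g$genes))
  tr <- fam$truth
  gc <- Biostrings::getGeneticCode("11")
  frac <- vapply(unique(tr$family_id)[1:40], function(f) {
    nt <- lookup$nt[match(tr$gene_id[tr$family_id == f], lookup$gene_id)]
    a <- nt[1]; b <- nt[2]
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    diffs <- mapply(function(x, y) sum(strsplit(x, "")[[1]] !=
                                         strsplit(y, "")[[1]]), ca, cb)
    nonsyn <- gc[ca] != gc[cb]
    c(sum(diffs[nonsyn]), sum(diffs))
  }, numeric(2))
  x <- sum(frac[1, ]) / sum(frac[2, ])
  # target 0.5 at the codon level; multi-hit codons blur it slightly
  expect_lt(abs(x - 0.5), 0.1)
})

test_that("always-present accessory families become core by definition", {
  fam <- simulate_genome_family(n_genomes = 3, n_core = 5, n_accessory = 3,
                                gene_length_mean = 450, gene_length_sd = 30,
                                accessory_presence = 1, seed = 9)
  cogs <- cluster_cogs(fam$genomes)
  expect_equal(length(unique(core_cogs(cogs)$cog_id)), 8L)
})

test_that("single-genome abundance puts every read in range and on source", {
  fam <- small_family()
  mg <- simulate_metagenome(fam$genomes, c(G01 = 1.0), n_reads = 1000,
                            seed = 2)
  expect_equal(length(mg$reads), 1000L)
  expect_true(all(grepl("^G01_", names(mg$reads))))
  lens <- nchar(mg$reads)
  expect_true(all(lens >= 200 & lens <= 350))
})

test_that("every read is a substring of its source genome up to strand", {
  fam <- small_family()
  mg <- simulate_metagenome(fam$genomes, c(G01 = 0.6, G02 = 0.4),
                            n_reads = 200, seed = 3, background = NULL)
  meta <- strsplit(names(mg$reads), "\\|")
  for (i in seq_along(mg$reads)) {
    m <- meta[[i]]
    src <- fam$genomes[[m[2]]]$replicons[[m[3]]]
    s <- mg$reads[[i]]
    if (m[5] == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(substr(src, as.integer(m[4]),
                        as.integer(m[4]) + nchar(s) - 1L), s)
  }
})

test_that("empirical composition converges to the requested abundances", {
  fam <- small_family()
  ab <- c(G01 = 0.15, G02 = 0.10, G03 = 0.05)
  mg <- simulate_metagenome(fam$genomes, ab, n_reads = 50000, seed = 4)
  src <- sub("_read.*$", "", names(mg$reads))
  emp <- table(src)[names(ab)] / 50000
  expect_true(all(abs(emp - ab) < 0.01))
  # background fills the remainder
  expect_equal(sum(src == "background") / 50000, 0.7, tolerance = 0.05)
  expect_equal(sum(mg$truth$n_reads), 50000L)
})

test_that("a fixed seed reproduces the metagenome byte for byte", {
  fam <- small_family()
  a <- simulate_metagenome(fam$genomes, c(G01 = 0.5), n_reads = 500,
                           seed = 11)
  b <- simulate_metagenome(fam$genomes, c(G01 = 0.5), n_reads = 500,
                           seed = 11)
  expect_identical(a$reads, b$reads)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  simulate_metagenome(fam$genomes, c(G01 = 0.5), n_reads = 500, seed = 11,
                      out = f1)
  simulate_metagenome(fam$genomes, c(G01 = 0.5), n_reads = 500, seed = 11,
                      out = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("substitution errors appear at the requested rate", {
  fam <- small_family()
  mg <- simulate_metagenome(fam$genomes, c(G01 = 1.0), n_reads = 400,
                            error_rate = 0.02, seed = 12)
  meta <- strsplit(names(mg$reads), "\\|")
  mism <- vapply(seq_along(mg$reads), function(i) {
    m <- meta[[i]]
    src <- fam$genomes[[m[2]]]$replicons[[m[3]]]
    s <- mg$reads[[i]]
    if (m[5] == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ref <- substr(src, as.integer(m[4]), as.integer(m[4]) + nchar(s) - 1L)
    mean(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1))
  expect_equal(mean(mism), 0.02, tolerance = 0.25)
})

test_that("an infeasible divergence target is rejected", {
  expect_error(
    simulate_genome_family(n_genomes = 2, n_core = 2, n_accessory = 0,
                           protein_identity = 0.1, nonsyn_fraction = 0.05,
                           seed = 1),
    "infeasible")
})
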