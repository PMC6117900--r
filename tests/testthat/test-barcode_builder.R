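toy_cog_set <- function(clusters, genomes) {
  structure(list(clusters = clusters, genomes = genomes),
            class = "cog_set")
}

# three core clusters over two genomes, 900 bp per gene
greedy_fixture <- function() {
  set.seed(41)
  genomes <- c("A", "B")
  cl <- tidyr::expand_grid(cog_id = c("COG1", "COG2", "COG3"),
                           genome_id = genomes)
  cl$gene_id <- paste0(cl$genome_id, "|", tolower(cl$cog_id))
  cl$is_core <- TRUE
  lookup <- tibble::tibble(
    gene_id = cl$gene_id,
    nt = vapply(seq_len(nrow(cl)), function(i) random_cds(300),
                character(1)),
    product = NA_character_)
  stats <- tibble::tibble(cog_id = c("COG1", "COG2", "COG3"),
                          score = c(0.20, 0.10, 0.05))
  list(cogs = toy_cog_set(cl, genomes), lookup = lookup, stats = stats)
}

test_that("core assembly follows score order and the minimum-length stop rule", {
  fx <- greedy_fixture()
  bs <- assemble_core_barcode(fx$stats, fx$cogs, fx$lookup, 1500)
  expect_equal(unname(nchar(bs$barcodes)), c(1800L, 1800L))
  expect_equal(attr(bs, "selected_cogs"), c("COG1", "COG2"))
  segA <- bs$segments[bs$segments$barcode_id == "A", ]
  expect_equal(segA$cog_id, c("COG1", "COG2"))
  expect_true(all(segA$origin == "core"))
})

test_that("a zero-length target yields empty barcodes", {
  fx <- greedy_fixture()
  bs <- assemble_core_barcode(fx$stats, fx$cogs, fx$lookup, 0)
  expect_true(all(nchar(bs$barcodes) == 0))
  expect_equal(nrow(bs$segments), 0L)
})

test_that("score ties are broken by the smaller cluster id", {
  fx <- greedy_fixture()
  fx$stats$score <- c(0.10, 0.10, 0.10)
  bs <- assemble_core_barcode(fx$stats, fx$cogs, fx$lookup, 100)
  expect_equal(attr(bs, "selected_cogs"), "COG1")
})

test_that("an unreachable target uses all clusters and warns", {
  fx <- greedy_fixture()
  expect_warning(
    bs <- assemble_core_barcode(fx$stats, fx$cogs, fx$lookup, 10000),
    "unreachable")
  expect_equal(attr(bs, "selected_cogs"), c("COG1", "COG2", "COG3"))
})

test_that("a universally shared accessory gene is selected for all genomes", {
  set.seed(42)
  genomes <- c("A", "B", "C")
  nt <- random_cds(200)   # 600 bp
  cl <- tibble::tibble(cog_id = "ACC1", genome_id = genomes,
                       gene_id = paste0(genomes, "|a1"), is_core = FALSE)
  lookup <- tibble::tibble(gene_id = cl$gene_id, nt = nt,
                           product = NA_character_)
  picks <- select_accessory_genes(cl, lookup, budget = 600,
                                  genomes = genomes)
  for (g in genomes) expect_equal(picks[[g]]$cog_id, "ACC1")
})

test_that("a genome without accessory genes stays core-only with a warning", {
  set.seed(43)
  genomes <- c("A", "B")
  cl <- tibble::tibble(cog_id = "ACC1", genome_id = "A",
                       gene_id = "A|a1", is_core = FALSE)
  lookup <- tibble::tibble(gene_id = "A|a1", nt = random_cds(200),
                           product = NA_character_)
  expect_warning(
    picks <- select_accessory_genes(cl, lookup, budget = 300,
                                    genomes = genomes),
    "budget not met")
  expect_equal(nrow(picks[["B"]]), 0L)
  expect_equal(nrow(picks[["A"]]), 1L)
})

test_that("greedy accessory cover achieves coverage whenever it is feasible", {
  # 9 genomes, 12 accessory families with a patchy presence matrix,
  # verified against exhaustive subset search
  set.seed(44)
  genomes <- sprintf("G%02d", 1:9)
  fams <- sprintf("ACC%02d", 1:12)
  pres <- matrix(stats::runif(9 * 12) < 0.45, 9, 12,
                 dimnames = list(genomes, fams))
  pres[4, ] <- FALSE          # one genome with no accessory genes at all
  lens <- sample(seq(300, 900, 3), 12)
  cl <- list(); lookup <- list()
  for (j in seq_len(12)) for (i in which(pres[, j])) {
    gid <- paste0(genomes[i], "|", tolower(fams[j]))
    cl[[length(cl) + 1L]] <- tibble::tibble(
      cog_id = fams[j], genome_id = genomes[i], gene_id = gid,
      is_core = FALSE)
    lookup[[length(lookup) + 1L]] <- tibble::tibble(
      gene_id = gid, nt = strrep("ACG", lens[j] / 3),
      product = NA_character_)
  }
  cl <- dplyr::bind_rows(cl); lookup <- dplyr::bind_rows(lookup)
  budget <- 1200
  picks <- suppressWarnings(
    select_accessory_genes(cl, lookup, budget = budget, genomes = genomes))
  got <- vapply(genomes, function(g) {
    sum(lens[match(picks[[g]]$cog_id, fams)])
  }, numeric(1))
  # brute force: is any subset of families sufficient for genome g?
  feasible <- vapply(seq_len(9), function(i) {
    sum(lens[pres[i, ]]) >= budget
  }, logical(1))
  expect_equal(unname(got >= budget), feasible)
})

test_that("barcode sequences are exact concatenations of their segments", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  lookup <- dplyr::bind_rows(lapply(fam$genomes, extract_cds))
  for (g in names(bs$barcodes)) {
    seg <- bs$segments[bs$segments$barcode_id == g, ]
    expect_equal(nchar(bs$barcodes[[g]]), sum(seg$end - seg$start))
    expect_equal(seg$start, c(0L, utils::head(seg$end, -1)))
    recomposed <- paste(lookup$nt[match(seg$gene_id, lookup$gene_id)],
                        collapse = "")
    expect_equal(unname(bs$barcodes[[g]]), recomposed)
  }
  # core segment order identical across genomes
  core_order <- lapply(names(bs$barcodes), function(g) {
    s <- bs$segments
    s$cog_id[s$barcode_id == g & s$origin == "core"]
  })
  expect_equal(length(unique(core_order)), 1L)
  # realized accessory fraction within one gene of the request
  acc_len <- vapply(names(bs$barcodes), function(g) {
    s <- bs$segments
    sum((s$end - s$start)[s$barcode_id == g & s$origin == "accessory"])
  }, numeric(1))
  longest_acc <- max(nchar(lookup$nt))
  expect_true(all(acc_len / nchar(bs$barcodes) <=
                    0.3 + longest_acc / 3000))
})

test_that("written outputs round-trip through FASTA and info coordinates", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  out <- withr::local_tempdir()
  paths <- write_barcode_outputs(bs, out)
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_setequal(names(fa), names(bs$barcodes))
  lookup <- dplyr::bind_rows(lapply(fam$genomes, extract_cds))
  for (p in paths$info) {
    info <- readr::read_tsv(p, show_col_types = FALSE)
    bseq <- as.character(fa[[info$barcode_id[1]]])
    expect_equal(nchar(bseq), max(info$end))
    for (i in seq_len(nrow(info))) {
      expect_equal(substr(bseq, info$start[i], info$end[i]),
                   lookup$nt[lookup$gene_id == info$gene_id[i]])
    }
  }
  empty <- metabarcoder:::new_barcode_set(
    character(0), bs$segments[0, ], 0, 0)
  expect_error(write_barcode_outputs(empty, out), "empty")
})

test_that("a barcode FASTA reads back for binning", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  out <- withr::local_tempdir()
  paths <- write_barcode_outputs(bs, out)
  back <- read_barcode_fasta(paths$fasta)
  expect_equal(back$barcodes[names(bs$barcodes)],
               vapply(bs$barcodes, identity, character(1)))
})
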