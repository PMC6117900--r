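test_that("an exact substring read scores its full length on its barcode", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  b1 <- bs$barcodes[[1]]
  read <- substr(b1, 301, 550)   # 250 bp exact
  h <- align_reads_to_barcodes(c(r1 = read), bs)
  top <- h[h$barcode_id == names(bs$barcodes)[1], ]
  expect_equal(top$raw_score, 250)
  expect_equal(top$read_length, 250L)
  # reverse-complement read aligns equally well
  rcread <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- align_reads_to_barcodes(c(r1 = rcread), bs)
  expect_equal(max(h2$raw_score), 250)
})

test_that("shuffled-composition reads almost never hit", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  set.seed(99)
  pool <- strsplit(substr(bs$barcodes[[1]], 1, 2750), "")[[1]]
  reads <- vapply(1:100, function(i)
    paste(sample(pool, 275), collapse = ""), character(1))
  names(reads) <- paste0("shuf", 1:100)
  h <- align_reads_to_barcodes(reads, bs)
  expect_lte(length(unique(h$read_id)), 2L)
})

test_that("a gene shared verbatim by two barcodes is hit twice with equal score", {
  set.seed(61)
  shared <- random_cds(120)          # 360 bp
  uniq1 <- random_cds(120); uniq2 <- random_cds(120)
  bs <- metabarcoder:::new_barcode_set(
    c(X = paste0(uniq1, shared), Y = paste0(shared, uniq2)),
    tibble::tibble(), 720, 0)
  read <- substr(shared, 51, 300)
  h <- align_reads_to_barcodes(c(r = read), bs)
  expect_setequal(h$barcode_id, c("X", "Y"))
  expect_equal(h$raw_score[1], h$raw_score[2])
  expect_equal(h$raw_score[1], 250)
})

test_that("S' reproduces its term-by-term evaluation", {
  expect_equal(compute_sprime(100, 250, 1000), oracle_sprime(100, 250, 1000),
               tolerance = 1e-12)
  expect_equal(compute_sprime(100, 250, 1000), 138.9053, tolerance = 1e-4)
  expect_equal(compute_sprime(200, 250, 10), oracle_sprime(200, 250, 10),
               tolerance = 1e-12)
  # S' > S when reads are longer than scores and the log term is small
  expect_gt(compute_sprime(200, 250, 10), 200)
  # L = S collapses the logistic term
  S <- 180
  expect_equal(compute_sprime(S, S, 500),
               S - 10 * (log((2 * S + 100) / (S + 100)) - 1))
  expect_error(compute_sprime(0, 250, 100), "positive")
  expect_error(compute_sprime(-5, 250, 100), "positive")
})

test_that("the S' filter removes sub-threshold hits and records pool statistics", {
  # 8 near-full-length hits plus 4 weaker reads: S' falls between the modes
  hits <- dplyr::bind_rows(
    hit_row(paste0("r", 1:8), "X", rep(250, 8), rep(250L, 8)),
    hit_row(paste0("r", 1:8), "Y", rep(120, 8), rep(250L, 8)),
    hit_row(paste0("q", 1:4), "Y", rep(120, 4), rep(250L, 4)))
  out <- sprime_filter(hits)
  st <- attr(out, "sprime_stats")
  S <- (8 * 250 + 4 * 120) / 12
  expect_equal(st$S, S); expect_equal(st$L, 250); expect_equal(st$N, 12)
  expect_equal(st$sprime, oracle_sprime(S, 250, 12))
  expect_gt(st$sprime, 120); expect_lt(st$sprime, 250)
  expect_true(all(out$raw_score >= st$sprime))
  expect_equal(st$filtered, 12L)   # every 120-scoring hit is removed
  expect_equal(nrow(out), 8L)
  expect_warning(sprime_filter(hit_row("r1", "X", 100, 250L)), "skipped")
})

test_that("alignment specificity hits its printed endpoints", {
  expect_equal(alignment_specificity(100, 100, 5), 1)
  expect_equal(alignment_specificity(500, 100, 5), 0)
  expect_equal(alignment_specificity(16, 10, 4), 0.8)
  expect_warning(v <- alignment_specificity(10, 10, 1), "single barcode")
  expect_equal(v, 1)
})

test_that("read specificity is the linear interpolant between its endpoints", {
  expect_equal(read_specificity(1, 9), 1)
  expect_equal(read_specificity(9, 9), 0)
  expect_equal(read_specificity(3, 9), 0.75)
  expect_equal(read_specificity(1:4, 4), c(1, 2/3, 1/3, 0))
})

test_that("vicinity follows the hand-computed Jaccard matrix", {
  hits <- dplyr::bind_rows(
    hit_row(c("r1", "r2", "r3"), "A", 200, 250L),
    hit_row(c("r1", "r2", "r4"), "B", 200, 250L),
    hit_row(c("r5", "r6"), "C", 200, 250L))
  v <- compute_vicinity(hits)
  D <- v$distance
  expect_equal(D["A", "B"], 0.5)
  expect_equal(D["A", "C"], 1)
  expect_equal(D["B", "C"], 1)
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D, t(D))
  pr <- v$per_read
  expect_equal(pr$r_vicinity[pr$read_id == "r1"], 5)   # 10 * 0.5 / 1
  expect_equal(pr$r_vicinity[pr$read_id == "r5"], 0)
  expect_equal(pr$r_vicinity[pr$read_id == "r3"], 0)   # single barcode
})

test_that("identical read sets give an all-zero matrix and zero vicinity", {
  hits <- dplyr::bind_rows(
    hit_row(c("r1", "r2"), "A", 200, 250L),
    hit_row(c("r1", "r2"), "B", 200, 250L))
  v <- compute_vicinity(hits)
  expect_true(all(v$distance == 0))
  expect_true(all(v$per_read$r_vicinity == 0))
})

test_that("vicinity stays within [0, 10] on random incidence tables", {
  set.seed(71)
  for (i in 1:50) {
    nb <- sample(2:10, 1)
    nr <- sample(5:40, 1)
    hits <- tibble::tibble(
      read_id = paste0("r", sample(nr, nr * 2, TRUE)),
      barcode_id = paste0("b", sample(nb, nr * 2, TRUE)),
      raw_score = 200, read_length = 250L, e_value = 1e-20)
    hits <- dplyr::distinct(hits, read_id, barcode_id, .keep_all = TRUE)
    v <- compute_vicinity(hits)
    expect_true(all(v$per_read$r_vicinity >= 0 &
                      v$per_read$r_vicinity <= 10))
  }
})

test_that("the read-score correction collapses as the formulas dictate", {
  # fully specific read: factor 1 in both scores
  expect_equal(metabarcoder:::score_correction(1, 0), 1)
  expect_equal(metabarcoder:::score_correction(1, 0, base = 1.5), 1)
  expect_equal(metabarcoder:::score_correction(1, 7), 1)  # r_spec = 1
  # worked evaluation of the exponential correction
  got <- 0.9 * metabarcoder:::score_correction(0.5, 5)
  expect_equal(got, 0.9 * (0.5 + exp(2.5) + 1) / (0.5 + exp(5) + 1),
               tolerance = 1e-12)
  expect_equal(got, 0.0821, tolerance = 1e-3)
  # the correction never exceeds 1 and penalizes promiscuous reads
  set.seed(72)
  rs <- stats::runif(200); rv <- stats::runif(200, 0, 10)
  expect_true(all(metabarcoder:::score_correction(rs, rv) <= 1 + 1e-12))
})

test_that("an empty pool scores every barcode zero and absent", {
  res <- compute_barcode_scores(hit_row(character(), character(),
                                        numeric(), integer()),
                                c(X = 1000, Y = 2000))
  expect_equal(res$score1, c(0, 0))
  expect_equal(res$score2, c(0, 0))
  expect_false(any(res$present))
})

test_that("a barcode without hits scores 0 (own-sum) or negative (global-sum)", {
  hits <- hit_row(paste0("r", 1:5), "X", 240, 250L)
  bl <- c(X = 1000, Y = 1000)
  res_pb <- compute_barcode_scores(hits, bl, eq6_score_sum = "per_barcode")
  expect_equal(res_pb$score1[res_pb$barcode_id == "Y"], 0)
  res_gl <- compute_barcode_scores(hits, bl, eq6_score_sum = "global")
  expect_lt(res_gl$score1[res_gl$barcode_id == "Y"], 0)
  expect_false(res_gl$present[res_gl$barcode_id == "Y"])
})

test_that("barcode scores match a term-by-term oracle in every mode", {
  fx <- eq6_micro_fixture()
  for (mode in c("per_barcode", "global", "raw")) {
    for (nr in c("aligned", "total")) {
      res <- compute_barcode_scores(fx$hits, fx$bl, n_total_reads = 20,
                                    eq6_score_sum = mode, nreads_mode = nr)
      orc <- oracle_eq6(fx$hits, fx$bl, mode, nr, n_total = 20)
      for (b in c("X", "Y", "Z")) {
        expect_equal(res$score1[res$barcode_id == b],
                     unname(orc[paste0(b, "_s1")]), tolerance = 1e-9)
        expect_equal(res$score2[res$barcode_id == b],
                     unname(orc[paste0(b, "_s2")]), tolerance = 1e-9)
      }
    }
  }
})

test_that("ReadScore1 is read-level while ReadScore2 is barcode-specific", {
  fx <- eq6_micro_fixture()
  res <- compute_barcode_scores(fx$hits, fx$bl)
  rs <- attr(res, "read_scores")
  per_read_rs1 <- tapply(rs$read_score1, rs$read_id,
                         function(x) length(unique(x)))
  expect_true(all(per_read_rs1 == 1))
  r6 <- rs[rs$read_id == "r6", ]
  expect_gt(length(unique(r6$read_score2)), 1)
})

test_that("BarcodeScore1 is non-decreasing in the number of specific reads", {
  bl <- c(X = 1000, Y = 1000, Z = 1000)
  prev <- -Inf
  for (n in c(1, 3, 10, 30, 100)) {
    hits <- dplyr::bind_rows(
      hit_row(paste0("x", seq_len(n)), "X", 240, 250L),
      hit_row(paste0("y", 1:20), "Y", 240, 250L))
    res <- compute_barcode_scores(hits, bl)
    s <- res$score1[res$barcode_id == "X"]
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("doubling all barcode lengths leaves the scores unchanged", {
  fx <- eq6_micro_fixture()
  for (mode in c("per_barcode", "global")) {
    a <- compute_barcode_scores(fx$hits, fx$bl, eq6_score_sum = mode)
    b <- compute_barcode_scores(fx$hits, fx$bl * 2, eq6_score_sum = mode)
    expect_equal(a$score1, b$score1, tolerance = 1e-12)
    expect_equal(a$score2, b$score2, tolerance = 1e-12)
  }
})

test_that("classification uses >= at the cut-offs under the AND rule", {
  res <- compute_barcode_scores(eq6_micro_fixture()$hits,
                                eq6_micro_fixture()$bl)
  res$score1 <- c(2.3, 5.0, 1.0)
  res$score2 <- c(0.5, 0.1, 5.0)
  out <- classify_barcodes(res, 2.3, 0.5)
  expect_equal(out$present, c(TRUE, FALSE, FALSE))
})

test_that("the one-shot binning pipeline recovers a dominant genome", {
  fam <- small_family()
  bs <- cached("small_bs", build_barcode_set(
    fam$genomes, requested_length = 3000, accessory_fraction = 0.3,
    cogs = small_cogs(), stats = small_stats()))
  mg <- simulate_metagenome(fam$genomes, c(G01 = 0.5), n_reads = 3000,
                            seed = 8)
  res <- bin_reads(mg$reads, bs)
  expect_true(res$present[res$barcode_id == "G01"])
  expect_false(any(res$present[res$barcode_id != "G01"]))
  gl <- glance(res)
  expect_gte(gl$a_specificity, 0)
  expect_lte(gl$a_specificity, 1)
})
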