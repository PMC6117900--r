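#' Translate a coding sequence
#'
#' Translates an in-frame coding-strand nucleotide sequence with a standard
#' genetic code (bacterial table 11 by default). A terminal stop codon is
#' stripped; codons containing ambiguous bases translate to `X`.
#'
#' @param nt_seq Character vector of coding sequences (A/C/G/T/N alphabet).
#' @param table Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()].
#' @return Character vector of protein sequences.
#' @examples
#' translate_cds("ATGAAA")     # "MK"
#' translate_cds("ATGGCTTAA")  # "MA"
#' @export
translate_cds <- function(nt_seq, table = "11") {
  gc <- Biostrings::getGeneticCode(table)
  vapply(nt_seq, function(s) {
    s <- normalize_dna(s)
    n <- nchar(s)
    if (n %% 3L != 0L) {
      stop("frame error: sequence length ", n, " is not a multiple of 3")
    }
    if (n == 0L) return("")
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

start_codons <- function(table = "11") {
  # canonical bacterial initiation codons
  if (identical(table, "11")) c("ATG", "GTG", "TTG") else "ATG"
}

new_genome <- function(genome_id, replicons, genes) {
  structure(list(genome_id = genome_id, replicons = replicons, genes = genes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", length(x$replicons), " replicon(s), ",
      nrow(x$genes), " CDS record(s), ",
      sum(nchar(x$replicons)), " bp\n", sep = "")
  invisible(x)
}

gene_tibble <- function(genome_id, replicon_id, start, end, strand, nt,
                        locus_tag, product) {
  gene_id <- ifelse(is.na(locus_tag) | locus_tag == "",
                    paste0(genome_id, "|cds", seq_along(start)),
                    paste0(genome_id, "|", locus_tag))
  aa <- rep(NA_character_, length(nt))
  ok <- nchar(nt) %% 3L == 0L & nchar(nt) > 0L
  if (any(ok)) aa[ok] <- translate_cds(nt[ok])
  tibble::tibble(
    gene_id = gene_id, replicon_id = replicon_id,
    start = as.integer(start), end = as.integer(end), strand = strand,
    nt = nt, aa = aa, product = product
  )
}

# slice a coding sequence out of a replicon given a 0-based half-open
# interval and strand
slice_cds <- function(repl_seq, start, end, strand) {
  s <- substr(repl_seq, start + 1L, end)
  if (strand == "-") s <- revcomp_chr(s) else s
}

#' Read an annotated genome
#'
#' Parses a complete annotated genome and extracts its CDS features. Two
#' input forms are supported: a (possibly multi-record, possibly
#' gzip-compressed) GenBank flat file, or a FASTA file plus a tab-separated
#' CDS coordinate table with columns `replicon_id`, `start`, `end` (1-based
#' inclusive), `strand` and `locus_tag` (optionally `product`).
#'
#' Coordinates are stored 0-based half-open internally; reported locations
#' in output files are 1-based inclusive. Gene identifiers are
#' `<genome_id>|<locus_tag>`, falling back to `<genome_id>|cds<ordinal>`.
#'
#' @param path GenBank file path (for `format = "genbank"`) or FASTA path.
#' @param format `"genbank"` or `"fasta+table"`.
#' @param cds_table Path of the CDS table when `format = "fasta+table"`.
#' @param genome_id Genome label; defaults to the file base name.
#' @param verbose Emit progress messages to standard error.
#' @return A `genome` object: list with `genome_id`, `replicons` (named
#'   character vector of A/C/G/T/N sequences) and `genes` (tibble of CDS
#'   records with coding-strand `nt` and translated `aa`).
#' @export
read_genome_file <- function(path, format = c("genbank", "fasta+table"),
                             cds_table = NULL, genome_id = NULL,
                             verbose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gb|gbk|gbff|genbank|fa|fasta|fna)(\\.gz)?$", "",
                     basename(path))
  }
  g <- if (format == "genbank") {
    parse_genbank(path, genome_id)
  } else {
    if (is.null(cds_table)) stop("fasta+table input requires `cds_table`")
    parse_fasta_table(path, cds_table, genome_id)
  }
  if (nrow(g$genes) == 0L) {
    stop("empty annotation: no CDS features found in ", path)
  }
  if (verbose) {
    message("read ", genome_id, ": ", length(g$replicons), " replicon(s), ",
            nrow(g$genes), " CDS record(s)")
  }
  g
}

parse_genbank <- function(path, genome_id) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) {
    stop("format error: no LOCUS line found in ", path,
         " (first line: ", substr(lines[1], 1, 40), ")")
  }
  ends <- c(locus_idx[-1] - 1L, length(lines))
  repl <- character(0)
  genes <- list()
  for (r in seq_along(locus_idx)) {
    block <- lines[locus_idx[r]:ends[r]]
    repl_id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    if (is.na(repl_id)) {
      stop("format error: unparseable LOCUS line in record ", r, " of ", path)
    }
    ori <- grep("^ORIGIN", block)
    if (length(ori) != 1L) {
      stop("format error: record ", repl_id, " has no ORIGIN section")
    }
    seq_lines <- block[(ori + 1L):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- normalize_dna(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    repl[repl_id] <- seq
    feat0 <- grep("^FEATURES", block)
    if (length(feat0) == 1L) {
      fblock <- block[(feat0 + 1L):(ori - 1L)]
      genes[[r]] <- parse_genbank_cds(fblock, repl_id, seq)
    }
  }
  gt <- dplyr::bind_rows(genes)
  if (nrow(gt) > 0L) {
    gt <- gene_tibble(genome_id, gt$replicon_id, gt$start, gt$end, gt$strand,
                      gt$nt, gt$locus_tag, gt$product)
  } else {
    gt <- gene_tibble(genome_id, character(), integer(), integer(),
                      character(), character(), character(), character())
  }
  new_genome(genome_id, repl, gt)
}

parse_genbank_cds <- function(fblock, repl_id, seq) {
  # feature keys start at column 6; qualifier/continuation lines are deeper
  key_idx <- grep("^ {5}\\S", fblock)
  if (length(key_idx) == 0L) return(NULL)
  key <- sub("^ {5}(\\S+).*$", "\\1", fblock[key_idx])
  bounds <- c(key_idx, length(fblock) + 1L)
  out <- list()
  for (i in which(key == "CDS")) {
    fl <- fblock[key_idx[i]:(bounds[i + 1L] - 1L)]
    # location may continue over lines until the first qualifier
    qual0 <- grep("^\\s+/", fl)
    loc_end <- if (length(qual0)) qual0[1] - 1L else length(fl)
    loc <- gsub("\\s", "", paste(sub("^ {5}CDS", "", fl[1:loc_end]),
                                 collapse = ""))
    quals <- paste(fl[seq_len(length(fl)) > loc_end], collapse = "\n")
    pseudo <- grepl("/pseudo(\\s|$|\n)", quals)
    locus_tag <- qual_value(quals, "locus_tag")
    product <- qual_value(quals, "product")
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    inner <- gsub("^complement\\(|\\)$", "", loc)
    if (grepl("join|order|<|>", inner)) next  # compound or partial location
    m <- regmatches(inner, regexec("^(\\d+)\\.\\.(\\d+)$", inner))[[1]]
    if (length(m) != 3L) next
    start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
    if (end1 > nchar(seq) || start1 < 1L) next
    nt <- slice_cds(seq, start1 - 1L, end1, strand)
    out[[length(out) + 1L]] <- tibble::tibble(
      replicon_id = repl_id, start = start1 - 1L, end = end1,
      strand = strand, nt = nt,
      locus_tag = locus_tag, product = product, pseudo = pseudo
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0L) res <- res[!res$pseudo, setdiff(names(res), "pseudo")]
  res
}

qual_value <- function(quals, name) {
  pat <- paste0("/", name, "=\"([^\"]*)\"")
  m <- regmatches(quals, regexec(pat, quals))[[1]]
  if (length(m) == 2L) gsub("\\s*\n\\s*", " ", m[2]) else NA_character_
}

parse_fasta_table <- function(fasta_path, table_path, genome_id) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  repl <- vapply(as.character(seqs), normalize_dna, character(1))
  names(repl) <- names(seqs)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("replicon_id", "start", "end", "strand", "locus_tag")
  if (!all(need %in% names(tab))) {
    stop("format error: CDS table must have columns ",
         paste(need, collapse = ", "))
  }
  if (!"product" %in% names(tab)) tab$product <- NA_character_
  bad <- !tab$replicon_id %in% names(repl)
  if (any(bad)) {
    stop("format error: CDS table row ", which(bad)[1],
         " references unknown replicon ", tab$replicon_id[which(bad)[1]])
  }
  nt <- vapply(seq_len(nrow(tab)), function(i) {
    slice_cds(repl[[tab$replicon_id[i]]], tab$start[i] - 1L, tab$end[i],
              tab$strand[i])
  }, character(1))
  gt <- gene_tibble(genome_id, tab$replicon_id, tab$start - 1L, tab$end,
                    tab$strand, nt, tab$locus_tag, tab$product)
  new_genome(genome_id, repl, gt)
}

#' Extract complete CDS records from a genome
#'
#' Applies the CDS completeness filter: length a multiple of 3, no internal
#' stop codon and (unless `relaxed`) a canonical initiation codon. Excluded
#' records are attached as the `"excluded"` attribute with a reason each.
#'
#' @param genome A `genome` object.
#' @param keep_partial Keep records failing the completeness filter.
#' @param relaxed Do not require a canonical start codon.
#' @param table Genetic code table used for the stop/start check.
#' @param verbose Log exclusions to standard error.
#' @return Tibble of retained CDS records (columns as in `genome$genes`).
#' @export
extract_cds <- function(genome, keep_partial = FALSE, relaxed = FALSE,
                        table = "11", verbose = FALSE) {
  g <- genome$genes
  if (nrow(g) == 0L) return(g)
  gc <- Biostrings::getGeneticCode(table)
  reason <- rep(NA_character_, nrow(g))
  len_bad <- nchar(g$nt) %% 3L != 0L
  reason[len_bad] <- "length not multiple of 3"
  for (i in which(!len_bad)) {
    s <- g$nt[i]
    n <- nchar(s)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(gc[codons])
    if (any(aa[-length(aa)] == "*", na.rm = TRUE)) {
      reason[i] <- "internal stop"
    } else if (!relaxed && !(codons[1] %in% start_codons(table))) {
      reason[i] <- "no start codon"
    }
  }
  keep <- is.na(reason)
  excluded <- tibble::tibble(gene_id = g$gene_id[!keep],
                             reason = reason[!keep])
  if (verbose && nrow(excluded) > 0L) {
    message("excluded ", nrow(excluded), " incomplete CDS record(s): ",
            paste(utils::head(paste0(excluded$gene_id, " (", excluded$reason, ")"), 5),
                  collapse = "; "))
  }
  res <- if (keep_partial) g else g[keep, ]
  attr(res, "excluded") <- excluded
  res
}
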