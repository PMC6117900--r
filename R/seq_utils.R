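# Low-level sequence coding helpers shared by the aligners and simulators.

# 256-entry lookup tables, built once at load time
.dna_lut <- local({
  lut <- rep(4L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

#' Integer-code a DNA string (A=0, C=1, G=2, T=3, other=4)
#' @noRd
encode_dna <- function(x) .dna_lut[utf8ToInt(x) + 1L]

#' Integer-code a vector of DNA strings
#' @noRd
encode_dna_all <- function(x) lapply(x, encode_dna)

# nucleotide scoring matrix under the read-alignment scheme
nt_submat <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5)
  diag(m)[1:4] <- match
  m[5, ] <- mismatch; m[, 5] <- mismatch
  m
}

# BLOSUM62 from Biostrings, fetched once
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

.aa_lut <- function() {
  if (is.null(.pkg_cache$aa_lut)) {
    b <- blosum62()
    lut <- rep(match("X", rownames(b)) - 1L, 256L)
    for (i in seq_along(rownames(b))) {
      ch <- rownames(b)[i]
      lut[utf8ToInt(ch) + 1L] <- i - 1L
      lo <- tolower(ch)
      if (lo != ch) lut[utf8ToInt(lo) + 1L] <- i - 1L
    }
    .pkg_cache$aa_lut <- lut
  }
  .pkg_cache$aa_lut
}

#' Integer-code a protein string against the BLOSUM62 alphabet (0-based)
#' @noRd
encode_aa <- function(x) .aa_lut()[utf8ToInt(x) + 1L]

#' Reverse complement of a plain character DNA string
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize a nucleotide string to the A/C/G/T/N alphabet
#' @noRd
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# 2-bit k-mer codes at given start positions of an integer-coded sequence.
# Positions whose window contains an ambiguous base get NA.
kmer_codes <- function(codes, k, starts = seq_len(length(codes) - k + 1L)) {
  if (length(codes) < k || length(starts) == 0L) {
    return(list(starts = integer(), codes = numeric()))
  }
  v <- numeric(length(starts))
  bad <- logical(length(starts))
  for (off in 0:(k - 1L)) {
    c_off <- codes[starts + off]
    bad <- bad | c_off > 3L
    v <- v * 4 + as.numeric(c_off)
  }
  list(starts = starts[!bad], codes = v[!bad])
}

# Karlin-Altschul e-value for a local alignment score. Constants are the
# standard ungapped +1/-2 nucleotide and gapped BLOSUM62 protein parameters;
# e-values are used for hit filtering and reporting, not for inference.
ka_evalue <- function(score, m, n, type = c("nt", "aa")) {
  type <- match.arg(type)
  p <- if (type == "nt") c(lambda = 1.33, K = 0.621) else c(lambda = 0.267, K = 0.041)
  unname(p["K"] * m * n * exp(-p["lambda"] * score))
}
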