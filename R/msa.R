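# Built-in progressive multiple protein aligner used for codon alignment of
# core orthologous clusters. Sequences are added one at a time to a growing
# profile; each addition is a global affine-gap alignment of the sequence
# against profile column scores (mean BLOSUM62 score against column
# residues, gaps contributing a fixed residue penalty).

.profile_gap_residue <- -1

profile_column_scores <- function(s_codes, prof) {
  bm <- blosum62()
  B <- bm[s_codes + 1L, , drop = FALSE]        # n_s x 25
  n_s <- length(s_codes); n_col <- ncol(prof)
  S <- matrix(0, n_s, n_col)
  for (r in seq_len(nrow(prof))) {
    codes <- prof[r, ] + 1L
    ok <- !is.na(codes)
    term <- matrix(.profile_gap_residue, n_s, n_col)
    if (any(ok)) term[, ok] <- B[, codes[ok], drop = FALSE]
    S <- S + term
  }
  S / nrow(prof)
}

#' Progressive multiple alignment of protein sequences
#'
#' @param seqs Named character vector of protein sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Named character vector of equal-length gapped sequences.
#' @export
align_proteins <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  codes <- lapply(seqs, encode_aa)
  # guide order: centre sequence = most shared 4-mers with the others
  kt <- aa_kmer_table(names(seqs), seqs, 4L)
  sim <- merge(kt, kt, by = "kmer", allow.cartesian = TRUE)
  sim <- sim[sim$id.x != sim$id.y, .N, by = c("id.x", "id.y")]
  tot <- tapply(sim$N, sim$id.x, sum)
  centre <- names(seqs)[order(-tot[names(seqs)], names(seqs))][1]
  rest <- setdiff(names(seqs), centre)
  csim <- stats::setNames(rep(0, length(rest)), rest)
  hit <- sim[sim$id.x == centre, ]
  csim[hit$id.y] <- hit$N
  order_in <- c(centre, rest[order(-csim, rest)])

  prof <- matrix(codes[[centre]], nrow = 1)
  rownames(prof) <- centre
  for (nm in order_in[-1]) {
    sc <- codes[[nm]]
    S <- profile_column_scores(sc, prof)
    al <- cpp_align_matrix(S, gap_open, gap_extend, local = FALSE)
    n_col <- length(al$a_idx)
    newprof <- matrix(NA_integer_, nrow(prof) + 1L, n_col)
    rownames(newprof) <- c(rownames(prof), nm)
    pj <- al$b_idx  # profile columns (0 = gap)
    si <- al$a_idx  # sequence positions (0 = gap)
    for (r in seq_len(nrow(prof))) {
      newprof[r, pj > 0L] <- prof[r, pj[pj > 0L]]
    }
    newprof[nrow(newprof), si > 0L] <- sc[si[si > 0L]]
    prof <- newprof
  }
  prof <- prof[names(seqs), , drop = FALSE]
  aa_chars <- rownames(blosum62())
  apply(prof, 1, function(row) {
    ch <- ifelse(is.na(row), "-", aa_chars[row + 1L])
    paste(ch, collapse = "")
  })
}

#' Codon alignment of a core orthologous cluster
#'
#' Aligns the member proteins with the built-in progressive aligner and
#' back-threads the gaps onto the coding sequences, so gaps appear as codon
#' triplets and removing the gaps from a row reproduces the member gene's
#' nucleotide sequence exactly (including a terminal stop codon when
#' present).
#'
#' @param members Tibble with `genome_id` and `gene_id` of the cluster
#'   members (one per genome).
#' @param gene_lookup Tibble of gene records (as from [extract_cds()])
#'   covering all members.
#' @param cog_id Cluster identifier carried through to the result.
#' @return A `codon_alignment`: list with `cog_id` and `rows`, a named
#'   (by genome) character vector of equal-length gapped nucleotide
#'   sequences whose column count is a multiple of 3.
#' @export
codon_align_cog <- function(members, gene_lookup, cog_id = NA_character_) {
  idx <- match(members$gene_id, gene_lookup$gene_id)
  if (anyNA(idx)) stop("gene_lookup is missing members: ",
                       paste(members$gene_id[is.na(idx)], collapse = ", "))
  nt <- gene_lookup$nt[idx]
  aa <- gene_lookup$aa[idx]
  names(nt) <- names(aa) <- members$genome_id
  if (any(nchar(nt) %% 3L != 0L) || anyNA(aa)) {
    stop("frame error in cluster ", cog_id)
  }
  gapped <- align_proteins(aa)
  n_codons <- nchar(nt) / 3L
  extra <- n_codons - nchar(aa)       # 1 when a terminal stop was stripped
  n_extra <- max(extra)
  rows <- vapply(names(nt), function(g) {
    s <- nt[[g]]
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    gp <- strsplit(gapped[[g]], "")[[1]]
    out <- character(length(gp) + n_extra)
    ci <- 0L
    for (i in seq_along(gp)) {
      if (gp[i] == "-") out[i] <- "---"
      else { ci <- ci + 1L; out[i] <- codons[ci] }
    }
    if (n_extra > 0L) {
      out[length(gp) + seq_len(n_extra)] <-
        if (extra[[g]] > 0L) c(codons[length(codons)],
                               rep("---", n_extra - 1L))
        else rep("---", n_extra)
    }
    paste(out, collapse = "")
  }, character(1))
  structure(list(cog_id = cog_id, rows = rows), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", x$cog_id, ": ", length(x$rows), " rows x ",
      nchar(x$rows[[1]]), " columns\n", sep = "")
  invisible(x)
}
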