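# Visual and text outputs: the 3D cluster scatter, the per-barcode score
# chart (optionally ordered by a phylogeny) and the tab-separated result
# report. SVG is written directly (SVG 1.1, standalone, well-formed XML).

svg_header <- function(width, height) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
            width, height, width, height))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x)
  x <- gsub("<", "&lt;", x)
  x <- gsub(">", "&gt;", x)
  gsub("\"", "&quot;", x)
}

#' Render the 3D cluster divergence scatter as SVG
#'
#' Clusters are dots at their (X, Y, Z) divergence coordinates in a
#' fixed-angle orthographic projection (X and Y span the floor plane, Z is
#' vertical); clusters selected for barcoding are highlighted in brown.
#'
#' @param stats Tibble from [score_core_cogs()] (`cog_id`, `X`, `Y`, `Z`).
#' @param selected Character vector of selected cluster ids.
#' @param path Output SVG path.
#' @return The path, invisibly.
#' @export
render_cog_scatter <- function(stats, selected = character(0), path) {
  stopifnot(nrow(stats) >= 1L)
  W <- 640L; H <- 480L
  # orthographic projection: u = X + 0.45 Y, v (up) = Z' + 0.30 Y
  zmax <- max(stats$Z, 1e-9)
  u <- stats$X + 0.45 * stats$Y
  v <- stats$Z / zmax + 0.30 * stats$Y
  px <- 60 + u / max(u, 1.45) * 500
  py <- 420 - v / max(v, 1.30) * 340
  sel <- stats$cog_id %in% selected
  lines <- c(
    svg_header(W, H),
    "<rect width=\"100%\" height=\"100%\" fill=\"white\"/>",
    "<g id=\"axes\" stroke=\"#444444\" stroke-width=\"1\">",
    "<line x1=\"60\" y1=\"420\" x2=\"560\" y2=\"420\"/>",
    "<line x1=\"60\" y1=\"420\" x2=\"60\" y2=\"60\"/>",
    "<line x1=\"60\" y1=\"420\" x2=\"235\" y2=\"310\"/>",
    "</g>",
    "<text x=\"540\" y=\"445\" font-size=\"13\">X (sense substitution fraction)</text>",
    "<text x=\"20\" y=\"55\" font-size=\"13\">Z ((pos-id)/id)</text>",
    "<text x=\"240\" y=\"300\" font-size=\"13\">Y (1 - identity)</text>",
    sprintf(paste0("<circle class=\"cog%s\" cx=\"%.2f\" cy=\"%.2f\" r=\"%s\"",
                   " fill=\"%s\" fill-opacity=\"0.75\"><title>%s</title></circle>"),
            ifelse(sel, " selected", ""), px, py, ifelse(sel, "5", "3.5"),
            ifelse(sel, "#8B4513", "#4477aa"),
            xml_escape(sprintf("%s X=%.3f Y=%.3f Z=%.3f score=%.4f",
                               stats$cog_id, stats$X, stats$Y, stats$Z,
                               stats$score))),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Leaf order of a phylogenetic tree file
#'
#' Accepts plain Newick as well as PHYLIP-style tree files (a numeric
#' first line followed by the tree); branch lengths are ignored, only the
#' leaf order is used.
#'
#' @param path Tree file.
#' @return Character vector of tip labels in display order.
#' @export
tree_leaf_order <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^\\s*\\d+\\s*$", lines[1])) {
    lines <- lines[-1]   # PHYLIP-style leading taxon count
  }
  tr <- ape::read.tree(text = paste(lines, collapse = ""))
  if (is.null(tr)) stop("unparseable tree file: ", path)
  tr$tip.label[tr$edge[tr$edge[, 2] <= ape::Ntip(tr), 2]]
}

#' Render the per-barcode score chart as SVG
#'
#' One bar per barcode with height proportional to BarcodeScore2 (floored
#' at 0); present calls are coloured green. When a tree leaf order is
#' supplied, bars follow it; barcodes absent from the tree are appended
#' after the ordered ones with a warning, and a tree matching no barcode
#' falls back to score order. The BarcodeScore2 cut-off is drawn as a
#' dashed line.
#'
#' @param result A `binning_result`.
#' @param path Output SVG path.
#' @param tree_order Optional character vector of genome ids (e.g. from
#'   [tree_leaf_order()]).
#' @return The path, invisibly.
#' @export
render_barcode_chart <- function(result, path, tree_order = NULL) {
  df <- tibble::as_tibble(result)
  if (!is.null(tree_order)) {
    matched <- intersect(tree_order, df$barcode_id)
    if (length(matched) == 0L) {
      warning("tree matches no barcode: falling back to score order")
      df <- df[order(-df$score2), ]
    } else {
      extra <- setdiff(df$barcode_id, matched)
      if (length(extra) > 0L) {
        warning("barcode(s) not in tree appended after tree order: ",
                paste(extra, collapse = ", "))
      }
      df <- df[match(c(matched, extra), df$barcode_id), ]
    }
  } else {
    df <- df[order(-df$score2), ]
  }
  co <- attr(result, "cutoffs")[["cutoff2"]]
  W <- 640L; H <- 420L
  n <- nrow(df)
  top <- max(c(df$score2, co, 0.1))
  x0 <- 70; plot_w <- 520; plot_h <- 300; base_y <- 360
  bw <- plot_w / n
  ys <- base_y - pmax(0, df$score2) / top * plot_h
  cut_y <- base_y - co / top * plot_h
  lines <- c(
    svg_header(W, H),
    "<rect width=\"100%\" height=\"100%\" fill=\"white\"/>",
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"#444444\"/>",
            x0, base_y, x0 + plot_w, base_y),
    sprintf(paste0("<line class=\"cutoff\" x1=\"%d\" y1=\"%.2f\" x2=\"%d\"",
                   " y2=\"%.2f\" stroke=\"#aa3333\" stroke-dasharray=\"6,4\"/>"),
            x0, cut_y, x0 + plot_w, cut_y),
    "<text x=\"15\" y=\"40\" font-size=\"13\">BarcodeScore2</text>",
    sprintf(paste0("<rect class=\"bar %s\" x=\"%.2f\" y=\"%.2f\" width=\"%.2f\"",
                   " height=\"%.2f\" fill=\"%s\"/>"),
            ifelse(df$present, "present", "absent"),
            x0 + (seq_len(n) - 1) * bw + 0.1 * bw, ys, 0.8 * bw,
            base_y - ys,
            ifelse(df$present, "#2e7d32", "#9e9e9e")),
    sprintf(paste0("<text x=\"%.2f\" y=\"%d\" font-size=\"11\"",
                   " transform=\"rotate(35 %.2f %d)\">%s</text>"),
            x0 + (seq_len(n) - 0.5) * bw, base_y + 16,
            x0 + (seq_len(n) - 0.5) * bw, base_y + 16,
            xml_escape(df$barcode_id)),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Write the binning result as a tab-separated text report
#'
#' Header comment lines carry the pool statistics (aligned reads, matches,
#' alignment specificity, S' and the cut-offs); the table lists one row per
#' barcode.
#'
#' @param result A `binning_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_text_report <- function(result, path) {
  pool <- attr(result, "pool")
  sp <- attr(result, "sprime_stats")
  co <- attr(result, "cutoffs")
  hdr <- c(
    sprintf("# n_total_reads\t%s", pool$n_total_reads %||% NA),
    sprintf("# n_aligned_reads\t%s", pool$n_aligned_reads %||% 0L),
    sprintf("# n_matches\t%s", pool$n_matches %||% 0L),
    sprintf("# a_specificity\t%s", format(pool$a_specificity %||% NA_real_,
                                          digits = 10)),
    sprintf("# sprime\t%s", format(if (is.null(sp)) NA_real_ else sp$sprime,
                                   digits = 10)),
    sprintf("# cutoff1\t%s", co[["cutoff1"]]),
    sprintf("# cutoff2\t%s", co[["cutoff2"]]))
  tab <- tibble::tibble(
    barcode_id = result$barcode_id,
    barcode_length = result$barcode_length,
    n_reads = result$n_reads,
    score1 = result$score1, score2 = result$score2,
    call = ifelse(result$present, "present", "absent"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(sprintf, c(list("%s\t%g\t%d\t%.10g\t%.10g\t%s"),
                                as.list(tab))), con)
  invisible(path)
}

#' Read a text report back
#'
#' @param path Report written by [write_text_report()].
#' @return List: `table` (tibble) and `stats` (named list from the header).
#' @export
read_text_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  stats <- stats::setNames(as.list(suppressWarnings(as.numeric(kv[, 2]))),
                           kv[, 1])
  tab <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                         show_col_types = FALSE)
  list(table = tab, stats = stats)
}
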