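# Scoring of binning calls against known composition: confusion counts,
# sensitivity/specificity and the true-positive over false-prediction
# ratio, ROC curves with trapezoid AUC, and grid search over cut-off pairs.

#' Confusion counts of binning calls against known composition
#'
#' A barcode whose genome was placed in the metagenome (abundance > 0) and
#' is called present is a true positive; uncalled, a false negative. A
#' barcode of an absent genome called present is a false positive;
#' uncalled, a true negative.
#'
#' @param calls Tibble with `barcode_id` and logical `present` (e.g. a
#'   `binning_result`).
#' @param truth Named abundance vector or tibble with `genome_id` and
#'   `abundance` covering every barcode.
#' @return One-row tibble `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(calls, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$abundance, truth$genome_id)
  }
  missing <- setdiff(calls$barcode_id, names(truth))
  if (length(missing) > 0L) {
    stop("no truth entry for barcode(s): ", paste(missing, collapse = ", "))
  }
  pres <- truth[calls$barcode_id] > 0
  tibble::tibble(
    TP = sum(pres & calls$present),
    FP = sum(!pres & calls$present),
    FN = sum(pres & !calls$present),
    TN = sum(!pres & !calls$present))
}

#' Sensitivity, specificity and TP / (FP + FN)
#'
#' Undefined ratios (zero denominators) are reported as `NA`.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @return One-row tibble `sensitivity`, `specificity`, `tp_over_false`.
#' @export
performance_metrics <- function(counts) {
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    sensitivity = rat(counts$TP, counts$TP + counts$FN),
    specificity = rat(counts$TN, counts$TN + counts$FP),
    tp_over_false = rat(counts$TP, counts$FP + counts$FN))
}

#' ROC curve and AUC of a barcode score against known composition
#'
#' Sweeps the present/absent threshold over the observed score values and
#' records (threshold, sensitivity, 1 - specificity); the area under the
#' curve is computed by the trapezoid rule.
#'
#' @param scores Numeric score per barcode.
#' @param truly_present Logical vector, same length.
#' @return A `roc_curve`: list with `points` (tibble `threshold`,
#'   `sensitivity`, `fpr`) and `auc`.
#' @export
roc_curve <- function(scores, truly_present) {
  stopifnot(length(scores) == length(truly_present))
  if (all(truly_present) || !any(truly_present)) {
    stop("undefined AUC: need at least one present and one absent barcode")
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- lapply(th, function(t) {
    call <- scores >= t
    tibble::tibble(threshold = t,
                   sensitivity = sum(call & truly_present) / sum(truly_present),
                   fpr = sum(call & !truly_present) / sum(!truly_present))
  })
  pts <- dplyr::bind_rows(pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sensitivity, -1) +
                                utils::tail(pts$sensitivity, -1)) / 2)
  structure(list(points = pts, auc = auc,
                 n_present = sum(truly_present),
                 n_absent = sum(!truly_present)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " thresholds, AUC = ",
      format(x$auc, digits = 4), " (", x$n_present, " present / ",
      x$n_absent, " absent)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_present = x$n_present, n_absent = x$n_absent)
}

#' @method tidy binning_result
#' @export
tidy.binning_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance binning_result
#' @export
glance.binning_result <- function(x, ...) {
  pool <- attr(x, "pool")
  sp <- attr(x, "sprime_stats")
  tibble::tibble(
    n_barcodes = nrow(x), n_present = sum(x$present),
    n_aligned_reads = pool$n_aligned_reads %||% NA_integer_,
    n_matches = pool$n_matches %||% NA_integer_,
    a_specificity = pool$a_specificity %||% NA_real_,
    sprime = if (is.null(sp)) NA_real_ else sp$sprime,
    cutoff1 = attr(x, "cutoffs")[["cutoff1"]],
    cutoff2 = attr(x, "cutoffs")[["cutoff2"]])
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot binning_result
#' @export
autoplot.binning_result <- function(object, ...) {
  co <- attr(object, "cutoffs")
  df <- tibble::as_tibble(object)
  df$barcode_id <- factor(df$barcode_id,
                          levels = df$barcode_id[order(-df$score2)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$barcode_id,
                                   y = pmax(0, .data$score2),
                                   fill = .data$present)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = co[["cutoff2"]], linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32",
                                          `FALSE` = "grey65")) +
    ggplot2::labs(x = NULL, y = "BarcodeScore2", fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Grid search over cut-off pairs
#'
#' Re-classifies replicated score tables with every (cutoff1, cutoff2) pair
#' under the AND rule and averages TP / (FP + FN) over replicates;
#' replicates with an undefined ratio are excluded from the mean and
#' counted.
#'
#' @param tables List of tibbles with `barcode_id`, `score1`, `score2` and
#'   a logical `truly_present` column (one per replicate).
#' @param grid1,grid2 Candidate cut-offs for BarcodeScore1 / BarcodeScore2.
#' @return Tibble `cutoff1`, `cutoff2`, `mean_ratio`, `n_valid`,
#'   `mean_sensitivity`, `mean_specificity`; the arg-max pair is attached
#'   as attribute `"best"`.
#' @export
cutoff_grid_search <- function(tables, grid1, grid2) {
  if (length(grid1) == 0L || length(grid2) == 0L) {
    stop("empty cut-off grid")
  }
  stopifnot(length(tables) >= 1L)
  grid <- tidyr::expand_grid(cutoff1 = grid1, cutoff2 = grid2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    c1 <- grid$cutoff1[i]; c2 <- grid$cutoff2[i]
    mets <- lapply(tables, function(tb) {
      calls <- tibble::tibble(
        barcode_id = tb$barcode_id,
        present = tb$score1 >= c1 & tb$score2 >= c2)
      truth <- stats::setNames(as.numeric(tb$truly_present), tb$barcode_id)
      cc <- confusion_counts(calls, truth)
      m <- performance_metrics(cc)
      # a perfect replicate (TP > 0, no false predictions) counts as +Inf;
      # only the vacuous 0/0 replicates are excluded from the mean
      m$tp_over_false <- if (cc$FP + cc$FN > 0) cc$TP / (cc$FP + cc$FN)
        else if (cc$TP > 0) Inf else NA_real_
      m
    })
    mets <- dplyr::bind_rows(mets)
    tibble::tibble(
      cutoff1 = c1, cutoff2 = c2,
      mean_ratio = mean(mets$tp_over_false, na.rm = TRUE),
      n_valid = sum(!is.na(mets$tp_over_false)),
      mean_sensitivity = mean(mets$sensitivity, na.rm = TRUE),
      mean_specificity = mean(mets$specificity, na.rm = TRUE))
  })
  out <- dplyr::bind_rows(rows)
  valid <- which(out$n_valid > 0 & !is.na(out$mean_ratio))
  best <- if (length(valid)) out[valid[which.max(out$mean_ratio[valid])], ]
          else out[0, ]
  attr(out, "best") <- best
  out
}
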