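.truth_keys <- function(alleles, resolution) {
  if (resolution == "two_digit") unique(group_key(alleles))
  else unique(protein_key(alleles))
}

# One sample's predicted items at a resolution. Each prediction slot yields
# one item: at two-digit resolution its allele group; at four-digit
# resolution its top-ranked (ex-equo) allele set, reduced to protein keys.
# An item is ambiguous when distinct names share an identical score and
# expect value: within the slot's top set (four-digit), or across slots
# tying exactly (two-digit).
.pred_items <- function(pred, resolution) {
  if (nrow(pred) == 0L)
    return(list())
  items <- list()
  sl <- split(pred, paste(pred$gene, pred$slot))
  # slot-level representative score/eval for cross-slot tie detection
  rep_score <- vapply(sl, function(x) max(x$score), 0)
  rep_eval <- vapply(sl, function(x) x$eval[which.max(x$score)], 0)
  genes <- vapply(sl, function(x) x$gene[1L], "")
  for (i in seq_along(sl)) {
    x <- sl[[i]]
    if (resolution == "two_digit") {
      keys <- unique(group_key(x$allele))
      same_score <- abs(rep_score - rep_score[i]) < 1e-9
      same_eval <- abs(rep_eval - rep_eval[i]) <=
        1e-9 * pmax(rep_eval, rep_eval[i])
      cross <- any(genes == genes[i] & seq_along(sl) != i &
                     same_score & same_eval)
      amb <- length(keys) > 1L || cross
    } else {
      keys <- unique(protein_key(x$allele))
      amb <- length(keys) > 1L
    }
    items[[length(items) + 1L]] <- list(keys = keys, ambiguous = amb)
  }
  items
}

#' Evaluate predictions against a truth set
#'
#' Compares predictions with spiked-in truth at allele-group (two-digit) or
#' protein-allele (four-digit) resolution, using proportion definitions:
#' sensitivity is the number of distinct truth groups/alleles detected over
#' the number of distinct groups/alleles chosen for the simulation;
#' ambiguity is the proportion of ambiguous predictions (distinct names with
#' identical score and probability) among all predictions; specificity is
#' the number of groups/alleles predicted accurately divided by the number
#' detected. All are percentages. P-designated names compare equal to their
#' protein allele at four-digit resolution.
#'
#' @param predictions An `hla_predictions` data.frame (one sample) or a list
#'   of them (counts are pooled before the ratios are taken).
#' @param truth Character vector of spiked allele names (one sample), or a
#'   list matching `predictions`, or an `hla_truth` data.frame with a
#'   `sample` column.
#' @param resolution `"two_digit"` or `"four_digit"`.
#' @return One-row data.frame of class `hla_metrics`: `resolution`,
#'   `sensitivity`, `specificity`, `ambiguity` plus the underlying counts
#'   (`truth_distinct`, `detected`, `accurate`, `ambiguous`,
#'   `predicted_total`).
#' @export
evaluate <- function(predictions, truth,
                     resolution = c("two_digit", "four_digit")) {
  resolution <- match.arg(resolution)
  if (inherits(predictions, "hla_predictions"))
    predictions <- list(predictions)
  if (inherits(truth, "hla_truth") || (is.data.frame(truth) &&
                                       "sample" %in% names(truth)))
    truth <- split(truth$allele, truth$sample)
  if (!is.list(truth)) truth <- list(truth)
  if (length(truth) != length(predictions))
    stop("predictions and truth must cover the same samples")
  if (any(lengths(truth) == 0L)) stop("empty truth set")

  tot <- c(truth_distinct = 0L, detected = 0L, accurate = 0L,
           ambiguous = 0L, predicted_total = 0L)
  for (i in seq_along(truth)) {
    tk <- .truth_keys(truth[[i]], resolution)
    items <- .pred_items(predictions[[i]], resolution)
    item_keys <- lapply(items, `[[`, "keys")
    matched_truth <- vapply(tk, function(k)
      any(vapply(item_keys, function(ks) k %in% ks, TRUE)), TRUE)
    item_match <- vapply(item_keys, function(ks) any(ks %in% tk), TRUE)
    tot["truth_distinct"] <- tot["truth_distinct"] + length(tk)
    tot["detected"] <- tot["detected"] + sum(matched_truth)
    tot["accurate"] <- tot["accurate"] + sum(item_match)
    tot["ambiguous"] <- tot["ambiguous"] +
      sum(vapply(items, `[[`, TRUE, "ambiguous"))
    tot["predicted_total"] <- tot["predicted_total"] + length(items)
  }
  out <- data.frame(
    resolution = resolution,
    sensitivity = 100 * tot[["detected"]] / tot[["truth_distinct"]],
    specificity = if (tot[["detected"]] > 0)
      100 * tot[["accurate"]] / tot[["detected"]] else NA_real_,
    ambiguity = if (tot[["predicted_total"]] > 0)
      100 * tot[["ambiguous"]] / tot[["predicted_total"]] else NA_real_,
    truth_distinct = tot[["truth_distinct"]], detected = tot[["detected"]],
    accurate = tot[["accurate"]], ambiguous = tot[["ambiguous"]],
    predicted_total = tot[["predicted_total"]],
    stringsAsFactors = FALSE)
  class(out) <- c("hla_metrics", "data.frame")
  out
}

#' Summarise replicate metrics per condition
#'
#' Arithmetic mean and sample standard deviation of each metric across
#' replicates, per condition — the benchmark-table shape
#' (`Sensitivity (mean +/- SD%)` etc.).
#'
#' @param results data.frame of per-replicate metric rows; every column that
#'   is not a metric (`sensitivity`, `specificity`, `ambiguity`) or a count
#'   is treated as a condition key.
#' @return data.frame with one row per condition and `<metric>_mean`,
#'   `<metric>_sd` columns.
#' @export
sweep_summary <- function(results) {
  metrics <- c("sensitivity", "specificity", "ambiguity")
  counts <- c("truth_distinct", "detected", "accurate", "ambiguous",
              "predicted_total", "replicate")
  keys <- setdiff(names(results), c(metrics, counts))
  if (length(keys) == 0L) {
    results$condition <- "all"
    keys <- "condition"
  }
  kf <- interaction(results[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(kf), function(lv) {
    sub <- results[kf == lv, , drop = FALSE]
    if (nrow(sub) < 2L) stop("need >= 2 replicates per condition")
    out <- sub[1L, keys, drop = FALSE]
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(sub[[m]], na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a benchmark summary as a formatted TSV
#'
#' Metric columns are rendered as `mean +/- sd` percentages.
#'
#' @param summary Output of [sweep_summary()].
#' @param path Output TSV path.
#' @export
write_sweep_tsv <- function(summary, path) {
  out <- summary
  for (m in c("sensitivity", "specificity", "ambiguity")) {
    mu <- out[[paste0(m, "_mean")]]
    sdv <- out[[paste0(m, "_sd")]]
    out[[m]] <- sprintf("%.2f ± %.2f", mu, sdv)
    out[[paste0(m, "_mean")]] <- NULL
    out[[paste0(m, "_sd")]] <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
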