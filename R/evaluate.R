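arch_key <- function(labels) paste(labels, collapse = ",")

clan_key <- function(labels, clans) {
  # families sharing a clan are equivalent position by position; a family
  # without a clan stands for itself
  mapped <- ifelse(labels %in% names(clans), unname(clans[labels]), labels)
  paste(mapped, collapse = ",")
}

prepare_eval <- function(cl, architectures, clans) {
  ann <- names(architectures)
  missing <- setdiff(ann, names(cl))
  if (length(missing)) {
    stop("annotated sequence absent from the clustering: ", missing[1])
  }
  list(
    ids = ann,
    cluster = unclass(cl)[ann],
    akey = vapply(architectures, arch_key, character(1)),
    ckey = vapply(architectures, clan_key, character(1), clans = clans))
}

#' Sequence-level clustering sensitivity
#'
#' For an annotated sequence: the number of sequences of the same domain
#' architecture in its cluster (itself included), divided by the number of
#' sequences of that architecture in the whole input. Architecture equality
#' is the exact ordered match of family labels.
#'
#' @param id an annotated sequence id.
#' @param cl a [clustering()].
#' @param architectures named list: id -> ordered family labels.
#' @export
sequence_sensitivity <- function(id, cl, architectures) {
  ev <- prepare_eval(cl, architectures, character())
  k <- match(id, ev$ids)
  if (is.na(k)) stop("sequence is not annotated: ", id)
  same_arch <- ev$akey == ev$akey[k]
  sum(same_arch & ev$cluster == ev$cluster[k]) / sum(same_arch)
}

#' Sequence-level clustering precision
#'
#' For an annotated sequence: the number of annotated sequences in its
#' cluster whose architecture is clan-equivalent to its own, divided by the
#' number of annotated sequences in the cluster. Two architectures are
#' clan-equivalent when they have equal length and their k-th families are
#' identical or belong to the same clan. Non-annotated cluster members are
#' ignored.
#'
#' @inheritParams sequence_sensitivity
#' @param clans named character vector: family label -> clan label.
#' @export
sequence_precision <- function(id, cl, architectures, clans = character()) {
  ev <- prepare_eval(cl, architectures, clans)
  k <- match(id, ev$ids)
  if (is.na(k)) stop("sequence is not annotated: ", id)
  in_cluster <- ev$cluster == ev$cluster[k]
  sum(in_cluster & ev$ckey == ev$ckey[k]) / sum(in_cluster)
}

#' Evaluate a clustering against domain-architecture annotations
#'
#' Computes the sequence-level sensitivity and precision for every annotated
#' sequence and aggregates them with the arithmetic mean. Non-annotated
#' sequences are ignored throughout (they contribute neither to architecture
#' counts nor to cluster sizes).
#'
#' @param cl a [clustering()]; must contain every annotated id.
#' @param architectures named list: id -> ordered family labels.
#' @param clans named character vector: family -> clan (used for precision).
#' @return An object of class `eval_result`: `per_sequence` data frame
#'   (`id`, `sensitivity`, `precision`), `mean_sensitivity`,
#'   `mean_precision` and `annotated`.
#' @export
evaluate_clustering <- function(cl, architectures, clans = character()) {
  ev <- prepare_eval(cl, architectures, clans)
  n <- length(ev$ids)
  if (n == 0L) stop("no annotated sequences to evaluate")
  arch_total <- table(ev$akey)
  arch_in_cluster <- table(paste(ev$cluster, ev$akey, sep = "\r"))
  clan_in_cluster <- table(paste(ev$cluster, ev$ckey, sep = "\r"))
  cluster_size <- table(ev$cluster)
  sens <- as.vector(arch_in_cluster[paste(ev$cluster, ev$akey, sep = "\r")]) /
    as.vector(arch_total[ev$akey])
  prec <- as.vector(clan_in_cluster[paste(ev$cluster, ev$ckey, sep = "\r")]) /
    as.vector(cluster_size[ev$cluster])
  structure(list(
    per_sequence = data.frame(id = ev$ids, sensitivity = sens,
                              precision = prec, stringsAsFactors = FALSE),
    mean_sensitivity = mean(sens),
    mean_precision = mean(prec),
    annotated = n), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("clustering evaluation over", x$annotated, "annotated sequences\n")
  cat(sprintf("  mean sensitivity: %.4f\n", x$mean_sensitivity))
  cat(sprintf("  mean precision:   %.4f\n", x$mean_precision))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per annotated sequence plus a trailing `__mean__` summary row.
#'
#' @param result an `eval_result` from [evaluate_clustering()].
#' @param path output path.
#' @export
write_eval_tsv <- function(result, path) {
  df <- result$per_sequence
  df <- rbind(df, data.frame(id = "__mean__",
                             sensitivity = result$mean_sensitivity,
                             precision = result$mean_precision))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
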