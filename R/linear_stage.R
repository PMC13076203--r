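#' Group sequences by shared seed
#'
#' Sequences carrying an identical seed key (under any of the supplied
#' shapes, optionally after minimizer subsampling) are gathered into groups.
#' Only groups with at least two members are returned; members are ordered
#' by decreasing length with ties broken by id, the ordering the linear-stage
#' interval sweep relies on.
#'
#' @param db a [sequence_db()].
#' @param shapes one or more [seed_shape()]s (or pattern strings).
#' @param window minimizer window size, or `NULL` to enumerate all seeds.
#' @return A list of integer vectors of record positions, one per seed group.
#' @export
group_by_seed <- function(db, shapes, window = NULL) {
  shapes <- as_shape_list(shapes)
  keys <- vector("list", length(shapes) * length(db))
  seqs <- vector("list", length(shapes) * length(db))
  k <- 0L
  for (sh in shapes) {
    for (r in seq_along(db$id)) {
      sd <- if (is.null(window)) cc_seed_keys(db$seq[r], sh$pattern)
            else cc_minimizers(db$seq[r], sh$pattern, as.integer(window))
      if (nrow(sd)) {
        k <- k + 1L
        keys[[k]] <- unique(sd$key)
        seqs[[k]] <- rep.int(r, length(keys[[k]]))
      }
    }
  }
  if (k == 0L) return(list())
  key <- unlist(keys[seq_len(k)], use.names = FALSE)
  rec <- unlist(seqs[seq_len(k)], use.names = FALSE)
  # distinct (key, record) pairs, then groups of >= 2 records
  dup <- duplicated(paste(key, rec))
  key <- key[!dup]; rec <- rec[!dup]
  groups <- split(rec, key)
  groups <- groups[lengths(groups) >= 2L]
  names(groups) <- NULL
  lapply(groups, function(g) {
    g[order(-db$length[g], db$id[g], method = "radix")]
  })
}

#' Candidate pairs of a seed group, uni-directional mode
#'
#' Every member is paired with the group's longest sequence only: under a
#' uni-directional coverage criterion the longest sequence is a priori the
#' most likely to recruit the rest of the group.
#'
#' @param group integer vector of record positions, length-sorted descending.
#' @return Two-column integer matrix (putative representative, member);
#'   `n - 1` rows for a group of `n`.
#' @export
candidates_uni <- function(group) {
  if (length(group) < 2L) return(matrix(integer(), ncol = 2L))
  cbind(rep.int(group[1L], length(group) - 1L), group[-1L])
}

#' Candidate pairs of a seed group, bi-directional mode
#'
#' Interval/median sweep over the length-sorted group: an interval `[i; j]`
#' of mutually length-compatible members (shorter/longer ratio at least
#' `c + delta`) is built, all its members are paired with the member at the
#' median index `floor((i + j) / 2)`, and the interval is advanced until it
#' reaches the end of the group. Pairs whose lengths cannot satisfy the
#' bi-directional coverage threshold are thereby never generated.
#'
#' @param group integer vector of record positions, length-sorted descending.
#' @param lengths sequence lengths, indexed by record position.
#' @param c coverage threshold.
#' @param delta stringency added to `c` for the length-ratio filter.
#' @return Two-column integer matrix (median member, other member).
#' @export
candidates_bi <- function(group, lengths, c, delta = 0.05) {
  n <- length(group)
  if (n < 2L || c + delta > 1) return(matrix(integer(), ncol = 2L))
  l <- lengths[group]
  pairs_a <- integer(); pairs_b <- integer()
  i <- 1L
  repeat {
    # largest j whose length is within ratio c + delta of the interval head
    j <- i
    while (j < n && l[j + 1L] / l[i] >= c + delta) j <- j + 1L
    if (j > i) {
      med <- (i + j) %/% 2L
      others <- setdiff(i:j, med)
      pairs_a <- c(pairs_a, rep.int(med, length(others)))
      pairs_b <- c(pairs_b, others)
    }
    if (j == n) break
    # advance: first index after i length-compatible with the next sequence
    i2 <- i + 1L
    while (i2 <= n && l[j + 1L] / l[i2] < c + delta) i2 <- i2 + 1L
    i <- i2
    if (i > n) break
  }
  cbind(group[pairs_a], group[pairs_b])
}

#' Run one linear-scaling candidate-generation round
#'
#' Groups sequences by shared seed, generates candidate pairs (against the
#' longest member in uni mode, via the interval/median sweep in bi mode),
#' aligns every candidate pair once (duplicates across groups and shapes are
#' merged) and keeps the alignments passing the round's criterion as
#' directed can-represent edges.
#'
#' @param db a [sequence_db()].
#' @param criterion a [cluster_criterion()].
#' @param shapes seed shapes for grouping.
#' @param window minimizer window or `NULL`.
#' @param delta length-ratio stringency for bi mode.
#' @param scoring a [scoring_scheme()].
#' @return A data frame of directed edges (`from`, `to` record positions;
#'   `from` can represent `to`) plus the hit columns of [align_pairs()].
#' @export
linear_round <- function(db, criterion, shapes, window = NULL, delta = 0.05,
                         scoring = scoring_scheme()) {
  groups <- group_by_seed(db, shapes, window)
  if (!length(groups)) return(empty_edges())
  pairs <- do.call(rbind, lapply(groups, function(g) {
    if (criterion$cov_mode == "uni") candidates_uni(g)
    else candidates_bi(g, db$length, criterion$min_cov, delta)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_edges())
  # canonical unordered key: each pair aligned once across groups and shapes
  a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- !duplicated(a * (length(db) + 1) + b)
  pairs <- pairs[keep, , drop = FALSE]
  hits <- align_pairs(db, pairs[, 1L], pairs[, 2L], scoring)
  hits_to_edges(hits, criterion, db)
}

empty_edges <- function() {
  data.frame(from = integer(), to = integer())
}

#' Turn criterion-checked alignments into directed edges
#'
#' In bi mode an alignment passing coverage of both sides yields both
#' directions; in uni mode the edge `A -> B` only requires coverage of `B`,
#' so each direction is checked separately.
#'
#' @param hits data frame from [align_pairs()].
#' @param criterion a [cluster_criterion()].
#' @param db the [sequence_db()] the hits refer to.
#' @return Data frame with `from` and `to` record positions.
#' @export
hits_to_edges <- function(hits, criterion, db) {
  qi <- match(hits$query, db$id); ti <- match(hits$target, db$id)
  fwd <- passes_criterion(hits, criterion, member = "target")
  rev <- passes_criterion(hits, criterion, member = "query")
  edges <- data.frame(from = c(qi[fwd], ti[rev]), to = c(ti[fwd], qi[rev]))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges[!duplicated(edges), , drop = FALSE]
}
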