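SENS_LEVELS <- c("faster", "fast", "default", "sensitive",
                 "very-sensitive", "ultra-sensitive")

# Modeled sensitivity ladder: each level maps to the set of seed shapes used
# for candidate generation in all-vs-all rounds (more, lighter-weight shapes
# as sensitivity rises); ultra-sensitive drops seeding entirely and
# evaluates every length-compatible pair.
sensitivity_shapes <- function(level) {
  switch(level,
    "faster" = list("1111111"),
    "fast" = list("1111111"),
    "default" = list("111111", "11011011", "110101011", "1010101011"),
    "sensitive" = list("11111", "110111", "1101011", "1100111",
                       "11001011", "10101011", "110010101", "101001011"),
    "very-sensitive" = list("1111", "11011", "110101", "101011", "1100101",
                            "1010011", "11000101", "10100101", "10010011",
                            "101000101", "100101001", "110001001"),
    "ultra-sensitive" = NULL,
    stop("unknown sensitivity level: ", level))
}

#' Specify one round of cascaded clustering
#'
#' @param sensitivity one of `"faster"`, `"fast"`, `"default"`,
#'   `"sensitive"`, `"very-sensitive"`, `"ultra-sensitive"`.
#' @param stage `"linear-with-minimizers"`, `"linear"` or `"all-vs-all"`.
#' @param shapes seed shapes; defaults to the ladder set for `sensitivity`.
#' @param window minimizer window (only for `"linear-with-minimizers"`).
#' @param depth greedy vertex cover search depth for this round.
#' @return An object of class `round_spec`.
#' @export
round_spec <- function(sensitivity, stage = c("all-vs-all", "linear",
                                              "linear-with-minimizers"),
                       shapes = NULL, window = NULL, depth = 1L) {
  stage <- match.arg(stage)
  sensitivity <- match.arg(sensitivity, SENS_LEVELS)
  if (is.null(shapes)) shapes <- sensitivity_shapes(sensitivity)
  if (!is.null(shapes)) shapes <- as_shape_list(shapes)
  if (stage == "linear-with-minimizers" && is.null(window)) window <- 12L
  structure(list(sensitivity = sensitivity, stage = stage, shapes = shapes,
                 window = window, depth = as.integer(depth)),
            class = "round_spec")
}

#' Search depth for a cascade round
#'
#' Depth 1 for the first two rounds, depth 3 for the remaining rounds; the
#' third round of the pure linear mode uses depth 2.
#'
#' @param round_index 1-based round number.
#' @param stage the round's stage kind.
#' @export
search_depth_for_round <- function(round_index, stage = "all-vs-all") {
  if (round_index <= 2L) return(1L)
  if (round_index == 3L && stage %in% c("linear", "linear-with-minimizers")) {
    return(2L)
  }
  3L
}

#' Default cascade configuration
#'
#' The standard cascade runs two linear rounds (the first with minimizer
#' subsampling, window 12) followed by all-vs-all rounds at escalating
#' sensitivity. The deep-clustering default is four rounds
#' (linear-with-minimizers, linear, default, sensitive); up to six rounds
#' extend through very-sensitive and ultra-sensitive.
#'
#' @param rounds total number of rounds, between 2 and 6.
#' @param criterion the base [cluster_criterion()].
#' @return An object of class `cascade_config` with `rounds` (list of
#'   [round_spec()]) and `criterion`.
#' @export
default_cascade <- function(rounds = 4L, criterion = cluster_criterion()) {
  rounds <- as.integer(rounds)
  if (rounds < 2L || rounds > 6L) stop("a cascade chains 2 to 6 rounds")
  ladder <- c("faster", "fast", "default", "sensitive", "very-sensitive",
              "ultra-sensitive")[seq_len(rounds)]
  specs <- vector("list", rounds)
  for (k in seq_len(rounds)) {
    stage <- if (k == 1L) "linear-with-minimizers"
             else if (k == 2L) "linear" else "all-vs-all"
    specs[[k]] <- round_spec(ladder[k], stage,
                             depth = search_depth_for_round(k, stage))
  }
  structure(list(rounds = specs, criterion = criterion),
            class = "cascade_config")
}

#' Effective criterion of a cascade round
#'
#' Earlier rounds use a more stringent criterion that is relaxed later:
#' every round up to and including default sensitivity adds +7% to both the
#' identity and the coverage thresholds; the sensitive round adds +5% to the
#' coverage threshold only; later rounds use the base criterion unchanged.
#' Thresholds are clamped at 1.
#'
#' @param base the base [cluster_criterion()].
#' @param round a [round_spec()].
#' @return A [cluster_criterion()].
#' @export
round_criterion <- function(base, round) {
  lev <- match(round$sensitivity, SENS_LEVELS)
  id <- base$min_id; cov <- base$min_cov
  if (lev <= match("default", SENS_LEVELS)) {
    id <- min(1, id + 0.07); cov <- min(1, cov + 0.07)
  } else if (round$sensitivity == "sensitive") {
    cov <- min(1, cov + 0.05)
  }
  cluster_criterion(base$max_evalue, id, cov, base$cov_mode)
}

#' All-vs-all self-comparison round
#'
#' Candidate pairs come from shared seeds at the round's sensitivity (every
#' pair evaluated once, exploiting query/target symmetry of
#' self-comparison); at ultra-sensitive sensitivity every pair is a
#' candidate. Under a bi-directional criterion, pairs whose length ratio
#' falls below `c - epsilon` are skipped before alignment via a scan over
#' the length-sorted index; the length-ratio property makes this pruning
#' lossless up to the epsilon gap allowance.
#'
#' @param db a [sequence_db()] of the current representatives.
#' @param criterion the round's [cluster_criterion()].
#' @param sensitivity sensitivity level (sets the seed shapes).
#' @param epsilon permissive tolerance subtracted from the coverage
#'   threshold for length pruning.
#' @param scoring a [scoring_scheme()].
#' @return Directed edge data frame as in [linear_round()].
#' @export
all_vs_all_round <- function(db, criterion, sensitivity = "ultra-sensitive",
                             epsilon = 0.05, scoring = scoring_scheme()) {
  n <- length(db)
  if (n < 2L) return(empty_edges())
  shapes <- sensitivity_shapes(match.arg(sensitivity, SENS_LEVELS))
  if (is.null(shapes)) {
    pairs <- all_pairs_length_scan(db, criterion, epsilon)
  } else {
    groups <- group_by_seed(db, shapes, window = NULL)
    if (!length(groups)) return(empty_edges())
    pairs <- do.call(rbind, lapply(groups, function(g) {
      idx <- t(utils::combn(g, 2L))
      idx
    }))
    a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
    keep <- !duplicated(a * (n + 1) + b)
    pairs <- cbind(a[keep], b[keep])
    if (criterion$cov_mode == "bi") {
      ok <- length_compatible(db$length[pairs[, 1L]], db$length[pairs[, 2L]],
                              criterion$min_cov, -epsilon)
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) return(empty_edges())
  hits <- align_pairs(db, pairs[, 1L], pairs[, 2L], scoring)
  hits_to_edges(hits, criterion, db)
}

# every unordered pair once; in bi mode only pairs within the
# length-compatible range of the descending length-sorted index
all_pairs_length_scan <- function(db, criterion, epsilon) {
  n <- length(db)
  ord <- db$by_length
  lens <- db$length[ord]
  lo <- if (criterion$cov_mode == "bi") criterion$min_cov - epsilon else 0
  pa <- vector("list", n - 1L)
  j <- 1L
  for (k in seq_len(n - 1L)) {
    if (j < k + 1L) j <- k + 1L
    while (j <= n && lens[j] / lens[k] >= lo) j <- j + 1L
    # targets k+1 .. j-1 are within ratio lo of query k
    if (j - 1L >= k + 1L) pa[[k]] <- cbind(ord[k], ord[(k + 1L):(j - 1L)])
  }
  out <- do.call(rbind, pa)
  if (is.null(out)) matrix(integer(), ncol = 2L) else out
}

#' Cascaded clustering
#'
#' Runs the configured rounds over a deduplicated sequence set: each round
#' self-compares the current representatives at its sensitivity and
#' stringency-adjusted criterion, extracts new representatives by greedy
#' vertex cover at the round's search depth, and passes them on. Per-round
#' assignments are composed into one final partition of all input ids.
#'
#' @param db a deduplicated [sequence_db()].
#' @param criterion the base [cluster_criterion()].
#' @param config a cascade configuration from [default_cascade()].
#' @param delta linear-stage length-ratio stringency.
#' @param epsilon all-vs-all length-pruning tolerance.
#' @param scoring a [scoring_scheme()].
#' @param verbose log per-round representative counts.
#' @return A [clustering()] with attributes `rounds` (per-round summary data
#'   frame) and `history` (the per-round clusterings, so that
#'   member-representative chains can be re-checked).
#' @export
cascade_cluster <- function(db, criterion = cluster_criterion(),
                            config = default_cascade(criterion = criterion),
                            delta = 0.05, epsilon = 0.05,
                            scoring = scoring_scheme(), verbose = FALSE) {
  overall <- clustering(structure(db$id, names = db$id))
  cur <- db
  history <- list()
  summary <- data.frame(round = integer(), stage = character(),
                        sensitivity = character(), depth = integer(),
                        representatives = integer())
  for (k in seq_along(config$rounds)) {
    rs <- config$rounds[[k]]
    crit <- round_criterion(config$criterion, rs)
    edges <- switch(rs$stage,
      "linear-with-minimizers" = linear_round(cur, crit, rs$shapes,
                                              rs$window, delta, scoring),
      "linear" = linear_round(cur, crit, rs$shapes, NULL, delta, scoring),
      "all-vs-all" = all_vs_all_round(cur, crit, rs$sensitivity, epsilon,
                                      scoring))
    graph <- align_graph(cur$id, edges, cur$length)
    cl <- greedy_vertex_cover(graph, rs$depth)
    overall <- compose_clusterings(cl, overall)
    cur <- db_subset(db, representatives(cl))
    history[[k]] <- cl
    summary <- rbind(summary, data.frame(
      round = k, stage = rs$stage, sensitivity = rs$sensitivity,
      depth = rs$depth, representatives = length(cur)))
    if (verbose) {
      message("round ", k, " (", rs$stage, ", ", rs$sensitivity, "): ",
              length(cur), " representatives")
    }
  }
  attr(overall, "rounds") <- summary
  attr(overall, "history") <- history
  overall
}

# deterministic 30-shape weight-10 set for the linear mode: the contiguous
# shape plus an even stride through the full pool of spaced weight-10
# patterns of span 11..max_span (care at both ends)
builtin_linear_shapes <- function(count = 30L, weight = 10L, max_span = 16L) {
  pool <- list()
  for (span in (weight + 1L):max_span) {
    combos <- utils::combn(span - 2L, weight - 2L)
    for (cmb in seq_len(ncol(combos))) {
      p <- rep(FALSE, span)
      p[c(1L, span)] <- TRUE
      p[combos[, cmb] + 1L] <- TRUE
      pool[[length(pool) + 1L]] <- p
    }
  }
  take <- unique(round(seq(1L, length(pool), length.out = count - 1L)))
  c(list(seed_shape(rep(TRUE, weight))),
    lapply(pool[take], seed_shape))[seq_len(count)]
}

#' Pure linear-mode clustering
#'
#' Cascaded clustering without any all-vs-all stage: the first two rounds
#' are identical to the standard cascade, and the third round runs the
#' linear-stage algorithm with 30 spaced seed shapes of weight 10 at search
#' depth 2.
#'
#' @param db a deduplicated [sequence_db()].
#' @param criterion the base [cluster_criterion()].
#' @param shapes30 the multiple spaced seeds for round 3; defaults to the
#'   built-in deterministic weight-10 set (learned shapes from
#'   [learn_shapes()] can be supplied instead).
#' @inheritParams cascade_cluster
#' @return A [clustering()] (with `rounds`/`history` attributes).
#' @export
linclust <- function(db, criterion = cluster_criterion(), shapes30 = NULL,
                     delta = 0.05, scoring = scoring_scheme(),
                     verbose = FALSE) {
  if (is.null(shapes30)) shapes30 <- builtin_linear_shapes()
  shapes30 <- as_shape_list(shapes30)
  specs <- list(
    round_spec("faster", "linear-with-minimizers", depth = 1L),
    round_spec("fast", "linear", depth = 1L),
    round_spec("sensitive", "linear", shapes = shapes30,
               depth = search_depth_for_round(3L, "linear")))
  config <- structure(list(rounds = specs, criterion = criterion),
                      class = "cascade_config")
  cascade_cluster(db, criterion, config, delta = delta, scoring = scoring,
                  verbose = verbose)
}

#' Add new sequences to an existing clustering
#'
#' Each new sequence is searched against the existing representatives
#' (shared-seed candidates with length pruning under a bi-directional
#' criterion); sequences passing the criterion join the best-scoring
#' representative (ties to the smaller id). The remainder is clustered among
#' itself with [cascade_cluster()] and merged. Existing assignments are
#' never changed.
#'
#' @param existing a [clustering()] of the current members.
#' @param rep_db [sequence_db()] holding the existing representatives.
#' @param new_db [sequence_db()] of new sequences; ids must not collide with
#'   existing members.
#' @param criterion the [cluster_criterion()].
#' @param config cascade configuration for the unassigned remainder.
#' @param scoring a [scoring_scheme()].
#' @return A [clustering()] over the union of old and new ids.
#' @export
add_sequences <- function(existing, rep_db, new_db,
                          criterion = cluster_criterion(),
                          config = default_cascade(criterion = criterion),
                          scoring = scoring_scheme()) {
  if (length(intersect(new_db$id, names(existing)))) {
    stop("new sequence ids collide with the existing clustering")
  }
  reps <- representatives(existing)
  if (!all(reps %in% rep_db$id)) stop("rep_db is missing representatives")
  joint <- sequence_db(c(rep_db$id, new_db$id), c(rep_db$seq, new_db$seq))
  nrep <- length(rep_db)
  # candidate representative per new sequence via shared seeds
  groups <- group_by_seed(joint, sensitivity_shapes("sensitive"))
  cand <- do.call(rbind, lapply(groups, function(g) {
    r <- g[g <= nrep]; m <- g[g > nrep]
    if (!length(r) || !length(m)) return(NULL)
    cbind(rep(r, each = length(m)), rep(m, length(r)))
  }))
  assigned <- structure(character(0), names = character(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[!duplicated(cand[, 1L] * (length(joint) + 1) + cand[, 2L]), ,
                 drop = FALSE]
    if (criterion$cov_mode == "bi") {
      ok <- length_compatible(joint$length[cand[, 1L]],
                              joint$length[cand[, 2L]],
                              criterion$min_cov, -0.05)
      cand <- cand[ok, , drop = FALSE]
    }
    if (nrow(cand)) {
      hits <- align_pairs(joint, cand[, 1L], cand[, 2L], scoring,
                          db_residues = sum(rep_db$length))
      pass <- passes_criterion(hits, criterion, member = "target")
      hits <- hits[pass, , drop = FALSE]
      if (nrow(hits)) {
        hits <- hits[order(hits$target, -hits$score, hits$query,
                           method = "radix"), ]
        best <- hits[!duplicated(hits$target), ]
        assigned <- structure(best$query, names = best$target)
      }
    }
  }
  rest_ids <- setdiff(new_db$id, names(assigned))
  parts <- unclass(existing)
  if (length(assigned)) {
    parts <- c(parts, structure(unname(assigned), names = names(assigned)))
  }
  if (length(rest_ids)) {
    rest_cl <- cascade_cluster(db_subset(new_db, rest_ids), criterion, config,
                               scoring = scoring)
    parts <- c(parts, unclass(rest_cl))
  }
  clustering(parts)
}
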