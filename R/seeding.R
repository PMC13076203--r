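#' Spaced-seed shape
#'
#' A shape is an ordered mask of care/don't-care positions. A seed hit
#' requires identical residues at all care positions; don't-care positions
#' are skipped when hashing, which trades specificity for sensitivity when
#' several shapes are combined. The first and last positions must be care
#' positions.
#'
#' @param pattern a string of `'1'`/`'0'` (e.g. `"1101011"`) or a logical
#'   vector, `TRUE`/`'1'` marking care positions.
#' @return An object of class `seed_shape` with `pattern` (logical),
#'   `weight`, `span` and `string`.
#' @export
seed_shape <- function(pattern) {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1, grepl("^[01]+$", pattern))
    pattern <- strsplit(pattern, "")[[1]] == "1"
  }
  pattern <- as.logical(pattern)
  if (!length(pattern) || !pattern[1] || !pattern[length(pattern)]) {
    stop("seed shape must begin and end with a care position")
  }
  structure(list(pattern = pattern, weight = sum(pattern),
                 span = length(pattern),
                 string = paste(ifelse(pattern, "1", "0"), collapse = "")),
            class = "seed_shape")
}

#' @export
print.seed_shape <- function(x, ...) {
  cat("seed_shape", x$string, "(weight", x$weight, ", span", x$span, ")\n")
  invisible(x)
}

as_shape_list <- function(shapes) {
  if (inherits(shapes, "seed_shape")) return(list(shapes))
  lapply(shapes, function(s) if (inherits(s, "seed_shape")) s else seed_shape(s))
}

#' Enumerate the spaced seeds of a sequence
#'
#' One seed per window position; the key is a deterministic 53-bit hash of
#' the residues at the shape's care positions.
#'
#' @param seq a residue string.
#' @param shape a [seed_shape()].
#' @return Data frame with `pos` (1-based window start) and `key` (numeric
#'   hash); empty when the sequence is shorter than the shape span.
#' @export
enumerate_seeds <- function(seq, shape) {
  shape <- as_shape_list(shape)[[1]]
  cc_seed_keys(seq, shape$pattern)
}

#' Subsample seeds with minimizers
#'
#' For every window of `w` consecutive seed positions the seed with the
#' minimal hashed key is kept (ties resolved to the leftmost); duplicate
#' picks from overlapping windows are merged. The number of minimizers thus
#' grows with sequence length. A sequence long enough to carry a seed but
#' shorter than `span + w - 1` emits its single minimal seed so that every
#' sequence stays seedable.
#'
#' @inheritParams enumerate_seeds
#' @param w window size in seed positions.
#' @return Data frame with `pos` and `key`, a subset of [enumerate_seeds()].
#' @export
sample_minimizers <- function(seq, shape, w = 12L) {
  shape <- as_shape_list(shape)[[1]]
  stopifnot(w >= 1)
  cc_minimizers(seq, shape$pattern, as.integer(w))
}

#' Column codes of a pairwise alignment
#'
#' Converts two gapped aligned strings of equal length into per-column codes:
#' 1 for an identical aligned residue pair, 0 for a mismatch, 2 for a gap
#' column.
#'
#' @param qaln,taln aligned strings with `-` for gaps.
#' @export
alignment_codes <- function(qaln, taln) {
  qs <- strsplit(qaln, "")[[1]]
  ts <- strsplit(taln, "")[[1]]
  if (length(qs) != length(ts)) stop("aligned strings differ in length")
  ifelse(qs == "-" | ts == "-", 2L, ifelse(qs == ts, 1L, 0L))
}

as_code_list <- function(alignments) {
  lapply(alignments, function(a) {
    if (is.integer(a) || is.numeric(a)) return(as.integer(a))
    alignment_codes(a$qaln, a$taln)
  })
}

#' Does a seed shape hit an alignment?
#'
#' A shape hits when some window of `span` consecutive gap-free alignment
#' columns carries identical residue pairs at every care position.
#'
#' @param shape a [seed_shape()].
#' @param alignment either an integer column-code vector (see
#'   [alignment_codes()]) or a list with `qaln`/`taln` strings.
#' @export
shape_hits_alignment <- function(shape, alignment) {
  shape <- as_shape_list(shape)[[1]]
  as.vector(cc_shape_hits(as_code_list(list(alignment)),
                          list(shape$pattern)))
}

all_shapes <- function(weight, max_span) {
  # every care mask of the given weight with care at both ends, span <= max_span
  out <- list()
  for (span in weight:max_span) {
    if (weight == 1 && span > 1) next
    interior <- span - 2L
    need <- weight - 2L
    combos <- if (need == 0) list(integer(0)) else
      asplit(utils::combn(interior, need), 2)
    for (cmb in combos) {
      p <- rep(FALSE, span)
      p[c(1L, span)] <- TRUE
      p[unlist(cmb) + 1L] <- TRUE
      out[[length(out) + 1L]] <- seed_shape(p)
    }
  }
  out
}

hill_climb_shape <- function(start, codes, max_span, n_restarts = 8L) {
  weight <- start$weight
  score_of <- function(mask) sum(cc_shape_hits(codes, list(mask)))
  climb <- function(mask) {
    best <- score_of(mask)
    repeat {
      improved <- FALSE
      care <- which(mask)
      for (mv in care) {
        for (slot in seq_len(max_span)) {
          if (slot <= length(mask) && mask[slot]) next
          cand <- mask
          cand[mv] <- FALSE
          if (slot > length(cand)) cand <- c(cand, rep(FALSE, slot - length(cand)))
          cand[slot] <- TRUE
          cand <- cand[seq_len(max(which(cand)))]
          cand <- cand[min(which(cand)):length(cand)]
          if (sum(cand) != weight) next
          s <- score_of(cand)
          if (s > best) { mask <- cand; best <- s; improved <- TRUE; break }
        }
        if (improved) break
      }
      if (!improved) return(list(mask = mask, score = best))
    }
  }
  starts <- list(start$pattern)
  for (r in seq_len(n_restarts)) {
    span <- (weight:max_span)[sample.int(max_span - weight + 1L, 1L)]
    p <- rep(FALSE, span); p[c(1, span)] <- TRUE
    if (weight > 2 && span > 2) {
      interior <- 2:(span - 1)
      p[interior[sample.int(length(interior), weight - 2L)]] <- TRUE
    }
    if (sum(p) == weight) starts[[length(starts) + 1L]] <- p
  }
  res <- lapply(starts, climb)
  scores <- vapply(res, `[[`, numeric(1), "score")
  res[[which.max(scores)]]
}

#' Learn multiple spaced-seed shapes from an alignment collection
#'
#' Greedy set cover: the shape (of the given weight, span at most `max_span`,
#' care at both ends) hitting the most remaining alignments is selected, the
#' alignments it hits are removed, and the process repeats up to `count`
#' times or until no alignment remains. For small shape spaces
#' (`weight <= 5` and `max_span <= 10`) the candidate search is exhaustive;
#' otherwise hill climbing from the contiguous shape with seeded random
#' restarts is used.
#'
#' @param alignments list of alignments (column-code vectors or
#'   `qaln`/`taln` pairs, see [shape_hits_alignment()]).
#' @param weight care-position count of every learned shape.
#' @param max_span maximum shape span.
#' @param count maximum number of shapes to learn.
#' @return A list with `shapes` (list of [seed_shape()], in selection order)
#'   and `hits` (alignments newly covered by each shape).
#' @export
learn_shapes <- function(alignments, weight = 10L, max_span = 16L,
                         count = 30L) {
  if (!length(alignments)) stop("alignment collection is empty")
  if (weight > max_span) stop("shape weight exceeds the maximum span")
  codes <- as_code_list(alignments)
  exhaustive <- weight <= 5 && max_span <= 10
  shapes <- list(); hits <- integer()
  if (exhaustive) {
    pool <- all_shapes(weight, max_span)
    hm <- cc_shape_hits(codes, lapply(pool, `[[`, "pattern"))
    remaining <- rep(TRUE, length(codes))
    for (k in seq_len(count)) {
      counts <- colSums(hm[remaining, , drop = FALSE])
      if (!any(counts > 0)) break
      # ties: lexicographically smallest pattern string, for determinism
      best <- which(counts == max(counts))
      best <- best[order(vapply(pool[best], `[[`, character(1), "string"))][1]
      shapes[[length(shapes) + 1L]] <- pool[[best]]
      hits <- c(hits, as.integer(max(counts)))
      remaining <- remaining & !hm[, best]
      if (!any(remaining)) break
    }
  } else {
    remaining <- seq_along(codes)
    contiguous <- seed_shape(rep(TRUE, weight))
    for (k in seq_len(count)) {
      if (!length(remaining)) break
      res <- hill_climb_shape(contiguous, codes[remaining], max_span)
      if (res$score == 0) break
      sh <- seed_shape(res$mask)
      covered <- as.vector(cc_shape_hits(codes[remaining], list(sh$pattern)))
      shapes[[length(shapes) + 1L]] <- sh
      hits <- c(hits, sum(covered))
      remaining <- remaining[!covered]
    }
  }
  list(shapes = shapes, hits = hits)
}
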