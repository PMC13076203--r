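#' Directed can-represent graph
#'
#' Nodes are sequence ids; a directed edge `A -> B` states that `A` can
#' represent `B` under the clustering criterion. Self-loops are implicit
#' (every sequence can represent itself) and not stored.
#'
#' @param ids node ids (every input sequence, including isolated ones).
#' @param edges data frame with `from`/`to` columns, either integer node
#'   positions or ids.
#' @param lengths optional sequence lengths (used for tie-breaking).
#' @return An object of class `align_graph`.
#' @export
align_graph <- function(ids, edges = empty_edges(), lengths = NULL) {
  from <- edges$from; to <- edges$to
  if (is.character(from)) from <- match(from, ids)
  if (is.character(to)) to <- match(to, ids)
  if (anyNA(from) || anyNA(to) ||
      (length(from) && (max(from, to) > length(ids) || min(from, to) < 1))) {
    stop("edge references an unknown node id")
  }
  keep <- from != to
  from <- as.integer(from[keep]); to <- as.integer(to[keep])
  dup <- duplicated(from * (length(ids) + 1) + to)
  structure(list(ids = ids, from = from[!dup], to = to[!dup],
                 lengths = lengths),
            class = "align_graph")
}

#' @export
print.align_graph <- function(x, ...) {
  cat("align_graph with", length(x$ids), "nodes and", length(x$from),
      "directed edges\n")
  invisible(x)
}

#' Build the can-represent graph from alignment hits
#'
#' @param db a [sequence_db()] (or character vector of ids).
#' @param hits criterion-checkable alignments from [align_pairs()].
#' @param criterion a [cluster_criterion()]; each hit direction is checked
#'   (both directions pass together in bi mode, separately in uni mode).
#' @return An [align_graph()] over all db ids, isolated nodes included.
#' @export
build_graph <- function(db, hits, criterion) {
  if (is.character(db)) db <- list(id = db, length = NULL)
  unknown <- setdiff(unique(c(hits$query, hits$target)), db$id)
  if (length(unknown)) stop("alignment references unknown id: ", unknown[1])
  edges <- if (nrow(hits)) hits_to_edges(hits, criterion, db) else empty_edges()
  align_graph(db$id, edges, db$length)
}

# deterministic representative choice: highest outdegree, then longest
# sequence, then lexicographically smallest id
pick_best <- function(cand, outdeg, lengths, ids) {
  o <- outdeg[cand]
  cand <- cand[o == max(o)]
  if (length(cand) > 1L && !is.null(lengths)) {
    l <- lengths[cand]
    cand <- cand[l == max(l)]
  }
  if (length(cand) > 1L) cand <- cand[order(ids[cand], method = "radix")[1L]]
  cand[1L]
}

#' Greedy vertex cover clustering
#'
#' Repeatedly selects the live node with the highest outdegree over live
#' nodes as a representative and absorbs all live nodes reachable from it
#' within `depth` directed hops into its cluster, removing them from the
#' graph, until every node is assigned. Ties are broken towards the longer
#' sequence, then the lexicographically smaller id.
#'
#' @param graph an [align_graph()].
#' @param depth positive search depth; 1 absorbs direct out-neighbors only.
#' @return A [clustering()] over the graph's node ids.
#' @export
greedy_vertex_cover <- function(graph, depth = 1L) {
  n <- length(graph$ids)
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  assignment <- rep(NA_character_, n)
  if (n == 0L) return(clustering(structure(character(), names = character())))
  adj_out <- split(graph$to, factor(graph$from, levels = seq_len(n)))
  adj_in <- split(graph$from, factor(graph$to, levels = seq_len(n)))
  outdeg <- lengths(adj_out)
  live <- rep(TRUE, n)
  remaining <- n
  while (remaining > 0L) {
    cand <- which(live)
    if (max(outdeg[cand]) == 0L) {  # rest are singletons
      assignment[cand] <- graph$ids[cand]
      break
    }
    r <- pick_best(cand, outdeg, graph$lengths, graph$ids)
    # breadth-first expansion over live nodes up to `depth` hops
    cluster <- r
    frontier <- r
    for (d in seq_len(depth)) {
      nxt <- unique(unlist(adj_out[frontier], use.names = FALSE))
      nxt <- nxt[live[nxt] & !(nxt %in% cluster)]
      if (!length(nxt)) break
      cluster <- c(cluster, nxt)
      frontier <- nxt
    }
    assignment[cluster] <- graph$ids[r]
    live[cluster] <- FALSE
    remaining <- remaining - length(cluster)
    # removal updates outdegrees of surviving in-neighbors
    touched <- unlist(adj_in[cluster], use.names = FALSE)
    touched <- touched[live[touched]]
    if (length(touched)) {
      dec <- table(touched)
      idx <- as.integer(names(dec))
      outdeg[idx] <- outdeg[idx] - as.integer(dec)
    }
  }
  clustering(structure(assignment, names = graph$ids))
}

#' Connected-component clustering
#'
#' Weakly connected components of the can-represent graph; the behavior of
#' greedy vertex cover in the limit of infinite search depth. The
#' representative of each component is its longest member (ties to the
#' smallest id).
#'
#' @param graph an [align_graph()].
#' @return A [clustering()].
#' @export
connected_components <- function(graph) {
  n <- length(graph$ids)
  if (n == 0L) return(clustering(structure(character(), names = character())))
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (length(graph$from)) {
    g <- igraph::add_edges(g, rbind(graph$from, graph$to))
  }
  comp <- igraph::components(g, mode = "weak")$membership
  assignment <- rep(NA_character_, n)
  for (members in split(seq_len(n), comp)) {
    if (!is.null(graph$lengths)) {
      members_best <- members[graph$lengths[members] == max(graph$lengths[members])]
    } else members_best <- members
    rep_id <- sort(graph$ids[members_best], method = "radix")[1L]
    assignment[members] <- rep_id
  }
  clustering(structure(assignment, names = graph$ids))
}

#' Compose two clustering levels
#'
#' `inner` assigns members to representatives; `outer` re-clusters exactly
#' those representatives. The result assigns every member of `inner` to its
#' final representative in `outer`.
#'
#' @param outer a [clustering()] whose member set equals the representative
#'   set of `inner`.
#' @param inner a [clustering()].
#' @return A [clustering()] over the members of `inner`.
#' @export
compose_clusterings <- function(outer, inner) {
  inner_reps <- representatives(inner)
  if (!setequal(names(outer), inner_reps)) {
    stop("outer clustering must partition exactly the inner representatives")
  }
  out <- unclass(outer)[unclass(inner)]
  clustering(structure(unname(out), names = names(inner)))
}
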