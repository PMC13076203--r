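# shared fixture builders; everything is generated in code, no data files

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_db <- function(n, len_range = c(60L, 200L), prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  sequence_db(sprintf("%s%03d", prefix, seq_len(n)),
              vapply(lens, random_aa, character(1)))
}

# hit row with hand-set fields, for criterion/coverage unit tests
fake_hit <- function(qlen = 100L, tlen = 100L, score = 200L,
                     identities = 50L, columns = 100L,
                     qstart = 1L, qend = qlen, tstart = 1L, tend = tlen,
                     evalue = 1e-10) {
  h <- data.frame(query = "q", target = "t", qlen = qlen, tlen = tlen,
                  score = score, identities = identities, columns = columns,
                  qstart = qstart, qend = qend, tstart = tstart, tend = tend,
                  evalue = evalue, stringsAsFactors = FALSE)
  h$pident <- ifelse(h$columns > 0, h$identities / h$columns, 0)
  h$qcov <- (h$qend - h$qstart + 1) / h$qlen
  h$tcov <- (h$tend - h$tstart + 1) / h$tlen
  h
}

# random directed graph as an edge data frame over n nodes
random_graph_edges <- function(n, p = 0.03) {
  from <- integer(); to <- integer()
  for (a in seq_len(n)) {
    hits <- which(runif(n) < p)
    hits <- hits[hits != a]
    from <- c(from, rep.int(a, length(hits)))
    to <- c(to, hits)
  }
  data.frame(from = from, to = to)
}

# independent brute-force greedy vertex cover over an adjacency matrix,
# recomputing live outdegrees by full scans each iteration
brute_vertex_cover <- function(ids, edges, lengths, depth) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) adj[cbind(edges$from, edges$to)] <- TRUE
  diag(adj) <- FALSE
  live <- rep(TRUE, n)
  assignment <- rep(NA_character_, n)
  while (any(live)) {
    sub <- adj & outer(live, live, "&")
    outdeg <- rowSums(sub)
    outdeg[!live] <- -1
    mx <- max(outdeg)
    cand <- which(live & outdeg == mx)
    cand <- cand[lengths[cand] == max(lengths[cand])]
    r <- cand[order(ids[cand], method = "radix")[1]]
    cluster <- r
    frontier <- r
    for (d in seq_len(depth)) {
      nxt <- which(live & apply(sub[frontier, , drop = FALSE], 2, any))
      nxt <- setdiff(nxt, cluster)
      if (!length(nxt)) break
      cluster <- c(cluster, nxt)
      frontier <- nxt
    }
    assignment[cluster] <- ids[r]
    live[cluster] <- FALSE
  }
  structure(assignment, names = ids)
}

# union-find reference for weakly connected components
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges$from[k]); b <- find(edges$to[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# naive quadratic recomputation of the evaluation metrics
naive_eval <- function(cl, architectures, clans = character()) {
  ann <- names(architectures)
  akey <- vapply(architectures, paste, character(1), collapse = ",")
  ckey <- vapply(architectures, function(l) {
    paste(ifelse(l %in% names(clans), unname(clans[l]), l), collapse = ",")
  }, character(1))
  memb <- unclass(cl)[ann]
  sens <- prec <- numeric(length(ann))
  for (k in seq_along(ann)) {
    same_cl <- memb == memb[k]
    sens[k] <- sum(same_cl & akey == akey[k]) / sum(akey == akey[k])
    prec[k] <- sum(same_cl & ckey == ckey[k]) / sum(same_cl)
  }
  list(sens = sens, prec = prec)
}

# identity of the gap-free co-linear mapping of two equal-length strings
colinear_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}
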