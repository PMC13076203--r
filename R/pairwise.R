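#' Alignment scoring scheme
#'
#' Local alignments are scored with a substitution matrix and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_ext`). E-values are
#' computed from the Karlin-Altschul formula with the supplied `lambda` and
#' `K`; the defaults are the standard gapped constants for BLOSUM62 with
#' penalties 11/1.
#'
#' @param matrix substitution matrix name (currently only `"BLOSUM62"`).
#' @param gap_open,gap_ext non-negative integer gap penalties,
#'   `gap_ext <= gap_open`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L, gap_ext = 1L,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_ext >= 0, gap_ext <= gap_open,
            lambda > 0, K > 0)
  structure(list(matrix_name = matrix, submat = substitution_matrix(matrix),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext), lambda = lambda, K = K),
            class = "scoring_scheme")
}

# 25x25 integer matrix over AA_ALPHABET25. Entries come from the named
# Biostrings matrix where both letters are defined; U and O (absent from
# BLOSUM62) score 0 against everything.
substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.cc_env[[key]])) return(.cc_env[[key]])
  src <- get(utils::data(list = name, package = "Biostrings",
                         envir = environment()))
  m <- matrix(0L, 25L, 25L, dimnames = list(AA_ALPHABET25, AA_ALPHABET25))
  shared <- intersect(AA_ALPHABET25, rownames(src))
  m[shared, shared] <- src[shared, shared]
  storage.mode(m) <- "integer"
  .cc_env[[key]] <- m
  m
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total residue count of the database searched (here: the current
#' representative set).
#'
#' @param score raw alignment score(s).
#' @param query_length query length in residues.
#' @param db_residues total residues in the database.
#' @param scoring a [scoring_scheme()].
#' @export
evalue <- function(score, query_length, db_residues, scoring = scoring_scheme()) {
  stopifnot(all(query_length > 0), all(db_residues > 0))
  scoring$K * query_length * db_residues * exp(-scoring$lambda * score)
}

#' Clustering criterion
#'
#' The acceptance rule for a pairwise local alignment: e-value at most
#' `max_evalue`, sequence identity at least `min_id` (0 disables the identity
#' threshold, i.e. deep clustering) and alignment coverage at least `min_cov`.
#' In `"bi"` (bi-directional) mode coverage is required of both sequences; in
#' `"uni"` mode only of the member (non-representative) sequence.
#'
#' @param max_evalue e-value bound.
#' @param min_id identity fraction in `[0, 1]`.
#' @param min_cov coverage fraction in `[0, 1]`.
#' @param cov_mode `"bi"` or `"uni"`.
#' @export
cluster_criterion <- function(max_evalue = 0.001, min_id = 0, min_cov = 0.8,
                              cov_mode = c("bi", "uni")) {
  cov_mode <- match.arg(cov_mode)
  stopifnot(max_evalue >= 0, min_id >= 0, min_id <= 1,
            min_cov >= 0, min_cov <= 1)
  structure(list(max_evalue = max_evalue, min_id = min_id,
                 min_cov = min_cov, cov_mode = cov_mode),
            class = "cluster_criterion")
}

#' Align pairs of database records by Smith-Waterman
#'
#' Computes the optimal local alignment (affine gaps, full dynamic program
#' with traceback) for each query/target position pair and derives identity,
#' per-side coverage and e-value.
#'
#' @param db a [sequence_db()].
#' @param qi,ti integer record positions (recycled to common length).
#' @param scoring a [scoring_scheme()].
#' @param db_residues database size for the e-value; defaults to the total
#'   residue count of `db`.
#' @param keep_aln if `TRUE`, include the aligned strings (`qaln`, `taln`).
#' @return A data frame of alignment hits: ids, lengths, `score`,
#'   `identities`, `columns`, 1-based inclusive spans (`qstart`..`qend`,
#'   `tstart`..`tend`; `end < start` for empty score-0 alignments), `pident`,
#'   `qcov`, `tcov` and `evalue`.
#' @export
align_pairs <- function(db, qi, ti, scoring = scoring_scheme(),
                        db_residues = NULL, keep_aln = FALSE) {
  n <- max(length(qi), length(ti))
  qi <- rep_len(as.integer(qi), n); ti <- rep_len(as.integer(ti), n)
  if (is.null(db_residues)) db_residues <- sum(db$length)
  unamb <- AA_ALPHABET25 %in% AA_STANDARD
  raw <- cc_sw_batch(db$seq[qi], db$seq[ti], scoring$submat,
                     paste(AA_ALPHABET25, collapse = ""), unamb,
                     scoring$gap_open, scoring$gap_ext, keep_aln)
  hits <- data.frame(query = db$id[qi], target = db$id[ti],
                     qlen = db$length[qi], tlen = db$length[ti],
                     score = raw$score, identities = raw$identities,
                     columns = raw$columns,
                     qstart = raw$qstart, qend = raw$qend,
                     tstart = raw$tstart, tend = raw$tend,
                     stringsAsFactors = FALSE)
  hits$pident <- ifelse(hits$columns > 0, hits$identities / hits$columns, 0)
  hits$qcov <- (hits$qend - hits$qstart + 1) / hits$qlen
  hits$tcov <- (hits$tend - hits$tstart + 1) / hits$tlen
  hits$evalue <- evalue(hits$score, hits$qlen, db_residues, scoring)
  if (keep_aln) { hits$qaln <- raw$qaln; hits$taln <- raw$taln }
  hits
}

#' Align a single query/target pair
#'
#' @param query,target residue strings or single-record ids into `db`.
#' @param db optional [sequence_db()] holding the two records.
#' @inheritParams align_pairs
#' @return A one-row alignment hit data frame (see [align_pairs()]).
#' @export
local_align <- function(query, target, scoring = scoring_scheme(),
                        db = NULL, db_residues = NULL, keep_aln = FALSE) {
  if (is.null(db)) {
    stopifnot(nzchar(query), nzchar(target))
    db <- sequence_db(c("query", "target"),
                      normalize_residues(c(query, target)))
    qi <- 1L; ti <- 2L
  } else {
    qi <- match(query, db$id); ti <- match(target, db$id)
    if (anyNA(c(qi, ti))) stop("unknown sequence id")
  }
  align_pairs(db, qi, ti, scoring, db_residues, keep_aln)
}

#' Coverage of one side of an alignment hit
#'
#' The length of the range spanned by the local alignment divided by the
#' length of the respective sequence.
#'
#' @param hit alignment hit row(s) from [align_pairs()].
#' @param side `"query"` or `"target"`.
#' @export
coverage <- function(hit, side = c("query", "target")) {
  side <- match.arg(side)
  if (side == "query") hit$qcov else hit$tcov
}

#' Identity fraction of an alignment hit
#'
#' Identical aligned residue pairs divided by the number of alignment
#' columns; gap columns are included in the denominator.
#'
#' @param hit alignment hit row(s).
#' @export
identity_fraction <- function(hit) {
  if (any(hit$identities > hit$columns)) {
    stop("invalid hit: identities exceed alignment columns")
  }
  ifelse(hit$columns > 0, hit$identities / hit$columns, 0)
}

#' Does an alignment satisfy the clustering criterion?
#'
#' The hit is read in the representative-to-member direction: the query is
#' the putative representative unless `member = "query"`.
#'
#' @param hit alignment hit row(s).
#' @param criterion a [cluster_criterion()].
#' @param member which alignment side is the member (co-clustered) sequence.
#' @return Logical vector.
#' @export
passes_criterion <- function(hit, criterion, member = c("target", "query")) {
  member <- match.arg(member)
  mem_cov <- if (member == "target") hit$tcov else hit$qcov
  rep_cov <- if (member == "target") hit$qcov else hit$tcov
  ok <- hit$evalue <= criterion$max_evalue &
    identity_fraction(hit) >= criterion$min_id &
    mem_cov >= criterion$min_cov
  if (criterion$cov_mode == "bi") ok <- ok & rep_cov >= criterion$min_cov
  ok
}

#' Can two sequence lengths satisfy a coverage threshold?
#'
#' A local alignment can only cover a fraction `c` of both sequences if the
#' shorter/longer length ratio is close to `c`. `tol` shifts the threshold:
#' negative (`-epsilon`) for the permissive pruning filter used before
#' all-vs-all alignment, positive (`+delta`) for the stringent filter of the
#' linear stage.
#'
#' @param l1,l2 positive sequence lengths (vectorized).
#' @param c coverage threshold in `(0, 1]`.
#' @param tol signed tolerance added to `c`.
#' @return Logical: `min(l1,l2)/max(l1,l2) >= c + tol`.
#' @export
length_compatible <- function(l1, l2, c, tol = 0) {
  stopifnot(all(l1 >= 1), all(l2 >= 1))
  pmin(l1, l2) / pmax(l1, l2) >= c + tol
}

#' Write alignment hits as tabular output
#'
#' BLAST-like 12-column tabular layout: query, target, percent identity,
#' alignment length, mismatches, gap columns, query start/end, target
#' start/end, e-value, score. When the hits carry aligned strings (from
#' `keep_aln = TRUE`) they are appended as columns 13 and 14, the format the
#' spaced-seed learner consumes.
#'
#' @param hits data frame from [align_pairs()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  qgaps <- hits$columns - (hits$qend - hits$qstart + 1)
  tgaps <- hits$columns - (hits$tend - hits$tstart + 1)
  df <- data.frame(hits$query, hits$target, round(100 * hits$pident, 1),
                   hits$columns,
                   hits$columns - hits$identities - qgaps - tgaps,
                   qgaps + tgaps,
                   hits$qstart, hits$qend, hits$tstart, hits$tend,
                   signif(hits$evalue, 3), hits$score)
  if (!is.null(hits$qaln)) df <- cbind(df, hits$qaln, hits$taln)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
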