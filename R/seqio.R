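#' Construct a sequence database
#'
#' A `sequence_db` holds amino-acid records with stable unique ids plus an
#' index of record positions sorted by length in descending order (ties keep
#' input order), which the length-ratio pruning of bi-directional coverage
#' clustering relies on.
#'
#' @param id character vector of unique, non-empty accessions.
#' @param seq character vector of residue strings (already normalized to the
#'   25-letter alphabet; see [read_fasta()]).
#' @return An object of class `sequence_db` with elements `id`, `seq`,
#'   `length` and `by_length` (positions sorted by decreasing length).
#' @export
sequence_db <- function(id, seq) {
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq))
  if (anyNA(id) || any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[anyDuplicated(id)])
  }
  if (length(seq) && any(!nzchar(seq))) {
    stop("empty sequence for record ", id[which(!nzchar(seq))[1]])
  }
  len <- nchar(seq)
  structure(
    list(id = id, seq = seq, length = len,
         by_length = order(-len)),  # order() is stable: ties keep input order
    class = "sequence_db")
}

#' @export
length.sequence_db <- function(x) length(x$id)

#' @export
print.sequence_db <- function(x, ...) {
  cat("sequence_db with", length(x), "records")
  if (length(x)) {
    cat("; length range [", min(x$length), ", ", max(x$length), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Subset a sequence database by record position or id
#' @param db a `sequence_db`.
#' @param i integer positions or character ids.
#' @return A new `sequence_db` with the selected records, reindexed.
#' @export
db_subset <- function(db, i) {
  if (is.character(i)) i <- match(i, db$id)
  if (anyNA(i)) stop("unknown sequence id in subset")
  sequence_db(db$id[i], db$seq[i])
}

normalize_residues <- function(seq) {
  seq <- toupper(seq)
  seq <- gsub("^\\*+|\\*+$", "", seq)  # stop codons at the sequence ends
  bad <- grepl(paste0("[^", paste(AA_ALPHABET25, collapse = ""), "]"), seq)
  if (any(bad)) {
    warning(sum(bad), " record(s) contain letters outside the 25-letter ",
            "amino-acid alphabet; replaced by 'X'")
    seq[bad] <- gsub(paste0("[^", paste(AA_ALPHABET25, collapse = ""), "]"),
                     "X", seq[bad])
  }
  seq
}

#' Read protein sequences from a FASTA file
#'
#' Residues are upper-cased, `*` stop characters are stripped from the
#' sequence ends and letters outside the 25-letter amino-acid alphabet are
#' replaced by `X` with a warning.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return A [sequence_db()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) return(sequence_db(character(), character()))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(ids))) {
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty id")
  }
  if (any(!nzchar(seqs))) {
    stop("FASTA record '", ids[which(!nzchar(seqs))[1]], "' has an empty sequence")
  }
  db <- sequence_db(ids, normalize_residues(seqs))
  message("read ", length(db), " sequences from ", path)
  db
}

#' Write a sequence database to FASTA
#' @param db a `sequence_db`.
#' @param path output path.
#' @param width line width for wrapping residues.
#' @export
write_fasta <- function(db, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(db$id)) {
    writeLines(paste0(">", db$id[k]), con)
    s <- db$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Collapse exact duplicate sequences
#'
#' Records with identical residue strings are collapsed to the first-seen
#' record. Clustering operates on the deduplicated set; the duplicate map can
#' be used to re-expand a clustering to all input ids afterwards.
#'
#' @param db a `sequence_db`.
#' @return A list with `db` (deduplicated `sequence_db`) and `duplicate_map`
#'   (named character vector: removed id -> kept id).
#' @export
deduplicate <- function(db) {
  keep_pos <- !duplicated(db$seq)
  first_of <- match(db$seq, db$seq[keep_pos])
  dup <- which(!keep_pos)
  map <- structure(db$id[keep_pos][first_of[dup]], names = db$id[dup])
  list(db = sequence_db(db$id[keep_pos], db$seq[keep_pos]),
       duplicate_map = map)
}

#' Construct a clustering (member to representative assignment)
#'
#' @param assignment named character vector mapping each member id to its
#'   representative id. Every representative must map to itself and every id
#'   must appear exactly once as a member (partition property).
#' @return An object of class `clustering`.
#' @export
clustering <- function(assignment) {
  members <- names(assignment)
  if (is.null(members) || anyNA(members) || any(!nzchar(members))) {
    stop("assignment must be a fully named character vector")
  }
  if (anyDuplicated(members)) {
    stop("member listed more than once: ", members[anyDuplicated(members)])
  }
  reps <- unique(unname(assignment))
  missing_self <- setdiff(reps, members)
  if (length(missing_self)) {
    stop("representative not listed as its own member: ", missing_self[1])
  }
  if (any(assignment[reps] != reps)) {
    bad <- reps[assignment[reps] != reps][1]
    stop("representative does not map to itself: ", bad)
  }
  structure(unclass(assignment), class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("clustering of", length(x), "sequences into",
      length(unique(unname(x))), "clusters\n")
  invisible(x)
}

#' Representative ids of a clustering
#' @param cl a `clustering`.
#' @export
representatives <- function(cl) unique(unname(unclass(cl)))

#' Write / read a clustering as two-column TSV
#'
#' Column 1 is the representative id, column 2 the member id, one row per
#' member; representatives are listed as their own members. Rows are sorted
#' by representative then member so output is byte-stable.
#'
#' @param cl a `clustering`.
#' @param path output (input) path.
#' @export
write_clusters <- function(cl, path) {
  stopifnot(inherits(cl, "clustering"))
  df <- data.frame(rep = unname(unclass(cl)), member = names(cl),
                   stringsAsFactors = FALSE)
  df <- df[order(df$rep, df$member, method = "radix"), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("rep", "member"))
  if (anyDuplicated(df$member)) {
    stop("cluster file lists member '",
         df$member[anyDuplicated(df$member)], "' more than once")
  }
  cl <- clustering(structure(df$rep, names = df$member))
  message("read ", length(cl), " assignments (",
          length(representatives(cl)), " clusters) from ", path)
  cl
}

#' Read domain-architecture annotations (and an optional clan map)
#'
#' The architecture file is a two-column TSV: sequence id and a
#' comma-separated ordered list of family labels. Sequences absent from the
#' file are treated as non-annotated. The optional clan file maps family
#' labels to clan labels.
#'
#' @param path architecture TSV.
#' @param clan_path optional family-to-clan TSV.
#' @return A list with `architectures` (named list of character vectors) and
#'   `clans` (named character vector, possibly empty).
#' @export
read_annotations <- function(path, clan_path = NULL) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("id", "arch"))
  if (anyDuplicated(df$id)) {
    stop("duplicate annotation row for id '", df$id[anyDuplicated(df$id)], "'")
  }
  architectures <- strsplit(df$arch, ",", fixed = TRUE)
  names(architectures) <- df$id
  clans <- character()
  if (!is.null(clan_path)) {
    cf <- read.delim(clan_path, header = FALSE, colClasses = "character",
                     col.names = c("family", "clan"))
    if (anyDuplicated(cf$family)) {
      stop("duplicate clan row for family '",
           cf$family[anyDuplicated(cf$family)], "'")
    }
    clans <- structure(cf$clan, names = cf$family)
  }
  list(architectures = architectures, clans = clans)
}
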