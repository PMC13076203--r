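# Background amino-acid frequencies (Robinson & Robinson style composition),
# normalized to sum to one. Used for random roots and for substitutions.
BG_FREQS <- c(
  A = 0.0780, C = 0.0193, D = 0.0538, E = 0.0629, F = 0.0386,
  G = 0.0737, H = 0.0219, I = 0.0514, K = 0.0574, L = 0.0901,
  M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
  S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0133, Y = 0.0321)

random_protein <- function(len) {
  paste(sample(names(BG_FREQS), len, replace = TRUE,
               prob = BG_FREQS / sum(BG_FREQS)), collapse = "")
}

#' Specification of a synthetic protein-family dataset
#'
#' The generator emulates protein families for end-to-end testing: per
#' family a random root sequence drawn from background amino-acid
#' frequencies, members derived by point substitution to a target identity,
#' optional short indels and terminal truncations (which bound the
#' attainable coverage), plus unrelated singleton sequences. Every sequence
#' carries a ground-truth family, architecture and clan label.
#'
#' @param families number of families.
#' @param members range (min, max) of members per family; the untruncated
#'   root is member 1.
#' @param root_length range of root lengths in residues.
#' @param identity range of target identities of members to their root.
#' @param truncation range of the terminal fraction removed from a member.
#' @param indel_rate expected indel events per residue.
#' @param singletons number of unrelated background sequences appended.
#' @param multi_domain number of families whose root is a concatenation of
#'   two domains joined by a 5-residue linker (two-label architectures).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(families = 20L, members = c(10L, 10L),
                        root_length = c(120L, 400L),
                        identity = c(0.85, 0.95), truncation = c(0, 0),
                        indel_rate = 0.005, singletons = 50L,
                        multi_domain = 0L, seed = 42L) {
  stopifnot(families >= 0, all(members >= 1), all(root_length >= 20),
            all(identity > 0), all(identity <= 1),
            all(truncation >= 0), all(truncation < 1),
            indel_rate >= 0, singletons >= 0, multi_domain <= families)
  structure(list(families = as.integer(families),
                 members = as.integer(rep_len(members, 2L)),
                 root_length = as.integer(rep_len(root_length, 2L)),
                 identity = rep_len(identity, 2L),
                 truncation = rep_len(truncation, 2L),
                 indel_rate = indel_rate, singletons = as.integer(singletons),
                 multi_domain = as.integer(multi_domain),
                 seed = as.integer(seed)),
            class = "family_spec")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])
sample_irange <- function(r) {
  if (r[1] == r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' Mutate a sequence to a target identity
#'
#' Applies point substitutions at `round((1 - identity) * length)` distinct
#' positions, each replaced by a background-drawn residue different from the
#' original (so the realized co-linear identity matches the target exactly
#' before indels), then inserts or deletes short segments at the given rate.
#'
#' @param root residue string.
#' @param identity target identity of the gap-free co-linear mapping.
#' @param indel_rate expected indel events per residue (lengths geometric).
#' @return The mutated residue string.
#' @export
mutate_to_identity <- function(root, identity, indel_rate = 0) {
  stopifnot(identity > 0, identity <= 1)
  chars <- strsplit(root, "")[[1]]
  L <- length(chars)
  k <- round((1 - identity) * L)
  if (k > 0) {
    pos <- sample.int(L, k)
    for (p in pos) {
      repeat {
        r <- sample(names(BG_FREQS), 1L, prob = BG_FREQS)
        if (r != chars[p]) break
      }
      chars[p] <- r
    }
  }
  if (indel_rate > 0) {
    n_ev <- stats::rpois(1L, indel_rate * L)
    for (e in seq_len(n_ev)) {
      len <- stats::rgeom(1L, 0.5) + 1L
      at <- sample.int(length(chars), 1L)
      if (runif(1) < 0.5) {
        ins <- sample(names(BG_FREQS), len, replace = TRUE, prob = BG_FREQS)
        chars <- append(chars, ins, after = at)
      } else if (length(chars) > len + 20L) {
        chars <- chars[-(at:min(at + len - 1L, length(chars)))]
      }
    }
  }
  paste(chars, collapse = "")
}

truncate_terminal <- function(seq, fraction) {
  if (fraction <= 0) return(seq)
  L <- nchar(seq)
  cut <- round(fraction * L)
  if (cut == 0) return(seq)
  # removed residues split between the two ends at random
  from_start <- sample.int(cut + 1L, 1L) - 1L
  substr(seq, from_start + 1L, L - (cut - from_start))
}

#' Simulate synthetic protein families with ground truth
#'
#' @param spec a [family_spec()].
#' @return A list with `db` (a [sequence_db()]) and `truth`: `family`
#'   (named id -> family label), `architectures` (named list of ordered
#'   domain labels), `clans` (family -> clan) and `clustering` (the
#'   ground-truth [clustering()] with each family's root as representative).
#' @export
simulate_families <- function(spec = family_spec()) {
  set.seed(spec$seed)
  ids <- character(); seqs <- character()
  family <- character(); architectures <- list()
  clans <- character()
  for (f in seq_len(spec$families)) {
    fam <- sprintf("FAM%03d", f)
    two_domain <- f <= spec$multi_domain
    if (two_domain) {
      doms <- c(sprintf("DOMA%03d", f), sprintf("DOMB%03d", f))
      root <- paste0(random_protein(sample_irange(spec$root_length)),
                     "GGGGS",
                     random_protein(sample_irange(spec$root_length)))
      arch <- doms
      clans[doms] <- sprintf("CL%03d", f)
    } else {
      root <- random_protein(sample_irange(spec$root_length))
      arch <- fam
      clans[fam] <- sprintf("CL%03d", f)
    }
    n_mem <- sample_irange(spec$members)
    for (m in seq_len(n_mem)) {
      id <- sprintf("%s_M%02d", fam, m)
      s <- if (m == 1L) root else
        truncate_terminal(
          mutate_to_identity(root, sample_range(spec$identity),
                             spec$indel_rate),
          sample_range(spec$truncation))
      ids <- c(ids, id); seqs <- c(seqs, s)
      family[id] <- fam
      architectures[[id]] <- arch
    }
  }
  for (s in seq_len(spec$singletons)) {
    id <- sprintf("SNG%04d", s)
    fam <- sprintf("SFAM%04d", s)
    ids <- c(ids, id)
    seqs <- c(seqs, random_protein(sample_irange(spec$root_length)))
    family[id] <- fam
    architectures[[id]] <- fam
    clans[fam] <- sprintf("SCL%04d", s)
  }
  db <- sequence_db(ids, seqs)
  roots <- vapply(split(ids, family[ids]), `[[`, character(1), 1L)
  truth_cl <- clustering(structure(unname(roots[family[ids]]), names = ids))
  list(db = db,
       truth = list(family = family, architectures = architectures,
                    clans = clans, clustering = truth_cl))
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>.truth.tsv` (ground-truth clustering),
#' `<prefix>.arch.tsv` (architecture annotations) and `<prefix>.clans.tsv`.
#'
#' @param sim result of [simulate_families()].
#' @param prefix output path prefix.
#' @export
write_simulation <- function(sim, prefix) {
  write_fasta(sim$db, paste0(prefix, ".fasta"))
  write_clusters(sim$truth$clustering, paste0(prefix, ".truth.tsv"))
  arch <- vapply(sim$truth$architectures, paste, character(1), collapse = ",")
  write.table(data.frame(names(arch), unname(arch)),
              paste0(prefix, ".arch.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(sim$truth$clans), unname(sim$truth$clans)),
              paste0(prefix, ".clans.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Simulate a column-level alignment collection
#'
#' Generates pairwise alignments of same-family members with explicit
#' match/mismatch/gap columns, the training input for [learn_shapes()].
#' Both members mutate independently from a common root at the pair's
#' identity, so the column identity of the pair is approximately the squared
#' root-to-member identity.
#'
#' @param n number of alignments.
#' @param identity range of member-to-root identities.
#' @param length range of alignment lengths (columns before gaps).
#' @param gap_rate per-column probability of a gap column.
#' @param seed RNG seed.
#' @return List of alignments, each a list with `qaln` and `taln`.
#' @export
simulate_alignment_collection <- function(n, identity = c(0.7, 0.95),
                                          length = c(100L, 300L),
                                          gap_rate = 0.02, seed = 42L) {
  set.seed(seed)
  out <- vector("list", n)
  aa <- names(BG_FREQS)
  for (k in seq_len(n)) {
    L <- sample_irange(as.integer(rep_len(length, 2L)))
    t <- sample_range(rep_len(identity, 2L))
    root <- sample(aa, L, replace = TRUE, prob = BG_FREQS)
    qs <- root; ts <- root
    mut <- function(chars) {
      m <- round((1 - t) * L)
      if (m > 0) {
        pos <- sample.int(L, m)
        for (p in pos) {
          repeat { r <- sample(aa, 1L, prob = BG_FREQS); if (r != chars[p]) break }
          chars[p] <- r
        }
      }
      chars
    }
    qs <- mut(qs); ts <- mut(ts)
    if (gap_rate > 0) {
      gaps <- which(runif(L) < gap_rate)
      for (g in gaps) {
        if (runif(1) < 0.5) qs[g] <- "-" else ts[g] <- "-"
      }
    }
    out[[k]] <- list(qaln = paste(qs, collapse = ""),
                     taln = paste(ts, collapse = ""))
  }
  out
}
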