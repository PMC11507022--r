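# Pairwise percent identity, nearest-reference ranking and identity
# matrices.
#
# Convention: percent identity = 100 * matches / aligned residue pairs
# (columns where both sequences carry a residue), computed after global
# alignment with BLOSUM62, gap open 10, gap extend 1. 'X' residues never
# count as matches.

#' Percent identity between two parvalbumin sequences
#'
#' @param a,b [pvalb_seq()] records (or plain residue strings).
#' @return Object of class `pvalb_identity`: `id_a`, `id_b`,
#'   `percent_identity` (0-100), `aligned_pairs`, `matches`.
#' @examples
#' s <- pvalb_seq("s", strrep("ADKF", 27))
#' percent_identity(s, s)$percent_identity  # 100
#' @export
percent_identity <- function(a, b) {
  a <- .coerce_seq(a, "a"); b <- .coerce_seq(b, "b")
  # canonicalize the argument order so that co-optimal alignments (which
  # the traceback may resolve differently for swapped arguments on very
  # distant pairs) cannot break symmetry
  ord <- order(c(a$residues, b$residues), c(a$id, b$id))
  pair <- list(a, b)[ord]
  x <- pair[[1]]; y <- pair[[2]]
  has_x <- grepl("X", paste0(a$residues, b$residues), fixed = TRUE)
  if (!has_x) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(x$residues), Biostrings::AAString(y$residues),
      type = "global",
      substitutionMatrix = .aln_defaults$substitutionMatrix,
      gapOpening = .aln_defaults$gapOpening,
      gapExtension = .aln_defaults$gapExtension)
    cnt <- c(aligned_pairs = Biostrings::nmatch(aln) +
               Biostrings::nmismatch(aln),
             matches = Biostrings::nmatch(aln))
  } else {
    aln <- .global_align(x$residues, y$residues)
    cnt <- .aligned_counts(aln$pattern[1], aln$subject[1])
  }
  if (cnt["aligned_pairs"] == 0L) {
    stop("no aligned residue pairs between [", a$id, "] and [", b$id, "]")
  }
  structure(list(id_a = a$id, id_b = b$id,
                 percent_identity = 100 * unname(cnt["matches"]) /
                   unname(cnt["aligned_pairs"]),
                 aligned_pairs = unname(cnt["aligned_pairs"]),
                 matches = unname(cnt["matches"])),
            class = "pvalb_identity")
}

#' @export
print.pvalb_identity <- function(x, ...) {
  cat(sprintf("<pvalb_identity> %s vs %s: %.2f%% (%d/%d)\n",
              x$id_a, x$id_b, x$percent_identity, x$matches,
              x$aligned_pairs))
  invisible(x)
}

.coerce_seq <- function(x, nm) {
  if (is_pvalb_seq(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(pvalb_seq(nm, x))
  stop("expected a pvalb_seq or residue string for '", nm, "'")
}

# Vectorized percent identity of one query against many references.
# One pairwiseAlignment call; returns a named numeric vector. When no
# sequence carries an X, matches/mismatches are counted in C
# (nmatch/nmismatch, which exclude gap columns — the same convention as
# .aligned_counts); otherwise the aligned strings are walked so that X
# never counts as a match.
.identity_to_many <- function(query_residues, ref_residues) {
  stopifnot(length(ref_residues) >= 1L)
  has_x <- grepl("X", query_residues, fixed = TRUE) ||
    any(grepl("X", ref_residues, fixed = TRUE))
  if (!has_x) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(ref_residues),
      Biostrings::AAString(query_residues),
      type = "global",
      substitutionMatrix = .aln_defaults$substitutionMatrix,
      gapOpening = .aln_defaults$gapOpening,
      gapExtension = .aln_defaults$gapExtension)
    m <- Biostrings::nmatch(aln)
    mm <- Biostrings::nmismatch(aln)
    out <- 100 * m / pmax(1L, m + mm)
  } else {
    aln <- .global_align(ref_residues, query_residues)
    out <- vapply(seq_along(ref_residues), function(i) {
      cnt <- .aligned_counts(aln$pattern[i], aln$subject[i])
      100 * cnt[["matches"]] / max(1L, cnt[["aligned_pairs"]])
    }, 0)
  }
  names(out) <- names(ref_residues)
  out
}

#' Rank panel references by identity to a query
#'
#' @param query A [pvalb_seq()] record.
#' @param panel A `pvalb_panel`.
#' @param restrict_to Optional character vector of families to keep.
#' @return Data frame ordered by descending `percent_identity` (ties
#'   broken lexicographically by entry id) with columns `id`, `species`,
#'   `lineage`, `family`, `percent_identity`.
#' @export
rank_references <- function(query, panel, restrict_to = NULL) {
  stopifnot(is_pvalb_seq(query), inherits(panel, "pvalb_panel"))
  meta <- panel$metadata
  if (!is.null(restrict_to)) {
    meta <- meta[meta$family %in% restrict_to, , drop = FALSE]
    if (nrow(meta) == 0L) {
      stop("family restriction (", paste(restrict_to, collapse = ", "),
           ") leaves no panel entries")
    }
  }
  refs <- vapply(panel$entries[meta$id], function(s) s$residues, "")
  pid <- .identity_to_many(query$residues, refs)
  out <- data.frame(id = meta$id, species = meta$species,
                    lineage = meta$lineage, family = meta$family,
                    percent_identity = unname(pid),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent_identity, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All-against-all identity matrix
#'
#' Computes each of the n(n-1)/2 pairs once; the result is symmetric
#' with a diagonal of exactly 100.
#'
#' @param seqs List of [pvalb_seq()] records with unique ids.
#' @return Object of class `pvalb_identity_matrix`: list with `ids` and
#'   `values` (numeric matrix). Attribute `n_computed` records the
#'   number of pairwise computations performed.
#' @export
identity_matrix <- function(seqs) {
  stopifnot(is.list(seqs), length(seqs) >= 2L)
  ids <- vapply(seqs, function(s) s$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(seqs)
  values <- matrix(100, n, n, dimnames = list(ids, ids))
  n_computed <- 0L
  for (i in seq_len(n - 1L)) {
    res <- .identity_to_many(
      seqs[[i]]$residues,
      vapply(seqs[(i + 1L):n], function(s) s$residues, ""))
    n_computed <- n_computed + length(res)
    values[i, (i + 1L):n] <- res
    values[(i + 1L):n, i] <- res
  }
  structure(list(ids = ids, values = values),
            class = "pvalb_identity_matrix", n_computed = n_computed)
}

#' @export
print.pvalb_identity_matrix <- function(x, ...) {
  cat("<pvalb_identity_matrix> ", length(x$ids), " sequences\n", sep = "")
  print(round(x$values, 1))
  invisible(x)
}

#' Write an identity matrix as TSV
#'
#' @param im A `pvalb_identity_matrix`.
#' @param path Output path.
#' @export
write_identity_matrix <- function(im, path) {
  stopifnot(inherits(im, "pvalb_identity_matrix"))
  df <- data.frame(id = im$ids, im$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
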