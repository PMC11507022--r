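# The 109-position canonical coordinate frame and query-to-frame mapping.
#
# All diagnostic-residue positions (e.g. "position 12") refer to this
# frame, whose numbering is anchored on the carp-type pvalb4 reference
# of the bundled panel. Position 109 may be unoccupied: many
# parvalbumins are one residue shorter.

CANONICAL_LENGTH <- 109L

#' Canonical parvalbumin coordinate frame
#'
#' Returns the fixed 109-position frame with per-position helix
#' annotation (six alpha-helices A-F separated by loops; the CD and EF
#' loops carry the two functional Ca2+-binding sites).
#'
#' @param anchor_id Id of the reference sequence that defines the
#'   numbering (default: the bundled carp-type pvalb4 anchor).
#' @return A list of class `pvalb_frame` with `length`,
#'   `helix_annotation` (character vector of 109 labels) and
#'   `anchor_id`.
#' @export
canonical_frame <- function(anchor_id = "Cca_pvalb4_ChrA_syn") {
  helix <- rep("loop", CANONICAL_LENGTH)
  helix[5:17]   <- "A"
  helix[26:33]  <- "B"
  helix[40:50]  <- "C"
  helix[60:70]  <- "D"
  helix[79:89]  <- "E"
  helix[99:108] <- "F"
  structure(list(length = CANONICAL_LENGTH, helix_annotation = helix,
                 anchor_id = anchor_id),
            class = "pvalb_frame")
}

#' Map a query sequence onto the canonical frame
#'
#' Globally aligns the query against each per-family profile consensus
#' of the panel (BLOSUM62, gap open 10, gap extend 1) and takes the
#' highest-scoring profile. Canonical positions then carry the frame's
#' numbering, so the residue reported at, e.g., position 12 is
#' addressable as position 12. Insertions relative to the frame are
#' recorded but not numbered. Queries covering less than half the frame,
#' or with no positive-scoring profile alignment, are rejected as not
#' alignable as parvalbumin.
#'
#' @param query A [pvalb_seq()] record.
#' @param panel A reference panel from [load_reference_panel()] or
#'   [bundled_panel()].
#' @return An object of class `pvalb_canonical` with fields `query_id`,
#'   `residues` (character vector of length 109; `"-"` where the frame
#'   position is unoccupied), `insertions` (data frame of
#'   `after_position`, `residue`), `coverage` (fraction of the 109
#'   positions occupied), `profile_family` and `score`.
#' @export
map_to_canonical <- function(query, panel) {
  stopifnot(is_pvalb_seq(query), inherits(panel, "pvalb_panel"))
  prof_strings <- vapply(panel$profiles, function(p) p$string, "")
  # cheap score-only pass picks the profile; only that alignment is
  # materialized
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(prof_strings),
    Biostrings::AAString(query$residues),
    type = "global",
    substitutionMatrix = .aln_defaults$substitutionMatrix,
    gapOpening = .aln_defaults$gapOpening,
    gapExtension = .aln_defaults$gapExtension, scoreOnly = TRUE)
  best <- which.max(scores)
  fam <- names(panel$profiles)[best]
  aln <- .global_align(prof_strings[best], query$residues)
  aln$score <- scores
  idx <- panel$profiles[[fam]]$index
  pat <- strsplit(aln$pattern[1], "")[[1]]
  sub <- strsplit(aln$subject[1], "")[[1]]

  residues <- rep("-", CANONICAL_LENGTH)
  ins_after <- integer(0)
  ins_res <- character(0)
  k <- 0L                               # position within profile string
  last_canon <- 0L
  for (i in seq_along(pat)) {
    if (pat[i] != "-") {
      k <- k + 1L
      last_canon <- idx[k]
      if (sub[i] != "-") residues[last_canon] <- sub[i]
    } else if (sub[i] != "-") {
      ins_after <- c(ins_after, last_canon)
      ins_res <- c(ins_res, sub[i])
    }
  }
  coverage <- sum(residues != "-") / CANONICAL_LENGTH
  if (coverage < 0.5 || scores[best] <= 0) {
    stop("query [", query$id, "] is not alignable as parvalbumin ",
         "(canonical coverage ", sprintf("%.2f", coverage),
         ", alignment score ", round(scores[best]), ")")
  }
  structure(list(query_id = query$id, residues = residues,
                 insertions = data.frame(after_position = ins_after,
                                         residue = ins_res),
                 coverage = coverage, profile_family = fam,
                 score = aln$score[best]),
            class = "pvalb_canonical")
}

#' @export
print.pvalb_canonical <- function(x, ...) {
  cat("<pvalb_canonical> ", x$query_id, ": coverage ",
      sprintf("%.3f", x$coverage), ", best profile ", x$profile_family,
      ", ", nrow(x$insertions), " insertion(s)\n", sep = "")
  invisible(x)
}

#' Residue at a canonical position
#'
#' @param aln A `pvalb_canonical` mapping.
#' @param position Canonical position (1-109).
#' @return Single residue character, or `"-"` if unoccupied.
#' @export
residue_at <- function(aln, position) {
  stopifnot(inherits(aln, "pvalb_canonical"),
            position >= 1L, position <= CANONICAL_LENGTH)
  aln$residues[position]
}

# Collapse a canonical mapping back to the plain residue string
# (canonical-frame residues only, query order preserved).
canonical_string <- function(aln) {
  paste(aln$residues[aln$residues != "-"], collapse = "")
}
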