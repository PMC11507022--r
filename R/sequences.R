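# Amino-acid alphabet and the ParvalbuminSequence record.

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Small-side-chain residues
#'
#' Residue set used to evaluate "a relatively small residue" at a
#' diagnostic position (glycine, alanine, serine, cysteine, threonine).
#' @export
SMALL_RESIDUES <- c("G", "A", "S", "C", "T")

#' Construct a parvalbumin sequence record
#'
#' A validated protein sequence record. Parvalbumins are small EF-hand
#' Ca2+-buffering proteins of typically 108-109 residues; sequences far
#' outside that range are rejected.
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues Amino-acid string, upper case; the 20 standard codes
#'   plus `X` for unknown residues are accepted.
#' @param species Species (or species-like) label.
#' @param source One of `"reference"`, `"query"`, `"synthetic"`.
#' @return An object of class `pvalb_seq` with fields `id`, `species`,
#'   `residues` and `source`.
#' @examples
#' s <- pvalb_seq("q1", strrep("A", 108))
#' nchar(s$residues)
#' @export
pvalb_seq <- function(id, residues, species = NA_character_,
                      source = c("query", "reference", "synthetic")) {
  source <- match.arg(source)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("sequence id must be a non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("residues must be a single string [", id, "]")
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("empty sequence [", id, "]")
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA20, "X"))
  if (length(bad) > 0L) {
    stop("invalid residue letter(s) ", paste(unique(bad), collapse = ", "),
         " in sequence [", id, "]")
  }
  n <- nchar(residues)
  if (n < 90L || n > 130L) {
    stop("sequence [", id, "] has length ", n,
         "; parvalbumins are expected in 90-130 residues")
  }
  structure(list(id = id, species = species, residues = residues,
                 source = source),
            class = "pvalb_seq")
}

#' @export
print.pvalb_seq <- function(x, ...) {
  cat("<pvalb_seq> ", x$id, " (", nchar(x$residues), " aa, ", x$source,
      if (!is.na(x$species)) paste0(", ", x$species), ")\n", sep = "")
  invisible(x)
}

is_pvalb_seq <- function(x) inherits(x, "pvalb_seq")

as_pvalb_seq <- function(x, source = "query") {
  if (is_pvalb_seq(x)) return(x)
  stop("expected a pvalb_seq object")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @param source Source tag applied to every record.
#' @param species Optional species label applied to every record.
#' @return List of [pvalb_seq()] records, named by id.
#' @export
read_pvalb_fasta <- function(path, source = "query", species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_along(set), function(i) {
    pvalb_seq(ids[i], as.character(set[[i]]), species = species,
              source = source)
  })
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs List of [pvalb_seq()] records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pvalb_fasta <- function(seqs, path) {
  stopifnot(is.list(seqs))
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
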