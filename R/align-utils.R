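# Low-level pairwise alignment helpers (BLOSUM62, gap open 10, extend 1).
# All user-facing identity and mapping code funnels through these.

.aln_defaults <- list(substitutionMatrix = "BLOSUM62",
                      gapOpening = 10, gapExtension = 1)

# Global alignment of one or more patterns against one subject.
# Returns a list with aligned pattern/subject strings and scores.
.global_align <- function(patterns, subject) {
  pat <- Biostrings::AAStringSet(patterns)
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::AAString(subject),
    type = "global",
    substitutionMatrix = .aln_defaults$substitutionMatrix,
    gapOpening = .aln_defaults$gapOpening,
    gapExtension = .aln_defaults$gapExtension)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

# Count matches / aligned residue pairs from two aligned strings.
# Columns where either side is a gap are skipped; 'X' never matches.
.aligned_counts <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  both <- p != "-" & s != "-"
  matches <- sum(both & p == s & p != "X")
  c(aligned_pairs = sum(both), matches = matches)
}
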