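# Translated-similarity locus finder for genomic scaffolds: six-frame
# Smith-Waterman seeds against the panel's family consensuses, chained
# into collinear same-strand exon blocks.
#
# Coordinates are 0-based half-open throughout this module (BED
# convention); printing adds 1-based positions for reading.

# Deduplicated family consensuses (pvalb6/7 and pvalb8/9 share one
# consensus each and are reported as a pair label).
.scan_consensuses <- function(panel) {
  strings <- vapply(panel$profiles, function(p) p$string, "")
  out <- list()
  for (i in seq_along(strings)) {
    hit <- which(vapply(out, function(o) o$string == strings[i], TRUE))
    if (length(hit) == 1L) {
      out[[hit]]$families <- c(out[[hit]]$families, names(strings)[i])
    } else {
      out[[length(out) + 1L]] <- list(string = strings[i],
                                      families = names(strings)[i])
    }
  }
  for (i in seq_along(out)) {
    fams <- out[[i]]$families
    out[[i]]$label <- if (length(fams) == 1L) fams else
      paste0(fams[1], "/", sub("pvalb", "", fams[2]))
  }
  out
}

# Iterated local alignments of one consensus against one translated
# frame, masking each hit before realigning. Seed alignments use stiff
# gap penalties (exons diverge by substitution, not indels), which stops
# local alignments from crawling into intron sequence or bridging short
# introns.
.frame_seeds <- function(consensus, aa, score_threshold, max_iter = 8L) {
  seeds <- list()
  subject <- aa
  for (iter in seq_len(max_iter)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(consensus), Biostrings::AAString(subject),
      type = "local",
      substitutionMatrix = .aln_defaults$substitutionMatrix,
      gapOpening = 12, gapExtension = 4)
    sc <- Biostrings::score(aln)
    if (sc < score_threshold) break
    ss <- Biostrings::start(Biostrings::subject(aln))
    se <- Biostrings::end(Biostrings::subject(aln))
    sub_aln <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                        "")[[1]]
    # stops within 10 positions of a seed edge are overextension into
    # flanking (intron) sequence, not internal stops
    stops <- which(sub_aln == "*")
    internal_stop <- any(stops > 10L & stops <= length(sub_aln) - 10L)
    seeds[[length(seeds) + 1L]] <- list(
      aa_start = ss, aa_end = se,
      q_start = Biostrings::start(Biostrings::pattern(aln)),
      q_end = Biostrings::end(Biostrings::pattern(aln)),
      score = sc,
      has_stop = internal_stop)
    substr(subject, ss, se) <- strrep("X", se - ss + 1L)
  }
  seeds
}

#' Find parvalbumin gene loci on genomic scaffolds
#'
#' Translates each scaffold in all six frames, seeds local alignments of
#' every panel family consensus above `score_threshold` (BLOSUM62, gap
#' open 10, gap extend 1), and chains collinear same-strand seeds within
#' `chain_gap` nucleotides into exon-block hits. Overlapping chains are
#' merged, keeping the best-scoring family. A hit is flagged as a
#' probable pseudogene (`intact = FALSE`) when its chained translation
#' contains an internal stop or covers less than `min_coverage` of the
#' 109-position canonical frame. pvalb6/pvalb7 and pvalb8/pvalb9 share a
#' consensus and are reported as a pair label; resolving them needs the
#' region identity of the scaffold (see [assign_locus_names()]).
#'
#' @param scaffolds Path to a nucleotide FASTA, or a named character
#'   vector of scaffold sequences.
#' @param panel A `pvalb_panel`.
#' @param score_threshold Minimum seed alignment score (default 60).
#' @param chain_gap Maximum nucleotide gap between chained seeds
#'   (default 10 kb).
#' @param min_coverage Minimum canonical-frame coverage for an intact
#'   call (default 0.7).
#' @return Data frame of class `pvalb_loci`: `scaffold`, `start`, `end`
#'   (0-based half-open span), `strand`, `exon_blocks`
#'   (`"start-end,..."`, 0-based half-open), `family` (possibly a pair
#'   label), `chained_score`, `coverage`, `intact`. Empty when nothing
#'   is found.
#' @export
find_parvalbumin_loci <- function(scaffolds, panel = bundled_panel(),
                                  score_threshold = 60, chain_gap = 10000L,
                                  min_coverage = 0.7) {
  if (is.character(scaffolds) && length(scaffolds) == 1L &&
      file.exists(scaffolds)) {
    set <- Biostrings::readDNAStringSet(scaffolds)
    scaffolds <- stats::setNames(as.character(set),
                                 sub("\\s.*$", "", names(set)))
  }
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)))
  consensuses <- .scan_consensuses(panel)

  all_hits <- list()
  for (sc_name in names(scaffolds)) {
    seq_fwd <- toupper(scaffolds[[sc_name]])
    L <- nchar(seq_fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(
          seq_fwd)))
      for (frame in 1:3) {
        len <- L - frame + 1L
        len <- len - (len %% 3L)
        if (len < 60L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::subseq(Biostrings::DNAString(s), frame,
                             frame + len - 1L),
          if.fuzzy.codon = "X")))
        for (ci in seq_along(consensuses)) {
          seeds <- .frame_seeds(consensuses[[ci]]$string, aa,
                                score_threshold)
          for (sd in seeds) {
            # gene-orientation nt coordinates (0-based half-open)
            g_start <- (frame - 1L) + 3L * (sd$aa_start - 1L)
            g_end <- (frame - 1L) + 3L * sd$aa_end
            all_hits[[length(all_hits) + 1L]] <- data.frame(
              scaffold = sc_name, strand = strand, ci = ci,
              g_start = g_start, g_end = g_end,
              q_start = sd$q_start, q_end = sd$q_end,
              score = sd$score, has_stop = sd$has_stop, L = L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(all_hits) == 0L) return(.empty_loci())
  hits <- do.call(rbind, all_hits)

  chains <- list()
  for (key in unique(paste(hits$scaffold, hits$strand, hits$ci))) {
    h <- hits[paste(hits$scaffold, hits$strand, hits$ci) == key, ,
              drop = FALSE]
    h <- h[order(h$g_start), , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      if (!is.null(cur)) chains[[length(chains) + 1L]] <<- cur
    }
    for (i in seq_len(nrow(h))) {
      row <- h[i, ]
      if (is.null(cur)) { cur <- .new_chain(row); next }
      gap <- row$g_start - cur$g_end
      # seeds may overextend a little past the exon boundary, so allow
      # a modest query-coordinate overlap between chained seeds
      collinear <- row$q_start >= cur$q_end - 25L
      if (gap >= 0L && gap <= chain_gap && collinear) {
        cur$blocks <- rbind(cur$blocks, c(row$g_start, row$g_end))
        cur$g_end <- row$g_end
        cur$q_end <- max(cur$q_end, row$q_end)
        cur$q_cov <- cur$q_cov + (row$q_end - row$q_start + 1L)
        cur$score <- cur$score + row$score
        cur$has_stop <- cur$has_stop || row$has_stop
      } else {
        flush(cur); cur <- .new_chain(row)
      }
    }
    flush(cur)
  }

  loci <- do.call(rbind, lapply(chains, function(ch) {
    blocks <- ch$blocks
    if (ch$strand == "-") {
      blocks <- cbind(ch$L - blocks[, 2], ch$L - blocks[, 1])
      blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
    }
    data.frame(scaffold = ch$scaffold, start = min(blocks[, 1]),
               end = max(blocks[, 2]), strand = ch$strand,
               exon_blocks = paste(apply(blocks, 1, paste, collapse = "-"),
                                   collapse = ","),
               family = consensuses[[ch$ci]]$label,
               chained_score = ch$score,
               coverage = ch$q_cov / CANONICAL_LENGTH,
               intact = !ch$has_stop && ch$q_cov / CANONICAL_LENGTH >=
                 min_coverage,
               stringsAsFactors = FALSE)
  }))

  # Merge overlapping hits on the same scaffold+strand: keep the best.
  loci <- loci[order(loci$scaffold, loci$strand, -loci$chained_score), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(loci))) {
      if (i == j || !keep[j]) next
      same <- loci$scaffold[i] == loci$scaffold[j] &&
        loci$strand[i] == loci$strand[j]
      if (same && loci$start[j] < loci$end[i] &&
          loci$end[j] > loci$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  class(loci) <- c("pvalb_loci", "data.frame")
  loci
}

.new_chain <- function(row) {
  list(scaffold = row$scaffold, strand = row$strand, ci = row$ci,
       blocks = matrix(c(row$g_start, row$g_end), 1L),
       g_end = row$g_end, q_end = row$q_end,
       q_cov = row$q_end - row$q_start + 1L,
       score = row$score, has_stop = row$has_stop, L = row$L)
}

.empty_loci <- function() {
  out <- data.frame(scaffold = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    exon_blocks = character(0), family = character(0),
                    chained_score = numeric(0), coverage = numeric(0),
                    intact = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("pvalb_loci", "data.frame")
  out
}

#' Write locus hits as a BED-like TSV
#'
#' Columns scaffold, start, end (0-based half-open), strand, family,
#' intact, exon_blocks, chained_score.
#'
#' @param loci A `pvalb_loci` data frame.
#' @param path Output path.
#' @export
write_locus_hits <- function(loci, path) {
  df <- as.data.frame(loci)[, c("scaffold", "start", "end", "strand",
                                "family", "intact", "exon_blocks",
                                "chained_score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
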