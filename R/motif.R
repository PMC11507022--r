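# Per-position residue frequencies, information content and
# diagnostic-rule discovery/evaluation on the canonical frame.

#' Published diagnostic residues for pvalb2, pvalb3 and pvalb4
#'
#' The minimal rule set stated for distinguishing the otherwise very
#' similar Beta-2 families: pvalb4 carries the interacting (D/E)16 and
#' K19 residues; pvalb3 carries T12 and Q19; pvalb2 carries A12 and a
#' relatively small residue ([SMALL_RESIDUES]) at position 19.
#'
#' @return A `pvalb_rules` data frame (columns `group`, `position`,
#'   `residues`, `weight`).
#' @export
published_rule_set <- function() {
  new_rule_set(data.frame(
    group = c("pvalb4", "pvalb4", "pvalb3", "pvalb3", "pvalb2", "pvalb2"),
    position = c(16L, 19L, 12L, 19L, 12L, 19L),
    residues = c("DE", "K", "T", "Q", "A",
                 paste(SMALL_RESIDUES, collapse = "")),
    weight = 1, stringsAsFactors = FALSE))
}

new_rule_set <- function(df) {
  stopifnot(all(c("group", "position", "residues", "weight") %in% names(df)))
  if (nrow(df) == 0L) stop("empty diagnostic rule set")
  if (any(df$position < 1L | df$position > CANONICAL_LENGTH)) {
    stop("rule positions must lie in 1..", CANONICAL_LENGTH)
  }
  if (any(!nzchar(df$residues))) stop("rule with empty residue set")
  class(df) <- c("pvalb_rules", "data.frame")
  df
}

#' Column frequencies and information content for an aligned group
#'
#' One profile per canonical position. Gaps are excluded from the
#' frequency distribution and tracked separately; information content is
#' `log2(20)` minus the Shannon entropy of the residue distribution (no
#' small-sample correction), as in a sequence logo.
#'
#' @param group List of `pvalb_canonical` mappings (at least 2).
#' @return Data frame with one row per position: `position`,
#'   `n_sequences` (residues observed), `gap_fraction`,
#'   `information_bits`, `consensus`, and a `frequencies` list column of
#'   named numeric vectors.
#' @export
column_frequencies <- function(group) {
  if (!is.list(group) || length(group) == 0L) {
    stop("empty alignment group")
  }
  if (length(group) < 2L) stop("need at least 2 aligned sequences")
  stopifnot(all(vapply(group, inherits, TRUE, "pvalb_canonical")))
  mat <- do.call(rbind, lapply(group, function(a) a$residues))
  out <- vector("list", CANONICAL_LENGTH)
  for (p in seq_len(CANONICAL_LENGTH)) {
    col <- mat[, p]
    res <- col[col != "-" & col != "X"]
    gap_fraction <- 1 - length(res) / length(col)
    if (length(res) == 0L) {
      out[[p]] <- list(position = p, n_sequences = 0L,
                       gap_fraction = gap_fraction,
                       information_bits = NA_real_,
                       consensus = NA_character_,
                       frequencies = list(numeric(0)))
      next
    }
    freq <- table(res) / length(res)
    h <- -sum(freq * log2(freq))
    out[[p]] <- list(position = p, n_sequences = length(res),
                     gap_fraction = gap_fraction,
                     information_bits = log2(20) - h,
                     consensus = names(freq)[which.max(freq)],
                     frequencies = list(stats::setNames(as.numeric(freq),
                                                        names(freq))))
  }
  df <- data.frame(position = vapply(out, `[[`, 0L, "position"),
                   n_sequences = vapply(out, `[[`, 0L, "n_sequences"),
                   gap_fraction = vapply(out, `[[`, 0, "gap_fraction"),
                   information_bits = vapply(out, `[[`, 0, "information_bits"),
                   consensus = vapply(out, `[[`, "", "consensus"),
                   stringsAsFactors = FALSE)
  df$frequencies <- lapply(out, function(x) x$frequencies[[1]])
  df
}

# Minimal residue set covering >= `threshold` of the column frequency,
# filling by decreasing frequency (ties alphabetically).
.majority_set <- function(freq, threshold = 0.8) {
  if (length(freq) == 0L) return(character(0))
  ord <- order(-freq, names(freq))
  cum <- cumsum(freq[ord])
  k <- which(cum >= threshold - 1e-9)[1]
  if (is.na(k)) k <- length(freq)
  sort(names(freq)[ord][seq_len(k)])
}

#' Discover diagnostic positions from a labeled panel
#'
#' For each group (family or lineage) and canonical position, forms the
#' minimal residue set covering at least `threshold` of the group's
#' observed residues; a diagnostic rule is emitted where that set is
#' disjoint from every other group's set. On the bundled panel, family
#' grouping recovers the published pvalb2/pvalb3/pvalb4 rules (see
#' [published_rule_set()]).
#'
#' @param panel A `pvalb_panel`.
#' @param grouping `"family"` or `"lineage"`.
#' @param threshold Majority threshold (default 0.8).
#' @return A `pvalb_rules` data frame.
#' @export
derive_diagnostic_positions <- function(panel,
                                        grouping = c("family", "lineage"),
                                        threshold = 0.8) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(panel, "pvalb_panel"))
  labels <- if (grouping == "family") panel$metadata$family else
    panel$metadata$lineage
  keep <- names(which(table(labels) >= 2L))
  dropped <- setdiff(unique(labels), keep)
  if (length(dropped) > 0L) {
    warning("group(s) with fewer than 2 members excluded: ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least two groups with >= 2 members")

  sets <- list()  # per position: named list of group residue sets
  for (p in seq_len(CANONICAL_LENGTH)) {
    sets[[p]] <- lapply(stats::setNames(keep, keep), function(g) {
      col <- panel$canonical[panel$metadata$id[labels == g], p]
      col <- col[col != "-" & col != "X"]
      if (length(col) == 0L) return(character(0))
      .majority_set(table(col) / length(col), threshold)
    })
  }
  rows <- list()
  for (p in seq_len(CANONICAL_LENGTH)) {
    for (g in keep) {
      gs <- sets[[p]][[g]]
      if (length(gs) == 0L) next
      others <- unlist(sets[[p]][setdiff(keep, g)], use.names = FALSE)
      if (length(intersect(gs, others)) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, position = p, residues = paste(gs, collapse = ""),
          weight = 1, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("no diagnostic positions found")
  new_rule_set(do.call(rbind, rows))
}

#' Does one rule set contain another?
#'
#' TRUE when every rule of `reference` has a counterpart in `rules` for
#' the same group and position whose allowed residues are a subset of
#' the reference rule's.
#'
#' @param rules,reference `pvalb_rules` data frames.
#' @export
ruleset_contains <- function(rules, reference) {
  for (i in seq_len(nrow(reference))) {
    j <- which(rules$group == reference$group[i] &
                 rules$position == reference$position[i])
    if (length(j) == 0L) return(FALSE)
    have <- strsplit(rules$residues[j[1]], "")[[1]]
    want <- strsplit(reference$residues[i], "")[[1]]
    if (!all(have %in% want)) return(FALSE)
  }
  TRUE
}

#' Score a canonical alignment against a diagnostic rule set
#'
#' Gaps and X at a rule position count as non-matches.
#'
#' @param aln A `pvalb_canonical` mapping.
#' @param rules A `pvalb_rules` data frame.
#' @return Data frame with one row per group: `group`, `matched_rules`,
#'   `total_rules`, `weighted_score` in `[0, 1]`.
#' @export
score_against_rules <- function(aln, rules) {
  stopifnot(inherits(aln, "pvalb_canonical"))
  if (!inherits(rules, "pvalb_rules") || nrow(rules) == 0L) {
    stop("empty diagnostic rule set")
  }
  groups <- unique(rules$group)
  out <- lapply(groups, function(g) {
    r <- rules[rules$group == g, , drop = FALSE]
    ok <- vapply(seq_len(nrow(r)), function(i) {
      res <- aln$residues[r$position[i]]
      res != "-" && res != "X" &&
        res %in% strsplit(r$residues[i], "")[[1]]
    }, TRUE)
    data.frame(group = g, matched_rules = sum(ok), total_rules = nrow(r),
               weighted_score = sum(r$weight[ok]) / sum(r$weight),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a diagnostic rule set as TSV
#'
#' @param rules A `pvalb_rules` data frame.
#' @param path File path.
#' @export
write_rule_set <- function(rules, path) {
  utils::write.table(as.data.frame(rules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rule_set
#' @export
read_rule_set <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(residues = "character"))
  new_rule_set(df)
}
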