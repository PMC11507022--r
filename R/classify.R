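# The gene-identity decision procedure: lineage call, then family call
# combining synteny, diagnostic motifs and identity ranking (in that
# order of precedence), plus sliding-window hybrid-gene detection.

#' Synteny context for a query locus
#'
#' @param chromosome_label Chromosome/scaffold label, matched against
#'   the panel's ohnologous-region labels (a trailing copy digit is
#'   ignored, so `"Chr.B2"` matches region `"Chr.B"`).
#' @param neighbor_genes Optional character vector of neighboring gene
#'   symbols, matched against [region_table()] when the label is absent
#'   or unknown.
#' @param tandem_neighbors Optional ids of other parvalbumin loci on the
#'   same scaffold.
#' @return Object of class `pvalb_synteny`.
#' @export
synteny_context <- function(chromosome_label = NULL, neighbor_genes = NULL,
                            tandem_neighbors = NULL) {
  if (is.null(chromosome_label) && is.null(neighbor_genes) &&
      is.null(tandem_neighbors)) {
    stop("synteny context requires at least one populated field")
  }
  structure(list(chromosome_label = chromosome_label,
                 neighbor_genes = neighbor_genes,
                 tandem_neighbors = tandem_neighbors),
            class = "pvalb_synteny")
}

# Resolve a synteny context to an ancestral region, or NA (with a
# warning when a label was supplied but is unknown to the panel).
.synteny_region <- function(synteny) {
  if (is.null(synteny)) return(NA_character_)
  stopifnot(inherits(synteny, "pvalb_synteny"))
  region <- NA_character_
  if (!is.null(synteny$chromosome_label)) {
    region <- .label_to_region(synteny$chromosome_label)
    if (is.na(region) && is.null(synteny$neighbor_genes)) {
      warning("chromosome label '", synteny$chromosome_label,
              "' unknown to panel; falling back to motif + identity")
    }
  }
  if (is.na(region) && !is.null(synteny$neighbor_genes)) {
    rt <- region_table()
    hits <- vapply(seq_len(nrow(rt)), function(i) {
      length(intersect(strsplit(rt$neighbors[i], ",")[[1]],
                       synteny$neighbor_genes))
    }, 0L)
    if (max(hits) > 0L && sum(hits == max(hits)) == 1L) {
      region <- rt$region[which.max(hits)]
    }
  }
  region
}

# Cached rule sets derived from the bundled panel.
bundled_rules <- function() {
  if (is.null(.pkg_cache$rules_family)) {
    .pkg_cache$rules_family <-
      derive_diagnostic_positions(bundled_panel(), "family")
  }
  .pkg_cache$rules_family
}

bundled_lineage_rules <- function() {
  if (is.null(.pkg_cache$rules_lineage)) {
    .pkg_cache$rules_lineage <-
      derive_diagnostic_positions(bundled_panel(), "lineage")
  }
  .pkg_cache$rules_lineage
}

#' Classify the evolutionary lineage of a parvalbumin
#'
#' The lineage of the top-ranked reference is accepted when its identity
#' exceeds the best entry of every other lineage by at least 2
#' percentage points; otherwise the call falls back to lineage-level
#' diagnostic motifs. Confidence reflects the identity margin (capped at
#' 1 for margins of 20 points or more).
#'
#' @param query A [pvalb_seq()] record.
#' @param panel A `pvalb_panel` (default: bundled panel).
#' @return List with `lineage`, `confidence`, `margin`, `method`,
#'   `top_id`.
#' @export
classify_lineage <- function(query, panel = bundled_panel()) {
  ranking <- rank_references(query, panel)
  .classify_lineage_ranked(query, panel, ranking)
}

.classify_lineage_ranked <- function(query, panel, ranking, aln = NULL) {
  top <- ranking[1, ]
  other <- ranking[ranking$lineage != top$lineage, , drop = FALSE]
  margin <- if (nrow(other) == 0L) 100 else
    top$percent_identity - max(other$percent_identity)
  if (margin >= 2) {
    return(list(lineage = top$lineage, confidence = min(1, margin / 20),
                margin = margin, method = "identity", top_id = top$id))
  }
  if (is.null(aln)) aln <- map_to_canonical(query, panel)
  lrules <- if (identical(panel, .pkg_cache$panel)) bundled_lineage_rules()
    else derive_diagnostic_positions(panel, "lineage")
  sc <- score_against_rules(aln, lrules)
  sc <- sc[order(-sc$weighted_score, sc$group), ]
  conf <- if (nrow(sc) > 1L) sc$weighted_score[1] - sc$weighted_score[2]
    else sc$weighted_score[1]
  list(lineage = sc$group[1], confidence = max(0, min(1, conf)),
       margin = margin, method = "motif", top_id = top$id)
}

.sibling_pair <- function(fams) {
  for (pair in c(AMBIGUOUS_PAIRS, list(c("pvalb1", "pvalb4"),
                                       c("pvalb2", "pvalb3")))) {
    if (setequal(fams, pair)) return(paste(sub("pvalb", "", pair),
                                           collapse = "/"))
  }
  NULL
}

#' Full gene-identity call for a parvalbumin query
#'
#' Implements the decision procedure used to assign gene identities:
#' lineage first, then family, weighing (in order of precedence)
#' synteny, diagnostic residue motifs and nearest-reference identity.
#' Within Beta-2 the call first separates pvalb1-4 vs pvalb5 vs pvalb10,
#' then resolves within pvalb1-4. pvalb6 vs pvalb7 and pvalb8 vs pvalb9
#' carry no reliable sequence differences: without synteny these return
#' the unresolved pair (a first-class result, not an error).
#'
#' @param query A [pvalb_seq()] record.
#' @param panel A `pvalb_panel`.
#' @param rules Family-level diagnostic rules (default: derived from the
#'   panel; cached for the bundled panel).
#' @param synteny Optional [synteny_context()].
#' @return Object of class `pvalb_call`: `query_id`, `lineage`,
#'   `lineage_confidence`, `family` (possibly `"pvalbX/Y unresolved"`),
#'   `unresolved`, `confidence`, `evidence` (data frame with `source`,
#'   `statement`, `weight`, `concordant`), `coverage`.
#' @export
classify_family <- function(query, panel = bundled_panel(), rules = NULL,
                            synteny = NULL) {
  stopifnot(is_pvalb_seq(query), inherits(panel, "pvalb_panel"))
  if (is.null(rules)) {
    rules <- if (identical(panel, .pkg_cache$panel)) bundled_rules()
      else derive_diagnostic_positions(panel, "family")
  }
  aln <- map_to_canonical(query, panel)
  ranking <- rank_references(query, panel)
  lin <- .classify_lineage_ranked(query, panel, ranking, aln)

  lineage_fams <- names(FAMILY_LINEAGE)[FAMILY_LINEAGE == lin$lineage]
  candidates <- intersect(unique(ranking$family), lineage_fams)

  evidence <- list()
  syn_families <- NULL
  region <- .synteny_region(synteny)
  if (!is.na(region)) {
    rf <- intersect(.region_families(region), candidates)
    if (length(rf) == 0L) {
      warning("synteny region ", region, " carries no candidate family of ",
              "lineage ", lin$lineage, "; ignoring synteny")
    } else {
      syn_families <- rf
      candidates <- rf
      evidence$synteny <- list(
        source = "synteny",
        statement = paste0("region ", region, " restricts candidates to ",
                           paste(rf, collapse = ",")),
        weight = 1)
    }
  }

  # Motif scores over candidate families that have rules.
  sc <- score_against_rules(aln, rules)
  sc <- sc[sc$group %in% candidates, , drop = FALSE]
  motif_top <- NULL
  if (nrow(sc) > 0L) {
    sc <- sc[order(-sc$weighted_score, sc$group), , drop = FALSE]
    decisive <- sc$weighted_score[1] > 0 &&
      (nrow(sc) == 1L || sc$weighted_score[1] > sc$weighted_score[2])
    if (decisive) motif_top <- sc$group[1]
  }

  rk <- ranking[ranking$family %in% candidates, , drop = FALSE]
  id_top <- rk$family[1]
  id_margin <- {
    other <- rk[rk$family != id_top, , drop = FALSE]
    if (nrow(other) == 0L) 100 else
      rk$percent_identity[1] - max(other$percent_identity)
  }

  # Decision.
  unresolved <- FALSE
  if (length(candidates) == 1L) {
    family <- candidates
  } else if (lin$lineage %in% c("Alpha", "Oncomodulin")) {
    # Sequence cannot separate these pairs; synteny was the only route.
    family <- paste0("pvalb", .sibling_pair(candidates))
    family <- paste(family, "unresolved")
    unresolved <- TRUE
  } else if (!is.null(motif_top)) {
    family <- motif_top
  } else if (id_margin >= 2 || is.null(.sibling_pair(unique(rk$family[
    rk$percent_identity >= rk$percent_identity[1] - 2])))) {
    family <- id_top
  } else {
    near <- unique(rk$family[rk$percent_identity >=
                               rk$percent_identity[1] - 2])
    family <- paste0("pvalb", .sibling_pair(near), " unresolved")
    unresolved <- TRUE
  }

  if (!is.null(motif_top)) {
    evidence$motif <- list(
      source = "motif",
      statement = paste0("diagnostic residues best match ", motif_top),
      weight = 1)
  }
  evidence$identity <- list(
    source = "identity",
    statement = sprintf("nearest reference %s (%s, %.1f%%, margin %.1f)",
                        rk$id[1], id_top, rk$percent_identity[1], id_margin),
    weight = 1)

  ev <- do.call(rbind, lapply(evidence, function(e) {
    data.frame(source = e$source, statement = e$statement,
               weight = e$weight, stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  concord <- function(fams) {
    if (is.null(fams)) return(FALSE)
    if (unresolved) {
      pair <- strsplit(sub("pvalb([0-9]+/[0-9]+) unresolved", "\\1",
                           family), "/")[[1]]
      any(fams %in% paste0("pvalb", pair))
    } else any(fams == family)
  }
  ev$concordant <- vapply(seq_len(nrow(ev)), function(i) {
    switch(ev$source[i],
           synteny = concord(syn_families),
           motif = concord(motif_top),
           identity = concord(id_top))
  }, TRUE)
  confidence <- sum(ev$weight[ev$concordant]) / sum(ev$weight)

  structure(list(query_id = query$id, lineage = lin$lineage,
                 lineage_confidence = lin$confidence, family = family,
                 unresolved = unresolved, confidence = confidence,
                 evidence = ev, coverage = aln$coverage),
            class = "pvalb_call")
}

#' @export
print.pvalb_call <- function(x, ...) {
  cat("<pvalb_call> ", x$query_id, ": ", x$lineage, " / ", x$family,
      sprintf(" (confidence %.2f)\n", x$confidence), sep = "")
  for (i in seq_len(nrow(x$evidence))) {
    cat("  [", x$evidence$source[i], "] ", x$evidence$statement[i], "\n",
        sep = "")
  }
  invisible(x)
}

#' Detect hybrid (recombinant) parvalbumin genes
#'
#' Adjacent similar genes occasionally recombine into hybrids whose 5'
#' part resembles one family and the rest another. Sliding-window
#' identities against the two best-matching family consensuses are
#' compared along the canonical frame; a hybrid is declared when the
#' favored family switches exactly once and each segment favors its
#' family by at least `margin` identity points on average. Such a gene
#' is named after its unique (minority-span) part.
#'
#' @param query A [pvalb_seq()] record.
#' @param panel A `pvalb_panel`.
#' @param window Window width in canonical positions (>= 10, default 20).
#' @param step Window step (>= 1, default 1).
#' @param margin Required mean per-segment identity margin in points.
#' @return Object of class `pvalb_hybrid`: `query_id`, `is_hybrid`,
#'   `component_a`/`component_b` (family + span), `breakpoint`
#'   (canonical position ending the 5' component), `note`,
#'   `name_suggestion`.
#' @export
detect_hybrid <- function(query, panel = bundled_panel(), window = 20L,
                          step = 1L, margin = 5) {
  stopifnot(is_pvalb_seq(query))
  if (window < 10L) stop("window must be >= 10")
  if (step < 1L) stop("step must be >= 1")
  if (nchar(query$residues) < window) {
    stop("sequence [", query$id, "] shorter than window (", window, ")")
  }
  aln <- map_to_canonical(query, panel)

  # Full-length identity to each family consensus on the frame.
  fams <- names(panel$profiles)
  matchmat <- matrix(NA, length(fams), CANONICAL_LENGTH,
                     dimnames = list(fams, NULL))
  for (f in fams) {
    cons <- panel$profiles[[f]]$canonical
    valid <- !is.na(cons) & aln$residues != "-"
    matchmat[f, valid] <- (aln$residues == cons & aln$residues != "X")[valid]
  }
  full <- apply(matchmat, 1, function(m) 100 * mean(m, na.rm = TRUE))
  ord <- order(-full, fams)
  f1 <- fams[ord[1]]; f2 <- fams[ord[2]]

  starts <- seq(1L, CANONICAL_LENGTH - window + 1L, by = step)
  wid <- function(f, s) {
    m <- matchmat[f, s:(s + window - 1L)]
    if (all(is.na(m))) NA_real_ else 100 * mean(m, na.rm = TRUE)
  }
  id1 <- vapply(starts, function(s) wid(f1, s), 0)
  id2 <- vapply(starts, function(s) wid(f2, s), 0)
  lab <- ifelse(is.na(id1) | is.na(id2) | id1 == id2, 0L,
                ifelse(id1 > id2, 1L, 2L))
  # Carry ties forward (and backfill leading ties).
  first <- which(lab != 0L)
  no_hybrid <- function(note) {
    structure(list(query_id = query$id, is_hybrid = FALSE,
                   component_a = list(family = f1,
                                      span = c(1L, CANONICAL_LENGTH)),
                   component_b = NULL, breakpoint = NA_integer_,
                   note = note, name_suggestion = f1),
              class = "pvalb_hybrid")
  }
  if (length(first) == 0L) return(no_hybrid("no discriminating windows"))
  lab[seq_len(first[1] - 1L)] <- lab[first[1]]
  for (i in seq_along(lab)[-1]) if (lab[i] == 0L) lab[i] <- lab[i - 1L]

  switches <- which(diff(lab) != 0L)
  if (length(switches) == 0L) return(no_hybrid("single family throughout"))
  if (length(switches) > 1L) return(no_hybrid("complex mosaic"))

  sw <- switches[1]
  seg_a <- seq_len(sw); seg_b <- seq(sw + 1L, length(starts))
  d <- id1 - id2
  fam_a <- if (lab[1] == 1L) f1 else f2
  fam_b <- if (lab[1] == 1L) f2 else f1
  mean_a <- mean(if (lab[1] == 1L) d[seg_a] else -d[seg_a], na.rm = TRUE)
  mean_b <- mean(if (lab[1] == 1L) -d[seg_b] else d[seg_b], na.rm = TRUE)
  if (is.na(mean_a) || is.na(mean_b) || mean_a < margin || mean_b < margin) {
    return(no_hybrid("segment margins below threshold"))
  }
  breakpoint <- starts[sw + 1L] + as.integer(floor(window / 2)) - 1L
  span_a <- c(1L, breakpoint)
  span_b <- c(breakpoint + 1L, CANONICAL_LENGTH)
  minority <- if (diff(span_a) <= diff(span_b)) fam_a else fam_b
  structure(list(query_id = query$id, is_hybrid = TRUE,
                 component_a = list(family = fam_a, span = span_a),
                 component_b = list(family = fam_b, span = span_b),
                 breakpoint = breakpoint, note = "single breakpoint",
                 name_suggestion = minority),
            class = "pvalb_hybrid")
}

#' @export
print.pvalb_hybrid <- function(x, ...) {
  if (x$is_hybrid) {
    cat("<pvalb_hybrid> ", x$query_id, ": HYBRID ",
        x$component_a$family, "(1-", x$breakpoint, ") / ",
        x$component_b$family, "(", x$breakpoint + 1L, "-109); name by ",
        x$name_suggestion, "\n", sep = "")
  } else {
    cat("<pvalb_hybrid> ", x$query_id, ": not hybrid (", x$note, ")\n",
        sep = "")
  }
  invisible(x)
}
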