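# Synthetic sequence architecture underlying the bundled reference
# panel and all sequence generators.
#
# The architecture fixes, once, a parvalbumin-like base sequence on the
# 109-position canonical frame and partitions the frame into:
#   * 42 conserved core positions (EF-hand loops, helix anchors) shared
#     by all families;
#   * 3 diagnostic positions (12, 16, 19) with family-specific residues,
#     reproducing the published discriminating residues for pvalb2
#     (A12, small 19), pvalb3 (T12, Q19) and pvalb4 ((D/E)16, K19);
#   * 9 further positions distinguishing pvalb1-pvalb4 from each other;
#   * 26 lineage positions separating Alpha and Oncomodulin from Beta-2;
#   * two 12-position blocks separating pvalb5 and pvalb10 from
#     pvalb1-4 within Beta-2;
#   * 5 free positions.
# pvalb6/pvalb7 share one Alpha consensus and pvalb8/pvalb9 one
# Oncomodulin consensus: within these pairs real paralogs carry no
# consistent sequence differences, and only chromosome context can
# separate them. pvalb5, pvalb8 and pvalb9 are one residue shorter and
# leave canonical position 109 unoccupied.

.architecture <- function() {
  if (!is.null(.pkg_cache$arch)) return(.pkg_cache$arch)

  base <- paste0("AFAGILSDAD", "ITAALQACKA", "AGTFNHKEFF", "AKVGLSGKSA",
                 "DDIKKVFGII", "DQDKSGFIEE", "DELKLFLQNF", "KAGARALTDA",
                 "ETKAFLKAGD", "SDGDGKIGVD", "EFTALVKAA")
  stopifnot(nchar(base) == CANONICAL_LENGTH)
  base <- strsplit(base, "")[[1]]

  core <- sort(c(51, 52, 53, 55, 56, 57, 59, 60, 61, 62,
                 90, 91, 92, 93, 95, 96, 97, 98, 100, 101,
                 5, 8, 21, 30, 34, 44, 49, 63, 70, 79, 82, 99, 106, 108,
                 35, 39, 43, 72, 78, 86, 102, 107))
  stopifnot(length(core) == 42L, !anyDuplicated(core))
  diag_pos <- c(12L, 16L, 19L)
  f14o <- c(26L, 33L, 41L, 48L, 65L, 74L, 84L, 88L, 104L)
  stopifnot(!any(f14o %in% core), !any(diag_pos %in% core))
  remaining <- setdiff(seq_len(CANONICAL_LENGTH), c(core, diag_pos, f14o))
  stopifnot(length(remaining) == 55L)

  arch <- .with_seed(20240L, {
    rem <- sample(remaining)
    L_pos <- sort(rem[1:26])
    b5_pos <- sort(rem[27:38])
    b10_pos <- sort(rem[39:50])
    extra <- sort(rem[51:55])

    # Diagnostic residues at 12/16/19 (one column per group).
    diag_res <- rbind(
      pvalb1 = c("S", "A", "N"), pvalb2 = c("A", "S", "G"),
      pvalb3 = c("T", "N", "Q"), pvalb4 = c("I", "D", "K"),
      pvalb5 = c("L", "Q", "E"), pvalb10 = c("V", "H", "D"),
      Alpha = c("M", "K", "V"), Oncomodulin = c("F", "R", "L"))
    colnames(diag_res) <- as.character(diag_pos)

    pick <- function(n, exclude) sample(setdiff(AA20, exclude), n)
    f14_res <- sapply(f14o, function(p) pick(4L, base[p]))
    dimnames(f14_res) <- list(c("pvalb1", "pvalb2", "pvalb3", "pvalb4"),
                              as.character(f14o))
    lin_res <- sapply(L_pos, function(p) pick(2L, base[p]))
    dimnames(lin_res) <- list(c("Alpha", "Oncomodulin"), as.character(L_pos))
    b5_res <- vapply(b5_pos, function(p) pick(1L, base[p]), "")
    names(b5_res) <- as.character(b5_pos)
    b10_res <- vapply(b10_pos, function(p) pick(1L, base[p]), "")
    names(b10_res) <- as.character(b10_pos)

    consensus <- list()
    beta_groups <- c("pvalb1", "pvalb2", "pvalb3", "pvalb4")
    for (fam in beta_groups) {
      s <- base
      s[diag_pos] <- diag_res[fam, ]
      s[f14o] <- f14_res[fam, ]
      consensus[[fam]] <- s
    }
    s <- base; s[diag_pos] <- diag_res["pvalb5", ]
    s[b5_pos] <- b5_res; consensus$pvalb5 <- s
    s <- base; s[diag_pos] <- diag_res["pvalb10", ]
    s[b10_pos] <- b10_res; consensus$pvalb10 <- s
    s <- base; s[diag_pos] <- diag_res["Alpha", ]
    s[L_pos] <- lin_res["Alpha", ]
    consensus$pvalb6 <- s; consensus$pvalb7 <- s
    s <- base; s[diag_pos] <- diag_res["Oncomodulin", ]
    s[L_pos] <- lin_res["Oncomodulin", ]
    consensus$pvalb8 <- s; consensus$pvalb9 <- s

    # pvalb5/8/9 lack a residue at canonical position 109.
    short_families <- c("pvalb5", "pvalb8", "pvalb9")
    for (fam in short_families) consensus[[fam]] <- consensus[[fam]][1:108]

    # Positions whose residues define each family against its
    # within-lineage alternatives (preserved by the generators when
    # preserve_diagnostics = TRUE).
    rule_positions <- list(
      pvalb1 = c(diag_pos, f14o), pvalb2 = c(diag_pos, f14o),
      pvalb3 = c(diag_pos, f14o), pvalb4 = c(diag_pos, f14o),
      pvalb5 = c(diag_pos, b5_pos), pvalb10 = c(diag_pos, b10_pos),
      pvalb6 = c(diag_pos, L_pos), pvalb7 = c(diag_pos, L_pos),
      pvalb8 = c(diag_pos, L_pos), pvalb9 = c(diag_pos, L_pos))

    # Positions where, within the family's lineage group, all consensus
    # sequences agree: species-level mutations there shift identities to
    # all within-group references equally.
    safe_positions <- list()
    all55 <- sort(c(L_pos, b5_pos, b10_pos, extra))
    for (fam in beta_groups) safe_positions[[fam]] <- all55
    safe_positions$pvalb5 <- sort(c(L_pos, b10_pos, extra, f14o))
    safe_positions$pvalb10 <- sort(c(L_pos, b5_pos, extra, f14o))
    ao <- sort(c(f14o, b5_pos, b10_pos, extra))
    for (fam in c("pvalb6", "pvalb7", "pvalb8", "pvalb9")) {
      safe_positions[[fam]] <- ao
    }

    list(base = base, core = core, diag_pos = diag_pos, f14o = f14o,
         L_pos = L_pos, b5_pos = b5_pos, b10_pos = b10_pos, extra = extra,
         diag_res = diag_res, f14_res = f14_res, lin_res = lin_res,
         b5_res = b5_res, b10_res = b10_res,
         consensus = consensus, short_families = short_families,
         rule_positions = rule_positions, safe_positions = safe_positions)
  })
  .pkg_cache$arch <- arch
  arch
}

# Family consensus from the architecture, as a residue vector.
.arch_consensus <- function(family) {
  arch <- .architecture()
  cons <- arch$consensus[[family]]
  if (is.null(cons)) stop("unknown family '", family, "'")
  cons
}

# Entry roster of the bundled panel: id, species tag, family, number of
# species-level substitutions away from the family consensus.
.panel_roster <- function() {
  roster <- rbind(
    c("Dre_pvalb1_syn", "Danio_rerio_like", "pvalb1", 0),
    c("Clu_pvalb1_syn", "Clupea_harengus_like", "pvalb1", 6),
    c("Dre_pvalb2_syn", "Danio_rerio_like", "pvalb2", 0),
    c("Gmo_pvalb2_syn", "Gadus_morhua_like", "pvalb2", 6),
    c("Dre_pvalb3_syn", "Danio_rerio_like", "pvalb3", 0),
    c("Gmo_pvalb3_syn", "Gadus_morhua_like", "pvalb3", 6),
    c("Cca_pvalb4_ChrA_syn", "Cyprinus_carpio_like", "pvalb4", 0),
    c("Dre_pvalb4_syn", "Danio_rerio_like", "pvalb4", 6),
    c("Gmo_pvalb4_syn", "Gadus_morhua_like", "pvalb4", 6),
    c("Dre_pvalb5_syn", "Danio_rerio_like", "pvalb5", 0),
    c("Ola_pvalb5_syn", "Oryzias_latipes_like", "pvalb5", 6),
    c("Dre_pvalb10_syn", "Danio_rerio_like", "pvalb10", 0),
    c("Elu_pvalb10_syn", "Esox_lucius_like", "pvalb10", 6),
    c("Dre_pvalb6_syn", "Danio_rerio_like", "pvalb6", 0),
    c("Elu_pvalb6_syn", "Esox_lucius_like", "pvalb6", 6),
    c("Dre_pvalb7_syn", "Danio_rerio_like", "pvalb7", 0),
    c("Elu_pvalb7_syn", "Esox_lucius_like", "pvalb7", 6),
    c("Dre_pvalb8_syn", "Danio_rerio_like", "pvalb8", 0),
    c("Elu_pvalb8_syn", "Esox_lucius_like", "pvalb8", 6),
    c("Dre_pvalb9_syn", "Danio_rerio_like", "pvalb9", 0),
    c("Elu_pvalb9_syn", "Esox_lucius_like", "pvalb9", 6))
  data.frame(id = roster[, 1], species = roster[, 2], family = roster[, 3],
             nmut = as.integer(roster[, 4]), stringsAsFactors = FALSE)
}

# Region (chromosome) label of a family in the ancestral layout.
.family_region <- function(family) {
  rt <- region_table()
  for (i in seq_len(nrow(rt))) {
    if (family %in% strsplit(rt$families[i], ",")[[1]]) return(rt$region[i])
  }
  NA_character_
}

#' Construct the bundled synthetic reference panel in memory
#'
#' Builds the 21-entry labeled panel that the package ships in
#' `inst/extdata` (one consensus-exact exemplar per family plus mutated
#' species-like exemplars, all flagged `_syn`). Within each family the
#' species-level substitutions fall on positions where the
#' within-lineage consensus sequences agree, so family-distinctive
#' residues stay intact. Deterministic: the same panel is produced on
#' every call.
#'
#' @return A `pvalb_panel`.
#' @export
synthetic_reference_panel <- function() {
  arch <- .architecture()
  roster <- .panel_roster()
  seqs <- list()
  used <- list()
  for (fam in unique(roster$family)) used[[fam]] <- integer(0)
  for (i in seq_len(nrow(roster))) {
    fam <- roster$family[i]
    cons <- arch$consensus[[fam]]
    s <- cons
    if (roster$nmut[i] > 0L) {
      safe <- setdiff(arch$safe_positions[[fam]], used[[fam]])
      safe <- safe[safe <= length(cons)]
      mut <- .with_seed(.string_seed(roster$id[i]), {
        pos <- sort(sample(safe, roster$nmut[i]))
        res <- vapply(pos, function(p) sample(setdiff(AA20, cons[p]), 1L), "")
        list(pos = pos, res = res)
      })
      s[mut$pos] <- mut$res
      used[[fam]] <- c(used[[fam]], mut$pos)
    }
    seqs[[roster$id[i]]] <- pvalb_seq(roster$id[i],
                                      paste(s, collapse = ""),
                                      species = roster$species[i],
                                      source = "reference")
  }
  meta <- data.frame(
    id = roster$id, species = roster$species,
    lineage = unname(FAMILY_LINEAGE[roster$family]),
    family = roster$family,
    chromosome_label = vapply(roster$family, .family_region, ""),
    stringsAsFactors = FALSE)
  suppressWarnings(build_panel(seqs, meta, anchor_id = "Cca_pvalb4_ChrA_syn"))
}
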