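# WHO/IUIS allergen-code parsing/formatting, identity-threshold-based
# isoallergen/variant assignment, and gene-name construction for tandem
# duplicates, WGD copies and pseudogenes.
#
# Thresholds (read strictly): allergen variants share >90% amino-acid
# identity; isoallergens share >67% but not >90%; at exactly 67% or
# below the relationship falls outside the isoallergen range and is
# flagged for expert/clinical decision rather than auto-assigned.

ISOALLERGEN_THRESHOLD <- 67
VARIANT_THRESHOLD <- 90

#' Parse a WHO/IUIS allergen code
#'
#' Codes have the form `"Abc d N.IIVV"`: a 3-4 letter capitalized genus
#' abbreviation, a 1-2 letter species part, the allergen number, and a
#' four-digit sub-number whose first two digits identify the isoallergen
#' and last two the variant.
#'
#' @param text Code string, e.g. `"Gad m 1.0201"`.
#' @return Object of class `allergen_code` with fields `genus_abbrev`,
#'   `species_abbrev`, `allergen_number`, `isoallergen`, `variant`.
#' @examples
#' parse_allergen_code("Gad m 1.0201")
#' @export
parse_allergen_code <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  norm <- trimws(gsub("[[:space:]]+", " ", text))
  parts <- strsplit(norm, " ")[[1]]
  if (length(parts) != 3L) {
    stop("allergen code parse error in '", text,
         "': expected 'Genus species N.IIVV' (3 space-separated fields, ",
         "got ", length(parts), ")")
  }
  if (!grepl("^[A-Z][a-z]{2,3}$", parts[1])) {
    stop("allergen code parse error in '", text, "' at field 1 ('",
         parts[1], "'): genus abbreviation must be a capital letter ",
         "followed by 2-3 lower-case letters")
  }
  if (!grepl("^[a-z]{1,2}$", parts[2])) {
    stop("allergen code parse error in '", text, "' at field 2 ('",
         parts[2], "'): species part must be 1-2 lower-case letters")
  }
  if (!grepl("^[0-9]+\\.[0-9]{4}$", parts[3])) {
    stop("allergen code parse error in '", text, "' at field 3 ('",
         parts[3], "'): expected allergen number followed by a ",
         "four-digit sub-number (two isoallergen + two variant digits)")
  }
  num <- strsplit(parts[3], "\\.")[[1]]
  iso <- substr(num[2], 1, 2)
  var <- substr(num[2], 3, 4)
  if (iso == "00" || var == "00") {
    stop("allergen code parse error in '", text,
         "': isoallergen and variant digits must be 01-99")
  }
  structure(list(genus_abbrev = parts[1], species_abbrev = parts[2],
                 allergen_number = as.integer(num[1]),
                 isoallergen = iso, variant = var),
            class = "allergen_code")
}

#' Format an allergen code
#'
#' Inverse of [parse_allergen_code()] on its own output.
#'
#' @param code An `allergen_code` object.
#' @return Canonical rendering, e.g. `"Seb m 1.0201"`.
#' @export
format_allergen_code <- function(code) {
  stopifnot(inherits(code, "allergen_code"))
  sprintf("%s %s %d.%s%s", code$genus_abbrev, code$species_abbrev,
          code$allergen_number, code$isoallergen, code$variant)
}

#' @export
print.allergen_code <- function(x, ...) {
  cat("<allergen_code> ", format_allergen_code(x),
      " (isoallergen ", x$isoallergen, ", variant ", x$variant, ")\n",
      sep = "")
  invisible(x)
}

#' Relate a query sequence to an allergen catalog
#'
#' Finds the highest-identity catalog entry (the anchor) and classifies
#' the relationship by the identity thresholds: >90% identity places the
#' query at variant level within the anchor's isoallergen; >67% but not
#' >90% makes it a new isoallergen; at or below 67% the query falls
#' outside the isoallergen range and is flagged for expert/clinical
#' decision (clinical grouping may still keep it under allergen number
#' 1, as cross-reactivity between lineages exists).
#'
#' @param query A [pvalb_seq()] record.
#' @param catalog Data frame with columns `allergen_code` and `sequence`
#'   (residue strings), e.g. from [bundled_allergen_catalog()].
#' @return Object of class `catalog_relationship`: `relation` (one of
#'   `same_variant`, `new_variant_of_isoallergen`, `new_isoallergen`,
#'   `below_isoallergen_threshold`), `anchor_code`, `proposed_code`
#'   (NULL when below threshold), `supporting_identity`, `note`.
#' @export
relate_to_catalog <- function(query, catalog) {
  stopifnot(is_pvalb_seq(query), is.data.frame(catalog),
            all(c("allergen_code", "sequence") %in% names(catalog)),
            nrow(catalog) >= 1L)
  pid <- .identity_to_many(query$residues,
                           stats::setNames(catalog$sequence,
                                           catalog$allergen_code))
  ord <- order(-pid, catalog$allergen_code)
  anchor_idx <- ord[1]
  best <- pid[anchor_idx]
  anchor <- parse_allergen_code(catalog$allergen_code[anchor_idx])
  codes <- lapply(catalog$allergen_code, parse_allergen_code)
  same_allergen <- vapply(codes, function(c) {
    c$genus_abbrev == anchor$genus_abbrev &&
      c$species_abbrev == anchor$species_abbrev &&
      c$allergen_number == anchor$allergen_number
  }, TRUE)

  if (best > VARIANT_THRESHOLD) {
    if (best == 100 &&
        .identity_to_many(query$residues,
                          catalog$sequence[anchor_idx])[[1]] == 100 &&
        nchar(query$residues) == nchar(catalog$sequence[anchor_idx])) {
      relation <- "same_variant"
      proposed <- anchor
      note <- "identical to anchor entry"
    } else {
      relation <- "new_variant_of_isoallergen"
      in_iso <- same_allergen & vapply(codes, function(c) {
        c$isoallergen == anchor$isoallergen
      }, TRUE)
      next_var <- max(as.integer(vapply(codes[in_iso], `[[`, "",
                                        "variant"))) + 1L
      proposed <- anchor
      proposed$variant <- sprintf("%02d", next_var)
      note <- "shares >90% identity with anchor"
    }
  } else if (best > ISOALLERGEN_THRESHOLD) {
    relation <- "new_isoallergen"
    next_iso <- max(as.integer(vapply(codes[same_allergen], `[[`, "",
                                      "isoallergen"))) + 1L
    proposed <- anchor
    proposed$isoallergen <- sprintf("%02d", next_iso)
    proposed$variant <- "01"
    note <- "shares >67% but not >90% identity with anchor"
  } else {
    relation <- "below_isoallergen_threshold"
    proposed <- NULL
    note <- paste("at or below 67% identity to every catalog entry;",
                  "flagged for expert decision (clinical grouping may",
                  "still assign allergen number",
                  anchor$allergen_number, ")")
  }
  structure(list(relation = relation, anchor_code = anchor,
                 proposed_code = proposed,
                 supporting_identity = unname(best), note = note),
            class = "catalog_relationship")
}

#' @export
print.catalog_relationship <- function(x, ...) {
  cat("<catalog_relationship> ", x$relation, " (anchor ",
      format_allergen_code(x$anchor_code), ", identity ",
      sprintf("%.1f%%", x$supporting_identity), ")\n", sep = "")
  if (!is.null(x$proposed_code)) {
    cat("  proposed code: ", format_allergen_code(x$proposed_code), "\n",
        sep = "")
  }
  cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------
# Gene names

#' Construct a gene name record
#'
#' @param family Family (`"pvalb1"` ... `"pvalb10"`).
#' @param tandem_letter Optional `"A"`, `"B"`, ... distinguishing
#'   intra-chromosomal tandem duplicates.
#' @param chromosome_suffix Optional chromosome designation
#'   distinguishing WGD copies, rendered as `"_(Chr.X)"`.
#' @param variant_digits Optional two-digit protein-variant suffix,
#'   rendered only in protein style (`"pvalb2.01"`).
#' @param pseudogene Flag probable pseudogenes (rendered with a psi).
#' @return Object of class `gene_name`.
#' @export
gene_name <- function(family, tandem_letter = NA_character_,
                      chromosome_suffix = NA_character_,
                      variant_digits = NA_character_, pseudogene = FALSE) {
  if (!family %in% names(FAMILY_LINEAGE)) {
    stop("unknown family '", family, "'")
  }
  if (!is.na(variant_digits) && !grepl("^[0-9]{2}$", variant_digits)) {
    stop("variant_digits must be two digits")
  }
  structure(list(family = family, tandem_letter = tandem_letter,
                 chromosome_suffix = chromosome_suffix,
                 variant_digits = variant_digits, pseudogene = pseudogene),
            class = "gene_name")
}

#' Render a gene name
#'
#' Gene symbols render upper case (`PVALB2A`, `PVALB4_(Chr.B3)`,
#' `PVALB1` + psi for pseudogenes); protein names render lower case with
#' an optional dotted variant suffix (`pvalb2.01`).
#'
#' @param x A `gene_name`.
#' @param style `"gene"` or `"protein"`.
#' @export
render_gene_name <- function(x, style = c("gene", "protein")) {
  style <- match.arg(style)
  stopifnot(inherits(x, "gene_name"))
  stem <- if (style == "gene") toupper(x$family) else x$family
  if (!is.na(x$tandem_letter)) stem <- paste0(stem, x$tandem_letter)
  if (!is.na(x$chromosome_suffix)) {
    stem <- paste0(stem, "_(", x$chromosome_suffix, ")")
  }
  if (style == "protein" && !is.na(x$variant_digits)) {
    stem <- paste0(stem, ".", x$variant_digits)
  }
  if (x$pseudogene) stem <- paste0(stem, "Ψ")
  stem
}

#' Parse a rendered gene name
#'
#' Inverse of [render_gene_name()] for both styles.
#'
#' @param text Rendered name, e.g. `"PVALB2A"`, `"pvalb3_(Chr.B12)"`.
#' @return A `gene_name`.
#' @export
parse_gene_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- paste0("^(PVALB|pvalb)(10|[1-9])([A-Z]?)",
                "(?:_\\(([^)]+)\\))?",
                "(?:\\.([0-9]{2}))?",
                "(Ψ?)$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) == 0L) stop("cannot parse gene name '", text, "'")
  gene_name(family = paste0("pvalb", m[3]),
            tandem_letter = if (nzchar(m[4])) m[4] else NA_character_,
            chromosome_suffix = if (nzchar(m[5])) m[5] else NA_character_,
            variant_digits = if (nzchar(m[6])) m[6] else NA_character_,
            pseudogene = nzchar(m[7]))
}

#' @export
print.gene_name <- function(x, ...) {
  cat("<gene_name> ", render_gene_name(x, "gene"), " / ",
      render_gene_name(x, "protein"), "\n", sep = "")
  invisible(x)
}

#' Assign names to a set of parvalbumin loci
#'
#' Implements the naming conventions for duplicated genes: tandem copies
#' of one family on the same chromosome get letters A, B, ... in
#' ascending coordinate order (on the plus-strand orientation of the
#' scaffold); copies of one family on different chromosomes get the
#' chromosome designation as a suffix; a single-copy family keeps the
#' bare name. Pseudogene loci are flagged with a psi and excluded from
#' letter assignment. Naming is a pure function of the (family,
#' chromosome, coordinate) triples: input order does not matter.
#'
#' @param loci Data frame with columns `locus_id`, `family`,
#'   `chromosome_label`, `start`, `end` and optional `pseudogene`
#'   (logical, default FALSE).
#' @return The input data frame with an added `gene_name` (rendered
#'   symbol) column and a `name_obj` list column of [gene_name()]
#'   records, ordered by chromosome then start.
#' @export
assign_locus_names <- function(loci) {
  req <- c("locus_id", "family", "chromosome_label", "start", "end")
  stopifnot(is.data.frame(loci), all(req %in% names(loci)))
  if (!"pseudogene" %in% names(loci)) loci$pseudogene <- FALSE
  if (any(is.na(loci$chromosome_label) | !nzchar(loci$chromosome_label))) {
    stop("locus without chromosome/scaffold label: ",
         paste(loci$locus_id[is.na(loci$chromosome_label) |
                               !nzchar(loci$chromosome_label)],
               collapse = ", "))
  }
  bad <- setdiff(unique(loci$family), names(FAMILY_LINEAGE))
  if (length(bad) > 0L) {
    stop("loci with unresolved or unknown family: ",
         paste(bad, collapse = ", "))
  }
  loci <- loci[order(loci$chromosome_label, loci$start, loci$locus_id), ,
               drop = FALSE]
  rownames(loci) <- NULL
  names_out <- vector("list", nrow(loci))
  for (fam in unique(loci$family)) {
    rows <- which(loci$family == fam)
    intact <- rows[!loci$pseudogene[rows]]
    chroms <- unique(loci$chromosome_label[intact])
    multi_chrom <- length(chroms) > 1L
    for (ch in unique(loci$chromosome_label[rows])) {
      on_ch <- intact[loci$chromosome_label[intact] == ch]
      tandem <- length(on_ch) > 1L
      for (k in seq_along(on_ch)) {
        names_out[[on_ch[k]]] <- gene_name(
          fam,
          tandem_letter = if (tandem) LETTERS[k] else NA_character_,
          chromosome_suffix = if (multi_chrom) ch else NA_character_)
      }
    }
    for (r in rows[loci$pseudogene[rows]]) {
      names_out[[r]] <- gene_name(
        fam,
        chromosome_suffix = if (multi_chrom) loci$chromosome_label[r]
          else NA_character_,
        pseudogene = TRUE)
    }
  }
  loci$gene_name <- vapply(names_out, render_gene_name, "")
  loci$name_obj <- names_out
  loci
}
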