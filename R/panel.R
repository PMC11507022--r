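# The curated reference panel: labeled parvalbumin sequences with
# lineage/family/chromosome metadata and per-family profile consensuses
# on the canonical frame.

#' Lineage membership of the ten ancestral parvalbumin families
#'
#' Six families belong to the Beta-2 lineage (pvalb1-pvalb5 and
#' pvalb10), two to the Oncomodulin lineage (pvalb8, pvalb9) and two to
#' the Alpha lineage (pvalb6, pvalb7).
#' @export
FAMILY_LINEAGE <- c(pvalb1 = "Beta2", pvalb2 = "Beta2", pvalb3 = "Beta2",
                    pvalb4 = "Beta2", pvalb5 = "Beta2", pvalb10 = "Beta2",
                    pvalb6 = "Alpha", pvalb7 = "Alpha",
                    pvalb8 = "Oncomodulin", pvalb9 = "Oncomodulin")

#' Families that identity alone cannot separate
#'
#' Within each of these pairs the members have hardly any consistent
#' distinguishing sequence features; the chromosome (ohnologous region)
#' on which a gene sits reveals its identity.
#' @export
AMBIGUOUS_PAIRS <- list(c("pvalb6", "pvalb7"), c("pvalb8", "pvalb9"))

LINEAGES <- c("Alpha", "Oncomodulin", "Beta2")

#' Ancestral ohnologous-region table
#'
#' The teleost ancestor carried its ten parvalbumin genes on four
#' chromosomal regions produced by two rounds of whole-genome
#' duplication. The bundled (synthetic) panel labels these regions
#' `Chr.A`-`Chr.D`; the listed neighboring gene symbols are synthetic
#' placeholders used by the synteny matcher.
#'
#' @return Data frame with columns `region`, `families`
#'   (comma-separated) and `neighbors` (comma-separated gene symbols).
#' @export
region_table <- function() {
  data.frame(
    region = c("Chr.A", "Chr.B", "Chr.C", "Chr.D"),
    families = c("pvalb8,pvalb4,pvalb1,pvalb5",
                 "pvalb9,pvalb2,pvalb3",
                 "pvalb6,pvalb10",
                 "pvalb7"),
    neighbors = c("tbx15s,rbm23s", "wars2s,dhrs3s",
                  "myod1s,otogs", "sergefs,kcnc1s"),
    stringsAsFactors = FALSE)
}

# region -> character vector of families
.region_families <- function(region) {
  rt <- region_table()
  i <- match(region, rt$region)
  if (is.na(i)) return(character(0))
  strsplit(rt$families[i], ",")[[1]]
}

# Normalize a chromosome label to a region: exact match, else strip a
# trailing copy digit ("Chr.B2" -> "Chr.B").
.label_to_region <- function(label) {
  if (is.null(label) || is.na(label) || !nzchar(label)) return(NA_character_)
  rt <- region_table()
  if (label %in% rt$region) return(label)
  stripped <- sub("[0-9]+$", "", label)
  if (stripped %in% rt$region) return(stripped)
  NA_character_
}

#' Load a labeled reference panel from FASTA + metadata TSV
#'
#' @param sequences_path Protein FASTA; every record id must appear in
#'   the metadata table.
#' @param metadata_path TSV with required columns `id`, `species`,
#'   `lineage`, `family` and optional `chromosome_label`.
#' @param anchor_id Id of the entry that defines canonical numbering;
#'   defaults to the first pvalb4 entry (or the first entry).
#' @return Object of class `pvalb_panel`: `entries` (list of
#'   [pvalb_seq()] with `lineage`, `family`, `chromosome_label`),
#'   `metadata`, `frame`, `profiles` (per-family canonical consensus),
#'   `canonical` (entries x 109 residue matrix).
#' @export
load_reference_panel <- function(sequences_path, metadata_path,
                                 anchor_id = NULL) {
  seqs <- read_pvalb_fasta(sequences_path, source = "reference")
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE)
  required <- c("id", "species", "lineage", "family")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("panel metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"chromosome_label" %in% names(meta)) meta$chromosome_label <- NA
  orphans <- setdiff(names(seqs), meta$id)
  if (length(orphans) > 0L) {
    stop("FASTA record(s) absent from metadata: ",
         paste(orphans, collapse = ", "))
  }
  meta <- meta[meta$id %in% names(seqs), , drop = FALSE]
  build_panel(seqs[meta$id], meta, anchor_id = anchor_id)
}

# Assemble and validate a panel from parsed pieces.
build_panel <- function(seqs, meta, anchor_id = NULL) {
  bad_fam <- setdiff(meta$family, names(FAMILY_LINEAGE))
  if (length(bad_fam) > 0L) {
    stop("unknown family label(s): ", paste(unique(bad_fam), collapse = ", "))
  }
  expect <- unname(FAMILY_LINEAGE[meta$family])
  clash <- meta$lineage != expect
  if (any(clash)) {
    stop("lineage/family contradiction for entry ",
         paste(meta$id[clash], collapse = ", "), ": family ",
         paste(meta$family[clash], collapse = ", "), " belongs to lineage ",
         paste(expect[clash], collapse = ", "))
  }
  absent <- setdiff(names(FAMILY_LINEAGE), meta$family)
  if (length(absent) > 0L) {
    warning("panel is missing families: ", paste(absent, collapse = ", "))
  }
  for (i in seq_len(nrow(meta))) {
    s <- seqs[[meta$id[i]]]
    s$species <- meta$species[i]
    s$lineage <- meta$lineage[i]
    s$family <- meta$family[i]
    s$chromosome_label <- meta$chromosome_label[i]
    seqs[[meta$id[i]]] <- s
  }
  if (is.null(anchor_id)) {
    p4 <- meta$id[meta$family == "pvalb4"]
    anchor_id <- if (length(p4) > 0L) p4[1] else meta$id[1]
  }
  if (!anchor_id %in% names(seqs)) {
    stop("anchor id '", anchor_id, "' not among panel entries")
  }

  # Map every entry onto the anchor to obtain canonical columns.
  anchor <- seqs[[anchor_id]]$residues
  canon <- matrix("-", nrow = length(seqs), ncol = CANONICAL_LENGTH,
                  dimnames = list(names(seqs), NULL))
  aln <- .global_align(vapply(seqs, function(s) s$residues, ""), anchor)
  for (i in seq_along(seqs)) {
    pat <- strsplit(aln$pattern[i], "")[[1]]  # entry
    sub <- strsplit(aln$subject[i], "")[[1]]  # anchor
    pos <- 0L
    for (j in seq_along(sub)) {
      if (sub[j] != "-") {
        pos <- pos + 1L
        if (pos <= CANONICAL_LENGTH && pat[j] != "-") {
          canon[i, pos] <- pat[j]
        }
      }
    }
  }

  profiles <- .derive_profiles(canon, meta)
  structure(list(entries = seqs, metadata = meta,
                 frame = canonical_frame(anchor_id),
                 profiles = profiles, canonical = canon),
            class = "pvalb_panel")
}

# Per-family majority consensus over canonical columns. Ties are broken
# by the whole-panel column majority, then alphabetically.
.derive_profiles <- function(canon, meta) {
  fams <- unique(meta$family)
  profiles <- list()
  for (fam in fams) {
    rows <- canon[meta$id[meta$family == fam], , drop = FALSE]
    cons <- character(CANONICAL_LENGTH)
    for (p in seq_len(CANONICAL_LENGTH)) {
      col <- rows[, p]
      col <- col[col != "-" & col != "X"]
      if (length(col) == 0L) { cons[p] <- NA_character_; next }
      tab <- sort(table(col), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        gcol <- canon[, p]
        gcol <- gcol[gcol %in% top]
        gtab <- sort(table(gcol), decreasing = TRUE)
        gtop <- names(gtab)[gtab == max(gtab)]
        top <- sort(gtop)
      }
      cons[p] <- top[1]
    }
    occupied <- which(!is.na(cons))
    profiles[[fam]] <- list(string = paste(cons[occupied], collapse = ""),
                            index = occupied, canonical = cons)
  }
  profiles[order(match(names(profiles), names(FAMILY_LINEAGE)))]
}

#' @export
print.pvalb_panel <- function(x, ...) {
  cat("<pvalb_panel> ", length(x$entries), " entries, ",
      length(unique(x$metadata$family)), " families; anchor ",
      x$frame$anchor_id, "\n", sep = "")
  invisible(x)
}

#' Per-family consensus sequence
#'
#' @param panel A `pvalb_panel`.
#' @param family Family name (`"pvalb1"` ... `"pvalb10"`).
#' @param as Either `"string"` (collapsed) or `"canonical"` (length-109
#'   vector with `NA` at unoccupied frame positions).
#' @export
family_consensus <- function(panel, family, as = c("string", "canonical")) {
  as <- match.arg(as)
  prof <- panel$profiles[[family]]
  if (is.null(prof)) stop("panel has no profile for family '", family, "'")
  if (as == "string") prof$string else prof$canonical
}

#' Write a panel back to FASTA + metadata TSV
#'
#' Inverse of [load_reference_panel()]: reloading the two files yields
#' an equal panel.
#'
#' @param panel A `pvalb_panel`.
#' @param sequences_path,metadata_path Output paths.
#' @export
write_reference_panel <- function(panel, sequences_path, metadata_path) {
  write_pvalb_fasta(panel$entries, sequences_path)
  utils::write.table(panel$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(sequences = sequences_path, metadata = metadata_path))
}

.pkg_cache <- new.env(parent = emptyenv())

#' The bundled synthetic reference panel
#'
#' Loads (and caches) the panel shipped with the package: 21 labeled
#' synthetic exemplar sequences covering all ten families, constructed
#' by [synthetic_reference_panel()]. The exemplars are synthetic
#' stand-ins whose species tags (zebrafish-like, cod-like, carp-like,
#' pike-like, ...) indicate the role the corresponding real reference
#' would play; they are not database accessions.
#'
#' @param refresh Reload from disk even if cached.
#' @return A `pvalb_panel`.
#' @export
bundled_panel <- function(refresh = FALSE) {
  if (!refresh && !is.null(.pkg_cache$panel)) return(.pkg_cache$panel)
  fa <- system.file("extdata", "panel_synthetic.fasta", package = "pvalbid")
  tsv <- system.file("extdata", "panel_synthetic_metadata.tsv",
                     package = "pvalbid")
  if (!nzchar(fa) || !nzchar(tsv)) {
    stop("bundled panel files not found; is the package installed?")
  }
  panel <- suppressWarnings(load_reference_panel(fa, tsv))
  .pkg_cache$panel <- panel
  panel
}
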