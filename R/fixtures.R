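# Deterministic worked-example fixtures: a red-seabream-like pvalb3
# query constructed to reproduce the published identity relationships
# (~85% to the zebrafish-like pvalb3 reference vs ~82% to pvalb2), a
# chum-salmon-like pvalb2A/2B tandem pair, and the bundled allergen
# catalog mirroring the WHO/IUIS parvalbumin entries.

#' Red-seabream-like pvalb3 query
#'
#' A synthetic stand-in for the red seabream pvalb3 protein: built on
#' the pvalb3 consensus with the diagnostic residues T12 and Q19 kept
#' intact and 16 substitutions placed so that identity to the
#' zebrafish-like pvalb3 reference is ~85% and to the zebrafish-like
#' pvalb2 reference ~82% — the identity relationship that supports the
#' pvalb3 (rather than pvalb2) call. Deterministic.
#'
#' @return A [pvalb_seq()] record.
#' @export
seabream_like_pvalb3 <- function() {
  arch <- .architecture()
  s <- arch$consensus$pvalb3
  # 8 substitutions inside the pvalb2/pvalb3-distinctive positions
  # (position 16 plus the first seven family-distinctive columns),
  # never to another family's residue...
  inside <- c(16L, arch$f14o[1:7])
  # ...and 8 outside them, at positions shared by the Beta-2 consensuses.
  outside <- sort(c(arch$L_pos, arch$b5_pos, arch$b10_pos,
                    arch$extra))[1:8]
  for (p in c(inside, outside)) {
    taken <- unique(c(s[p], arch$base[p],
                      vapply(arch$consensus, function(cc)
                        if (p <= length(cc)) cc[p] else "", "")))
    s[p] <- setdiff(AA20, taken)[1]
  }
  pvalb_seq("Pma_pvalb3_like_syn", paste(s, collapse = ""),
            species = "Pagrus_major_like", source = "synthetic")
}

#' Chum-salmon-like pvalb2A/pvalb2B tandem pair
#'
#' Two synthetic stand-ins for the salmonid pvalb2A/pvalb2B tandem
#' duplicates: both carry the pvalb2 diagnostics (A12, small residue at
#' 19) and sit closer to the cod-like pvalb2 reference than to the
#' cod-like pvalb3 reference. Deterministic.
#'
#' @return Named list of two [pvalb_seq()] records (`pvalb2A`,
#'   `pvalb2B`).
#' @export
chum_like_pvalb2_pair <- function() {
  out <- lapply(c(A = 77101L, B = 77102L), function(seed) {
    simulate_family_sequence("pvalb2", target_identity = 93,
                             preserve_diagnostics = TRUE, seed = seed)$seq
  })
  out$A$id <- "Oke_pvalb2A_like_syn"
  out$B$id <- "Oke_pvalb2B_like_syn"
  out$A$species <- out$B$species <- "Oncorhynchus_keta_like"
  names(out) <- c("pvalb2A", "pvalb2B")
  out
}

# The 23 catalogued parvalbumin allergens with their gene-based names.
.table1_rows <- function() {
  rows <- rbind(
    c("Clupea harengus", "Clu h 1.0101", "pvalb3"),
    c("Clupea harengus", "Clu h 1.0201", "pvalb1"),
    c("Clupea harengus", "Clu h 1.0301", "pvalb4"),
    c("Ctenopharyngodon idella", "Cten i 1.0101", "pvalb4"),
    c("Cyprinus carpio", "Cyp c 1.0101", "pvalb3_(Chr.B12)"),
    c("Cyprinus carpio", "Cyp c 1.0201", "pvalb4_(Chr.B3)"),
    c("Gadus morhua", "Gad m 1.0101", "pvalb2.01"),
    c("Gadus morhua", "Gad m 1.0102", "pvalb2.02"),
    c("Gadus morhua", "Gad m 1.0201", "pvalb3.01"),
    c("Gadus morhua", "Gad m 1.0202", "pvalb3.02"),
    c("Lates calcarifer", "Lat c 1.0101", "pvalb3"),
    c("Lates calcarifer", "Lat c 1.0201", "pvalb4"),
    c("Lepidorhombus whiffiagonis", "Lep w 1.0101", "pvalb1"),
    c("Pangasianodon hypophthalmus", "Pan h 1.0101", "pvalb4"),
    c("Pangasianodon hypophthalmus", "Pan h 1.0201", "pvalb7"),
    c("Rastrelliger kanagurta", "Ras k 1.0101", "pvalb4"),
    c("Salmo salar", "Sal s 1.0101", "pvalb4_(Chr.3)"),
    c("Sardinops sagax", "Sar sa 1.0101", "pvalb4"),
    c("Scomber scombrus", "Sco s 1.0101", "pvalb4"),
    c("Sebastes marinus", "Seb m 1.0101", "pvalb3"),
    c("Sebastes marinus", "Seb m 1.0201", "pvalb4"),
    c("Thunnus albacares", "Thu a 1.0101", "pvalb3"),
    c("Xiphias gladius", "Xip g 1.0101", "pvalb4"))
  data.frame(species = rows[, 1], allergen_code = rows[, 2],
             gene_based_name = rows[, 3], stringsAsFactors = FALSE)
}

#' Family component of a gene-based name
#'
#' Strips tandem letters, chromosome suffixes, variant digits and
#' pseudogene flags: `"pvalb3_(Chr.B12)"` and `"pvalb2.01"` both yield
#' their bare family.
#'
#' @param name Rendered gene-based name(s).
#' @return Character vector of family names.
#' @export
gene_name_family <- function(name) {
  vapply(name, function(n) parse_gene_name(n)$family, "",
         USE.NAMES = FALSE)
}

#' Build the bundled allergen-catalog fixture in memory
#'
#' The 23 catalogued fish parvalbumin allergens with their official
#' codes and gene-based names, paired with synthetic stand-in sequences:
#' each entry is generated from its family consensus with diagnostics
#' preserved (seeded per code); the cod entries reuse the panel's
#' cod-like references, and each `.x102`/`.x202` variant differs from
#' its `.x101`/`.x201` counterpart by exactly one residue. Entries whose
#' family requires chromosome context for identification (pvalb7) carry
#' a `chromosome_label`.
#'
#' @return Data frame: `species`, `allergen_code`, `gene_based_name`,
#'   `chromosome_label`, `seq_id`, `sequence`.
#' @export
build_table1_catalog <- function() {
  rows <- .table1_rows()
  panel <- bundled_panel()
  arch <- .architecture()
  seqs <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    code <- rows$allergen_code[i]
    fam <- gene_name_family(rows$gene_based_name[i])
    if (code == "Gad m 1.0101") {
      seqs[i] <- panel$entries$Gmo_pvalb2_syn$residues
    } else if (code == "Gad m 1.0201") {
      seqs[i] <- panel$entries$Gmo_pvalb3_syn$residues
    } else if (code %in% c("Gad m 1.0102", "Gad m 1.0202")) {
      base <- if (code == "Gad m 1.0102") seqs[i - 1L] else seqs[i - 1L]
      s <- strsplit(base, "")[[1]]
      safe <- arch$safe_positions[[fam]]
      p <- safe[length(safe)]
      s[p] <- setdiff(AA20, s[p])[1]
      seqs[i] <- paste(s, collapse = "")
    } else {
      seqs[i] <- simulate_family_sequence(
        fam, target_identity = 93, preserve_diagnostics = TRUE,
        seed = .string_seed(code))$seq$residues
    }
  }
  fams <- gene_name_family(rows$gene_based_name)
  rows$chromosome_label <- ifelse(
    fams %in% unlist(AMBIGUOUS_PAIRS),
    vapply(fams, .family_region, ""), NA_character_)
  rows$seq_id <- gsub("[ .]", "_", rows$allergen_code)
  rows$sequence <- seqs
  rows
}

#' The bundled allergen catalog
#'
#' Loads (and caches) the catalog fixture shipped in `inst/extdata`
#' (synthetic stand-in sequences; see [build_table1_catalog()]).
#'
#' @param refresh Reload from disk even if cached.
#' @return Data frame as in [build_table1_catalog()].
#' @export
bundled_allergen_catalog <- function(refresh = FALSE) {
  if (!refresh && !is.null(.pkg_cache$catalog)) return(.pkg_cache$catalog)
  tsv <- system.file("extdata", "allergen_catalog_synthetic.tsv",
                     package = "pvalbid")
  fa <- system.file("extdata", "allergen_catalog_synthetic.fasta",
                    package = "pvalbid")
  if (!nzchar(tsv) || !nzchar(fa)) {
    stop("bundled allergen catalog not found; is the package installed?")
  }
  df <- utils::read.delim(tsv, sep = "\t", stringsAsFactors = FALSE)
  seqs <- read_pvalb_fasta(fa, source = "reference")
  df$sequence <- vapply(df$seq_id, function(id) seqs[[id]]$residues, "")
  .pkg_cache$catalog <- df
  df
}
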