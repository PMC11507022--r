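# Allergen-code grammar, catalog relationships and gene naming.

test_that("allergen codes parse into their components", {
  c1 <- parse_allergen_code("Gad m 1.0201")
  expect_equal(c1$genus_abbrev, "Gad")
  expect_equal(c1$species_abbrev, "m")
  expect_equal(c1$allergen_number, 1L)
  expect_equal(c1$isoallergen, "02")
  expect_equal(c1$variant, "01")

  # two-letter species part and four-letter genus part
  expect_equal(parse_allergen_code("Sar sa 1.0101")$species_abbrev, "sa")
  expect_equal(parse_allergen_code("Cten i 1.0101")$genus_abbrev, "Cten")

  expect_error(parse_allergen_code("Gad m 1.201"), "four-digit")
  expect_error(parse_allergen_code("Gad 1.0101"), "3 space-separated")
  expect_error(parse_allergen_code("gad m 1.0101"), "field 1")
  expect_error(parse_allergen_code("Gad m x.0101"), "field 3")
})

test_that("parse/format round-trips catalog codes and random codes", {
  for (code in bundled_allergen_catalog()$allergen_code) {
    expect_identical(format_allergen_code(parse_allergen_code(code)), code)
  }
  set.seed(123)
  for (i in seq_len(1000)) {
    code <- sprintf("%s%s %s %d.%02d%02d",
                    sample(LETTERS, 1),
                    paste(sample(letters, sample(2:3, 1), TRUE),
                          collapse = ""),
                    paste(sample(letters, sample(1:2, 1), TRUE),
                          collapse = ""),
                    sample(1:12, 1), sample(1:99, 1), sample(1:99, 1))
    expect_identical(format_allergen_code(parse_allergen_code(code)), code)
  }
})

test_that("catalog relationships follow the identity thresholds", {
  catalog <- bundled_allergen_catalog()[, c("allergen_code", "sequence")]
  g101 <- pvalb_seq("q", catalog$sequence[
    catalog$allergen_code == "Gad m 1.0101"])
  expect_equal(relate_to_catalog(g101, catalog)$relation, "same_variant")

  # one residue off: a new variant of the same isoallergen
  s <- strsplit(g101$residues, "")[[1]]
  s[100] <- if (s[100] == "A") "G" else "A"
  near <- pvalb_seq("near", paste(s, collapse = ""))
  rel <- relate_to_catalog(near, catalog)
  expect_equal(rel$relation, "new_variant_of_isoallergen")
  expect_equal(format_allergen_code(rel$proposed_code), "Gad m 1.0103")

  # ~80% identity: new isoallergen with the next free digits
  q80 <- simulate_family_sequence("pvalb2", 82, FALSE, 11)$seq
  rel80 <- relate_to_catalog(q80, catalog)
  expect_equal(rel80$relation, "new_isoallergen")
  expect_equal(rel80$proposed_code$isoallergen, "03")

  # an alpha-parvalbumin against a beta-2 catalog falls below 67%
  alpha <- simulate_family_sequence("pvalb7", 92, TRUE, 3)$seq
  beta_cat <- bundled_allergen_catalog()
  beta_cat <- beta_cat[beta_cat$gene_based_name != "pvalb7",
                       c("allergen_code", "sequence")]
  relA <- relate_to_catalog(alpha, beta_cat)
  expect_equal(relA$relation, "below_isoallergen_threshold")
  expect_null(relA$proposed_code)
  expect_match(relA$note, "clinical")
})

test_that("threshold boundaries are strict and match a brute-force
           oracle", {
  catalog_of <- function(seq) data.frame(allergen_code = "Syn t 1.0101",
                                         sequence = seq,
                                         stringsAsFactors = FALSE)
  oracle <- function(identity) {
    if (identity > 90) "new_variant_of_isoallergen"
    else if (identity > 67) "new_isoallergen"
    else "below_isoallergen_threshold"
  }
  # exact boundary cases on length-100 sequences: 90.0 and 67.0
  for (n_mm in c(10L, 33L)) {
    pair <- mismatch_pair(n_mm)
    rel <- relate_to_catalog(pair$b, catalog_of(pair$a$residues))
    expect_equal(rel$supporting_identity, 100 - n_mm)
    expect_equal(rel$relation, oracle(100 - n_mm))
  }
  set.seed(99)
  for (n_mm in sample(1:50, 30)) {
    pair <- mismatch_pair(n_mm)
    rel <- relate_to_catalog(pair$b, catalog_of(pair$a$residues))
    expect_equal(rel$relation, oracle(rel$supporting_identity))
  }
})

test_that("gene names render and parse in both styles", {
  g <- gene_name("pvalb2", tandem_letter = "A")
  expect_equal(render_gene_name(g), "PVALB2A")
  expect_equal(render_gene_name(g, "protein"), "pvalb2A")

  g2 <- gene_name("pvalb4", chromosome_suffix = "Chr.B3")
  expect_equal(render_gene_name(g2), "PVALB4_(Chr.B3)")

  g3 <- gene_name("pvalb2", variant_digits = "01")
  expect_equal(render_gene_name(g3, "protein"), "pvalb2.01")
  expect_equal(render_gene_name(g3, "gene"), "PVALB2")

  for (txt in c("PVALB2A", "PVALB4_(Chr.B3)", "pvalb3_(Chr.B12)",
                "pvalb2.01", "PVALB1Ψ", "PVALB10")) {
    parsed <- parse_gene_name(txt)
    style <- if (grepl("^PVALB", txt)) "gene" else "protein"
    expect_identical(render_gene_name(parsed, style), txt)
  }
  expect_error(parse_gene_name("PVALB11"), "cannot parse")
})

test_that("locus naming follows the tandem/WGD/pseudogene conventions", {
  loci <- data.frame(
    locus_id = c("l1", "l2", "l3", "l4", "l5", "l6"),
    family = c("pvalb2", "pvalb2", "pvalb4", "pvalb4", "pvalb1",
               "pvalb1"),
    chromosome_label = c("Chr.B", "Chr.B", "Chr.A3", "Chr.B3", "Chr.A",
                         "Chr.A"),
    start = c(100, 9000, 50, 60, 10, 5000),
    end = c(700, 9600, 650, 660, 610, 5400),
    pseudogene = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  named <- assign_locus_names(loci)
  nm <- stats::setNames(named$gene_name, named$locus_id)
  expect_equal(unname(nm[c("l1", "l2")]), c("PVALB2A", "PVALB2B"))
  expect_equal(unname(nm[c("l3", "l4")]),
               c("PVALB4_(Chr.A3)", "PVALB4_(Chr.B3)"))
  expect_equal(unname(nm["l5"]), "PVALB1")
  expect_equal(unname(nm["l6"]), "PVALB1Ψ")

  # permutation invariance
  shuffled <- assign_locus_names(loci[c(4, 6, 1, 5, 3, 2), ])
  expect_equal(stats::setNames(shuffled$gene_name, shuffled$locus_id)[
    names(nm)], nm)

  # a locus without a label cannot be named
  loci$chromosome_label[1] <- ""
  expect_error(assign_locus_names(loci), "without chromosome")
})
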