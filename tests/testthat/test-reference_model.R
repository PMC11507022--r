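# Reference panel loading, validation and canonical-frame mapping.

test_that("sequence records validate residues and length", {
  s <- pvalb_seq("ok", strrep("ADKF", 27))
  expect_s3_class(s, "pvalb_seq")
  expect_error(pvalb_seq("bad", "ADKF1ADKF"), "invalid residue")
  expect_error(pvalb_seq("short", "ADKF"), "length")
  expect_error(pvalb_seq("", strrep("A", 100)), "non-empty")
  # lower case is normalized, X tolerated
  expect_equal(pvalb_seq("lc", tolower(strrep("adkx", 25)))$residues,
               strrep("ADKX", 25))
})

test_that("bundled panel satisfies the lineage/family invariants", {
  expect_length(tp$entries, 21L)
  expect_setequal(unique(tp$metadata$family), names(FAMILY_LINEAGE))
  expect_identical(unname(FAMILY_LINEAGE[tp$metadata$family]),
                   tp$metadata$lineage)
  # every family has a profile on the canonical frame
  expect_setequal(names(tp$profiles), names(FAMILY_LINEAGE))
})

test_that("panel loading rejects inconsistent metadata", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "p.fasta"); tsv <- file.path(dir, "p.tsv")
  write_reference_panel(tp, fa, tsv)

  meta <- utils::read.delim(tsv)
  meta$lineage[meta$family == "pvalb8"][1] <- "Alpha"
  bad <- file.path(dir, "bad.tsv")
  utils::write.table(meta, bad, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_reference_panel(fa, bad), "lineage/family contradiction")

  meta <- utils::read.delim(tsv)
  meta$family[1] <- "pvalb99"
  utils::write.table(meta, bad, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_reference_panel(fa, bad), "unknown family")

  meta <- utils::read.delim(tsv)[-1, ]
  utils::write.table(meta, bad, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_reference_panel(fa, bad),
               "absent from metadata.*Dre_pvalb1_syn")
})

test_that("panel round-trips through FASTA + TSV", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "p.fasta"); tsv <- file.path(dir, "p.tsv")
  write_reference_panel(tp, fa, tsv)
  re <- load_reference_panel(fa, tsv)
  expect_identical(re$metadata, tp$metadata)
  expect_identical(vapply(re$entries, function(s) s$residues, ""),
                   vapply(tp$entries, function(s) s$residues, ""))
  expect_identical(re$profiles, tp$profiles)
})

test_that("anchor maps onto itself with full coverage", {
  anchor <- tp$entries[[tp$frame$anchor_id]]
  aln <- map_to_canonical(anchor, tp)
  expect_equal(aln$coverage, 1.0)
  expect_identical(canonical_string(aln), anchor$residues)
  expect_equal(nrow(aln$insertions), 0L)
})

test_that("a 108-residue reference lacks position 109", {
  short <- tp$entries$Dre_pvalb5_syn
  expect_equal(nchar(short$residues), 108L)
  aln <- map_to_canonical(short, tp)
  expect_equal(aln$coverage, 108 / 109)
  expect_identical(residue_at(aln, 109L), "-")
})

test_that("mapping recovers planted diagnostic residues and is idempotent", {
  sim <- simulate_family_sequence("pvalb2", 90, TRUE, seed = 21)
  aln <- map_to_canonical(sim$seq, tp)
  expect_identical(residue_at(aln, 12L), "A")
  # remap of the canonicalized residues changes nothing
  re <- map_to_canonical(pvalb_seq("re", canonical_string(aln)), tp)
  expect_identical(re$residues, aln$residues)
})

test_that("diagnostic residues of panel entries match family expectations", {
  pub <- published_rule_set()
  for (i in seq_len(nrow(pub))) {
    fam <- pub$group[i]
    allowed <- strsplit(pub$residues[i], "")[[1]]
    ids <- tp$metadata$id[tp$metadata$family == fam]
    expect_true(all(tp$canonical[ids, pub$position[i]] %in% allowed),
                label = paste(fam, "position", pub$position[i]))
  }
})

test_that("unalignable queries are rejected", {
  junk <- pvalb_seq("junk", strrep("W", 100))
  expect_error(map_to_canonical(junk, tp), "not alignable")
})

test_that("the in-memory synthetic panel equals the shipped fixture", {
  mem <- synthetic_reference_panel()
  expect_identical(vapply(mem$entries, function(s) s$residues, ""),
                   vapply(tp$entries, function(s) s$residues, ""))
  expect_identical(mem$metadata, tp$metadata)
})
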