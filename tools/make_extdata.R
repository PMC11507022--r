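# Regenerates the bundled plain-text fixtures in inst/extdata from the
# deterministic in-package builders. Run from the package root:
#   Rscript tools/make_extdata.R
suppressMessages(devtools::load_all(".", quiet = TRUE))

panel <- synthetic_reference_panel()
write_reference_panel(panel,
                      "inst/extdata/panel_synthetic.fasta",
                      "inst/extdata/panel_synthetic_metadata.tsv")

catalog <- build_table1_catalog()
seqs <- lapply(seq_len(nrow(catalog)), function(i)
  pvalb_seq(catalog$seq_id[i], catalog$sequence[i],
            species = catalog$species[i], source = "reference"))
write_pvalb_fasta(seqs, "inst/extdata/allergen_catalog_synthetic.fasta")
utils::write.table(
  catalog[, c("species", "allergen_code", "gene_based_name",
              "chromosome_label", "seq_id")],
  "inst/extdata/allergen_catalog_synthetic.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(catalog), "catalog entries and",
    length(panel$entries), "panel entries\n")
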