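# Generator contracts: determinism, identity targets, preserved
# diagnostics, genome layouts and catalog identity structure.

test_that("family-sequence generator hits its identity target", {
  for (target in c(100, 90, 85, 70)) {
    sim <- simulate_family_sequence("pvalb3", target, TRUE, seed = 7)
    cons <- pvalb_seq("cons", family_consensus(tp, "pvalb3"))
    realized <- percent_identity(sim$seq, cons)$percent_identity
    expect_lte(abs(realized - target), 2)
  }
  exact <- simulate_family_sequence("pvalb4", 100, TRUE, 1)
  expect_identical(exact$seq$residues, family_consensus(tp, "pvalb4"))
  expect_error(simulate_family_sequence("pvalb4", 45, TRUE, 1),
               "target_identity")
})

test_that("generators are pure functions of their seed", {
  a <- simulate_family_sequence("pvalb3", 90, TRUE, 7)
  b <- simulate_family_sequence("pvalb3", 90, TRUE, 7)
  expect_identical(a$seq$residues, b$seq$residues)
  expect_identical(a$truth, b$truth)
  c <- simulate_family_sequence("pvalb3", 90, TRUE, 8)
  expect_false(identical(a$seq$residues, c$seq$residues))
  # the global RNG stream is left untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_family_sequence("pvalb1", 90, TRUE, 3))
  expect_identical(runif(1), x1)
})

test_that("preserve_diagnostics keeps the diagnostic residues intact", {
  sim <- simulate_family_sequence("pvalb3", 85, TRUE, seed = 70)
  aln <- map_to_canonical(sim$seq, tp)
  expect_identical(residue_at(aln, 12L), "T")
  expect_identical(residue_at(aln, 19L), "Q")
})

test_that("genome simulation records a faithful truth table", {
  plan <- plan_chum_like(202)
  sim <- simulate_genome(plan)
  expect_equal(nrow(sim$truth), 15L)
  expect_equal(sum(sim$truth$intact), 13L)
  expect_equal(sum(!sim$truth$intact), 2L)
  expect_setequal(sim$truth$family[!sim$truth$intact],
                  c("pvalb1", "pvalb10"))
  # the pvalb2A/2B tandem pair sits on one scaffold
  b1 <- sim$truth[sim$truth$scaffold == "cs_scaffold_B1", ]
  expect_equal(sum(b1$family == "pvalb2"), 2L)

  # intact genes are embedded as two exon blocks; pseudogenes as one
  n_blocks <- lengths(strsplit(sim$truth$exon_blocks, ","))
  expect_true(all(n_blocks[sim$truth$intact] == 2L))
  expect_true(all(n_blocks[!sim$truth$intact] == 1L))

  # determinism and the empty plan
  again <- simulate_genome(plan)
  expect_identical(sim$scaffolds, again$scaffolds)
  empty <- simulate_genome(genome_plan(list(), seed = 1))
  expect_length(empty$scaffolds, 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("an embedded gene translates back to its protein", {
  plan <- plan_seabream_like(55)
  sim <- simulate_genome(plan)
  row <- sim$truth[sim$truth$family == "pvalb3", ]
  blocks <- strsplit(row$exon_blocks, ",")[[1]]
  sc <- sim$scaffolds[[row$scaffold]]
  cds <- paste(vapply(blocks, function(b) {
    be <- as.integer(strsplit(b, "-")[[1]])
    substr(sc, be[1] + 1L, be[2])
  }, ""), collapse = "")
  if (row$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  expect_match(aa, "\\*$")
  prot <- sub("\\*$", "", aa)
  aln <- map_to_canonical(pvalb_seq("reborn", prot), tp)
  expect_identical(residue_at(aln, 12L), "T")
})

test_that("overlapping planned loci are rejected", {
  plan <- genome_plan(list(list(
    name = "s1", chromosome_label = "Chr.A",
    genes = list(list(family = "pvalb4", start = 2000),
                 list(family = "pvalb1", start = 2100)))), seed = 1)
  expect_error(simulate_genome(plan), "overlapping")
})

test_that("simulated allergen catalogs realize the planted identity
           bands", {
  sim <- simulate_allergen_catalog(2, 2, seed = 1)
  expect_equal(nrow(sim$catalog), 4L)
  seqs <- lapply(seq_len(nrow(sim$catalog)), function(i)
    pvalb_seq(sim$catalog$allergen_code[i], sim$catalog$sequence[i]))
  im <- identity_matrix(seqs)
  iso <- sim$catalog$isoallergen
  for (i in 1:3) for (j in (i + 1):4) {
    v <- im$values[i, j]
    if (iso[i] == iso[j]) expect_gt(v, 90)
    else { expect_gt(v, 67); expect_lt(v, 90) }
  }
  # relate_to_catalog reproduces the planted structure
  rel <- relate_to_catalog(seqs[[2]],
                           sim$catalog[-2, c("allergen_code", "sequence")])
  expect_equal(rel$relation, "new_variant_of_isoallergen")
  expect_equal(rel$anchor_code$isoallergen, "01")
  expect_error(simulate_allergen_catalog(20, 1, 1), "infeasible")
  single <- simulate_allergen_catalog(1, 1, 1)
  q <- pvalb_seq("q", single$catalog$sequence[1])
  expect_equal(relate_to_catalog(q, single$catalog)$relation,
               "same_variant")
})
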