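# Lineage and family calls, synteny resolution, evidence, and hybrid
# detection.

test_that("lineage calls separate the three ancient lineages", {
  onco <- pvalb_seq("onco_copy", tp$entries$Dre_pvalb8_syn$residues)
  lin <- classify_lineage(onco, tp)
  expect_equal(lin$lineage, "Oncomodulin")
  expect_equal(lin$confidence, 1.0)

  alpha <- simulate_family_sequence("pvalb7", 90, TRUE, 3)$seq
  expect_equal(classify_lineage(alpha, tp)$lineage, "Alpha")
  beta <- simulate_family_sequence("pvalb2", 90, TRUE, 3)$seq
  expect_equal(classify_lineage(beta, tp)$lineage, "Beta2")
})

test_that("the seabream-style pvalb3 call is supported by motif and
           identity evidence", {
  q <- seabream_like_pvalb3()
  aln <- map_to_canonical(q, tp)
  expect_identical(residue_at(aln, 12L), "T")
  expect_identical(residue_at(aln, 19L), "Q")
  call <- classify_family(q, tp, tp_rules)
  expect_equal(call$family, "pvalb3")
  expect_setequal(call$evidence$source, c("motif", "identity"))
  expect_true(all(call$evidence$concordant))
  # nearest pvalb3 reference beats every pvalb2 reference
  rk <- rank_references(q, tp, restrict_to = c("pvalb2", "pvalb3"))
  expect_equal(rk$family[1], "pvalb3")
})

test_that("the chum-salmon-style tandem pair is called pvalb2", {
  pair <- chum_like_pvalb2_pair()
  for (q in pair) {
    aln <- map_to_canonical(q, tp)
    expect_identical(residue_at(aln, 12L), "A")
    expect_true(residue_at(aln, 19L) %in% SMALL_RESIDUES)
    call <- classify_family(q, tp, tp_rules)
    expect_equal(call$family, "pvalb2")
  }
  # on average closer to cod-like pvalb2 than cod-like pvalb3
  mean_id <- function(ref) mean(vapply(pair, function(q)
    percent_identity(q, tp$entries[[ref]])$percent_identity, 0))
  expect_gt(mean_id("Gmo_pvalb2_syn"), mean_id("Gmo_pvalb3_syn"))
})

test_that("pvalb6/7 and pvalb8/9 need synteny and never guess wrong", {
  for (fam in c("pvalb6", "pvalb7", "pvalb8", "pvalb9")) {
    sim <- simulate_family_sequence(fam, 90, TRUE, seed = 17)
    bare <- classify_family(sim$seq, tp, tp_rules)
    expect_true(bare$unresolved)
    expect_match(bare$family, "unresolved")
    with_syn <- classify_family(
      sim$seq, tp, tp_rules,
      synteny = synteny_context(chromosome_label = sim$truth$region))
    expect_equal(with_syn$family, fam)
    expect_false(with_syn$unresolved)
  }
})

test_that("neighbor genes can stand in for a chromosome label", {
  sim <- simulate_family_sequence("pvalb7", 90, TRUE, seed = 4)
  rt <- region_table()
  neigh <- strsplit(rt$neighbors[rt$region == "Chr.D"], ",")[[1]]
  call <- classify_family(sim$seq, tp, tp_rules,
                          synteny = synteny_context(neighbor_genes = neigh))
  expect_equal(call$family, "pvalb7")
})

test_that("an unknown chromosome label warns and falls back", {
  sim <- simulate_family_sequence("pvalb3", 90, TRUE, seed = 6)
  expect_warning(
    call <- classify_family(sim$seq, tp, tp_rules,
                            synteny = synteny_context(
                              chromosome_label = "scaffold_unplaced_77")),
    "unknown to panel")
  expect_equal(call$family, "pvalb3")
})

test_that("calls are deterministic and lineage-consistent", {
  sim <- simulate_family_sequence("pvalb10", 88, TRUE, seed = 12)
  c1 <- classify_family(sim$seq, tp, tp_rules)
  c2 <- classify_family(sim$seq, tp, tp_rules)
  expect_identical(c1$evidence, c2$evidence)
  expect_identical(c1$family, c2$family)
  expect_equal(unname(FAMILY_LINEAGE[c1$family]), c1$lineage)
})

test_that("confidence never increases under cumulative mutation", {
  arch <- pvalbid:::.architecture()
  cons <- arch$consensus$pvalb3
  set.seed(7)
  cand <- setdiff(seq_along(cons), arch$rule_positions$pvalb3)
  ordmut <- sample(cand)
  s <- cons
  prev <- Inf
  for (step in seq(5, 50, by = 5)) {
    for (p in ordmut[(step - 4):step]) {
      s[p] <- pvalbid:::.biased_substitution(s[p])
    }
    call <- classify_family(
      pvalb_seq("mono", paste(s, collapse = "")), tp, tp_rules,
      synteny = synteny_context(chromosome_label = "Chr.B"))
    expect_lte(call$confidence, prev + 1e-9)
    prev <- call$confidence
  }
})

test_that("hybrid detection recovers a planted breakpoint", {
  h <- simulate_hybrid_sequence("pvalb3", "pvalb2", 30)
  res <- detect_hybrid(h$seq, tp)
  expect_true(res$is_hybrid)
  expect_equal(res$component_a$family, "pvalb3")
  expect_equal(res$component_b$family, "pvalb2")
  expect_lte(abs(res$breakpoint - 30), 10)
  # spans partition the frame at the breakpoint
  expect_equal(res$component_a$span[2] + 1L, res$component_b$span[1])
  # named after the unique (minority) part
  expect_equal(res$name_suggestion, "pvalb3")
})

test_that("pure sequences and two-switch mosaics are not hybrids", {
  pure <- simulate_family_sequence("pvalb4", 95, TRUE, 5)$seq
  expect_false(detect_hybrid(pure, tp)$is_hybrid)

  arch <- pvalbid:::.architecture()
  mosaic <- c(arch$consensus$pvalb3[1:30], arch$consensus$pvalb2[31:70],
              arch$consensus$pvalb3[71:109])
  res <- detect_hybrid(pvalb_seq("mosaic", paste(mosaic, collapse = "")),
                       tp)
  expect_false(res$is_hybrid)
  expect_equal(res$note, "complex mosaic")
})

test_that("hybrid scan validates its window arguments", {
  q <- simulate_family_sequence("pvalb1", 95, TRUE, 2)$seq
  expect_error(detect_hybrid(q, tp, window = 5L), "window")
  expect_error(detect_hybrid(q, tp, step = 0L), "step")
})
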