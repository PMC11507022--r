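# Column frequencies, information content, diagnostic-rule discovery
# and rule scoring.

make_group <- function(strings) {
  lapply(seq_along(strings), function(i) {
    map_to_canonical(pvalb_seq(paste0("g", i), strings[i]), tp)
  })
}

test_that("information content matches closed-form values", {
  cons <- family_consensus(tp, "pvalb4")
  grp <- make_group(c(cons, cons))
  prof <- column_frequencies(grp)
  # pure column: log2(20) bits
  expect_equal(prof$information_bits[1], log2(20))

  # 50/50 column: log2(20) - 1 bits
  alt <- strsplit(cons, "")[[1]]
  alt[30] <- if (alt[30] == "A") "G" else "A"
  grp2 <- make_group(c(cons, paste(alt, collapse = "")))
  prof2 <- column_frequencies(grp2)
  expect_equal(prof2$information_bits[30], log2(20) - 1)

  # uniform over all 20 residues: 0 bits
  base <- strsplit(cons, "")[[1]]
  strings <- vapply(AA20, function(r) {
    s <- base; s[30] <- r; paste(s, collapse = "")
  }, "")
  prof3 <- column_frequencies(make_group(strings))
  expect_equal(prof3$information_bits[30], 0)
  expect_error(column_frequencies(list()), "empty")
})

test_that("information content is permutation-invariant and decreases
           with contamination", {
  cons <- family_consensus(tp, "pvalb2")
  alt <- strsplit(cons, "")[[1]]; alt[40] <- "W"
  alt <- paste(alt, collapse = "")
  bits <- vapply(seq(0, 5), function(k) {
    grp <- make_group(c(rep(alt, k), rep(cons, 10 - k)))
    column_frequencies(grp)$information_bits[40]
  }, 0)
  expect_true(all(diff(bits) < 0))
  shuffled <- make_group(c(rep(cons, 7), rep(alt, 3)))
  ordered <- make_group(c(rep(alt, 3), rep(cons, 7)))
  expect_equal(column_frequencies(shuffled)$information_bits[40],
               column_frequencies(ordered)$information_bits[40])
})

test_that("derived rules contain the published diagnostic residues", {
  expect_true(ruleset_contains(tp_rules, published_rule_set()))
  # and specifically pvalb3@12=T / pvalb4@19=K are recovered
  expect_true(any(tp_rules$group == "pvalb3" & tp_rules$position == 12 &
                    tp_rules$residues == "T"))
  expect_true(any(tp_rules$group == "pvalb4" & tp_rules$position == 19 &
                    tp_rules$residues == "K"))
})

test_that("a single planted discriminating column yields a single rule", {
  cons <- strsplit(family_consensus(tp, "pvalb4"), "")[[1]]
  a1 <- a2 <- b1 <- b2 <- cons
  b1[50] <- b2[50] <- if (cons[50] == "A") "G" else "A"
  seqs <- list(pvalb_seq("a1", paste(a1, collapse = "")),
               pvalb_seq("a2", paste(a2, collapse = "")),
               pvalb_seq("b1", paste(b1, collapse = "")),
               pvalb_seq("b2", paste(b2, collapse = "")))
  meta <- data.frame(id = c("a1", "a2", "b1", "b2"),
                     species = "syn",
                     lineage = "Beta2",
                     family = c("pvalb4", "pvalb4", "pvalb1", "pvalb1"),
                     chromosome_label = NA, stringsAsFactors = FALSE)
  panel2 <- suppressWarnings(pvalbid:::build_panel(
    stats::setNames(seqs, meta$id), meta, anchor_id = "a1"))
  rules <- suppressWarnings(derive_diagnostic_positions(panel2, "family"))
  expect_equal(nrow(rules), 2L)          # one rule per group
  expect_equal(unique(rules$position), 50L)
})

test_that("rule scoring follows the published criteria", {
  pub <- published_rule_set()
  sim3 <- simulate_family_sequence("pvalb3", 92, TRUE, 5)
  aln3 <- map_to_canonical(sim3$seq, tp)
  sc3 <- score_against_rules(aln3, pub)
  expect_equal(sc3$weighted_score[sc3$group == "pvalb3"], 1.0)

  # A12 with G19: G is a small residue, so pvalb2 scores 1
  sim2 <- simulate_family_sequence("pvalb2", 92, TRUE, 5)
  aln2 <- map_to_canonical(sim2$seq, tp)
  expect_identical(residue_at(aln2, 12L), "A")
  expect_true(residue_at(aln2, 19L) %in% SMALL_RESIDUES)
  sc2 <- score_against_rules(aln2, pub)
  expect_equal(sc2$weighted_score[sc2$group == "pvalb2"], 1.0)

  # a gap at position 12 penalizes both pvalb2 and pvalb3 rules
  gapped <- aln3
  gapped$residues[12] <- "-"
  scg <- score_against_rules(gapped, pub)
  expect_lt(scg$weighted_score[scg$group == "pvalb3"], 1.0)
  expect_lt(scg$weighted_score[scg$group == "pvalb2"], 1.0)
  expect_error(score_against_rules(aln3, NULL), "empty")
})

test_that("rule sets round-trip through TSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rules.tsv")
  write_rule_set(tp_rules, path)
  back <- read_rule_set(path)
  expect_equal(as.data.frame(back), as.data.frame(tp_rules))
})
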