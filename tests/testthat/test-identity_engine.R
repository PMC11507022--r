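# Percent identity, reference ranking and identity matrices.

test_that("percent identity handles the base cases", {
  s <- tp$entries$Dre_pvalb3_syn
  expect_equal(percent_identity(s, s)$percent_identity, 100)

  pair <- mismatch_pair(1L, L = 109L)
  r <- percent_identity(pair$a, pair$b)
  expect_equal(r$aligned_pairs, 109L)
  expect_equal(r$matches, 108L)
  expect_equal(r$percent_identity, 100 * 108 / 109)
})

test_that("percent identity is symmetric and id-invariant", {
  for (seed in 1:5) {
    a <- pvalb_seq("a", random_residues(109, seed))
    sim <- simulate_family_sequence("pvalb4", 85, FALSE, seed)
    b <- sim$seq
    ab <- percent_identity(a, b)$percent_identity
    ba <- percent_identity(b, a)$percent_identity
    expect_equal(ab, ba)
    renamed <- pvalb_seq("zzz", a$residues)
    expect_equal(percent_identity(renamed, b)$percent_identity, ab)
  }
})

test_that("gap-free equal-length identity equals the Hamming oracle", {
  for (n_mm in c(0L, 3L, 10L, 25L)) {
    pair <- mismatch_pair(n_mm, L = 109L)
    hamming <- 100 * mean(strsplit(pair$a$residues, "")[[1]] ==
                            strsplit(pair$b$residues, "")[[1]])
    expect_equal(percent_identity(pair$a, pair$b)$percent_identity,
                 hamming)
  }
})

test_that("X residues never count as matches", {
  a <- pvalb_seq("xa", paste0("X", strrep("ADKF", 27)))
  b <- pvalb_seq("xb", paste0("X", strrep("ADKF", 27)))
  r <- percent_identity(a, b)
  expect_equal(r$matches, 108L)
  expect_lt(r$percent_identity, 100)
})

test_that("reference ranking is ordered, restricted and deterministic", {
  q <- tp$entries$Gmo_pvalb3_syn
  rk <- rank_references(q, tp)
  expect_equal(rk$id[1], "Gmo_pvalb3_syn")
  expect_equal(rk$percent_identity[1], 100)
  expect_true(all(diff(rk$percent_identity) <= 0))

  restricted <- rank_references(q, tp, restrict_to = c("pvalb2", "pvalb3"))
  expect_setequal(unique(restricted$family), c("pvalb2", "pvalb3"))
  expect_error(rank_references(q, tp, restrict_to = "pvalb99"),
               "no panel entries")

  # deterministic tie-break: identical sequences rank lexicographically
  again <- rank_references(q, tp)
  expect_identical(rk, again)
})

test_that("a family-consensus query ranks its own family first", {
  sim <- simulate_family_sequence("pvalb3", 95, TRUE, seed = 33)
  rk <- rank_references(sim$seq, tp)
  p3_best <- max(rk$percent_identity[rk$family == "pvalb3"])
  p2_best <- max(rk$percent_identity[rk$family == "pvalb2"])
  expect_gt(p3_best, p2_best)
})

test_that("identity matrix satisfies its invariants", {
  seqs <- tp$entries[c("Dre_pvalb2_syn", "Gmo_pvalb2_syn",
                       "Dre_pvalb3_syn", "Dre_pvalb7_syn")]
  im <- identity_matrix(seqs)
  expect_identical(im$values, t(im$values))
  expect_equal(unname(diag(im$values)), rep(100, 4))
  expect_true(all(im$values >= 0 & im$values <= 100))
  expect_equal(attr(im, "n_computed"), 4 * 3 / 2)
  expect_error(identity_matrix(c(seqs, seqs[1])), "duplicate")

  dup <- identity_matrix(list(seqs[[1]],
                              pvalb_seq("copy", seqs[[1]]$residues)))
  expect_equal(dup$values[1, 2], 100)
})

test_that("within-family identity exceeds cross-lineage identity", {
  im <- identity_matrix(tp$entries)
  meta <- tp$metadata
  within <- c(); cross <- c()
  for (i in seq_len(nrow(meta) - 1)) {
    for (j in (i + 1):nrow(meta)) {
      v <- im$values[meta$id[i], meta$id[j]]
      if (meta$family[i] == meta$family[j]) within <- c(within, v)
      else if (meta$lineage[i] != meta$lineage[j]) cross <- c(cross, v)
    }
  }
  expect_gt(mean(within), mean(cross))
  expect_gt(min(within), max(cross))
})

test_that("identity matrix TSV export round-trips values", {
  dir <- withr::local_tempdir()
  seqs <- tp$entries[1:3]
  im <- identity_matrix(seqs)
  path <- file.path(dir, "im.tsv")
  write_identity_matrix(im, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               unname(im$values), ignore_attr = TRUE, tolerance = 1e-8)
})
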