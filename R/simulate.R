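# Seeded generators for benchmark fixtures: family-consistent protein
# sequences, genomic locus layouts (tandem duplicates, WGD copies,
# pseudogene fragments), hybrid genes, and allergen catalogs with
# controlled identity structure. All generators are pure functions of
# their seed and parameters; every output carries a truth record
# sufficient to score the downstream operations.

.blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# BLOSUM62-biased substitution: replacement drawn with probability
# proportional to exp(score/2) among the 19 alternatives.
.biased_substitution <- function(orig, n = 1L) {
  B <- .blosum62()
  alt <- setdiff(AA20, orig)
  w <- exp(B[orig, alt] / 2)
  sample(alt, n, replace = TRUE, prob = w)
}

#' Simulate a family-consistent parvalbumin sequence
#'
#' Starts from the family consensus and applies BLOSUM62-biased
#' substitutions at uniformly sampled positions until the realized
#' identity to the consensus meets `target_identity` (exact to within
#' rounding of the mutation count, always within 2 points). With
#' `preserve_diagnostics` the family's rule positions (diagnostic and
#' family-distinctive residues) are never touched.
#'
#' @param family Family name.
#' @param target_identity Target percent identity to the family
#'   consensus, in `[50, 100]`; parvalbumins below ~50% identity are
#'   outside family plausibility and rejected.
#' @param preserve_diagnostics Keep diagnostic positions intact
#'   (default TRUE).
#' @param seed Integer seed.
#' @return List with `seq` (a [pvalb_seq()], source `"synthetic"`) and
#'   `truth` (`family`, `lineage`, `region`, `target_identity`,
#'   `mutated_positions`).
#' @export
simulate_family_sequence <- function(family, target_identity,
                                     preserve_diagnostics = TRUE,
                                     seed = 1L) {
  cons <- .arch_consensus(family)
  if (target_identity < 50 || target_identity > 100) {
    stop("target_identity must be in [50, 100]: parvalbumins share >45% ",
         "identity in most cases and the generator stays above that")
  }
  arch <- .architecture()
  L <- length(cons)
  n_mut <- round(L * (1 - target_identity / 100))
  candidates <- seq_len(L)
  if (preserve_diagnostics) {
    candidates <- setdiff(candidates, arch$rule_positions[[family]])
  }
  if (n_mut > length(candidates)) {
    stop("target_identity too low to respect preserved positions")
  }
  out <- .with_seed(seed, {
    pos <- sort(sample(candidates, n_mut))
    s <- cons
    for (p in pos) s[p] <- .biased_substitution(cons[p])
    list(s = s, pos = pos)
  })
  id <- sprintf("%s_sim%d_t%02d", family, as.integer(seed),
                as.integer(round(target_identity)))
  list(seq = pvalb_seq(id, paste(out$s, collapse = ""),
                       species = "synthetic", source = "synthetic"),
       truth = list(family = family,
                    lineage = unname(FAMILY_LINEAGE[family]),
                    region = .family_region(family),
                    target_identity = target_identity,
                    mutated_positions = out$pos))
}

#' Simulate a hybrid (recombinant) parvalbumin
#'
#' Joins the 5' part of one family consensus (canonical positions 1 to
#' `breakpoint`) to the 3' part of another, emulating intergenic
#' recombination between adjacent similar genes.
#'
#' @param family_a,family_b Donor families (must differ).
#' @param breakpoint Last canonical position taken from `family_a`
#'   (10-99).
#' @param seed Integer seed (used for the sequence id only; the hybrid
#'   itself is deterministic).
#' @return List with `seq` and `truth` (`family_a`, `family_b`,
#'   `breakpoint`).
#' @export
simulate_hybrid_sequence <- function(family_a, family_b, breakpoint,
                                     seed = 1L) {
  if (family_a == family_b) stop("hybrid donors must differ")
  if (breakpoint < 10 || breakpoint > 99) {
    stop("breakpoint must lie in 10-99")
  }
  ca <- .arch_consensus(family_a)
  cb <- .arch_consensus(family_b)
  n <- min(length(ca), length(cb))
  s <- c(ca[seq_len(breakpoint)], cb[(breakpoint + 1L):n])
  id <- sprintf("hybrid_%s_%s_b%d_s%d", family_a, family_b,
                as.integer(breakpoint), as.integer(seed))
  list(seq = pvalb_seq(id, paste(s, collapse = ""), species = "synthetic",
                       source = "synthetic"),
       truth = list(family_a = family_a, family_b = family_b,
                    breakpoint = as.integer(breakpoint)))
}

# ---------------------------------------------------------------------
# Genome simulation

.codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

# Uniform random choice among synonymous codons (seeded by caller).
.back_translate <- function(residues) {
  tab <- .codon_table()
  paste(vapply(residues, function(r) {
    opts <- tab[[r]]
    if (is.null(opts)) "NNN" else opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a genome simulation plan
#'
#' @param scaffolds List of scaffold specs: each a list with `name`,
#'   `chromosome_label`, and `genes` — a list of gene specs
#'   (`family`, optional `strand` (default `"+"`), optional `pseudogene`
#'   (default FALSE), optional `target_identity` (default 92), optional
#'   explicit `start`).
#' @param seed Integer seed.
#' @return Object of class `pvalb_genome_plan`.
#' @export
genome_plan <- function(scaffolds, seed = 1L) {
  stopifnot(is.list(scaffolds))
  structure(list(scaffolds = scaffolds, seed = seed),
            class = "pvalb_genome_plan")
}

#' Simulate a genome with planted parvalbumin loci
#'
#' Each planned intact gene is embedded as two coding exons split after
#' codon 57, separated by a random 200-2000 nt intron, and
#' reverse-complemented for minus-strand genes; pseudogenes are embedded
#' as 5' coding fragments carrying an internal stop codon. The truth
#' table records every planted locus (0-based half-open coordinates,
#' BED-style).
#'
#' @param plan A [genome_plan()].
#' @return List with `scaffolds` (named character vector of nucleotide
#'   sequences) and `truth` (data frame: `locus_id`, `scaffold`,
#'   `chromosome_label`, `start`, `end`, `strand`, `family`, `intact`,
#'   `exon_blocks`).
#' @export
simulate_genome <- function(plan) {
  stopifnot(inherits(plan, "pvalb_genome_plan"))
  if (length(plan$scaffolds) == 0L) {
    return(list(scaffolds = character(0), truth = .empty_truth()))
  }
  .with_seed(plan$seed, {
    fa <- character(0)
    truth <- list()
    gene_counter <- 0L
    for (sc in plan$scaffolds) {
      stopifnot(!is.null(sc$name), !is.null(sc$genes))
      pieces <- .random_dna(round(stats::runif(1, 800, 1500)))
      cursor <- nchar(pieces)
      explicit <- vapply(sc$genes, function(g) !is.null(g$start), TRUE)
      if (any(explicit)) {
        starts <- vapply(sc$genes, function(g)
          if (is.null(g$start)) NA_real_ else g$start, 0)
        ord <- order(starts)
        if (any(diff(stats::na.omit(sort(starts))) < 3000)) {
          stop("overlapping planned loci on scaffold ", sc$name)
        }
        sc$genes <- sc$genes[ord]
      }
      for (g in sc$genes) {
        gene_counter <- gene_counter + 1L
        strand <- if (is.null(g$strand)) "+" else g$strand
        pseudo <- isTRUE(g$pseudogene)
        tid <- if (is.null(g$target_identity)) 92 else g$target_identity
        sim <- simulate_family_sequence(
          g$family, tid, preserve_diagnostics = TRUE,
          seed = (as.numeric(plan$seed) * 1000 + gene_counter) %% 2147483647)
        residues <- strsplit(sim$seq$residues, "")[[1]]
        if (pseudo) {
          frag <- residues[1:55]
          cds <- .back_translate(frag)
          # internal stop at codon 30
          substr(cds, 88, 90) <- "TAA"
          cassette <- cds
          blocks_local <- matrix(c(0L, nchar(cds)), 1L)
        } else {
          cds <- paste0(.back_translate(residues), "TAA")
          cut <- 57L * 3L
          intron <- .random_dna(round(stats::runif(1, 200, 2000)))
          exon1 <- substr(cds, 1L, cut)
          exon2 <- substr(cds, cut + 1L, nchar(cds))
          cassette <- paste0(exon1, intron, exon2)
          blocks_local <- rbind(
            c(0L, nchar(exon1)),
            c(nchar(exon1) + nchar(intron), nchar(cassette)))
        }
        if (strand == "-") {
          n <- nchar(cassette)
          cassette <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cassette)))
          blocks_local <- cbind(n - blocks_local[, 2], n - blocks_local[, 1])
          blocks_local <- blocks_local[order(blocks_local[, 1]), ,
                                       drop = FALSE]
        }
        if (!is.null(g$start)) {
          if (g$start < cursor) {
            stop("overlapping planned loci on scaffold ", sc$name)
          }
          pieces <- paste0(pieces, .random_dna(g$start - cursor))
          cursor <- g$start
        }
        offset <- cursor
        pieces <- paste0(pieces, cassette)
        cursor <- cursor + nchar(cassette)
        spacer <- .random_dna(round(stats::runif(1, 2000, 4000)))
        pieces <- paste0(pieces, spacer)
        cursor <- cursor + nchar(spacer)
        blocks <- blocks_local + offset
        truth[[length(truth) + 1L]] <- data.frame(
          locus_id = sprintf("%s_locus%d", sc$name, gene_counter),
          scaffold = sc$name,
          chromosome_label = if (is.null(sc$chromosome_label))
            NA_character_ else sc$chromosome_label,
          start = offset, end = offset + nchar(cassette),
          strand = strand, family = g$family, intact = !pseudo,
          exon_blocks = paste(apply(blocks, 1, paste, collapse = "-"),
                              collapse = ","),
          stringsAsFactors = FALSE)
      }
      fa[sc$name] <- pieces
    }
    list(scaffolds = fa,
         truth = if (length(truth) == 0L) .empty_truth() else
           do.call(rbind, truth))
  })
}

.empty_truth <- function() {
  data.frame(locus_id = character(0), scaffold = character(0),
             chromosome_label = character(0), start = integer(0),
             end = integer(0), strand = character(0), family = character(0),
             intact = logical(0), exon_blocks = character(0),
             stringsAsFactors = FALSE)
}

#' Genome plan mirroring a nine-gene acanthopterygian layout
#'
#' Four ohnologous regions with the ancestral gene content minus pvalb2
#' (lost in most neoteleosts): nine intact parvalbumin genes.
#'
#' @param seed Integer seed.
#' @export
plan_seabream_like <- function(seed = 101L) {
  gene <- function(family, strand = "+") list(family = family,
                                              strand = strand)
  genome_plan(list(
    list(name = "sb_scaffold_A", chromosome_label = "Chr.A",
         genes = list(gene("pvalb8"), gene("pvalb4", "-"), gene("pvalb1"),
                      gene("pvalb5"))),
    list(name = "sb_scaffold_B", chromosome_label = "Chr.B",
         genes = list(gene("pvalb9"), gene("pvalb3", "-"))),
    list(name = "sb_scaffold_C", chromosome_label = "Chr.C",
         genes = list(gene("pvalb6"), gene("pvalb10"))),
    list(name = "sb_scaffold_D", chromosome_label = "Chr.D",
         genes = list(gene("pvalb7")))), seed = seed)
}

#' Genome plan mirroring a salmonid layout
#'
#' A salmonid-specific extra WGD doubled the regions; one duplicate of
#' the pvalb8/4/1/5 region was lost again, and two loci survive only as
#' pseudogene fragments (pvalb1, pvalb10). Thirteen intact genes, two
#' pseudogenes, with the pvalb2A/pvalb2B tandem pair and the loss of
#' pvalb3.
#'
#' @param seed Integer seed.
#' @export
plan_chum_like <- function(seed = 202L) {
  gene <- function(family, strand = "+", pseudogene = FALSE) {
    list(family = family, strand = strand, pseudogene = pseudogene)
  }
  genome_plan(list(
    list(name = "cs_scaffold_A1", chromosome_label = "Chr.A1",
         genes = list(gene("pvalb8"), gene("pvalb4"),
                      gene("pvalb1", pseudogene = TRUE), gene("pvalb5"))),
    list(name = "cs_scaffold_B1", chromosome_label = "Chr.B1",
         genes = list(gene("pvalb9"), gene("pvalb2"), gene("pvalb2"))),
    list(name = "cs_scaffold_B2", chromosome_label = "Chr.B2",
         genes = list(gene("pvalb9", "-"), gene("pvalb2"))),
    list(name = "cs_scaffold_C1", chromosome_label = "Chr.C1",
         genes = list(gene("pvalb6"), gene("pvalb10"))),
    list(name = "cs_scaffold_C2", chromosome_label = "Chr.C2",
         genes = list(gene("pvalb6"),
                      gene("pvalb10", pseudogene = TRUE))),
    list(name = "cs_scaffold_D1", chromosome_label = "Chr.D1",
         genes = list(gene("pvalb7"))),
    list(name = "cs_scaffold_D2", chromosome_label = "Chr.D2",
         genes = list(gene("pvalb7", "-")))), seed = seed)
}

# ---------------------------------------------------------------------
# Allergen catalog simulation

#' Simulate an allergen catalog with controlled identity structure
#'
#' Builds `n_isoallergens` isoallergen groups around a common center
#' sequence: each isoallergen applies substitutions on its own block of
#' 13 positions (pairwise cross-isoallergen identity ~76%, within the
#' >67/<90 band), and variants within an isoallergen differ by 1-3
#' further substitutions (identity >90%).
#'
#' @param n_isoallergens Number of isoallergen groups (1-7).
#' @param variants_per_isoallergen Variants per group.
#' @param seed Integer seed.
#' @return List with `catalog` (data frame: `allergen_code`, `sequence`,
#'   `isoallergen`, `variant`) and `truth` (block positions per
#'   isoallergen).
#' @export
simulate_allergen_catalog <- function(n_isoallergens,
                                      variants_per_isoallergen = 1L,
                                      seed = 1L) {
  if (n_isoallergens < 1L) stop("need at least one isoallergen")
  arch <- .architecture()
  center <- arch$consensus$pvalb2
  free <- setdiff(seq_along(center), arch$core)
  if (n_isoallergens * 13L > length(free)) {
    stop("infeasible identity structure: too many isoallergens for the ",
         "sequence length")
  }
  .with_seed(seed, {
    blocks <- split(sample(free, n_isoallergens * 13L),
                    rep(seq_len(n_isoallergens), each = 13L))
    rows <- list()
    for (iso in seq_len(n_isoallergens)) {
      iso_seq <- center
      for (p in blocks[[iso]]) {
        iso_seq[p] <- sample(setdiff(AA20, center[p]), 1L)
      }
      for (v in seq_len(variants_per_isoallergen)) {
        s <- iso_seq
        if (v > 1L) {
          vp <- sample(setdiff(free, unlist(blocks)),
                       sample(1:3, 1L))
          for (p in vp) s[p] <- sample(setdiff(AA20, s[p]), 1L)
        }
        code <- sprintf("Syn t 1.%02d%02d", iso, v)
        rows[[length(rows) + 1L]] <- data.frame(
          allergen_code = code, sequence = paste(s, collapse = ""),
          isoallergen = iso, variant = v, stringsAsFactors = FALSE)
      }
    }
    list(catalog = do.call(rbind, rows), truth = list(blocks = blocks))
  })
}
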