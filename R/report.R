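# Pipeline surface: configuration, end-to-end classification of a FASTA
# of queries, locus naming from a scan, and report writers (TSV primary,
# JSON mirror; logging to stderr, results to files only).

#' Default run configuration
#'
#' All defaults are loadable with zero user input; every threshold is
#' echoed into the run log by the pipeline functions.
#'
#' @param seed Seed used wherever randomness is involved.
#' @param hybrid_window,hybrid_step,hybrid_margin Hybrid-scan settings
#'   (see [detect_hybrid()]).
#' @param score_threshold,chain_gap,min_coverage Locus-finder settings
#'   (see [find_parvalbumin_loci()]).
#' @param verbose Emit progress messages on stderr.
#' @return List of class `pvalb_config`.
#' @export
default_config <- function(seed = 1L, hybrid_window = 20L, hybrid_step = 1L,
                           hybrid_margin = 5, score_threshold = 60,
                           chain_gap = 10000L, min_coverage = 0.7,
                           verbose = FALSE) {
  structure(list(seed = seed, hybrid_window = hybrid_window,
                 hybrid_step = hybrid_step, hybrid_margin = hybrid_margin,
                 score_threshold = score_threshold, chain_gap = chain_gap,
                 min_coverage = min_coverage, verbose = verbose),
            class = "pvalb_config")
}

.log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
  invisible(NULL)
}

# Reproducibility block: configuration, seed and panel checksum.
.log_run_header <- function(config, panel) {
  vals <- unlist(config[names(config) != "verbose"])
  .log(config, "pvalbid run: ",
       paste(names(vals), vals, sep = "=", collapse = " "),
       " panel_checksum=", panel_checksum(panel))
}

#' Checksum of a reference panel
#'
#' Order-independent digest of entry ids and residues, recorded in run
#' logs so reports can be tied to the exact panel used.
#'
#' @param panel A `pvalb_panel`.
#' @return Hex string.
#' @export
panel_checksum <- function(panel) {
  txt <- sort(vapply(panel$entries, function(s) paste0(s$id, s$residues),
                     ""))
  v <- utf8ToInt(paste(txt, collapse = "|"))
  sprintf("%08x", sum(v * (seq_along(v) %% 9973)) %% 4294967291)
}

# Read a synteny TSV (columns: id, chromosome_label, optional
# neighbor_genes comma-separated) into a per-id list of contexts.
read_synteny_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chromosome_label") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    ng <- if ("neighbor_genes" %in% names(df) &&
              nzchar(df$neighbor_genes[i] %||% "")) {
      strsplit(df$neighbor_genes[i], ",")[[1]]
    } else NULL
    cl <- df$chromosome_label[i]
    if (is.na(cl) || !nzchar(cl)) cl <- NULL
    if (is.null(cl) && is.null(ng)) return(NULL)
    synteny_context(chromosome_label = cl, neighbor_genes = ng)
  })
  names(out) <- df$id
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Classify every sequence in a FASTA
#'
#' End-to-end pipeline: maps each query to the canonical frame, calls
#' lineage and family (using synteny where provided) and screens for
#' hybrid genes. One report row per query; two runs with identical
#' inputs and configuration produce identical reports.
#'
#' @param fasta Path to a protein FASTA (or a list of [pvalb_seq()]).
#' @param synteny Optional: path to a synteny TSV (columns `id`,
#'   `chromosome_label`, optional `neighbor_genes`) or a named list of
#'   [synteny_context()] objects keyed by query id.
#' @param panel A `pvalb_panel`.
#' @param config A [default_config()] list.
#' @return Data frame: `query_id`, `lineage`, `lineage_confidence`,
#'   `family`, `unresolved`, `confidence`, `hybrid`,
#'   `hybrid_breakpoint`, `coverage`, `evidence`.
#' @export
classify_fasta <- function(fasta, synteny = NULL, panel = bundled_panel(),
                           config = default_config()) {
  .log_run_header(config, panel)
  queries <- if (is.list(fasta)) fasta else read_pvalb_fasta(fasta)
  if (length(queries) == 0L) {
    warning("no sequences in input; writing empty report")
    return(.empty_report())
  }
  if (is.character(synteny)) synteny <- read_synteny_tsv(synteny)
  rows <- lapply(queries, function(q) {
    syn <- if (!is.null(synteny)) synteny[[q$id]] else NULL
    call <- classify_family(q, panel, synteny = syn)
    hyb <- detect_hybrid(q, panel, window = config$hybrid_window,
                         step = config$hybrid_step,
                         margin = config$hybrid_margin)
    .log(config, "classified ", q$id, ": ", call$lineage, "/",
         call$family)
    data.frame(
      query_id = q$id, lineage = call$lineage,
      lineage_confidence = round(call$lineage_confidence, 3),
      family = call$family, unresolved = call$unresolved,
      confidence = round(call$confidence, 3), hybrid = hyb$is_hybrid,
      hybrid_breakpoint = if (hyb$is_hybrid) hyb$breakpoint else
        NA_integer_,
      coverage = round(call$coverage, 3),
      evidence = paste(sprintf("[%s] %s", call$evidence$source,
                               call$evidence$statement), collapse = " | "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_report <- function() {
  data.frame(query_id = character(0), lineage = character(0),
             lineage_confidence = numeric(0), family = character(0),
             unresolved = logical(0), confidence = numeric(0),
             hybrid = logical(0), hybrid_breakpoint = integer(0),
             coverage = numeric(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

#' Write a report as TSV with a JSON mirror
#'
#' @param report Data frame.
#' @param path Output TSV path; the JSON mirror replaces the extension
#'   with `.json`.
#' @return Invisible list of the two paths.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  json_path <- sub("\\.[a-zA-Z]+$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  jsonlite::write_json(report, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(tsv = path, json = json_path))
}

#' Name parvalbumin loci from a genome scan
#'
#' Resolves pair-ambiguous scan families (pvalb6/7, pvalb8/9) through
#' each scaffold's chromosome label, then applies the gene-naming
#' conventions of [assign_locus_names()].
#'
#' @param loci A `pvalb_loci` data frame from [find_parvalbumin_loci()]
#'   (or a truth table from [simulate_genome()]).
#' @param chromosome_labels Named character vector mapping scaffold name
#'   to chromosome label; unnecessary if the loci already carry a
#'   `chromosome_label` column.
#' @return Data frame with `gene_name` column (see
#'   [assign_locus_names()]).
#' @export
name_scanned_loci <- function(loci, chromosome_labels = NULL) {
  df <- as.data.frame(loci)
  if (!"chromosome_label" %in% names(df)) {
    if (is.null(chromosome_labels)) {
      stop("chromosome labels required to name loci")
    }
    df$chromosome_label <- unname(chromosome_labels[df$scaffold])
  }
  if (!"locus_id" %in% names(df)) {
    df$locus_id <- sprintf("%s:%d-%d", df$scaffold, df$start, df$end)
  }
  if (!"pseudogene" %in% names(df) && "intact" %in% names(df)) {
    df$pseudogene <- !df$intact
  }
  # Resolve pair labels via the region of the scaffold.
  amb <- grepl("/", df$family)
  for (i in which(amb)) {
    region <- .label_to_region(df$chromosome_label[i])
    fams <- strsplit(sub("pvalb([0-9]+)/([0-9]+)", "pvalb\\1,pvalb\\2",
                         df$family[i]), ",")[[1]]
    hit <- intersect(fams, .region_families(region))
    if (length(hit) == 1L) df$family[i] <- hit
  }
  assign_locus_names(df)
}
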