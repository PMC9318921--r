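# Functional-category enrichment of motif-positive loci and the pipeline
# orchestrator. The enrichment statistic is the count N of motif-positive
# genes per category, reported as log2(N + 1).

#' log2(N + 1) enrichment score
#' @param N non-negative integer count(s) of motif-positive genes.
#' @return `log2(N + 1)`.
#' @export
enrichment_score <- function(N) {
  if (any(N < 0)) .stopf("enrichment_score: N must be >= 0")
  log2(N + 1)
}

#' Count motif-positive genes per functional category
#'
#' A gene counts toward its category iff its operon leader's promoter
#' classification is not `none`; genes without an annotation pool under
#' `"-"`. Annotations for unknown genes are skipped with a warning; a gene
#' annotated twice is an error.
#'
#' @param classes classification data frame (from
#'   [classify_promoters()]`$classes`).
#' @param operons operon data frame from [call_operons()].
#' @param annotations data frame (`gene_id`, `category`) or named character
#'   vector keyed by gene id.
#' @return named integer vector of counts N per category.
#' @export
tabulate_regulon <- function(classes, operons, annotations) {
  if (is.data.frame(annotations)) {
    if (anyDuplicated(annotations$gene_id)) {
      .stopf("tabulate_regulon: gene annotated twice: %s",
             annotations$gene_id[duplicated(annotations$gene_id)][1L])
    }
    ann <- stats::setNames(as.character(annotations$category),
                           annotations$gene_id)
  } else {
    if (anyDuplicated(names(annotations))) {
      .stopf("tabulate_regulon: gene annotated twice: %s",
             names(annotations)[duplicated(names(annotations))][1L])
    }
    ann <- annotations
  }
  unknown <- setdiff(names(ann), operons$gene_id)
  if (length(unknown)) {
    warning(sprintf("tabulate_regulon: %d annotation(s) for unknown gene(s) skipped",
                    length(unknown)), call. = FALSE)
    ann <- ann[!names(ann) %in% unknown]
  }
  pos_leaders <- classes$locus_id[classes$category != "none"]
  pos_ops <- operons$operon_id[operons$gene_id %in% pos_leaders &
                                 operons$is_leader]
  pos_genes <- operons$gene_id[operons$operon_id %in% pos_ops]
  cat_of <- ann[pos_genes]
  cat_of[is.na(cat_of) | cat_of == ""] <- "-"
  tab <- table(cat_of)
  stats::setNames(as.integer(tab), names(tab))
}

#' Assemble a category x genome enrichment matrix
#'
#' @param counts_by_genome named list of per-genome count vectors from
#'   [tabulate_regulon()].
#' @return a `synr_enrichment` list with integer matrix `N` and numeric
#'   matrix `score = log2(N + 1)` (rows: sorted categories, columns: sorted
#'   genome labels).
#' @export
enrichment_matrix <- function(counts_by_genome) {
  genomes <- sort(names(counts_by_genome))
  cats <- sort(unique(unlist(lapply(counts_by_genome, names))))
  N <- matrix(0L, nrow = length(cats), ncol = length(genomes),
              dimnames = list(cats, genomes))
  for (g in genomes) {
    v <- counts_by_genome[[g]]
    N[names(v), g] <- as.integer(v)
  }
  structure(list(N = N, score = enrichment_score(N)),
            class = "synr_enrichment")
}

#' Write an enrichment matrix as TSV (scores at 6 decimals)
#'
#' @param matrix a `synr_enrichment` from [enrichment_matrix()].
#' @param path output file.
#' @param heatmap optional path for a convenience heatmap (PDF/PNG;
#'   requires the pheatmap package).
#' @return `path`, invisibly.
#' @export
write_enrichment_matrix <- function(matrix, path, heatmap = NULL) {
  sc <- matrix$score
  df <- data.frame(category = rownames(sc),
                   apply(sc, 2L, function(col) sprintf("%.6f", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("category", colnames(sc))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) .stopf("write_enrichment_matrix: cannot write %s: %s",
                                path, conditionMessage(e)))
  if (!is.null(heatmap) && nrow(sc) > 1L && ncol(sc) > 1L &&
      requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::pdf(heatmap)
    pheatmap::pheatmap(sc, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read an enrichment matrix TSV written by [write_enrichment_matrix()]
#' @param path TSV file.
#' @return numeric score matrix.
#' @export
read_enrichment_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$category
  m
}

#' Read a gene -> functional category table (TSV)
#' @param path two-column TSV (`gene_id`, `category`), with header.
#' @return annotation data frame.
#' @export
read_annotations_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
}

#' Run the full regulon-inference pipeline from a config
#'
#' Stages: domain screen (optional) -> promoter extraction -> dyad
#' discovery (or a supplied motif) -> genome scan and classification ->
#' enrichment. All artifacts are written under `output_dir`; identical
#' configs yield identical outputs.
#'
#' @param config path to a YAML file or an equivalent named list. Keys:
#'   `seed`, `output_dir`, `genome` (`fasta`, `gff`), optional `domains`
#'   (`domtbl`, `domain_a`, `domain_b`, `evalue_max`), `promoters`
#'   (`window`, `max_gap`, `clip`), optional `discovery` (dyad_config
#'   fields), `scan` (`canonical`, `canonical_mm`, optional `motif_json`,
#'   `p_threshold`), optional `annotations` (TSV path), optional
#'   `genome_label`.
#' @return named list of artifact file paths, invisibly; also the in-memory
#'   results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("run_pipeline: config not found: %s",
                                     config)
    config <- yaml::read_yaml(config)
  }
  need <- function(x, key, stage) {
    if (is.null(x)) .stopf("%s: config key '%s' missing", stage, key)
    x
  }
  out_dir <- need(config$output_dir, "output_dir", "setup")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  label <- config$genome_label %||% "genome"
  artifacts <- list()
  results <- list()

  # --- domain screen ------------------------------------------------------
  if (!is.null(config$domains)) {
    dm <- config$domains
    hits <- parse_domtblout(need(dm$domtbl, "domains.domtbl",
                                 "screen-domains"))
    sc <- screen_config(dm$domain_a %||% "PF06018",
                        dm$domain_b %||% "PF08222",
                        dm$evalue_max %||% 1e-3)
    cand <- screen_cooccurrence(hits, sc)
    artifacts$candidates <- file.path(out_dir, "candidates.tsv")
    utils::write.table(cand, artifacts$candidates, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$candidates <- cand
  }

  # --- promoters ----------------------------------------------------------
  gcfg <- need(config$genome, "genome", "extract-promoters")
  g <- read_fasta(need(gcfg$fasta, "genome.fasta", "extract-promoters"))
  g <- read_gff3(need(gcfg$gff, "genome.gff", "extract-promoters"), g)
  pcfg_in <- config$promoters %||% list()
  pcfg <- promoter_config(window = pcfg_in$window %||% 400L,
                          clip_at_upstream_gene = pcfg_in$clip %||% TRUE,
                          operon_max_gap = pcfg_in$max_gap %||% 50L)
  operons <- call_operons(g, pcfg)
  promoters <- build_promoter_set(g, pcfg)
  artifacts$promoters <- file.path(out_dir, "promoters.tsv")
  write_promoters_tsv(promoters, artifacts$promoters)
  results$promoters <- promoters
  results$operons <- operons

  # --- extended motif: discovery or supplied ------------------------------
  scfg <- config$scan %||% list()
  if (!is.null(scfg$motif_json)) {
    model <- read_dyad_json(scfg$motif_json)
  } else {
    dcfg_in <- config$discovery %||% list()
    dcfg <- dyad_config(
      arm_len = dcfg_in$arm_len %||% 6L,
      spacer_min = dcfg_in$spacer_min %||% 0L,
      spacer_max = dcfg_in$spacer_max %||% 30L,
      min_at_fraction = dcfg_in$min_at_fraction %||% (5 / 6),
      palindrome_mismatch_max = dcfg_in$palindrome_mismatch_max %||% 2L,
      seed = seed)
    model <- tryCatch(discover_dyads(promoters, dcfg),
                      error = function(e) {
                        .stopf("discover-dyads: %s", conditionMessage(e))
                      })
  }
  artifacts$motif <- file.path(out_dir, "motif.json")
  write_dyad_json(model, artifacts$motif)
  results$motif <- model

  # --- scan + classify ----------------------------------------------------
  canonical <- spaced_pattern("codY_box",
                              scfg$canonical %||% "AATTTTCWGAAAATT", 0L, "",
                              scfg$canonical_mm %||% 1L)
  extended <- spaced_pattern(
    "extended_palindrome", model$left_arm,
    model$spacer_len, model$right_arm,
    scfg$extended_mm %||% attr(model, "mm") %||% 1L)
  can_hits <- scan_promoter_set(promoters, canonical)
  ext_hits <- scan_promoter_set(promoters, extended)
  artifacts$hits <- file.path(out_dir, "hits.tsv")
  utils::write.table(rbind(can_hits, ext_hits), artifacts$hits, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cls <- classify_promoters(promoters, canonical, extended,
                            operons = operons, n_genes = nrow(g$genes))
  artifacts$classes <- file.path(out_dir, "classes.tsv")
  utils::write.table(cls$classes, artifacts$classes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  artifacts$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(cls$summary, artifacts$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$classes <- cls

  # --- enrichment ---------------------------------------------------------
  if (!is.null(config$annotations)) {
    ann <- read_annotations_tsv(config$annotations)
    counts <- tabulate_regulon(cls$classes, operons, ann)
    mat <- enrichment_matrix(stats::setNames(list(counts), label))
    artifacts$matrix <- file.path(out_dir, "matrix.tsv")
    write_enrichment_matrix(mat, artifacts$matrix)
    results$enrichment <- mat
  }

  # provenance
  prov <- list(
    package = "synregulon",
    version = as.character(utils::packageVersion("synregulon")),
    seed = seed, config = config, timestamp = NULL)
  artifacts$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, artifacts$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  out <- artifacts
  attr(out, "results") <- results
  invisible(out)
}
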