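# Genome containers, FASTA/GFF3 input, operon calling and promoter
# extraction. Coordinates are 0-based half-open internally; GFF3's 1-based
# inclusive convention is converted on read.

#' Promoter extraction configuration
#'
#' @param window upstream window in bases (default 400, the fixed window
#'   used for leader-gene promoter extraction).
#' @param clip_at_upstream_gene truncate the window at the nearest annotated
#'   gene boundary. Default `TRUE` (genome-wide scans); set `FALSE` for
#'   fixed-window extraction of a single promoter.
#' @param operon_max_gap maximum intergenic gap (bases) for two same-strand
#'   neighbours to be co-transcribed (default 50).
#' @param require_same_strand operons never span a strand switch
#'   (default `TRUE`).
#' @return a `synr_promoter_config` list.
#' @export
promoter_config <- function(window = 400L, clip_at_upstream_gene = TRUE,
                            operon_max_gap = 50L,
                            require_same_strand = TRUE) {
  if (window <= 0) .stopf("promoter_config: window must be > 0")
  if (operon_max_gap < 0) .stopf("promoter_config: operon_max_gap must be >= 0")
  structure(list(window = as.integer(window),
                 clip_at_upstream_gene = isTRUE(clip_at_upstream_gene),
                 operon_max_gap = as.integer(operon_max_gap),
                 require_same_strand = isTRUE(require_same_strand)),
            class = "synr_promoter_config")
}

.empty_genes <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), category = character(),
             stringsAsFactors = FALSE)
}

#' Construct a genome object
#'
#' @param contigs named character vector of uppercase DNA sequences over
#'   `{A,C,G,T,N}`.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`); optional `product`,
#'   `category`.
#' @return a `synr_genome` object with genes sorted by (contig, start).
#' @export
genome <- function(contigs, genes = NULL) {
  if (is.null(names(contigs)) || anyNA(names(contigs)) ||
      any(names(contigs) == "")) {
    .stopf("genome: contigs must be a named character vector")
  }
  if (anyDuplicated(names(contigs))) .stopf("genome: duplicate contig ids")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    .stopf("genome: contig '%s' has characters outside {A,C,G,T,N}",
           names(contigs)[which(bad)[1L]])
  }
  if (is.null(genes)) genes <- .empty_genes()
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!("product" %in% names(genes))) genes$product <- NA_character_
  if (!("category" %in% names(genes))) genes$category <- NA_character_
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) .stopf("genome: genes missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (nrow(genes)) {
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    if (anyDuplicated(genes$gene_id)) .stopf("genome: duplicate gene_id")
    if (!all(genes$strand %in% c("+", "-"))) {
      .stopf("genome: strand must be '+' or '-'")
    }
    unknown <- setdiff(genes$contig_id, names(contigs))
    if (length(unknown)) {
      .stopf("genome: gene(s) on unknown contig(s): %s",
             paste(unknown, collapse = ", "))
    }
    clen <- nchar(contigs)[genes$contig_id]
    off <- genes$start < 0L | genes$start >= genes$end | genes$end > clen
    if (any(off)) {
      .stopf("genome: coordinates outside contig for gene(s): %s",
             paste(genes$gene_id[off], collapse = ", "))
    }
    genes <- genes[order(genes$contig_id, genes$start, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(contigs = contigs, genes = genes), class = "synr_genome")
}

#' @export
print.synr_genome <- function(x, ...) {
  cat(sprintf("<synr_genome> %d contig(s), %s bp, %d gene(s)\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Read genome contigs from a FASTA file
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N}` are replaced
#' by `N` with a warning giving the replacement count.
#'
#' @param path FASTA file.
#' @return a `synr_genome` with contigs and no genes.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("read_fasta: file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    .stopf("read_fasta: %s is not FASTA (line 1 does not start with '>')",
           path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("read_fasta: no records in %s", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, numeric(1L)))
  if (n_bad > 0) {
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1L))
    warning(sprintf("read_fasta: replaced %d non-{A,C,G,T,N} character(s) with N",
                    n_bad), call. = FALSE)
  }
  genome(seqs)
}

#' Attach gene annotations from a GFF3 file
#'
#' Keeps `gene` features (falling back to `CDS` when no `gene` rows exist),
#' converts 1-based inclusive GFF3 coordinates to 0-based half-open, and
#' sorts genes by (contig, start). Features on contigs absent from `genome`
#' are an error.
#'
#' @param path GFF3 file.
#' @param genome a `synr_genome` whose contigs are already loaded.
#' @return the genome with `genes` populated.
#' @export
read_gff3 <- function(path, genome) {
  if (!inherits(genome, "synr_genome")) .stopf("read_gff3: need a synr_genome")
  if (!file.exists(path)) .stopf("read_gff3: file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) == "gene"
  if (!any(keep)) keep <- as.character(gr$type) == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) .stopf("read_gff3: no gene/CDS features in %s", path)
  ids <- as.character(gr$ID)
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    ids <- ifelse(is.na(ids) | ids == "", lt, ids)
  }
  if (anyNA(ids) | any(ids == "")) .stopf("read_gff3: feature without ID")
  product <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product,
    stringsAsFactors = FALSE
  )
  genome(genome$contigs, genes)
}

#' Group genes into operons by a same-strand distance heuristic
#'
#' Consecutive genes on one contig and strand whose intergenic gap is at
#' most `operon_max_gap` are grouped into one operon. Genes are listed in
#' transcription order; the first listed gene is the operon leader (the
#' rightmost gene for "-" strand operons).
#'
#' @param genome a `synr_genome` with genes.
#' @param config a [promoter_config()].
#' @return data frame with columns `operon_id`, `gene_id`, `contig_id`,
#'   `strand`, `is_leader`, rows in transcription order within operon.
#' @export
call_operons <- function(genome, config = promoter_config()) {
  g <- genome$genes
  if (nrow(g) == 0L) {
    return(data.frame(operon_id = integer(), gene_id = character(),
                      contig_id = character(), strand = character(),
                      is_leader = logical(), stringsAsFactors = FALSE))
  }
  op <- integer(nrow(g))
  op[1L] <- 1L
  if (nrow(g) > 1L) {
    for (i in 2L:nrow(g)) {
      same_contig <- g$contig_id[i] == g$contig_id[i - 1L]
      same_strand <- !config$require_same_strand ||
        g$strand[i] == g$strand[i - 1L]
      gap <- g$start[i] - g$end[i - 1L]
      joined <- same_contig && same_strand && gap <= config$operon_max_gap
      op[i] <- if (joined) op[i - 1L] else op[i - 1L] + 1L
    }
  }
  out <- lapply(split(seq_len(nrow(g)), op), function(idx) {
    strand <- g$strand[idx[1L]]
    # transcription order: leftmost first on "+", rightmost first on "-"
    if (strand == "-" ) idx <- rev(idx)
    data.frame(operon_id = op[idx[1L]], gene_id = g$gene_id[idx],
               contig_id = g$contig_id[idx], strand = g$strand[idx],
               is_leader = seq_along(idx) == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# genomic slice with bounds already validated
.slice <- function(contig_seq, start, end) {
  if (end <= start) return("")
  substr(contig_seq, start + 1L, end)
}

#' Extract the upstream (promoter) region of a gene
#'
#' For a "+"-strand gene `[s, e)` the region is `[max(0, s - window), s)`;
#' for a "-"-strand gene it is the reverse complement of
#' `[e, min(L, e + window))`, so the returned sequence reads 5'->3' relative
#' to the downstream gene. With `clip_at_upstream_gene`, the window is
#' truncated at the nearest other annotated gene boundary.
#'
#' @param genome a `synr_genome`.
#' @param locus_id gene id to extract upstream of.
#' @param config a [promoter_config()].
#' @return one-row data frame (`locus_id`, `contig_id`, `start`, `end`,
#'   `strand`, `sequence`, `empty`); a zero-length region is flagged
#'   `empty = TRUE`, not an error.
#' @export
extract_upstream <- function(genome, locus_id, config = promoter_config()) {
  g <- genome$genes
  i <- match(locus_id, g$gene_id)
  if (is.na(i)) .stopf("extract_upstream: unknown locus '%s'", locus_id)
  contig <- g$contig_id[i]
  cs <- genome$contigs[[contig]]
  L <- nchar(cs)
  others <- g[g$contig_id == contig & g$gene_id != locus_id, , drop = FALSE]
  if (g$strand[i] == "+") {
    s <- g$start[i]
    lo <- max(0L, s - config$window)
    if (config$clip_at_upstream_gene && nrow(others)) {
      ov <- others[others$start < s, , drop = FALSE]
      if (nrow(ov)) lo <- max(lo, min(max(ov$end), s))
    }
    int <- c(lo, s)
    seq <- .slice(cs, lo, s)
  } else {
    e <- g$end[i]
    hi <- min(L, e + config$window)
    if (config$clip_at_upstream_gene && nrow(others)) {
      ov <- others[others$end > e, , drop = FALSE]
      if (nrow(ov)) hi <- min(hi, max(min(ov$start), e))
    }
    int <- c(e, hi)
    seq <- if (hi > e) .revcomp(.slice(cs, e, hi)) else ""
  }
  data.frame(locus_id = locus_id, contig_id = contig,
             start = int[1L], end = int[2L], strand = g$strand[i],
             sequence = seq, empty = nchar(seq) == 0L,
             stringsAsFactors = FALSE)
}

#' Build the promoter set of a genome (one promoter per operon leader)
#'
#' @param genome a `synr_genome` with genes.
#' @param config a [promoter_config()].
#' @return data frame of non-empty promoters in deterministic
#'   (contig, interval start) order, columns as in [extract_upstream()].
#' @export
build_promoter_set <- function(genome, config = promoter_config()) {
  ops <- call_operons(genome, config)
  leaders <- ops$gene_id[ops$is_leader]
  if (length(leaders) == 0L) {
    return(data.frame(locus_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      empty = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(leaders, extract_upstream, genome = genome, config = config)
  out <- do.call(rbind, rows)
  out <- out[!out$empty, , drop = FALSE]
  out <- out[order(out$contig_id, out$start, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write genome contigs to FASTA
#' @param genome a `synr_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write gene annotations to GFF3
#' @param genome a `synr_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  g <- genome$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g)) {
    attrs <- sprintf("ID=%s", g$gene_id)
    has_prod <- !is.na(g$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              g$product[has_prod])
    writeLines(paste(g$contig_id, "synregulon", "gene",
                     g$start + 1L, g$end, ".", g$strand, ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a promoter set as TSV
#' @param promoters promoter data frame from [build_promoter_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoters_tsv <- function(promoters, path) {
  utils::write.table(
    promoters[, c("locus_id", "contig_id", "start", "end", "strand",
                  "sequence")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter TSV written by [write_promoters_tsv()]
#' @param path TSV file.
#' @return promoter data frame.
#' @export
read_promoters_tsv <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", quote = "")
  p$start <- as.integer(p$start)
  p$end <- as.integer(p$end)
  p$empty <- nchar(p$sequence) == 0L
  p
}
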