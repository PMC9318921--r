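# Seeded generators for every pipeline input: background promoters at a
# target GC, planted dyads with truth tables, operon-structured genomes
# with GFF3 annotations, HMMER-style domain-hit fixtures, and the
# binding-probe variant series used to dissect arm contributions.

#' Synthetic promoter specification
#'
#' @param n_promoters number of promoters.
#' @param length promoter length in bases (default 400, matching the
#'   upstream window used for promoter extraction).
#' @param gc GC fraction in `[0,1]` (default 0.5595, the genomic GC of
#'   *Cloacibacillus evryensis* DSM 19522).
#' @param planted optional literal dyad `list(left=, spacer=, right=)`.
#' @param plant_fraction fraction of promoters receiving a planted site.
#' @param seed integer seed.
#' @return a `synr_synth_spec` list.
#' @export
synthetic_spec <- function(n_promoters, length = 400L, gc = 0.5595,
                           planted = NULL, plant_fraction = 0, seed = 1L) {
  if (gc < 0 || gc > 1) .stopf("synthetic_spec: gc must be in [0,1]")
  if (plant_fraction < 0 || plant_fraction > 1) {
    .stopf("synthetic_spec: plant_fraction must be in [0,1]")
  }
  if (!is.null(planted)) {
    span <- nchar(planted$left) + planted$spacer + nchar(planted$right)
    if (length < span) .stopf("synthetic_spec: length < planted span")
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 length = as.integer(length), gc = gc, planted = planted,
                 plant_fraction = plant_fraction, seed = as.integer(seed)),
            class = "synr_synth_spec")
}

# n random bases at GC fraction gc, vector of single characters
.random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate background promoters at a specified GC fraction
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`; reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return promoter data frame (`locus_id`, `sequence`).
#' @export
gen_background <- function(spec) {
  .with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_promoters), function(i) {
      paste(.random_bases(spec$length, spec$gc), collapse = "")
    }, character(1L))
  })
  data.frame(locus_id = sprintf("synthP%03d", seq_len(spec$n_promoters)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Plant a literal dyad into a fraction of promoters
#'
#' In a seeded random subset of `round(fraction * n)` promoters, one
#' instance of `left + (random spacer of the stated length) + right` is
#' written at a random valid offset on a random strand; all other bases are
#' untouched.
#'
#' @param promoters promoter data frame.
#' @param left,right literal arm words.
#' @param spacer_len spacer length in bases.
#' @param fraction fraction of promoters to plant.
#' @param seed integer seed.
#' @param gc GC fraction for the random spacer bases (default 0.5).
#' @return list with `promoters` (modified) and `truth` (data frame
#'   `locus_id`, `planted`, `offset` (0-based), `strand`, `spacer_seq`).
#' @export
plant_dyad <- function(promoters, left, spacer_len, right, fraction,
                       seed = 1L, gc = 0.5) {
  n <- nrow(promoters)
  span <- nchar(left) + spacer_len + nchar(right)
  if (any(nchar(promoters$sequence) < span)) {
    .stopf("plant_dyad: dyad span %d exceeds a promoter length", span)
  }
  n_plant <- round(fraction * n)
  truth <- data.frame(locus_id = promoters$locus_id, planted = FALSE,
                      offset = NA_integer_, strand = NA_character_,
                      spacer_seq = NA_character_, stringsAsFactors = FALSE)
  out <- promoters
  .with_seed(seed, {
    chosen <- if (n_plant > 0) sort(sample.int(n, n_plant)) else integer(0L)
    for (i in chosen) {
      L <- nchar(out$sequence[i])
      off <- sample.int(L - span + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      spacer_seq <- paste(.random_bases(spacer_len, gc), collapse = "")
      site <- paste0(left, spacer_seq, right)
      if (strand == "-") site <- .revcomp(site)
      substr(out$sequence[i], off + 1L, off + span) <- site
      truth$planted[i] <- TRUE
      truth$offset[i] <- off
      truth$strand[i] <- strand
      truth$spacer_seq[i] <- spacer_seq
    }
  })
  list(promoters = out, truth = truth)
}

#' Generate an operon-structured synthetic genome
#'
#' Assembles one contig of alternating promoter and gene blocks: within an
#' operon, genes are separated by gaps below the operon-joining threshold;
#' operons are separated by the promoter block (longer than the threshold).
#' The planted dyad, when requested, is written only into designated
#' leaders' promoter windows (strand-aware, so extraction recovers the
#' site on the leader's strand).
#'
#' @param n_operons number of operons.
#' @param genes_per_operon genes per operon.
#' @param spec a [synthetic_spec()]; `spec$planted` and
#'   `spec$plant_fraction` control planting into leader promoters,
#'   `spec$length` is the promoter block length.
#' @param gene_len gene length in bases (default 900).
#' @param intra_gap within-operon intergenic gap (default 20, below the
#'   50-base operon-joining threshold).
#' @return list with `genome` (a `synr_genome`), `truth` (per-operon
#'   data frame: `operon_id`, `leader`, `strand`, `planted`,
#'   `offset_in_promoter`).
#' @export
gen_synthetic_genome <- function(n_operons, genes_per_operon, spec,
                                 gene_len = 900L, intra_gap = 20L) {
  stopifnot(n_operons >= 1L, genes_per_operon >= 1L)
  prom_len <- spec$length
  planted <- spec$planted
  n_plant <- round(spec$plant_fraction * n_operons)
  blocks <- character(0L)
  genes <- list()
  truth <- list()
  pos <- 0L
  gene_no <- 0L
  .with_seed(spec$seed, {
    plant_ops <- if (n_plant > 0) sort(sample.int(n_operons, n_plant))
    else integer(0L)
    strands <- sample(c("+", "-"), n_operons, replace = TRUE)
    for (k in seq_len(n_operons)) {
      strand <- strands[k]
      prom <- paste(.random_bases(prom_len, spec$gc), collapse = "")
      off <- NA_integer_
      if (k %in% plant_ops) {
        span <- nchar(planted$left) + planted$spacer + nchar(planted$right)
        off <- sample.int(prom_len - span + 1L, 1L) - 1L
        site <- paste0(planted$left,
                       paste(.random_bases(planted$spacer, spec$gc),
                             collapse = ""),
                       planted$right)
        substr(prom, off + 1L, off + span) <- site
      }
      op_genes <- character(genes_per_operon)
      for (j in seq_len(genes_per_operon)) {
        gene_no <- gene_no + 1L
        op_genes[j] <- sprintf("synthG%04d", gene_no)
      }
      # genomic layout left->right; "-" operons run right->left with the
      # promoter block on the right
      gene_block <- paste(
        vapply(seq_len(genes_per_operon), function(j) {
          paste(.random_bases(gene_len, spec$gc), collapse = "")
        }, character(1L)),
        collapse = paste(.random_bases(intra_gap, spec$gc), collapse = ""))
      if (strand == "+") {
        prom_seq <- prom
        blocks <- c(blocks, prom_seq, gene_block)
        gstart <- pos + prom_len
        order_ids <- op_genes
      } else {
        # promoter reads 5'->3' on the gene strand; genomic slice is its rc
        prom_seq <- .revcomp(prom)
        blocks <- c(blocks, gene_block, prom_seq)
        gstart <- pos
        order_ids <- rev(op_genes)  # leftmost gene is the last of the operon
      }
      for (j in seq_len(genes_per_operon)) {
        s <- gstart + (j - 1L) * (gene_len + intra_gap)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = order_ids[j], contig_id = "synth_contig_1",
          start = s, end = s + gene_len, strand = strand,
          stringsAsFactors = FALSE)
      }
      pos <- pos + prom_len +
        genes_per_operon * gene_len + (genes_per_operon - 1L) * intra_gap
      truth[[k]] <- data.frame(
        operon_id = k, leader = op_genes[1L], strand = strand,
        planted = k %in% plant_ops, offset_in_promoter = off,
        stringsAsFactors = FALSE)
    }
  })
  contig <- paste(blocks, collapse = "")
  g <- genome(c(synth_contig_1 = contig), do.call(rbind, genes))
  list(genome = g, truth = do.call(rbind, truth))
}

#' Write a HMMER per-domain table fixture with known truth
#'
#' Generates `n_with_both` proteins with significant hits to both domains,
#' `n_with_one` proteins with a significant hit to one domain only, and the
#' remainder with no significant hit (insignificant rows above the cutoff
#' are still written so the parser and threshold are exercised).
#'
#' @param n_proteins total proteins.
#' @param n_with_both proteins with both domains significant.
#' @param n_with_one proteins with exactly one domain significant.
#' @param seed integer seed.
#' @param path output file (default a tempfile).
#' @param domain_a,domain_b domain accessions (defaults as in
#'   [screen_config()]).
#' @param evalue_max significance cutoff the fixture is built around.
#' @param boundary_protein also emit one extra protein whose second domain
#'   sits exactly at `evalue_max` (strictly non-significant).
#' @return list with `path` and `truth` (character vector of protein ids
#'   with both domains significant).
#' @export
gen_domtblout_fixture <- function(n_proteins, n_with_both, n_with_one = 0L,
                                  seed = 1L, path = tempfile(fileext = ".tbl"),
                                  domain_a = "PF06018", domain_b = "PF08222",
                                  evalue_max = 1e-3,
                                  boundary_protein = FALSE) {
  if (n_with_both + n_with_one > n_proteins) {
    .stopf("gen_domtblout_fixture: counts exceed n_proteins")
  }
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  row_line <- function(id, dom, ev, score, from, to) {
    # 23-column HMMER3 domtblout layout
    paste(id, "-", 300, dom, dom, 120, ev, score, 0.1, 1, 1,
          ev, ev, score, 0.1, 1, 120, from, to, from, to, 0.9, "synthetic",
          sep = " ")
  }
  lines <- c("# synthetic per-domain hits", "#")
  truth <- character(0L)
  .with_seed(seed, {
    roles <- rep("none", n_proteins)
    both_idx <- sample.int(n_proteins, n_with_both)
    roles[both_idx] <- "both"
    rest <- setdiff(seq_len(n_proteins), both_idx)
    if (n_with_one > 0) roles[sample(rest, n_with_one)] <- "one"
    sig_e <- function() 10^stats::runif(1L, -8, log10(evalue_max) - 0.5)
    insig_e <- function() 10^stats::runif(1L, log10(evalue_max) + 0.5, 1)
    for (i in seq_len(n_proteins)) {
      id <- ids[i]
      if (roles[i] == "both") {
        lines <- c(lines,
                   row_line(id, domain_a, signif(sig_e(), 3), 55.1, 5, 110),
                   row_line(id, domain_b, signif(sig_e(), 3), 40.2, 150, 200))
        truth <- c(truth, id)
      } else if (roles[i] == "one") {
        dom <- sample(c(domain_a, domain_b), 1L)
        lines <- c(lines,
                   row_line(id, dom, signif(sig_e(), 3), 48.0, 5, 110),
                   row_line(id, setdiff(c(domain_a, domain_b), dom),
                            signif(insig_e(), 3), 6.1, 150, 200))
      } else {
        lines <- c(lines,
                   row_line(id, domain_a, signif(insig_e(), 3), 4.0, 5, 60))
      }
    }
  })
  if (boundary_protein) {
    id <- sprintf("prot%04d", n_proteins + 1L)
    lines <- c(lines,
               row_line(id, domain_a, 1e-6, 50.0, 5, 110),
               row_line(id, domain_b, evalue_max, 12.0, 150, 200))
  }
  writeLines(c(lines, "#"), path)
  list(path = path, truth = sort(truth))
}

#' Build the six binding-probe variants of a three-arm probe
#'
#' Variant I is the unchanged probe; II, III and IV substitute the first,
#' middle and last AT-rich arm with `CCCCCC`; V substitutes all three arms
#' with `GGGGGG`; VI substitutes all three with seeded random hexamers each
#' containing at least one G or C.
#'
#' @param seq probe sequence containing at least three arm occurrences.
#' @param arm_words arm words located with [find_arms()].
#' @param seed integer seed for variant VI.
#' @return named character vector of variants `I`..`VI`.
#' @export
make_probe_variants <- function(seq, arm_words, seed = 1L) {
  arms <- find_arms(seq, arm_words)
  if (nrow(arms) < 3L) {
    .stopf("make_probe_variants: need >= 3 arm occurrences, found %d at offsets [%s]",
           nrow(arms), paste(arms$offset, collapse = ", "))
  }
  k <- nchar(arms$word[1L])
  first <- 1L
  last <- nrow(arms)
  middle <- ceiling((1L + last) / 2)
  sub_at <- function(s, offsets, repl) {
    for (ii in seq_along(offsets)) {
      substr(s, offsets[ii] + 1L, offsets[ii] + k) <- repl[ii]
    }
    s
  }
  all_off <- arms$offset[c(first, middle, last)]
  rand_hex <- .with_seed(seed, {
    vapply(1:3, function(i) {
      repeat {
        w <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
        if (grepl("[GC]", w)) return(w)
      }
    }, character(1L))
  })
  c(I = seq,
    II = sub_at(seq, arms$offset[first], strrep("C", k)),
    III = sub_at(seq, arms$offset[middle], strrep("C", k)),
    IV = sub_at(seq, arms$offset[last], strrep("C", k)),
    V = sub_at(seq, all_off, rep(strrep("G", k), 3L)),
    VI = sub_at(seq, all_off, rand_hex))
}
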