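# Domain-architecture screen: parse HMMER3 per-domain tables and nominate
# CodY-like proteins carrying both a GAF and a winged-HTH domain.

#' Domain co-occurrence screen configuration
#'
#' Defaults follow the GAF (PF06018) + winged HTH (PF08222) definition of a
#' CodY-like protein with per-domain independent e-value strictly below
#' 1e-3.
#'
#' @param domain_a,domain_b accession strings of the two required domains.
#' @param evalue_max strict upper bound on the per-domain independent
#'   e-value.
#' @return a `synr_screen_config` list.
#' @export
screen_config <- function(domain_a = "PF06018", domain_b = "PF08222",
                          evalue_max = 1e-3) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    .stopf("screen_config: evalue_max must be > 0")
  }
  structure(list(domain_a = domain_a, domain_b = domain_b,
                 evalue_max = evalue_max),
            class = "synr_screen_config")
}

#' Parse a HMMER3 per-domain tabular file (domtblout)
#'
#' Comment lines starting with `#` are skipped. Per data row, the target
#' name becomes `protein_id`, the query accession (falling back to the
#' query name when the accession field is `-`) becomes `domain_accession`,
#' and the independent e-value column becomes `i_evalue`.
#'
#' @param path domtblout file.
#' @return data frame with columns `protein_id`, `domain_accession`,
#'   `i_evalue`, `bitscore`, `env_start`, `env_end`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) .stopf("parse_domtblout: file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  out <- data.frame(protein_id = character(), domain_accession = character(),
                    i_evalue = numeric(), bitscore = numeric(),
                    env_start = integer(), env_end = integer(),
                    stringsAsFactors = FALSE)
  if (length(data_lines) == 0L) return(out)
  lineno <- which(keep)
  rows <- strsplit(trimws(data_lines), "\\s+")
  n_fields <- vapply(rows, length, integer(1L))
  if (any(n_fields < 22L)) {
    .stopf("parse_domtblout: line %d has %d fields (expected >= 22)",
           lineno[which(n_fields < 22L)[1L]], min(n_fields))
  }
  f <- function(i) vapply(rows, `[`, character(1L), i)
  acc <- f(5L)
  acc[acc == "-"] <- f(4L)[acc == "-"]
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(v)) {
      .stopf("parse_domtblout: non-numeric %s at line %d",
             what, lineno[which(is.na(v))[1L]])
    }
    v
  }
  data.frame(protein_id = f(1L), domain_accession = acc,
             i_evalue = num(13L, "i-Evalue"), bitscore = num(14L, "score"),
             env_start = as.integer(num(20L, "env from")),
             env_end = as.integer(num(21L, "env to")),
             stringsAsFactors = FALSE)
}

#' Two-domain co-occurrence screen for CodY-like candidates
#'
#' A protein is a candidate iff it has at least one hit to each of the two
#' configured domains, each with independent e-value strictly below
#' `evalue_max`. The best (lowest e-value) hit per domain is retained.
#'
#' @param hits data frame from [parse_domtblout()].
#' @param config a [screen_config()].
#' @return data frame sorted by `protein_id` with columns `protein_id`,
#'   `evalue_a`, `evalue_b`, `bitscore_a`, `bitscore_b`.
#' @export
screen_cooccurrence <- function(hits, config = screen_config()) {
  sig <- hits[hits$i_evalue < config$evalue_max, , drop = FALSE]
  best_per <- function(domain) {
    h <- sig[sig$domain_accession == domain, , drop = FALSE]
    if (nrow(h) == 0L) return(h)
    h <- h[order(h$protein_id, h$i_evalue, -h$bitscore), , drop = FALSE]
    h[!duplicated(h$protein_id), , drop = FALSE]
  }
  a <- best_per(config$domain_a)
  b <- best_per(config$domain_b)
  ids <- sort(intersect(a$protein_id, b$protein_id))
  data.frame(
    protein_id = ids,
    evalue_a = a$i_evalue[match(ids, a$protein_id)],
    evalue_b = b$i_evalue[match(ids, b$protein_id)],
    bitscore_a = a$bitscore[match(ids, a$protein_id)],
    bitscore_b = b$bitscore[match(ids, b$protein_id)],
    stringsAsFactors = FALSE)
}
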