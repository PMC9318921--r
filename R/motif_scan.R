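# Genome-wide motif scanning: degenerate IUPAC patterns with mismatches,
# spaced two-arm patterns, and log-odds PWMs with exact p-values from a
# dynamic-programming score distribution. Promoters are classified by
# canonical-box / extended-palindrome content.

#' Spaced (or contiguous) degenerate pattern
#'
#' Contiguous patterns use `spacer_lens = 0` and an empty `right` arm.
#'
#' @param pattern_id label attached to hits.
#' @param left left arm, IUPAC alphabet.
#' @param spacer_lens integer vector of admissible spacer lengths.
#' @param right right arm, IUPAC alphabet ("" for contiguous patterns).
#' @param max_mismatch shared mismatch budget across both arms (default 0).
#' @return a `synr_pattern` list.
#' @export
spaced_pattern <- function(pattern_id, left, spacer_lens = 0L, right = "",
                           max_mismatch = 0L) {
  for (s in c(left, right)) {
    if (nchar(s) && grepl(sprintf("[^%s]", paste(names(IUPAC_SETS),
                                                 collapse = "")), s)) {
      .stopf("spaced_pattern: non-IUPAC character in '%s'", s)
    }
  }
  if (max_mismatch < 0) .stopf("spaced_pattern: max_mismatch must be >= 0")
  if (any(spacer_lens < 0)) .stopf("spaced_pattern: spacer lengths must be >= 0")
  structure(list(pattern_id = pattern_id, left = left,
                 spacer_lens = sort(unique(as.integer(spacer_lens))),
                 right = right, max_mismatch = as.integer(max_mismatch)),
            class = "synr_pattern")
}

#' The canonical Firmicutes CodY box as a scan pattern
#'
#' 5'-AATTTTCWGAAAATT with a default tolerance of one mismatch (the
#' tolerance at which the Synergistes/Cloacibacillus consensus, which
#' carries T at the degenerate-adjacent G position, still registers).
#'
#' @param max_mismatch mismatch budget (default 1).
#' @return a `synr_pattern`.
#' @export
canonical_cody_box <- function(max_mismatch = 1L) {
  spaced_pattern("codY_box", "AATTTTCWGAAAATT", 0L, "", max_mismatch)
}

# logical 4 x m matrix: allowed[b, j] for IUPAC pattern string
.iupac_allowed <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  m <- vapply(chars, function(ch) DNA_BASES %in% IUPAC_SETS[[ch]],
              logical(4L))
  matrix(m, nrow = 4L, dimnames = list(DNA_BASES, NULL))
}

# mismatch count of every window of `seq` against an IUPAC pattern;
# sequence N counts as a mismatch unless the pattern column allows all four
.window_mismatches <- function(seq, allowed) {
  m <- ncol(allowed)
  idx <- .encode_dna(seq)
  n <- length(idx)
  if (n < m) return(integer(0L))
  nwin <- n - m + 1L
  mism <- integer(nwin)
  all4 <- colSums(allowed) == 4L
  for (j in seq_len(m)) {
    v <- idx[j:(j + nwin - 1L)]
    viol <- rep(!all4[j], nwin)
    okv <- !is.na(v)
    viol[okv] <- !allowed[cbind(v[okv], j)]
    mism <- mism + as.integer(viol)
  }
  mism
}

.empty_hits <- function() {
  data.frame(sequence_id = character(), offset = integer(),
             strand = character(), pattern_id = character(),
             spacer = integer(), span = integer(), mismatches = integer(),
             score = numeric(), p_value = numeric(), stringsAsFactors = FALSE)
}

# order hits: ascending offset, "+" before "-"
.order_hits <- function(h) {
  h <- h[order(h$offset, match(h$strand, c("+", "-"))), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Scan a sequence with a contiguous IUPAC pattern
#'
#' Both strands are scanned; a window matches when the number of positions
#' violating the pattern's IUPAC class is at most `max_mismatch`. Offsets
#' are 0-based on the forward sequence; hits are returned in ascending
#' offset order with "+" before "-" at equal offset.
#'
#' @param seq DNA string.
#' @param pattern a [spaced_pattern()] with `spacer_lens = 0` and empty
#'   right arm, or a plain IUPAC string.
#' @param max_mismatch overrides the pattern's budget when given.
#' @param sequence_id id attached to hits.
#' @return hit data frame (`sequence_id`, `offset`, `strand`, `pattern_id`,
#'   `spacer`, `span`, `mismatches`, `score`, `p_value`).
#' @export
scan_iupac <- function(seq, pattern, max_mismatch = NULL,
                       sequence_id = "seq") {
  if (is.character(pattern)) {
    pattern <- spaced_pattern(pattern, pattern, 0L, "",
                              max_mismatch %||% 0L)
  } else if (!is.null(max_mismatch)) {
    pattern$max_mismatch <- as.integer(max_mismatch)
  }
  scan_spaced(seq, pattern, sequence_id = sequence_id)
}

#' Scan a sequence with a spaced two-arm pattern
#'
#' For each admissible spacer length `d`, matches `left + N_d + right`
#' under the shared mismatch budget on both strands; spacer bases are
#' unconstrained. A motif span exceeding the sequence yields an empty
#' result, not an error.
#'
#' @param seq DNA string.
#' @param pattern a [spaced_pattern()].
#' @param sequence_id id attached to hits.
#' @return hit data frame as in [scan_iupac()].
#' @export
scan_spaced <- function(seq, pattern, sequence_id = "seq") {
  stopifnot(inherits(pattern, "synr_pattern"))
  L <- nchar(seq)
  rows <- list()
  rc <- .revcomp(seq)
  for (d in pattern$spacer_lens) {
    full <- paste0(pattern$left, strrep("N", d), pattern$right)
    span <- nchar(full)
    if (span > L) next
    allowed <- .iupac_allowed(full)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else rc
      mism <- .window_mismatches(s, allowed)
      hit <- which(mism <= pattern$max_mismatch)
      if (!length(hit)) next
      off <- hit - 1L
      if (strand == "-") off <- L - span - off
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sequence_id, offset = off, strand = strand,
        pattern_id = pattern$pattern_id, spacer = d, span = span,
        mismatches = mism[hit], score = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_hits())
  .order_hits(do.call(rbind, rows))
}

#' Construct a log-odds position weight matrix
#'
#' @param freq 4 x L column-stochastic frequency matrix (rows A,C,G,T).
#' @param background base probabilities (must sum to 1).
#' @param pseudocount fraction of background mixed into each column to keep
#'   log-odds finite (default 0.01; set 0 for already-positive matrices).
#' @param score_scale integer discretisation factor for exact p-values
#'   (default 1000).
#' @return a `synr_pwm` with `matrix` (log2 odds), `background`,
#'   `score_scale`.
#' @export
pwm_model <- function(freq, background = rep(0.25, 4L), pseudocount = 0.01,
                      score_scale = 1000L) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4L) .stopf("pwm_model: freq must have 4 rows (A,C,G,T)")
  if (abs(sum(background) - 1) > 1e-9) {
    .stopf("pwm_model: background must sum to 1")
  }
  if (pseudocount > 0) {
    freq <- sweep(freq, 2L, colSums(freq), "/")
    freq <- (freq + pseudocount * background) / (1 + pseudocount)
  }
  lo <- log2(sweep(freq, 1L, background, "/"))
  if (any(!is.finite(lo))) {
    .stopf("pwm_model: non-finite log-odds; use a positive pseudocount")
  }
  rownames(lo) <- DNA_BASES
  structure(list(matrix = lo, background = stats::setNames(background,
                                                           DNA_BASES),
                 score_scale = as.integer(score_scale)),
            class = "synr_pwm")
}

#' PWM over the full span of a refined dyad model
#'
#' Left arm columns, `spacer` background columns (zero information), right
#' arm columns.
#'
#' @param model a `synr_dyad_model`.
#' @param spacer spacer length (default the model's modal spacer).
#' @param background base probabilities (default the model's background).
#' @param ... passed to [pwm_model()].
#' @return a `synr_pwm`.
#' @export
dyad_pwm <- function(model, spacer = model$spacer_len,
                     background = model$background, ...) {
  bgc <- matrix(rep(as.numeric(background), spacer), nrow = 4L)
  freq <- cbind(model$left_matrix, bgc, model$right_matrix)
  pwm_model(freq, as.numeric(background), ...)
}

# integer column scores of a PWM (discretised log-odds)
.pwm_int <- function(pwm) {
  round(pwm$matrix * pwm$score_scale)
}

#' Exact PWM score distribution under the background
#'
#' Scores are discretised at `score_scale`; the null distribution of the
#' total window score is computed by dynamic programming (convolution of
#' per-column score distributions under the background). The returned tail
#' is monotone non-increasing and the full distribution sums to 1.
#'
#' @param pwm a [pwm_model()].
#' @return a `synr_pwm_table` with `min_score`, `probs` (density over
#'   integer scores `min_score:max_score`), `tail` (upper-tail
#'   probabilities), `score_scale`.
#' @export
pwm_pvalue_table <- function(pwm) {
  k <- .pwm_int(pwm)
  L <- ncol(k)
  bg <- as.numeric(pwm$background)
  lo <- sum(apply(k, 2L, min))
  hi <- sum(apply(k, 2L, max))
  width <- hi - lo + 1L
  probs <- numeric(width)
  # DP over columns; cur[s - cum_lo + 1] = P(partial score == s)
  cur <- 1
  cum_lo <- 0L
  for (j in seq_len(L)) {
    cj <- k[, j]
    new_lo <- cum_lo + min(cj)
    new_hi <- cum_lo + length(cur) - 1L + max(cj)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cum_lo + cj[b] - new_lo
      idxs <- seq_along(cur) + sh
      nxt[idxs] <- nxt[idxs] + cur * bg[b]
    }
    cur <- nxt
    cum_lo <- new_lo
  }
  probs <- cur
  tail <- rev(cumsum(rev(probs)))
  structure(list(min_score = cum_lo, probs = probs, tail = tail,
                 score_scale = pwm$score_scale),
            class = "synr_pwm_table")
}

#' P-value of a discretised PWM score
#' @param table a [pwm_pvalue_table()].
#' @param score_int integer (discretised) window score(s).
#' @return upper-tail probability `P[score >= s]`.
#' @export
pwm_pvalue <- function(table, score_int) {
  i <- score_int - table$min_score + 1L
  i <- pmin(pmax(i, 1L), length(table$tail) + 1L)
  out <- c(table$tail, 0)[i]
  out[score_int < table$min_score] <- 1
  out
}

# integer window scores of a sequence under a PWM; NA windows (with N) get -Inf
.window_scores_int <- function(seq, k_int) {
  m <- ncol(k_int)
  idx <- .encode_dna(seq)
  n <- length(idx)
  if (n < m) return(numeric(0L))
  nwin <- n - m + 1L
  sc <- numeric(nwin)
  for (j in seq_len(m)) {
    v <- idx[j:(j + nwin - 1L)]
    add <- rep(-Inf, nwin)
    okv <- !is.na(v)
    add[okv] <- k_int[cbind(v[okv], j)]
    sc <- sc + add
  }
  sc
}

#' Scan a sequence with a PWM at an exact p-value threshold
#'
#' Both strands; every window whose exact background p-value is at most
#' `p_threshold` is reported.
#'
#' @param seq DNA string.
#' @param pwm a [pwm_model()].
#' @param p_threshold maximum p-value (default 1e-4).
#' @param table precomputed [pwm_pvalue_table()] (computed when `NULL`).
#' @param sequence_id id attached to hits.
#' @return hit data frame as in [scan_iupac()] with `score` (log2 odds) and
#'   `p_value` filled.
#' @export
pwm_scan <- function(seq, pwm, p_threshold = 1e-4, table = NULL,
                     sequence_id = "seq") {
  if (is.null(table)) table <- pwm_pvalue_table(pwm)
  k <- .pwm_int(pwm)
  m <- ncol(k)
  L <- nchar(seq)
  rc <- .revcomp(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    sc <- .window_scores_int(s, k)
    if (!length(sc)) next
    finite <- is.finite(sc)
    pv <- rep(NA_real_, length(sc))
    pv[finite] <- pwm_pvalue(table, sc[finite])
    hit <- which(finite & pv <= p_threshold)
    if (!length(hit)) next
    off <- hit - 1L
    if (strand == "-") off <- L - m - off
    rows[[length(rows) + 1L]] <- data.frame(
      sequence_id = sequence_id, offset = off, strand = strand,
      pattern_id = "pwm", spacer = NA_integer_, span = m,
      mismatches = NA_integer_, score = sc[hit] / pwm$score_scale,
      p_value = pv[hit], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_hits())
  .order_hits(do.call(rbind, rows))
}

#' Scan every promoter of a set with a pattern or PWM
#'
#' @param promoters promoter data frame or named character vector.
#' @param motif a `synr_pattern` or `synr_pwm`.
#' @param p_threshold PWM p-value threshold (default 1e-4).
#' @return combined hit data frame.
#' @export
scan_promoter_set <- function(promoters, motif, p_threshold = 1e-4) {
  seqs <- .promoter_seqs(promoters)
  table <- if (inherits(motif, "synr_pwm")) pwm_pvalue_table(motif)
  rows <- lapply(seq_along(seqs), function(i) {
    if (inherits(motif, "synr_pwm")) {
      pwm_scan(seqs[[i]], motif, p_threshold, table,
               sequence_id = names(seqs)[i])
    } else {
      scan_spaced(seqs[[i]], motif, sequence_id = names(seqs)[i])
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .empty_hits()
  rownames(out) <- NULL
  out
}

#' Classify promoters by canonical-box and extended-palindrome content
#'
#' Each promoter is flagged for the canonical CodY box and for the extended
#' palindromic motif, and assigned to exactly one of the categories
#' `canonical-only`, `extended-only`, `both`, `none` (a partition). The
#' summary reports per-category locus counts; when operons and the gene
#' total are supplied, genes of an operon inherit their leader promoter's
#' classification and the percentage of target genes is reported, otherwise
#' the percentage is over promoters (leaders).
#'
#' @param promoters promoter data frame or named character vector.
#' @param canonical a `synr_pattern` (default [canonical_cody_box()]).
#' @param extended a `synr_pattern` or `synr_pwm` for the extended
#'   palindrome.
#' @param operons operon data frame from [call_operons()] (optional).
#' @param n_genes total annotated genes for the percentage denominator
#'   (optional; defaults to the operon gene total when operons are given).
#' @param p_threshold PWM p-value threshold (default 1e-4).
#' @param bh_qvalues add Benjamini-Hochberg q-values over promoter-level
#'   best PWM p-values (default FALSE).
#' @return list with `classes` (data frame `locus_id`, `has_canonical`,
#'   `has_extended`, `category`) and `summary` (category counts,
#'   `n_promoters`, `n_targets`, `pct_targets`, `denominator`).
#' @export
classify_promoters <- function(promoters, canonical = canonical_cody_box(),
                               extended, operons = NULL, n_genes = NULL,
                               p_threshold = 1e-4, bh_qvalues = FALSE) {
  seqs <- .promoter_seqs(promoters)
  ids <- names(seqs)
  can_hits <- scan_promoter_set(seqs, canonical)
  ext_hits <- scan_promoter_set(seqs, extended, p_threshold)
  has_can <- ids %in% can_hits$sequence_id
  has_ext <- ids %in% ext_hits$sequence_id
  category <- ifelse(has_can & has_ext, "both",
              ifelse(has_can, "canonical-only",
              ifelse(has_ext, "extended-only", "none")))
  classes <- data.frame(locus_id = ids, has_canonical = has_can,
                        has_extended = has_ext, category = category,
                        stringsAsFactors = FALSE)
  if (bh_qvalues && nrow(ext_hits) && !all(is.na(ext_hits$p_value))) {
    best <- tapply(ext_hits$p_value, ext_hits$sequence_id, min)
    q <- stats::p.adjust(best, method = "BH")
    classes$ext_q_value <- as.numeric(q[classes$locus_id])
  }
  counts <- table(factor(category, levels = c("canonical-only",
                                              "extended-only", "both",
                                              "none")))
  if (!is.null(operons)) {
    pos_leaders <- classes$locus_id[classes$category != "none"]
    pos_ops <- unique(operons$operon_id[operons$gene_id %in% pos_leaders &
                                          operons$is_leader])
    n_target <- sum(operons$operon_id %in% pos_ops)
    denom <- if (is.null(n_genes)) nrow(operons) else n_genes
    denominator <- "genes"
  } else {
    n_target <- sum(category != "none")
    denom <- if (is.null(n_genes)) length(ids) else n_genes
    denominator <- "promoters"
  }
  summary <- list(counts = as.list(counts), n_promoters = length(ids),
                  n_targets = n_target,
                  pct_targets = if (denom > 0) 100 * n_target / denom else 0,
                  denominator = denominator)
  list(classes = classes, summary = summary)
}
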