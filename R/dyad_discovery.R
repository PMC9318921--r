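# Spaced-dyad motif discovery: an AT-rich arm, an unconstrained spacer of
# variable length, and the (near) reverse complement of the arm. Candidate
# (arm word, spacer) models are enumerated exhaustively, scored with a
# binomial occurrence test against an order-0 background, and the winner is
# refined into position frequency matrices plus a spacer-length
# distribution by ZOOPS expectation-maximization.

#' Dyad discovery configuration
#'
#' @param arm_len arm length in bases (default 6).
#' @param spacer_min,spacer_max spacer length range searched (default 0-30).
#' @param min_at_fraction minimum A/T fraction for a candidate arm word
#'   (default 5/6: "AT-rich" admits one G/C per 6-mer arm).
#' @param palindrome_mismatch_max maximum mismatches allowed between the
#'   right arm and the reverse complement of the left arm (default 2, the
#'   largest deviation from perfect palindromy observed among the genus
#'   consensus dyads this model targets).
#' @param pseudocount pseudocount for matrix initialisation (default 0.1).
#' @param em_tolerance EM stops when the log-likelihood gain falls below
#'   this (default 1e-6).
#' @param em_max_iter maximum EM iterations (default 200).
#' @param seed integer seed for any stochastic step.
#' @param min_motif_span minimum total motif span `2*arm_len + spacer`
#'   considered (default 15, the minimum site length used for discovery).
#' @return a `synr_dyad_config` list.
#' @export
dyad_config <- function(arm_len = 6L, spacer_min = 0L, spacer_max = 30L,
                        min_at_fraction = 5 / 6,
                        palindrome_mismatch_max = 2L, pseudocount = 0.1,
                        em_tolerance = 1e-6, em_max_iter = 200L, seed = 1L,
                        min_motif_span = 15L) {
  if (spacer_min > spacer_max) .stopf("dyad_config: spacer_min > spacer_max")
  if (min_at_fraction < 0 || min_at_fraction > 1) {
    .stopf("dyad_config: min_at_fraction must be in [0,1]")
  }
  structure(list(arm_len = as.integer(arm_len),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 min_at_fraction = min_at_fraction,
                 palindrome_mismatch_max = as.integer(palindrome_mismatch_max),
                 pseudocount = pseudocount, em_tolerance = em_tolerance,
                 em_max_iter = as.integer(em_max_iter),
                 seed = as.integer(seed),
                 min_motif_span = as.integer(min_motif_span)),
            class = "synr_dyad_config")
}

# promoter argument: data frame with $sequence, or plain character vector
.promoter_seqs <- function(promoters) {
  if (is.data.frame(promoters)) {
    if (!("sequence" %in% names(promoters))) {
      .stopf("promoters data frame needs a 'sequence' column")
    }
    s <- promoters$sequence
    names(s) <- if ("locus_id" %in% names(promoters)) promoters$locus_id
    else sprintf("promoter_%d", seq_along(s))
  } else if (is.character(promoters)) {
    s <- promoters
    if (is.null(names(s))) names(s) <- sprintf("promoter_%d", seq_along(s))
  } else {
    .stopf("promoters must be a data frame or character vector")
  }
  s
}

#' Locate exact arm-word occurrences in a sequence
#'
#' Reports every exact occurrence (overlaps allowed) of any word in
#' `arm_words` or of its reverse complement, in ascending offset order.
#' `sense` is `"forward-arm"` when the matched word is one of `arm_words`
#' (taking precedence) and `"reverse-arm"` when only its reverse complement
#' is.
#'
#' @param seq DNA string.
#' @param arm_words character vector of equal-length arm words.
#' @return data frame with columns `offset` (0-based), `word`, `sense`.
#' @export
find_arms <- function(seq, arm_words) {
  lens <- unique(nchar(arm_words))
  if (length(lens) != 1L) .stopf("find_arms: arm words must share one length")
  k <- lens
  fwd <- unique(arm_words)
  rev <- setdiff(unique(.revcomp(fwd)), fwd)
  codes <- .kmer_codes(seq, k)
  word_of <- c(fwd, rev)
  sense_of <- c(rep("forward-arm", length(fwd)), rep("reverse-arm", length(rev)))
  target <- vapply(word_of, function(w) .kmer_codes(w, k), integer(1L))
  hit <- match(codes, target)
  idx <- which(!is.na(hit))
  data.frame(offset = idx - 1L, word = word_of[hit[idx]],
             sense = sense_of[hit[idx]], stringsAsFactors = FALSE)
}

#' Pair arm occurrences into reverse-complement dyads
#'
#' Every ordered pair of arm occurrences on one sequence in which the
#' right-hand word is within `max_mismatch` mismatches of the reverse
#' complement of the left-hand word, with a non-negative spacer, is
#' reported.
#'
#' @param arms data frame from [find_arms()].
#' @param max_mismatch mismatch tolerance between the right word and the
#'   reverse complement of the left word (default 1).
#' @return data frame with columns `left_offset`, `left_word`,
#'   `right_offset`, `right_word`, `spacer`, `mismatches`.
#' @export
pair_arms <- function(arms, max_mismatch = 1L) {
  out <- data.frame(left_offset = integer(), left_word = character(),
                    right_offset = integer(), right_word = character(),
                    spacer = integer(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  n <- nrow(arms)
  if (n < 2L) return(out)
  k <- nchar(arms$word[1L])
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      spacer <- arms$offset[j] - (arms$offset[i] + k)
      if (spacer < 0L) next
      mm <- .hamming_str(arms$word[j], .revcomp(arms$word[i]))
      if (mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          left_offset = arms$offset[i], left_word = arms$word[i],
          right_offset = arms$offset[j], right_word = arms$word[j],
          spacer = spacer, mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All arm words of a given length passing the A/T-fraction filter
#'
#' @param arm_len word length.
#' @param min_at_fraction minimum fraction of A/T positions.
#' @return character vector of words in lexicographic order.
#' @export
candidate_arm_words <- function(arm_len = 6L, min_at_fraction = 5 / 6) {
  codes <- .candidate_arm_codes(arm_len, min_at_fraction)
  .decode_kmer(codes, arm_len)
}

.candidate_arm_codes <- function(arm_len, min_at_fraction) {
  all_codes <- 0:(4L^arm_len - 1L)
  at <- integer(length(all_codes))
  c0 <- all_codes
  for (j in seq_len(arm_len)) {
    b <- c0 %% 4L
    at <- at + as.integer(b == 0L | b == 3L)  # A=0, T=3
    c0 <- c0 %/% 4L
  }
  all_codes[at / arm_len >= min_at_fraction - 1e-12]
}

# P(random word ~ order-0 bg is within mm mismatches of target word `t`)
# DP over positions with states = mismatches so far.
.ball_prob <- function(target_digits, bg, mm) {
  q <- c(1, rep(0, mm))
  for (j in seq_along(target_digits)) {
    pm <- bg[target_digits[j]]
    qn <- q * pm
    if (mm >= 1L) qn[2:(mm + 1L)] <- qn[2:(mm + 1L)] + q[1:mm] * (1 - pm)
    q <- qn
  }
  sum(q)
}

#' Per-promoter background occurrence probability of a dyad
#'
#' Under an order-0 background estimated from the pooled promoter base
#' frequencies (strand-averaged, so the null is complement-symmetric and
#' double-stranded scans are strand-invariant), the probability that a
#' single site position carries the
#' dyad is `P(left arm exact) * P(right window within `mismatch` of the
#' reverse complement of the arm)`; spacer positions are unconstrained. The
#' per-promoter probability of at least one occurrence is
#' `1 - (1 - p_site)^(2*S)` with `S` valid start positions in a promoter of
#' the median length (factor 2 for the two strands).
#'
#' @param promoters promoter data frame or character vector.
#' @param word left arm word.
#' @param spacer spacer length.
#' @param mismatch palindrome mismatch allowance on the right arm
#'   (default 0, which reduces to the exact product over the `2*arm_len`
#'   specified positions).
#' @return per-promoter occurrence probability `p0` in `[0, 1)`, with
#'   attributes `p_site` and `n_sites`.
#' @export
background_word_prob <- function(promoters, word, spacer, mismatch = 0L) {
  seqs <- .promoter_seqs(promoters)
  if (length(seqs) == 0L) .stopf("background_word_prob: no promoters")
  k <- nchar(word)
  bg <- .base_background(seqs)
  wd <- match(strsplit(word, "")[[1L]], DNA_BASES)
  if (anyNA(wd)) .stopf("background_word_prob: word must be over {A,C,G,T}")
  p_left <- prod(bg[wd])
  rc_digits <- match(strsplit(.revcomp(word), "")[[1L]], DNA_BASES)
  p_right <- .ball_prob(rc_digits, bg, as.integer(mismatch))
  p_site <- p_left * p_right
  span <- 2L * k + as.integer(spacer)
  med_len <- stats::median(nchar(seqs))
  S <- max(0L, as.integer(med_len) - span + 1L)
  p0 <- -expm1(2 * S * log1p(-p_site))
  p0 <- min(max(p0, 0), 1 - 1e-15)
  attr(p0, "p_site") <- p_site
  attr(p0, "n_sites") <- S
  p0
}

#' Binomial significance of a dyad's promoter support
#'
#' Upper-tail binomial probability `P[X >= k | n, p0]`, Bonferroni-scaled by
#' the number of tested (word, spacer) hypotheses and clamped to at most 1.
#'
#' @param k number of supporting promoters.
#' @param n number of promoters.
#' @param p0 per-promoter background occurrence probability.
#' @param m number of tested hypotheses (Bonferroni factor, >= 1).
#' @return p-value in (0, 1].
#' @export
score_dyad_significance <- function(k, n, p0, m = 1L) {
  if (any(k < 0) || any(k > n)) .stopf("score_dyad_significance: need 0 <= k <= n")
  if (any(p0 < 0) || any(p0 > 1)) .stopf("score_dyad_significance: p0 outside [0,1]")
  if (any(m < 1)) .stopf("score_dyad_significance: m must be >= 1")
  tail <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, m * tail)
}

#' Enumerate and rank spaced-dyad models over a promoter set
#'
#' For every arm word passing the A/T filter and every admissible spacer
#' length, counts the promoters containing `word + N_spacer + word'` on
#' either strand, where `word'` lies within `palindrome_mismatch_max`
#' mismatches of the reverse complement of `word`. Each supported model is
#' assigned a Bonferroni-corrected binomial p-value against the order-0
#' background. Models are ranked by ascending p-value, ties broken by
#' higher support, then lexicographic (word, spacer).
#'
#' @param promoters promoter data frame or character vector (non-empty).
#' @param config a [dyad_config()].
#' @return data frame of class `synr_dyad_ranking` with columns `word`,
#'   `spacer`, `support`, `p0`, `p_value`; attributes `n_promoters`,
#'   `n_hypotheses`, `config`.
#' @export
enumerate_dyads <- function(promoters, config = dyad_config()) {
  seqs <- .promoter_seqs(promoters)
  if (length(seqs) == 0L) .stopf("enumerate_dyads: empty promoter set")
  a <- config$arm_len
  mm <- config$palindrome_mismatch_max
  d_lo <- max(config$spacer_min, config$min_motif_span - 2L * a)
  d_hi <- config$spacer_max
  if (d_lo > d_hi) .stopf("enumerate_dyads: no admissible spacer length")
  spacers <- d_lo:d_hi
  cand <- .candidate_arm_codes(a, config$min_at_fraction)
  is_cand <- logical(4L^a)
  is_cand[cand + 1L] <- TRUE
  rc_of <- vapply(0:(4L^a - 1L), .revcomp_code, integer(1L), k = a)

  n <- length(seqs)
  support <- matrix(0L, nrow = 4L^a, ncol = length(spacers))
  for (i in seq_len(n)) {
    strands <- list(.kmer_codes(seqs[[i]], a),
                    .kmer_codes(.revcomp(seqs[[i]]), a))
    for (di in seq_along(spacers)) {
      d <- spacers[di]
      words <- integer(0L)
      for (codes in strands) {
        nw <- length(codes)
        S <- nw - (a + d)
        if (S < 1L) next
        L <- codes[1:S]
        R <- codes[(a + d + 1L):(a + d + S)]
        ok <- !is.na(L) & !is.na(R)
        ok[ok] <- is_cand[L[ok] + 1L]
        if (!any(ok)) next
        Lk <- L[ok]
        Rk <- R[ok]
        hit <- .hamming_codes(Rk, rc_of[Lk + 1L], a) <= mm
        if (any(hit)) words <- c(words, Lk[hit])
      }
      words <- unique(words)
      if (length(words)) {
        support[words + 1L, di] <- support[words + 1L, di] + 1L
      }
    }
  }

  m_hyp <- length(cand) * length(spacers)
  nz <- which(support > 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    out <- data.frame(word = character(), spacer = integer(),
                      support = integer(), p0 = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  } else {
    codes_nz <- nz[, 1L] - 1L
    d_nz <- spacers[nz[, 2L]]
    k_nz <- support[nz]
    bg <- .base_background(seqs)
    med_len <- as.integer(stats::median(nchar(seqs)))
    # p_site per word (independent of spacer), then p0 per (word, spacer)
    u_codes <- sort(unique(codes_nz))
    p_site_u <- vapply(u_codes, function(code) {
      digs <- .kmer_digits(code, a)
      prod(bg[digs]) * .ball_prob(.kmer_digits(rc_of[code + 1L], a), bg, mm)
    }, numeric(1L))
    p_site <- p_site_u[match(codes_nz, u_codes)]
    S <- pmax(0L, med_len - (2L * a + d_nz) + 1L)
    p0 <- pmin(pmax(-expm1(2 * S * log1p(-p_site)), 0), 1 - 1e-15)
    pv <- score_dyad_significance(k_nz, n, p0, m_hyp)
    word <- .decode_kmer(codes_nz, a)
    ord <- order(pv, -k_nz, word, d_nz)
    out <- data.frame(word = word[ord], spacer = d_nz[ord],
                      support = k_nz[ord], p0 = p0[ord], p_value = pv[ord],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_promoters") <- n
  attr(out, "n_hypotheses") <- m_hyp
  attr(out, "config") <- config
  class(out) <- c("synr_dyad_ranking", class(out))
  out
}

# information content (bits, uniform reference) of the right-arm windows
# matched by a (word, spacer) model: one best occurrence per promoter
# (minimal right-arm mismatch, then leftmost, forward strand first)
.right_arm_ic <- function(seqs, word, d, config) {
  a <- nchar(word)
  mm <- config$palindrome_mismatch_max
  rc_of <- vapply(0:(4L^a - 1L), .revcomp_code, integer(1L), k = a)
  wcode <- .kmer_codes(word, a)
  counts <- matrix(0, 4L, a)
  n_used <- 0L
  for (s in seqs) {
    best <- NULL
    for (str_seq in c(s, .revcomp(s))) {
      codes <- .kmer_codes(str_seq, a)
      st <- .dyad_starts(codes, wcode, d, a, mm, rc_of)
      if (!length(st)) next
      mmv <- .hamming_codes(codes[st + a + d], rc_of[wcode + 1L], a)
      i <- st[order(mmv, st)][1L]
      cand <- list(mm = min(mmv), digits = .kmer_digits(codes[i + a + d], a))
      if (is.null(best) || cand$mm < best$mm) best <- cand
    }
    if (is.null(best)) next
    counts[cbind(best$digits, seq_len(a))] <-
      counts[cbind(best$digits, seq_len(a))] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(0)
  f <- counts / n_used
  sum(apply(f, 2L, function(col) {
    2 + sum(ifelse(col > 0, col * log2(col), 0))
  }))
}

#' Discover the best-supported dyad model in a promoter set
#'
#' Runs the exhaustive enumeration, rescores the top-ranked candidates by
#' the information content of their matched right-arm windows (so that a
#' register whose right arm is consistent across promoters beats a shifted
#' register that merely rides on the mismatch tolerance), and refines the
#' selected seed by ZOOPS EM.
#'
#' @param promoters promoter data frame or character vector.
#' @param config a [dyad_config()].
#' @param top_k number of top-ranked enumeration candidates rescored
#'   (default 10).
#' @param refine run the EM refinement (default TRUE; FALSE returns the
#'   selected seed as a degenerate model without matrices).
#' @return a `synr_dyad_model` (see [refine_em()]); with `refine = FALSE`,
#'   the selected ranking row as a one-row data frame.
#' @export
discover_dyads <- function(promoters, config = dyad_config(), top_k = 10L,
                           refine = TRUE) {
  rk <- enumerate_dyads(promoters, config)
  if (nrow(rk) == 0L) .stopf("discover_dyads: no dyad found")
  seqs <- .promoter_seqs(promoters)
  top <- utils::head(rk, top_k)
  ic <- vapply(seq_len(nrow(top)), function(i) {
    .right_arm_ic(seqs, top$word[i], top$spacer[i], config)
  }, numeric(1L))
  sel <- order(-top$support, -ic, seq_len(nrow(top)))[1L]
  seed <- top[sel, , drop = FALSE]
  if (!refine) return(seed)
  refine_em(promoters, seed, config)
}

# exact occurrences of a (word, spacer) dyad in one sequence (one strand):
# left window == word, right window within mm of revcomp(word).
# Returns 1-based left-start positions.
.dyad_starts <- function(codes, wcode, d, a, mm, rc_of) {
  nw <- length(codes)
  S <- nw - (a + d)
  if (S < 1L) return(integer(0L))
  L <- codes[1:S]
  R <- codes[(a + d + 1L):(a + d + S)]
  ok <- !is.na(L) & !is.na(R) & L == wcode
  if (!any(ok)) return(integer(0L))
  pos <- which(ok)
  pos[.hamming_codes(R[pos], rc_of[wcode + 1L], a) <= mm]
}

#' Refine a seed dyad into a probabilistic model by ZOOPS EM
#'
#' Fits a zero-or-one-occurrence-per-sequence mixture in which each
#' promoter either contains no site (probability `1 - gamma`) or one dyad
#' site at a uniformly chosen strand and offset, with spacer length drawn
#' from a weight vector over `[spacer_min, spacer_max]`. Arm columns are
#' multinomial; spacer bases follow the background. Arm matrices are
#' initialised from the seed model's matched occurrences plus a
#' pseudocount; the M-step is maximum likelihood, so the log-likelihood is
#' non-decreasing across iterations.
#'
#' @param promoters promoter data frame or character vector.
#' @param seed_model a row of an [enumerate_dyads()] ranking (or any list
#'   with `word`/`left_arm` and `spacer`/`spacer_len`).
#' @param config a [dyad_config()].
#' @return a `synr_dyad_model` list: `left_matrix`, `right_matrix` (4 x
#'   arm_len column-stochastic), `spacer_weights`, `spacer_len` (modal),
#'   `gamma`, `loglik`, `loglik_trace`, `iterations`, `converged`,
#'   `left_arm`, `right_arm` (column-argmax words), `arm_len`,
#'   `n_promoters`.
#' @export
refine_em <- function(promoters, seed_model, config = dyad_config()) {
  seqs <- .promoter_seqs(promoters)
  if (is.data.frame(seed_model)) seed_model <- as.list(seed_model[1L, ])
  word <- seed_model$word
  if (is.null(word)) word <- seed_model$left_arm
  seed_d <- seed_model$spacer
  if (is.null(seed_d)) seed_d <- seed_model$spacer_len
  if (is.null(word) || is.null(seed_d)) {
    .stopf("refine_em: seed_model needs an arm word and a spacer length")
  }
  a <- nchar(word)
  mm <- config$palindrome_mismatch_max
  pc <- config$pseudocount
  dmin <- config$spacer_min
  dmax <- config$spacer_max
  spacers <- dmin:dmax
  bg <- .base_background(seqs)
  n <- length(seqs)

  rc_of <- vapply(0:(4L^a - 1L), .revcomp_code, integer(1L), k = a)
  wcode <- .kmer_codes(word, a)

  # encoded promoters, both strands
  enc <- lapply(seqs, function(s) {
    list(f = .encode_dna(s), r = .encode_dna(.revcomp(s)))
  })
  codes <- lapply(seqs, function(s) {
    list(f = .kmer_codes(s, a), r = .kmer_codes(.revcomp(s), a))
  })

  # --- initialisation: seed-occurrence counts + pseudocount --------------
  cl <- matrix(pc, 4L, a, dimnames = list(DNA_BASES, NULL))
  cr <- matrix(pc, 4L, a, dimnames = list(DNA_BASES, NULL))
  n_occ <- 0L
  for (i in seq_len(n)) {
    for (str in c("f", "r")) {
      st <- .dyad_starts(codes[[i]][[str]], wcode, seed_d, a, mm, rc_of)
      for (p0s in st) {
        lf <- enc[[i]][[str]][p0s:(p0s + a - 1L)]
        rt <- enc[[i]][[str]][(p0s + a + seed_d):(p0s + 2L * a + seed_d - 1L)]
        if (anyNA(lf) || anyNA(rt)) next
        cl[cbind(lf, seq_len(a))] <- cl[cbind(lf, seq_len(a))] + 1
        cr[cbind(rt, seq_len(a))] <- cr[cbind(rt, seq_len(a))] + 1
        n_occ <- n_occ + 1L
      }
    }
  }
  if (n_occ == 0L) {
    # fall back to the literal seed word
    wd <- match(strsplit(word, "")[[1L]], DNA_BASES)
    cl[cbind(wd, seq_len(a))] <- cl[cbind(wd, seq_len(a))] + 1
    rd <- match(strsplit(.revcomp(word), "")[[1L]], DNA_BASES)
    cr[cbind(rd, seq_len(a))] <- cr[cbind(rd, seq_len(a))] + 1
  }
  fL <- sweep(cl, 2L, colSums(cl), "/")
  fR <- sweep(cr, 2L, colSums(cr), "/")
  lambda <- 0.1 + (spacers == seed_d)
  lambda <- lambda / sum(lambda)
  gamma <- min(max(n_occ / n, 0.1), 0.9)

  log_pbg <- vapply(seqs, function(s) {
    idx <- .encode_dna(s)
    sum(log(bg[idx[!is.na(idx)]]))
  }, numeric(1L))
  const <- sum(log_pbg)

  lens <- nchar(seqs)
  trace <- numeric(0L)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(config$em_max_iter)) {
    oddsL_bg <- log(fL) - log(bg)  # 4 x a, may contain -Inf
    oddsR_bg <- log(fR) - log(bg)

    ll <- const
    cl <- matrix(0, 4L, a, dimnames = list(DNA_BASES, NULL))
    cr <- matrix(0, 4L, a, dimnames = list(DNA_BASES, NULL))
    lam_acc <- numeric(length(spacers))
    gamma_acc <- 0

    for (i in seq_len(n)) {
      Li <- lens[i]
      nwin <- Li - a + 1L
      if (nwin < 1L) {
        ll <- ll + log(1 - gamma)
        next
      }
      per_strand <- list()
      for (str in c("f", "r")) {
        idx <- enc[[i]][[str]]
        # per-window arm odds (product of f/bg over the arm)
        wl <- numeric(nwin)
        wr <- numeric(nwin)
        for (j in seq_len(a)) {
          v <- idx[j:(j + nwin - 1L)]
          okv <- !is.na(v)
          addl <- rep(-Inf, nwin)
          addr <- rep(-Inf, nwin)
          addl[okv] <- oddsL_bg[cbind(v[okv], j)]
          addr[okv] <- oddsR_bg[cbind(v[okv], j)]
          wl <- wl + addl
          wr <- wr + addr
        }
        per_strand[[str]] <- list(el = exp(wl), er = exp(wr))
      }
      # site weights per (strand, d, offset), kept for the count pass
      vlist <- list(f = vector("list", length(spacers)),
                    r = vector("list", length(spacers)))
      tot <- 0
      for (di in seq_along(spacers)) {
        d <- spacers[di]
        S <- Li - (2L * a + d) + 1L
        if (S < 1L) next
        for (str in c("f", "r")) {
          ps <- per_strand[[str]]
          v <- gamma * lambda[di] / (2 * S) *
            ps$el[1:S] * ps$er[(a + d + 1L):(a + d + S)]
          v[!is.finite(v)] <- 0
          if (any(v > 0)) {
            vlist[[str]][[di]] <- v
            tot <- tot + sum(v)
          }
        }
      }
      denom <- (1 - gamma) + tot
      if (!is.finite(denom) || denom <= 0) {
        .stopf("refine_em: non-finite likelihood at iteration %d", iter)
      }
      ll <- ll + log(denom)
      gamma_acc <- gamma_acc + tot / denom
      # collapse posteriors to per-offset arm-start weights, then count
      for (str in c("f", "r")) {
        u <- numeric(nwin)   # left-arm start weight
        rv <- numeric(nwin)  # right-arm start weight
        any_z <- FALSE
        for (di in seq_along(spacers)) {
          v <- vlist[[str]][[di]]
          if (is.null(v)) next
          z <- v / denom
          lam_acc[di] <- lam_acc[di] + sum(z)
          S <- length(z)
          d <- spacers[di]
          u[1:S] <- u[1:S] + z
          rv[(a + d + 1L):(a + d + S)] <- rv[(a + d + 1L):(a + d + S)] + z
          any_z <- TRUE
        }
        if (!any_z) next
        idx <- enc[[i]][[str]]
        for (j in seq_len(a)) {
          v <- idx[j:(j + nwin - 1L)]
          for (b in 1:4) {
            sel <- which(v == b)
            if (length(sel)) {
              cl[b, j] <- cl[b, j] + sum(u[sel])
              cr[b, j] <- cr[b, j] + sum(rv[sel])
            }
          }
        }
      }
    }

    trace <- c(trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < config$em_tolerance) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # --- M-step (maximum likelihood) -------------------------------------
    gamma <- gamma_acc / n
    if (sum(lam_acc) > 0) lambda <- lam_acc / sum(lam_acc)
    csl <- colSums(cl)
    csr <- colSums(cr)
    upd <- csl > 0
    fL[, upd] <- sweep(cl[, upd, drop = FALSE], 2L, csl[upd], "/")
    upd <- csr > 0
    fR[, upd] <- sweep(cr[, upd, drop = FALSE], 2L, csr[upd], "/")
  }

  names(lambda) <- spacers
  modal_d <- spacers[which.max(lambda)]
  structure(list(
    arm_len = a,
    left_matrix = fL, right_matrix = fR,
    spacer_weights = lambda, spacer_len = modal_d,
    gamma = gamma,
    loglik = trace[length(trace)], loglik_trace = trace,
    iterations = iter, converged = converged,
    left_arm = paste(DNA_BASES[apply(fL, 2L, which.max)], collapse = ""),
    right_arm = paste(DNA_BASES[apply(fR, 2L, which.max)], collapse = ""),
    seed_word = word, seed_spacer = as.integer(seed_d),
    support = seed_model$support, p_value = seed_model$p_value,
    n_promoters = n, background = bg, seed = config$seed
  ), class = "synr_dyad_model")
}

#' @export
print.synr_dyad_model <- function(x, ...) {
  cat(sprintf("<synr_dyad_model> %s-N%d-%s  gamma=%.3f  loglik=%.2f (%d iter%s)\n",
              x$left_arm, x$spacer_len, x$right_arm, x$gamma, x$loglik,
              x$iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

.iupac_from_set <- function() {
  m <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""),
              character(1L))
  stats::setNames(names(m), m)
}

#' IUPAC consensus string of a dyad model
#'
#' Per matrix column, the set of bases with frequency at or above
#' `include_threshold` maps to its IUPAC code; an empty set maps to `N`.
#' The spacer is rendered as `N` repeated at the modal spacer length.
#'
#' @param model a `synr_dyad_model` (or any list with `left_matrix`,
#'   `right_matrix`, `spacer_len`).
#' @param include_threshold inclusion threshold (default 0.3).
#' @return IUPAC string `left arm + N*spacer + right arm`.
#' @export
consensus_iupac <- function(model, include_threshold = 0.3) {
  codes <- .iupac_from_set()
  col_code <- function(freq) {
    b <- sort(DNA_BASES[freq >= include_threshold])
    if (length(b) == 0L) return("N")
    codes[[paste(b, collapse = "")]]
  }
  left <- paste(apply(model$left_matrix, 2L, col_code), collapse = "")
  right <- paste(apply(model$right_matrix, 2L, col_code), collapse = "")
  paste0(left, strrep("N", model$spacer_len), right)
}

#' Export a dyad model to JSON
#' @param model a `synr_dyad_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dyad_json <- function(model, path) {
  x <- model
  x$left_matrix <- unclass(as.data.frame(t(x$left_matrix)))
  x$right_matrix <- unclass(as.data.frame(t(x$right_matrix)))
  x$loglik_trace <- NULL
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dyad model from JSON written by [write_dyad_json()]
#' @param path JSON file.
#' @return a `synr_dyad_model`.
#' @export
read_dyad_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$left_matrix <- t(as.matrix(as.data.frame(x$left_matrix)))
  rownames(x$left_matrix) <- DNA_BASES
  x$right_matrix <- t(as.matrix(as.data.frame(x$right_matrix)))
  rownames(x$right_matrix) <- DNA_BASES
  sw <- unlist(x$spacer_weights)
  x$spacer_weights <- sw
  x$background <- stats::setNames(unlist(x$background), DNA_BASES)
  structure(x, class = "synr_dyad_model")
}

#' Export a dyad model in MEME minimal motif format
#'
#' Writes the full-span letter-probability matrix (left arm, spacer columns
#' at background frequencies, right arm) so the refined model can be used
#' by standard motif tools.
#'
#' @param model a `synr_dyad_model`.
#' @param path output file.
#' @param name motif name (default the IUPAC consensus).
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(model, path, name = consensus_iupac(model)) {
  bg <- model$background
  spacer_cols <- matrix(rep(bg, model$spacer_len), nrow = 4L)
  full <- cbind(model$left_matrix, spacer_cols, model$right_matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1L], bg[2L], bg[3L], bg[4L]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
                       ncol(full), max(1L, model$n_promoters %||% 1L),
                       model$p_value %||% 1)), con)
  writeLines(apply(full, 2L, function(col) {
    sprintf("%.6f %.6f %.6f %.6f", col[1L], col[2L], col[3L], col[4L])
  }), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
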