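test_that("the canonical box registers on the printed consensus at 1 mismatch", {
  cons <- synergistes_consensus()
  hits <- scan_iupac(cons, canonical_cody_box(1L))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 0L)
  expect_equal(fwd$mismatches, 1L)  # only position 9 (G vs T) violates
  expect_equal(nrow(scan_iupac(cons, canonical_cody_box(0L))[
    scan_iupac(cons, canonical_cody_box(0L))$strand == "+", , drop = FALSE]),
    0L)
})

test_that("IUPAC scanning handles identity, degeneracy and impossibility", {
  h <- scan_iupac("AATTTTCAGAAAATT", spaced_pattern("p", "AATTTTCWGAAAATT"))
  expect_equal(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(h$offset[h$strand == "+"], 0L)
  expect_equal(nrow(scan_iupac(strrep("G", 30),
                               spaced_pattern("p", "AATTTT", max_mismatch = 5L))),
               0L)
  expect_error(spaced_pattern("p", "AAZTTT"), "non-IUPAC")
})

test_that("spaced scanning matches arms across an unconstrained spacer", {
  cons <- synergistes_consensus()
  pat <- spaced_pattern("outer", "AAAATT", 15L, "AATTTT")
  h <- scan_spaced(cons, pat)
  expect_true(any(h$offset == 9L & h$strand == "+"))

  lit <- paste0("AATATT", random_dna(21), "AAAATA")
  expect_equal(nrow(scan_spaced(lit, spaced_pattern("t", "AATATT", 21L,
                                                    "AAAATA"))[
    scan_spaced(lit, spaced_pattern("t", "AATATT", 21L, "AAAATA"))$strand == "+",
    , drop = FALSE]), 1L)
  # spacer length is exact
  expect_equal(nrow(scan_spaced(lit, spaced_pattern("t", "AATATT", 20L,
                                                    "AAAATA"))), 0L)
  # span exceeding the sequence is empty, not an error
  expect_equal(nrow(scan_spaced("AATATT", spaced_pattern("t", "AATATT", 21L,
                                                         "AAAATA"))), 0L)
})

test_that("PWM p-value table equals exhaustive enumeration of 4^6 words", {
  set.seed(11)
  freq <- matrix(stats::runif(24), 4, 6)
  freq <- sweep(freq, 2, colSums(freq), "/")
  bg <- c(0.3, 0.2, 0.2, 0.3)
  pwm <- pwm_model(freq, bg, pseudocount = 0)
  tab <- pwm_pvalue_table(pwm)
  expect_equal(sum(tab$probs), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$tail) <= 1e-12))
  k <- round(pwm$matrix * pwm$score_scale)
  grid <- as.matrix(expand.grid(rep(list(1:4), 6)))
  scores <- apply(grid, 1, function(w) sum(k[cbind(w, 1:6)]))
  wprob <- apply(grid, 1, function(w) prod(bg[w]))
  for (s in quantile(scores, c(0, 0.25, 0.5, 0.75, 1))) {
    expect_equal(pwm_pvalue(tab, s), sum(wprob[scores >= s]),
                 tolerance = 1e-9)
  }
})

test_that("a unique max-scoring word has p-value (1/4)^6 at uniform background", {
  freq <- matrix(0.05, 4, 6)
  for (j in 1:6) freq[((j - 1) %% 4) + 1, j] <- 0.85
  pwm <- pwm_model(freq, rep(0.25, 4), pseudocount = 0)
  tab <- pwm_pvalue_table(pwm)
  max_s <- sum(apply(round(pwm$matrix * pwm$score_scale), 2, max))
  expect_equal(pwm_pvalue(tab, max_s), 0.25^6, tolerance = 1e-12)
  h <- pwm_scan("ACGTAC", pwm, p_threshold = 1e-3)
  expect_equal(nrow(h), 1L)
  expect_equal(h$p_value, 0.25^6, tolerance = 1e-12)
  expect_equal(nrow(pwm_scan("ACGTAC", pwm, p_threshold = 0)), 0L)
})

test_that("PWM scan equals the exhaustive-window oracle on short sequences", {
  set.seed(21)
  freq <- matrix(stats::runif(24), 4, 6)
  freq <- sweep(freq, 2, colSums(freq), "/")
  pwm <- pwm_model(freq, rep(0.25, 4), pseudocount = 0)
  tab <- pwm_pvalue_table(pwm)
  k <- round(pwm$matrix * pwm$score_scale)
  score_word <- function(w) {
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    sum(k[cbind(idx, seq_along(idx))])
  }
  for (rep in 1:15) {
    s <- random_dna(sample(8:30, 1))
    L <- nchar(s)
    oracle <- list()
    for (strand in c("+", "-")) {
      str_seq <- if (strand == "+") s else reverse_complement(s)
      for (o in 0:(L - 6)) {
        sc <- score_word(substr(str_seq, o + 1, o + 6))
        p <- pwm_pvalue(tab, sc)
        if (p <= 0.01) {
          off <- if (strand == "+") o else L - 6 - o
          oracle[[length(oracle) + 1]] <- sprintf("%d%s", off, strand)
        }
      }
    }
    got <- pwm_scan(s, pwm, p_threshold = 0.01, tab)
    expect_setequal(sprintf("%d%s", got$offset, got$strand),
                    as.character(unlist(oracle)))
  }
})

test_that("hits are strand-symmetric under reverse complementation", {
  pat <- spaced_pattern("t", "AATATT", 21L, "AAAATA", max_mismatch = 1L)
  set.seed(5)
  for (rep in 1:5) {
    s <- paste0(random_dna(40), "AATATT", random_dna(21), "AAAATA",
                random_dna(40))
    h <- scan_spaced(s, pat)
    h_rc <- scan_spaced(reverse_complement(s), pat)
    L <- nchar(s)
    mirrored <- sprintf("%d%s", L - h$span - h$offset,
                        ifelse(h$strand == "+", "-", "+"))
    expect_setequal(sprintf("%d%s", h_rc$offset, h_rc$strand), mirrored)
  }
})

test_that("promoter classification partitions and matches planted truth", {
  set.seed(13)
  n <- 100L
  proms <- data.frame(locus_id = sprintf("L%03d", 1:n),
                      sequence = vapply(1:n, function(i) random_dna(400, 0.56),
                                        character(1)),
                      stringsAsFactors = FALSE)
  canonical_site <- "AATTTTCAGAAAATT"
  extended <- spaced_pattern("ext", "AATATT", 21L, "AAAATA")
  put <- function(i, site, at) {
    substr(proms$sequence[i], at + 1, at + nchar(site)) <<- site
  }
  for (i in 1:10) put(i, canonical_site, 50)                       # canonical only
  for (i in 11:15) put(i, paste0("AATATT", random_dna(21), "AAAATA"), 120)
  for (i in 16:17) {                                               # both
    put(i, canonical_site, 50)
    put(i, paste0("AATATT", random_dna(21), "AAAATA"), 200)
  }
  cl <- classify_promoters(proms, canonical_cody_box(), extended)
  counts <- cl$summary$counts
  expect_equal(counts[["canonical-only"]], 10L)
  expect_equal(counts[["extended-only"]], 5L)
  expect_equal(counts[["both"]], 2L)
  expect_equal(cl$summary$pct_targets, 17)
  # partition property
  expect_equal(Reduce(`+`, counts), n)
  expect_equal(sum(cl$classes$category == "none"), counts[["none"]])
  # nothing planted
  none <- classify_promoters(proms[30:40, ], canonical_cody_box(), extended)
  expect_equal(none$summary$n_targets, 0L)
  expect_equal(none$summary$pct_targets, 0)
})

test_that("classification categories always partition random promoter sets", {
  extended <- spaced_pattern("ext", "AATTTT", 15L, "AAAATT", max_mismatch = 1L)
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    proms <- vapply(1:n, function(i) random_dna(200, runif(1, 0.3, 0.6)),
                    character(1))
    names(proms) <- sprintf("P%d", 1:n)
    cl <- classify_promoters(proms, canonical_cody_box(), extended)
    expect_equal(Reduce(`+`, cl$summary$counts), n)
    expect_true(all((cl$classes$category == "both") ==
                      (cl$classes$has_canonical & cl$classes$has_extended)))
  }
})

test_that("planted-fraction estimates stay in the exact binomial 99% band", {
  dyad <- genus_dyads()$synergistes
  pat <- spaced_pattern("ext", dyad$left, dyad$spacer, dyad$right)
  n <- 40L
  frac <- 0.3
  lo <- qbinom(0.005, n, frac)
  hi <- qbinom(0.995, n, frac)
  for (seed in 1:10) {
    pl <- plant_case(dyad, seed = 300 + seed, n = n, fraction = frac)
    cl <- classify_promoters(pl$promoters, canonical_cody_box(0L), pat)
    est <- sum(cl$classes$has_extended)
    expect_gte(est, lo)
    expect_lte(est, hi)
  }
})

test_that("a PWM built from a refined dyad classifies planted promoters", {
  dyad <- genus_dyads()$synergistes
  pl <- plant_case(dyad, seed = 404, n = 15)
  m <- refine_em(pl$promoters, list(word = dyad$left, spacer = dyad$spacer),
                 dyad_config())
  pwm <- dyad_pwm(m)
  cl <- classify_promoters(pl$promoters, canonical_cody_box(), pwm,
                           p_threshold = 1e-4)
  expect_equal(sum(cl$classes$has_extended), 15L)
})
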