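test_that("find_arms locates the three AT-rich arms of the consensus", {
  cons <- synergistes_consensus()
  arms <- find_arms(cons, c("AATTTT", "AAAATT"))
  expect_equal(nrow(arms), 3L)
  expect_equal(arms$offset, c(0L, 9L, 30L))

  expect_equal(nrow(find_arms("GGGGGGGG", c("AATTTT", "AAAATT"))), 0L)

  tandem <- find_arms("AATTTTAATTTT", "AATTTT")
  expect_equal(tandem$offset[tandem$sense == "forward-arm"], c(0L, 6L))

  expect_error(find_arms(cons, c("AATTTT", "AAAAT")), "one length")
})

test_that("pair_arms finds the two reverse-complement pairs, outer spacer 15", {
  arms <- find_arms(synergistes_consensus(), c("AATTTT", "AAAATT"))
  pairs <- pair_arms(arms)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$spacer, c(3L, 15L))
  outer <- pairs[pairs$spacer == 15L, ]
  expect_equal(outer$left_word, "AAAATT")
  expect_equal(outer$right_word, "AATTTT")
  expect_equal(outer$left_offset, 9L)
})

test_that("candidate arm words respect the A/T-fraction filter", {
  w <- candidate_arm_words(6, 5 / 6)
  expect_length(w, 448L)  # 64 pure-AT + 6*64 single-GC words
  expect_true("AATTTT" %in% w && "ATTTTC" %in% w)
  expect_false("AACCTT" %in% w)
})

test_that("background word probability matches closed forms", {
  uniform <- vapply(1:8, function(i) random_dna(100, gc = 0.5), character(1))
  p0 <- background_word_prob(uniform, "AATTTT", 3, mismatch = 0)
  raw <- table(factor(strsplit(paste(uniform, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T"))) / (8 * 100)
  bg <- c(A = (raw[["A"]] + raw[["T"]]) / 2, C = (raw[["C"]] + raw[["G"]]) / 2,
          G = (raw[["C"]] + raw[["G"]]) / 2, T = (raw[["A"]] + raw[["T"]]) / 2)
  p_site_exp <- prod(bg[strsplit("AATTTT", "")[[1]]]) *
    prod(bg[strsplit("AAAATT", "")[[1]]])
  expect_equal(attr(p0, "p_site"), unname(p_site_exp), tolerance = 1e-12)

  # uniform composition: p_site = (1/4)^12 for any exact 12-base dyad
  u <- strrep("ACGT", 25)
  p0u <- background_word_prob(u, "AATTTT", 3, mismatch = 0)
  expect_equal(attr(p0u, "p_site"), 0.25^12, tolerance = 1e-12)

  # pure-GC background with AT-only arms: zero
  p0gc <- background_word_prob(strrep("GC", 200), "AATTTT", 3)
  expect_equal(as.numeric(p0gc), 0)

  # single promoter of exactly the motif span: p0 = 2p - p^2
  span_seq <- random_dna(15, gc = 0.5)
  p1 <- background_word_prob(span_seq, "AATTTT", 3, mismatch = 0)
  ps <- attr(p1, "p_site")
  expect_equal(attr(p1, "n_sites"), 1L)
  expect_equal(as.numeric(p1), 2 * ps - ps^2, tolerance = 1e-12)

  # mismatch ball enlarges the null probability
  p_mm <- background_word_prob(uniform, "AATTTT", 3, mismatch = 2)
  expect_gt(attr(p_mm, "p_site"), attr(p0, "p_site"))
})

test_that("dyad significance equals the direct binomial summation", {
  expect_equal(score_dyad_significance(0, 10, 0.1), 1.0)
  expect_equal(score_dyad_significance(10, 10, 0.3, m = 1), 0.3^10)
  direct <- sum(vapply(3:10, function(j) choose(10, j) * 0.1^j * 0.9^(10 - j),
                       numeric(1)))
  expect_equal(score_dyad_significance(3, 10, 0.1, m = 1), direct,
               tolerance = 1e-12)
  expect_equal(score_dyad_significance(1, 5, 0.5, m = 100), 1.0)  # clamped
  expect_error(score_dyad_significance(-1, 10, 0.1), "k")
  expect_error(score_dyad_significance(2, 10, 1.5), "p0")
})

test_that("enumeration on the printed consensus contains both dyads", {
  rk <- enumerate_dyads(synergistes_consensus(), dyad_config())
  key <- paste(rk$word, rk$spacer)
  expect_true("AATTTT 3" %in% key)
  expect_true("AAAATT 15" %in% key)
  # pure G/C promoters yield an empty ranking
  empty <- enumerate_dyads(rep(strrep("GC", 100), 3), dyad_config())
  expect_equal(nrow(empty), 0L)
  expect_error(enumerate_dyads(character(0)), "empty")
})

test_that("enumeration is deterministic and strand-symmetric", {
  pl <- plant_case(genus_dyads()$synergistes, seed = 91)
  rk1 <- enumerate_dyads(pl$promoters, dyad_config())
  rk2 <- enumerate_dyads(pl$promoters, dyad_config())
  expect_identical(rk1, rk2)
  rc_proms <- reverse_complement(pl$promoters$sequence)
  rk_rc <- enumerate_dyads(rc_proms, dyad_config())
  expect_identical(as.data.frame(rk1), as.data.frame(rk_rc))
})

test_that("discovery recovers each planted genus dyad across seeds", {
  dyads <- genus_dyads()
  for (nm in names(dyads)) {
    hits <- 0L
    for (seed in 1:20) {
      pl <- plant_case(dyads[[nm]], seed = seed * 7L)
      top <- discover_dyads(pl$promoters, dyad_config(), refine = FALSE)
      if (matches_planted(top$word, top$spacer, dyads[[nm]])) hits <- hits + 1L
    }
    expect_gte(hits, 19L)  # >= 95% of 20 replicates
  }
})

test_that("background-only promoter sets rarely reach significance", {
  n_sig <- 0L
  m_total <- 0L
  for (seed in 1:50) {
    bg <- gen_background(synthetic_spec(20, 200, gc = 0.5, seed = 5000 + seed))
    rk <- enumerate_dyads(bg, dyad_config())
    n_sig <- n_sig + sum(rk$p_value < 0.05)
    m_total <- m_total + attr(rk, "n_hypotheses")
  }
  expect_lte(n_sig / m_total, 0.05)
})

test_that("EM refinement recovers a noiseless planted dyad", {
  cfg <- dyad_config(spacer_min = 0, spacer_max = 10, seed = 3)
  bg <- gen_background(synthetic_spec(12, 200, gc = 0.5, seed = 31))
  pl <- plant_dyad(bg, "AATTTT", 5, "AAAATT", 1.0, seed = 32)
  m <- refine_em(pl$promoters, list(word = "AATTTT", spacer = 5L), cfg)
  expect_true(m$converged)
  expect_equal(m$spacer_len, 5L)
  wl <- strsplit("AATTTT", "")[[1]]
  wr <- strsplit("AAAATT", "")[[1]]
  for (j in 1:6) {
    expect_gte(m$left_matrix[wl[j], j], 0.9)
    expect_gte(m$right_matrix[wr[j], j], 0.9)
  }
  # frequency columns are stochastic
  expect_equal(colSums(m$left_matrix), rep(1, 6), tolerance = 1e-9)
  expect_equal(sum(m$spacer_weights), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood never decreases, on varied random inputs", {
  cfg <- dyad_config(spacer_min = 0, spacer_max = 8, em_max_iter = 25,
                     seed = 1)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    len <- sample(80:150, 1)
    gc <- runif(1, 0.3, 0.7)
    proms <- vapply(seq_len(n), function(i) random_dna(len, gc), character(1))
    if (rep %% 2 == 0) {  # half the fixtures carry a partial signal
      pl <- plant_dyad(data.frame(locus_id = as.character(seq_len(n)),
                                  sequence = proms, stringsAsFactors = FALSE),
                       "AAATTT", 4, "AAATTT", 0.5, seed = rep)
      proms <- pl$promoters$sequence
    }
    m <- refine_em(proms, list(word = "AAATTT", spacer = 4L), cfg)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("EM is deterministic for a fixed seed", {
  pl <- plant_case(genus_dyads()$synergistes, seed = 55)
  cfg <- dyad_config(seed = 9)
  m1 <- refine_em(pl$promoters, list(word = "AATTTT", spacer = 15L), cfg)
  m2 <- refine_em(pl$promoters, list(word = "AATTTT", spacer = 15L), cfg)
  expect_identical(m1$left_matrix, m2$left_matrix)
  expect_identical(m1$spacer_weights, m2$spacer_weights)
  expect_identical(m1$loglik_trace, m2$loglik_trace)
})

test_that("IUPAC consensus maps column base sets to degeneracy codes", {
  mk <- function(cols) {
    m <- do.call(cbind, cols)
    rownames(m) <- c("A", "C", "G", "T")
    m
  }
  model <- list(
    left_matrix = mk(list(c(0, 0.5, 0.5, 0),    # S
                          c(1, 0, 0, 0),        # A
                          c(0.28, 0.26, 0.24, 0.22))),  # none -> N
    right_matrix = mk(list(c(0.5, 0, 0, 0.5))), # W
    spacer_len = 2L)
  expect_equal(consensus_iupac(model), "SANNNW")
})

test_that("dyad models round-trip through JSON and export MEME format", {
  pl <- plant_case(genus_dyads()$synergistes, seed = 77, n = 10)
  m <- refine_em(pl$promoters, list(word = "AATTTT", spacer = 15L),
                 dyad_config())
  f <- withr::local_tempfile(fileext = ".json")
  write_dyad_json(m, f)
  m2 <- read_dyad_json(f)
  expect_equal(m2$left_matrix, m$left_matrix, tolerance = 1e-12)
  expect_equal(m2$spacer_len, m$spacer_len)
  expect_equal(consensus_iupac(m2), consensus_iupac(m))
  meme <- withr::local_tempfile(fileext = ".txt")
  write_meme_minimal(m, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
  expect_equal(sum(grepl("^[0-9.]+ [0-9.]+ [0-9.]+ [0-9.]+$", lines)),
               12L + m$spacer_len)
})
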