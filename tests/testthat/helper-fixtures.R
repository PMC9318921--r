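# Shared fixtures, all built in code.

# The 36-base Synergistes/Cloacibacillus consensus; position 18 is the
# degenerate S (C/G), instantiated as C for sequence-level tests (it lies
# in the spacer, outside every arm).
synergistes_consensus <- function(instantiate = TRUE) {
  cons <- "AATTTTCTTAAAATTTCSCTTGATATTTACAATTTT"
  if (instantiate) gsub("S", "C", cons, fixed = TRUE) else cons
}

# the four genus dyads (degenerate positions instantiated by the
# lexicographically-first IUPAC expansion: Y -> C, W -> A)
genus_dyads <- function() {
  list(
    synergistes      = list(left = "AATTTT", spacer = 15L, right = "AAAATT"),
    thermanaerovibrio = list(left = "AATATT", spacer = 21L, right = "AAAATA"),
    pyramidobacter   = list(left = "ATTTTC", spacer = 14L, right = "AAAAAT"),
    acetomicrobium   = list(left = "AATTTT", spacer = 12L, right = "ATAATT"))
}

# a planted promoter set under the standard simulation conditions
plant_case <- function(dyad, seed, n = 20L, len = 400L, gc = 0.5,
                       fraction = 1.0) {
  bg <- gen_background(synthetic_spec(n, len, gc = gc, seed = seed))
  plant_dyad(bg, dyad$left, dyad$spacer, dyad$right, fraction,
             seed = seed + 10000L)
}

# a discovered dyad matches a planted one up to strand orientation
matches_planted <- function(word, spacer, dyad) {
  rev_left <- reverse_complement(dyad$right)
  spacer == dyad$spacer && word %in% c(dyad$left, rev_left)
}

# tiny two-contig genome with hand-placed genes
toy_genome <- function() {
  c1 <- paste(rep("ACGT", 300), collapse = "")   # 1200 bp
  c2 <- paste(rep("TTGCA", 100), collapse = "")  # 500 bp
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    contig_id = c("c1", "c1", "c1", "c2"),
    start = c(100L, 510L, 900L, 50L),
    end = c(400L, 800L, 1100L, 300L),
    strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  genome(c(c1 = c1, c2 = c2), genes)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
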