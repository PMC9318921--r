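# Internal sequence utilities shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed-base membership over A,C,G,T (row order DNA_BASES)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# complement map covering the full IUPAC alphabet
IUPAC_COMPLEMENT_FROM <- "ACGTMRWSYKVHDBN"
IUPAC_COMPLEMENT_TO   <- "TGCAKYWSRMBDHVN"

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.reverse_chars <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# reverse complement over the IUPAC alphabet; no validation (internal)
.revcomp <- function(x) {
  .reverse_chars(chartr(IUPAC_COMPLEMENT_FROM, IUPAC_COMPLEMENT_TO, x))
}

#' Reverse complement of a DNA sequence
#'
#' Strict `{A,C,G,T,N}` alphabet; `N` maps to `N`. Vectorised over `seq`.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AATTTT") # "AAAATT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) .stopf("reverse_complement: 'seq' must be character")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    .stopf("reverse_complement: non-{A,C,G,T,N} character in sequence %d",
           which(bad)[1L])
  }
  .revcomp(seq)
}

# encode a DNA string as integers A=1,C=2,G=3,T=4; anything else NA
.encode_dna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  m
}

# integer code of every k-mer window (base-4, A=0..T=3), NA where a window
# contains a non-ACGT character; returns integer vector of length n - k + 1
.kmer_codes <- function(seq, k) {
  idx <- .encode_dna(seq) - 1L
  n <- length(idx)
  if (n < k) return(integer(0L))
  nw <- n - k + 1L
  code <- integer(nw)
  nas <- logical(nw)
  for (j in seq_len(k)) {
    v <- idx[j:(j + nw - 1L)]
    nas <- nas | is.na(v)
    v[is.na(v)] <- 0L
    code <- code * 4L + v
  }
  code[nas] <- NA_integer_
  code
}

# decode base-4 k-mer code to string
.decode_kmer <- function(code, k) {
  out <- character(length(code))
  for (i in seq_along(code)) {
    c0 <- code[i]
    b <- integer(k)
    for (j in k:1) {
      b[j] <- c0 %% 4L
      c0 <- c0 %/% 4L
    }
    out[i] <- paste(DNA_BASES[b + 1L], collapse = "")
  }
  out
}

# base-4 digits (1-based base indices) of a k-mer code, leftmost first
.kmer_digits <- function(code, k) {
  d <- integer(k)
  for (j in k:1) {
    d[j] <- code %% 4L
    code <- code %/% 4L
  }
  d + 1L
}

# code of the reverse complement of a k-mer code
.revcomp_code <- function(code, k) {
  rc <- 0L
  for (j in seq_len(k)) {
    b <- code %% 4L         # rightmost remaining digit
    rc <- rc * 4L + (3L - b) # complement, appended -> reversal
    code <- code %/% 4L
  }
  rc
}

# Hamming distance between equal-length k-mer codes (vectorised)
.hamming_codes <- function(a, b, k) {
  d <- integer(length(a))
  for (j in seq_len(k)) {
    d <- d + as.integer(a %% 4L != b %% 4L)
    a <- a %/% 4L
    b <- b %/% 4L
  }
  d
}

.hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# run code with a local RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .stopf("seed must be a single integer")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# pooled mononucleotide background of a character vector of sequences,
# named numeric over A,C,G,T (N ignored); strand-averaged by default so
# double-stranded scans see a complement-symmetric null; uniform fallback
# for empty input
.base_background <- function(seqs, symmetrize = TRUE) {
  tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                      levels = DNA_BASES))
  tot <- sum(tab)
  if (tot == 0L) {
    p <- rep(0.25, 4L)
  } else {
    p <- as.numeric(tab) / tot
  }
  if (symmetrize) {
    p <- c((p[1L] + p[4L]) / 2, (p[2L] + p[3L]) / 2,
           (p[2L] + p[3L]) / 2, (p[1L] + p[4L]) / 2)
  }
  names(p) <- DNA_BASES
  p
}
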