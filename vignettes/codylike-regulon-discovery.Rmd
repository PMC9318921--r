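---
title: "Discovering CodY-like regulons from spaced palindromic dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering CodY-like regulons from spaced palindromic dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synregulon)
```

## The problem

CodY is the master nutritional regulator of Firmicutes: a GAF domain senses
branched-chain amino acids and GTP, and a winged helix-turn-helix (wHTH)
domain represses target promoters through the palindromic CodY box
5'-AATTTTCWGAAAATT. Because CodY is the only known protein that carries
both a GAF and a wHTH domain, that architecture alone is a usable search
criterion in phyla far outside Firmicutes. In the Gram-negative phylum
Synergistetes, CodY-like proteins recognise a different but related
operator: two AT-rich ~6-base arms, one the reverse complement of the
other, separated by an unconstrained spacer whose length varies by genus
(for example `AATATT-N21-AAAATA` in *Thermanaerovibrio* and
`AATTTT-N15-AAAATT` in *Synergistes*/*Cloacibacillus*).

`synregulon` implements the full inference chain for such regulons:

1. **Domain screen** — nominate CodY-like proteins from HMMER per-domain
   tables (`parse_domtblout()`, `screen_cooccurrence()`).
2. **Promoter extraction** — operon-aware upstream windows from
   FASTA + GFF3 (`call_operons()`, `build_promoter_set()`).
3. **Dyad discovery** — find the spaced palindromic motif in a promoter set
   (`enumerate_dyads()`, `discover_dyads()`, `refine_em()`).
4. **Genome-wide scan** — classify every promoter by canonical-box /
   extended-palindrome content (`scan_spaced()`, `pwm_scan()`,
   `classify_promoters()`).
5. **Enrichment** — count motif-positive genes per functional category and
   report `log2(N + 1)` (`tabulate_regulon()`, `enrichment_matrix()`).

A seeded synthetic-data module (`gen_background()`, `plant_dyad()`,
`gen_synthetic_genome()`, `gen_domtblout_fixture()`) generates every input
the pipeline consumes, so all stages are testable without downloads.

## The dyad model

A dyad is a triple `(w, d, w')`: a left arm word `w` of length `a`
(default 6), an unconstrained spacer of length `d`, and a right arm `w'`
close to the reverse complement of `w`. Discovery proceeds in three steps.

### Enumeration

For every arm word with A/T fraction at least 5/6 (448 candidate 6-mers)
and every spacer `d` such that the total span `2a + d` is at least the
minimum site length of 15 and `d` is within the configured range (default
0-30), `enumerate_dyads()` counts the promoters that contain
`w + N_d + w'` on either strand, where `w'` may deviate from
`revcomp(w)` by at most `palindrome_mismatch_max` positions.

Two tolerances deserve comment, because the field's printed consensus
sequences force them:

* **"AT-rich" = at least 5 of 6 positions.** This admits arms such as
  `ATTTTC` (one C) while excluding GC-balanced words.
* **Palindrome tolerance default 2.** The genus dyads are *near*
  palindromes: `ATTTTC/AAAAAT` deviates by one position, and
  `AATATT/AAAATA` by two (`revcomp(AATATT)` is `AATATT` itself, which
  differs from `AAAATA` at two positions). A tolerance of 1 would make the
  two-mismatch genus dyad undiscoverable in principle, so the discovery
  default is 2. The `pair_arms()` helper, which annotates arm pairs inside
  a single already-known consensus, keeps the stricter tolerance of 1: at
  tolerance 2 the two identical outer arms of the 36-base consensus
  (`AATTTT ... AATTTT`, mutual distance 2 from palindromy) would pair with
  each other, which is not how that consensus is read.

### Significance

Support is tested against an order-0 background estimated from the pooled
promoter base frequencies and **strand-averaged**
(`P(A)=P(T)`, `P(C)=P(G)`), so a double-stranded scan has an exactly
strand-invariant null. The single-position site probability is

```
p_site = P(left window = w) * P(right window within mm of revcomp(w))
```

where the second factor sums the order-0 probabilities over the Hamming
ball — this matters: ignoring the mismatch allowance would make the test
anti-conservative. The per-promoter occurrence probability is
`p0 = 1 - (1 - p_site)^(2S)` (computed via `expm1`/`log1p` for accuracy),
with `S` valid starts in a promoter of the median length and the factor 2
for the two strands. The support `k` out of `n` promoters is then scored
with the exact binomial upper tail `P[X >= k | n, p0]`, Bonferroni-scaled
by the number of (word, spacer) hypotheses. Rankings are totally ordered:
ascending p-value, then higher support, then lexicographic `(w, d)`.

### Seed selection and the shifted-register problem

A planted dyad with a self-complementary arm creates *shadow models*: for
`AATATT-N21-AAAATA`, the model `(AATATT, 23)` also matches every planted
promoter, because its right window covers four planted bases plus two free
positions that the two-mismatch budget absorbs. Shadows tie the true
register on support and can edge it out on p-value (longer spans have
fewer possible starts, hence slightly smaller `p0`). Binary
occurrence-counting cannot distinguish them — but the *consistency* of the
matched right arms can: in the true register the right windows are the
same word in every promoter; in a shadow register some columns are random.
`discover_dyads()` therefore rescores the top-ranked candidates by the
information content (bits, uniform reference) of their matched right-arm
windows and selects the most informative one before refinement, the same
idea MEME uses to pick EM starting points.

Dyads on double-stranded DNA have no intrinsic orientation: the model
`(w, d, w')` and its reverse representation `(revcomp(w'), d, revcomp(w))`
describe the same physical site. The ranking anchors the exact arm on
either strand, so a planted dyad may surface in its reverse
representation; tests and downstream comparisons treat the two-member
orientation class as one motif.

### ZOOPS-EM refinement

`refine_em()` fits a zero-or-one-occurrence-per-sequence mixture: a
promoter has no site with probability `1 - gamma`, or one site at a
uniformly chosen strand and offset with spacer length drawn from a weight
vector over the configured range. Arm columns are independent multinomials;
spacer bases follow the background. Arm matrices are initialised from the
seed model's matched occurrences plus a pseudocount (default 0.1); the
M-step is pure maximum likelihood, so the log-likelihood is monotone
non-decreasing — a property the test suite asserts on every fixture.
Iteration stops when the gain drops below `em_tolerance` (default 1e-6) or
after `em_max_iter` (default 200) iterations. The procedure is
deterministic given the configuration, and the modal spacer weight is
reported as the refined spacer length. `consensus_iupac()` renders the
matrices as a degenerate string: per column, the set of bases at frequency
`>= 0.3` maps to its IUPAC code, and the spacer is written as `N` repeated.

## Scanning and classification

Two scan modes mirror the two ways a consensus can be used:

* **IUPAC / spaced patterns** (`scan_iupac()`, `scan_spaced()`): degenerate
  strings with a shared mismatch budget across both arms; spacer positions
  are unconstrained. The canonical CodY box is scanned at 1 mismatch by
  default — the 15-base box variant carried by the Synergistetes consensus
  differs from the Firmicutes box at exactly one position — while 6-base
  arms default to 0 mismatches.
* **PWM log-odds** (`pwm_model()`, `pwm_scan()`): matrices in log2
  odds-to-background, scores discretised at 1/1000, and *exact* p-values
  from a dynamic-programming convolution of per-column score distributions
  under the background. The default report threshold is p <= 1e-4, the
  conventional default for this kind of scan. The table is validated in
  tests against exhaustive enumeration of all 4^6 words.

`classify_promoters()` assigns each operon-leader promoter to exactly one
of `canonical-only`, `extended-only`, `both`, `none` — a partition the
tests assert invariantly. Percentages can be reported over two
denominators: promoters (leaders) when no operon table is supplied, or all
annotated genes when it is, in which case every gene of an operon inherits
its leader's classification. Multiple-testing correction is *not* applied
to classification (existence of a hit is the criterion); Benjamini-
Hochberg q-values over promoter-level best p-values are available as an
optional column.

## Promoters and operons

Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
convention is converted on read, which removes the usual off-by-one
ambiguity. Operons are called with a distance heuristic: consecutive
same-contig, same-strand genes with an intergenic gap of at most 50 bases
(configurable) are co-transcribed, and the transcription-first gene — the
rightmost one on the minus strand — is the leader whose upstream window
(default 400 bases) is the operon's promoter. Two uses of the window are
reconciled by a flag: fixed-window extraction of a known promoter leaves
`clip_at_upstream_gene = FALSE`, genome-wide promoter sets default to
clipping at the nearest annotated gene boundary. A region shared by two
divergently transcribed leaders is extracted for both, so a site in it is
credited to both operons. Zero-length windows yield a flagged empty
promoter, not an error, and are excluded from promoter sets.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

* `gen_background()` draws bases independently at a target GC fraction
  (default 0.5595, the genomic GC of *Cloacibacillus evryensis*
  DSM 19522). This order-0 model matches everything the background is
  specified by (a GC percentage); it deliberately does *not* reproduce
  dinucleotide bias, homopolymer tracts, or the AT-skew of real intergenic
  DNA, so passing recovery tests demonstrate correctness of the machinery,
  not expected sensitivity on real genomes.
* `plant_dyad()` writes one literal site per selected promoter at a random
  offset and strand, with a random spacer, and records the truth table.
  Recovery simulations use 20 promoters of 400 bases at GC 0.5 with plant
  fraction 1.0 — the size of a typical per-genus promoter collection.
  Degenerate positions in printed consensi are instantiated by a fixed
  neutral rule, the lexicographically first IUPAC expansion (Y -> C,
  W -> A).
* `gen_synthetic_genome()` assembles alternating promoter/gene blocks with
  within-operon gaps below the 50-base threshold and between-operon gaps
  above it, planting sites only in designated leaders' promoters
  (strand-aware), so `call_operons()` and `classify_promoters()` can be
  checked against construction truth.
* `gen_domtblout_fixture()` emits valid HMMER per-domain tables with
  proteins carrying both, one, or neither domain at controlled e-values,
  including an optional protein placed exactly at the cutoff to pin the
  strict-inequality semantics.
* `make_probe_variants()` reproduces the binding-probe dissection series:
  variants substituting the first, middle, or last AT-rich arm with
  `CCCCCC`, and all three with `GGGGGG` or random GC-containing hexamers.
  The substitution base for the middle arm is a package choice (symmetric
  with the flank substitutions); the source experiments specified it only
  for the flanks.

Every generator is a pure function of its specification and seed;
regeneration is byte-identical, and no global random state is touched.

## Numerical and design choices

* Strict `<` on the domain-screen e-value cutoff (1e-3), applied to the
  per-domain independent e-value — the quantity that measures evidence for
  the *domain's* presence; domain order on the protein is not enforced.
* Binomial tails via `stats::pbinom`; `p0` via `expm1`/`log1p` to avoid
  cancellation at small site probabilities.
* PWM construction mixes `pseudocount * background` into each frequency
  column (default 0.01) so log-odds stay finite; p-value tables sum to 1
  to within 1e-9 by construction.
* All rankings and hit lists carry total, documented orderings (ascending
  offset with `+` before `-`; p-value, support, lexicographic word/spacer)
  so outputs are reproducible byte-for-byte.
* Unknown sequence characters are normalised to `N`; `N` never matches an
  arm word and counts as a PWM window excluded from scoring.

## Worked example

```{r example, eval = FALSE}
# promoters planted with the Thermanaerovibrio dyad, then rediscovered
spec <- synthetic_spec(20, 400, gc = 0.5, seed = 7)
pl <- plant_dyad(gen_background(spec), "AATATT", 21, "AAAATA",
                 fraction = 1.0, seed = 8)
model <- discover_dyads(pl$promoters, dyad_config(seed = 7))
consensus_iupac(model)   # "AATATT" + 21 N's + "AAAATA"

# classify a synthetic genome against canonical box + discovered motif
gspec <- synthetic_spec(1, 400, gc = 0.5595, seed = 3,
                        planted = list(left = "AATTTT", spacer = 15,
                                       right = "AAAATT"),
                        plant_fraction = 0.5)
gg <- gen_synthetic_genome(20, 3, gspec)
proms <- build_promoter_set(gg$genome)
cl <- classify_promoters(proms,
                         canonical = canonical_cody_box(),
                         extended = spaced_pattern("ext", "AATTTT", 15,
                                                   "AAAATT"),
                         operons = call_operons(gg$genome))
cl$summary
```

## Problem sizes used by the test suite

Discovery recovery runs use 20 promoters x 400 bp per replicate (20 seed
replicates per genus consensus); the null-calibration suite uses 50
background-only sets of 20 x 200 bp; EM properties use 4-12 promoters of
80-200 bp; PWM oracles enumerate all 4^6 words and score sequences up to
30 bp exhaustively; the screen oracle uses 100-protein fixtures. These
sizes exercise every code path at full fidelity while keeping the default
check fast.

## Limitations

* The operon heuristic ignores transcription-unit evidence beyond gene
  spacing and strand; real operon callers use conservation and RNA-seq.
* The order-0 background understates the structure of real intergenic DNA;
  significance on real genomes should be read comparatively, not as
  calibrated false-positive rates.
* Enumeration anchors one exact arm; dyads whose *both* arms deviate from
  every candidate word are found only through the EM refinement of a
  nearby seed.
* Functional categories are consumed as an input table; no orthology or
  pathway inference is performed, and no statistical enrichment test is
  applied beyond the `log2(N + 1)` transform, which is a display scale,
  not a p-value.
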