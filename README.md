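# synregulon

Discovery and genome-wide mapping of CodY-like regulons in the bacterial
phylum Synergistetes.

CodY, the master nutritional regulator of Firmicutes, couples a
ligand-sensing GAF domain to a winged helix-turn-helix (wHTH) DNA-binding
domain and represses targets through the palindromic operator
5'-AATTTTCWGAAAATT (the *CodY box*). CodY is the only known protein with
that two-domain architecture, which makes the architecture itself a search
criterion: proteins of distant phyla carrying both a GAF (PF06018) and a
wHTH (PF08222) domain at a per-domain e-value below 1e-3 are CodY-like
candidates. In Synergistetes such proteins recognise *spaced palindromic
dyads* — two AT-rich ~6-base arms, one the reverse complement of the
other, separated by an unconstrained spacer whose length varies by genus,
e.g. `AATATT-N21-AAAATA`, `ATTTTY-N14-AAAAAT`, `WWTTTT-N12-ATAATT`, and the
extended palindrome `AATTTT-N15-AAAATT`.

`synregulon` implements the complete inference chain as tested, reusable R
functions:

| Stage | Functions |
|---|---|
| Domain screen (HMMER domtblout in) | `parse_domtblout()`, `screen_cooccurrence()` |
| Promoters from FASTA + GFF3 | `read_fasta()`, `read_gff3()`, `call_operons()`, `build_promoter_set()` |
| Spaced-dyad discovery | `enumerate_dyads()`, `discover_dyads()`, `refine_em()`, `consensus_iupac()` |
| Genome-wide scanning | `scan_iupac()`, `scan_spaced()`, `pwm_model()`, `pwm_scan()` (exact DP p-values), `classify_promoters()` |
| Enrichment, log2(N+1) | `tabulate_regulon()`, `enrichment_matrix()`, `write_enrichment_matrix()` |
| Synthetic data with truth tables | `gen_background()`, `plant_dyad()`, `gen_synthetic_genome()`, `gen_domtblout_fixture()`, `make_probe_variants()` |
| Orchestration | `run_pipeline()` (YAML config), `inst/scripts/synregulon.R` (CLI) |

The discovery statistic is an exact binomial test of per-promoter dyad
occurrence against a strand-averaged order-0 background (Bonferroni-scaled
over all arm-word x spacer hypotheses), followed by information-content
seed selection and ZOOPS expectation-maximization refinement into position
frequency matrices plus a spacer-length distribution. See the methods
vignette (`vignettes/codylike-regulon-discovery.Rmd`) for the model and
every tunable parameter.

## Worked example

The 36-base Synergistes/Cloacibacillus consensus contains three AT-rich
arms forming two palindromic dyads:

```r
library(synregulon)
cons <- "AATTTTCTTAAAATTTCCCTTGATATTTACAATTTT"
arms <- find_arms(cons, c("AATTTT", "AAAATT"))
arms
#>   offset   word       sense
#> 1      0 AATTTT forward-arm
#> 2      9 AAAATT forward-arm
#> 3     30 AATTTT forward-arm
pair_arms(arms)
#>   left_offset left_word right_offset right_word spacer mismatches
#> 1           0    AATTTT            9     AAAATT      3          0
#> 2           9    AAAATT           30     AATTTT     15          0
```

The inner pair (spacer 3) is the canonical CodY box embedded in the
consensus; the outer pair is the extended `AAAATT-N15-AATTTT` palindrome.
Discovery on a synthetic promoter set planted with the
*Thermanaerovibrio* dyad recovers arms and spacer exactly:

```r
spec <- synthetic_spec(20, 400, gc = 0.5, seed = 7)
pl <- plant_dyad(gen_background(spec), "AATATT", 21, "AAAATA",
                 fraction = 1.0, seed = 8)
model <- discover_dyads(pl$promoters, dyad_config(seed = 7))
model
#> <synr_dyad_model> AATATT-N21-AAAATA  gamma=1.000  loglik=-10892.33 (6 iter, converged)
consensus_iupac(model)
#> [1] "AATATTNNNNNNNNNNNNNNNNNNNNNAAAATA"
```

`gamma` is the fitted fraction of promoters carrying a site (here 1.0, the
planted fraction); the consensus string is the refined left arm, the modal
spacer written as `N`s, and the refined right arm.

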