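---
title: "Methods: consensus transcript lists and promoter motif over-representation"
author: "certl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus transcript lists and promoter motif over-representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certl)
```

## The problem

The human endometrium is receptive to embryo implantation only during a
short mid-secretory interval, the window of implantation. Several
independent microarray studies profiled endometrial tissue across this
transition, each publishing its own lists of up- and down-regulated
transcripts under different platforms, fold-change cut-offs and sample
sizes. Any single list is noisy; the transcripts worth following up are the
ones that recur, in the same direction, across independent studies. A
second, downstream question is regulatory: if a cluster of genes moves
together during the acquisition of receptivity, their promoters may share
transcription-factor binding sites (TFBS), detectable as motif
over-representation relative to background promoters.

`certl` implements this research-synthesis workflow as reusable, tested
code: identifier harmonization and direction-aware vote counting to build a
consensus endometrial receptivity transcript list (CERTL); exact
hypergeometric gene-set over-representation with FDR control; position
weight matrix (PWM) construction and strand-aware promoter scanning; an
ensemble of three motif over-representation statistics with a cross-method
consensus rule; and a synthetic-data module that generates both study lists
and promoter sets with planted ground truth, so every stage has a
parameter-recovery test surface.

## Vote-counting consensus

Each study contributes at most one vote per gene per direction. Raw records
are first harmonized onto canonical cluster identifiers through a mapping
table (`harmonize()`): concordant duplicate probes collapse to one vote,
unmapped identifiers are dropped and counted, and a gene called both up and
down *within one study* is an intra-study contradiction, excluded from that
study's votes and reported. Mapping rows that send one source identifier to
several canonical identifiers within a namespace are refused outright
rather than resolved by guesswork.

The harmonized calls form a gene-by-study matrix of direction calls
(`build_vote_table()`). Votes are counted per direction against
direction-specific electorates: a study that does not disclose its
down-regulated transcripts cannot vote "down", so the down-electorate may
be smaller than the up-electorate. In the bundled seven-study design, one
study discloses only its up-regulated list, giving electorates of 7 (up)
and 6 (down) — and that asymmetry is why the default thresholds differ:
at least `min_up = 4` of 7 supporting studies for up-regulation and
`min_down = 3` of 6 for down-regulation.

A gene meeting both thresholds would be a `conflict`; it is excluded from
both consensus lists and reported, preserving the requirement that a
consensus gene shows a *consistent* transcriptional response. Absence from
a study is treated as no information, never as evidence against: the
intersection logic only counts positive calls.

### The bundled direction matrix

`certl_calls()` returns the packaged transcription of the published
seven-study comparison tables: 225 direction calls over 61 genes keyed by
UniGene cluster id (40 genes listed as up-regulated, 21 as down-regulated),
with `certl_studies()` carrying the study metadata. Two properties of this
matrix are worth knowing. First, the down-regulated block is exactly
reproduced by the default `min_down = 3` filter: all 21 genes have at least
three down votes (OLFM1 leads with five). Second, the up-regulated block is
*not* internally consistent with the stated four-study rule: only 18 of the
40 listed genes carry four or more up votes, while 22 carry exactly three
(the blocks of the printed table are support-sorted, so this is a property
of the published matrix itself, not of the transcription). On this matrix
the full 40-gene up list corresponds to an effective up-threshold of 3.
Both thresholds are exposed as arguments so either convention can be
computed; the package defaults implement the stated 4/3 rule.

## Gene-set over-representation

Functional annotation of a consensus list is a one-sided hypergeometric
tail test (`hypergeom_tail()`): for a query of $n$ genes drawn from a
universe of $N$, of which $K$ carry an annotation, the probability of an
overlap of at least $k$ is
$$P(X \ge k) = \sum_{i \ge k} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$
computed exactly (it equals the one-sided Fisher test on the implied 2x2
table). Adjustment across terms is Benjamini–Hochberg (`bh_adjust()`).

The universe is caller-supplied because it is the single most consequential
choice in over-representation testing; the pragmatic default in pipeline
use is the union of all genes appearing in the study lists. Terms with
fewer than two members in the universe are skipped as uninformative. There
is no ontology-graph propagation and no fuzzy clustering of terms: one
term, one test.

## Position weight models and scanning

A count matrix becomes a model (`build_pwm()`) via a pseudocount spread by
background frequency,
$$\mathrm{ppm}_{b,i} = \frac{c_{b,i} + s\,\pi_b}{\sum_b c_{b,i} + s},$$
with total pseudocount weight $s = 0.8$ per column by default (a common
practice value; small enough not to blur sharp columns, large enough to
keep log-odds finite). Derived quantities are the log-odds matrix
$\log_2(\mathrm{ppm}_{b,i}/\pi_b)$ and the per-column information content
$I_i = 2 + \sum_b \mathrm{ppm}_{b,i}\log_2 \mathrm{ppm}_{b,i}$ bits.

Two scores are available per window. The information-weighted matrix
similarity (`matsim_score()`) is
$$\mathrm{sim}(w) = \frac{\sum_i I_i \cdot \mathrm{ppm}_{w_i,i}}
                        {\sum_i I_i \cdot \max_b \mathrm{ppm}_{b,i}} \in [0,1],$$
which reaches 1 exactly at per-position argmax words and discounts
mismatches at uninformative positions. The log-odds score
(`logodds_score()`) is the plain PSSM sum in bits. Conventions for
degenerate cases are fixed and tested: an all-uniform model has zero total
weight and scores every word 1 by definition (the scanner never divides by
zero); an `N` in a window contributes zero to either score.

`scan_promoters()` slides a model over every window of every promoter.
Coordinates are 0-based and half-open throughout; reverse-strand hits are
found by scoring the reverse-complemented model on the forward strand and
are reported at the forward coordinate of the window start. Windows
containing `N` are skipped by default (`n_policy = "penalize"` instead
lets them compete with the `N` positions zeroed). The default similarity
threshold is 0.85; thresholds are a free parameter because none of the
upstream tools this replaces published theirs.

One behavior deserves emphasis: sites *sampled from* a weakly informative
model frequently miss a 0.85 similarity threshold. With roughly one bit
per column, a sampled word deviates from the consensus at two or more
positions about 40% of the time, and two deviations already score below
0.85. High recall of planted sites at that threshold therefore presumes a
crisp matrix (about 1.7 bits per column and up); the package's recovery
tests use such a matrix for recall claims and keep the ~1 bit regime for
enrichment claims, where partial recall is immaterial because it applies
equally to foreground and background.

## The motif over-representation ensemble

Given scan hits over disjoint foreground and background promoter sets,
`summarize_incidence()` tallies per-promoter site counts,
promoters-with-at-least-one-site, and scanned windows ($L - W + 1$ per
strand). Three statistics then ask "is this motif over-represented in the
foreground?" in different currencies:

* **gene-level** (`gene_level_test()`): hypergeometric tail on
  promoters-with-hit, drawn from the pooled promoter universe — robust to
  a single promoter hosting many sites;
* **site-rate** (`site_rate_test()`): exact binomial tail on the total
  foreground site count with the background per-window rate as success
  probability (add-one smoothing when the background has zero sites);
* **permutation** (`permutation_test()`): redraw the foreground label set
  uniformly from the pooled universe holding per-promoter counts fixed,
  with the add-one estimator $p = (1 + \#\{T^* \ge T\})/(1 + R)$,
  $R = 999$ by default — the exact reference the other two approximate.

`motif_enrichment()` runs all three for every motif, adjusts each
statistic across motifs by Benjamini–Hochberg separately (the three are on
different scales, so pooling their p-values would be meaningless), flags
the statistics with $q \le \alpha$, and calls a motif a consensus hit when
at least `min_methods` (default 2) of the three agree. This formalizes the
informal practice of trusting motifs that several independent
over-representation tools agree on.

### What cross-method agreement does and does not buy

The three statistics are computed from the *same* scan, so under the null
they are strongly correlated: a chance foreground excess of sites moves
all three p-values together. Requiring 2 of 3 therefore provides much less
false-positive protection than it would for independent methods. With 20
null motifs alongside one real one, the BH rank-2 threshold is about
$2\alpha/21 \approx 0.005$, and the chance that *some* null motif crosses
it in two correlated statistics at once is roughly
$1 - (1 - 0.005)^{20} \approx 9\%$ per analysis. Simulations confirm a
~9% rate of a single spurious co-flag under realistic decoys that do
accumulate chance hits. Users who need a strictly controlled family-wise
rate should read the permutation q-value alone, or demand
`min_methods = 3`; the ensemble's value is interpretive (agreement in
different incidence currencies), not an independent-replication guarantee.
The original multi-tool practice escaped this correlation only to the
extent that different tools used different matrices, scanners and
backgrounds.

A second caveat: the site-rate binomial treats scanned windows as
independent trials. Overlapping windows, two-strand scanning and
within-promoter site clustering make the true count distribution
overdispersed, so extreme site-rate p-values overstate the evidence; the
permutation test is the calibrated reference in the tails.

## The synthetic-data generator

`simulate_studies()` emulates the multi-study design as a vote-counting
process: a universe of `n_universe = 1000` genes, `n_studies = 7` studies,
30 planted up- and 20 planted down-regulated genes, each detected by each
study independently with probability `p_detect = 0.9` in its true
direction, plus false calls on non-planted genes at `p_false = 0.005` per
study with direction chosen by fair coin (no directional noise model is
implied by the design being emulated; symmetry is the neutral choice).
The defaults make planted support Binomial(7, 0.9), so the default 4/3
thresholds recover planted genes with probability above 0.99 while a false
consensus gene requires four coincident false calls — expected well below
one per analysis.

`simulate_promoters()` draws foreground and background promoters from a
background Markov model (order 0 with given base frequencies, or order 1
with a 4x4 transition table; uniform order-0 by default), then plants
motif instances sampled column-wise from the model's probability matrix at
Poisson rates per promoter (`lambda_fg` vs `lambda_bg`), on the reverse
strand with probability 0.5. Planting is by overwriting background bases;
sites are placed uniformly, never cross a promoter boundary, and never
overlap one another (overlapping draws are rejected and resampled), so the
ground-truth site log is unambiguous. Poisson counts, rather than fixed
counts per promoter, match the rate-based framing of the incidence
statistics.

Decoy matrices for specificity testing come from `random_decoy_motifs()`.
A purely random decoy can resemble the planted motif — often in a shifted
or reverse-complement register — and then fires on the planted sites
themselves, silently turning a negative control into a partial positive.
When given `avoid = <model>`, the generator rejects candidates whose
consensus aligns to the avoided consensus at 75% or more identity over any
five-plus-base overlap on either strand. This is the same
keep-ground-truth-unambiguous principle as non-overlapping planting.

What the generator deliberately does *not* emulate: microarray
intensities, fold-changes or platform effects (the consensus machinery
consumes gene lists, not expression values); promoter GC/CpG structure,
repeats, or motif co-occurrence and clustering; and any correlation
between a gene's expression behavior and its promoter composition.
Passing parameter-recovery tests therefore demonstrates that the
algorithms recover known signal under an idealized, well-specified noise
model — not that real endometrial promoters are free of the confounders
that real motif analyses must confront.

## Numerical and interface conventions

* Reproducibility: every stochastic function takes a `seed`; seeding is
  local and restores the caller's RNG state. Identical seeds give
  bit-identical outputs.
* Writers are deterministic: stable sort orders (p ascending with term-name
  tie-break; support descending with symbol tie-break; flagged-method count
  then minimum q for motifs), floats at six significant digits, and a
  `#`-comment header carrying the package version and seed on every output
  file.
* Coordinates are 0-based half-open everywhere; BED6 output scales
  similarity scores by 1000 (log-odds by 100, clamped) into the integer
  score column.
* The pipeline driver (`run_pipeline()`) takes one YAML (or equivalent
  list) configuration; stages run when their block is present; all inputs
  are verified before any output is written; a `manifest.yaml` records
  version, seed, input digests and per-stage row counts. A thin
  command-line front end (`inst/cli/certl.R`) exposes the stages as
  subcommands.

## Validation problem sizes

The shipped test-suite checks were sized to be decisive yet quick: exact
enumeration oracles up to universes of 20 (where all $\binom{N}{n}$ draws
are enumerable); 500-replicate null-calibration runs for the three motif
statistics and the gene-set test (bounding rejection at
$0.05 + 3\,\mathrm{SE}$); 100-seed parameter-recovery runs for both the
consensus filter (1000-gene universes) and the motif ensemble (250
promoters of 500 bases, 21 motifs, 999 permutations). These sizes are the
package's own validation choices and scale linearly if users want more
replicates.

## Known limitations

* Vote counting weighs all studies equally; it ignores study quality,
  sample size and effect size, and cannot distinguish "absent" from "not
  assayed on that platform".
* Exact reproduction of historical web-tool annotation p-values is out of
  reach in principle: those depended on contemporaneous ontology releases
  and undisclosed background universes. The statistic is reproduced; the
  historical numbers are not.
* The matrix-similarity formula is one published convention of
  information-weighted scoring; other scanners differ in weighting and
  normalization, so absolute thresholds are not transferable between
  implementations.
* The 2-of-3 consensus rule inherits the correlation caveat above; its
  false-flag rate over many candidate motifs is closer to the per-statistic
  FDR than to its square.
* Real TRANSFAC matrices are proprietary and are not shipped; all packaged
  matrices are synthetic and labelled as such.
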