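---
title: "Models and methods behind minorlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minorlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

minorlens analyses the splicing of minor (U12-dependent) introns from
RNA-seq-style evidence: it builds an intron catalog, classifies introns
as minor or major and into A-type (AT-AN terminal dinucleotides) versus
G-type (GT-AN / GC-AG) subtypes, quantifies intron retention (Ψ), tests
for differential retention between two conditions, screens for cryptic
splice-site activation, and ranks genes by phylogenetic-profile
co-occurrence. This vignette documents the models, their assumptions,
and the design decisions a user should know about.

```{r setup, message = FALSE}
library(minorlens)
library(dplyr)
```

## Intron catalog

`read_genome()` and `read_annotation()` load a FASTA genome and a GTF
annotation; internally every interval is 0-based half-open (GTF input is
1-based inclusive, BED output 0-based half-open). `extract_introns()`
turns every gap between consecutive exons into an intron, deduplicating
across transcripts by (contig, start, end, strand). The host gene of a
shared intron is taken from the first contributing transcript and
ambiguity across genes is messaged; `intron_index` numbers introns
within each gene in transcription order, so index 1 is the promoter-
proximal intron on either strand.

Introns shorter than 30 nt are skipped with a warning: the branch-point
search window reaches 40 nt from the 3' end, and nothing shorter than
~30 nt can host distinct donor and branch-point signals. All sequence
windows are extracted strand-aware, so the donor window is the first 9
*transcribed* bases and the 3' region the last 40, regardless of strand.

## Splice-site scoring and classification

Minor introns are recognised by their long, conserved 5' splice-site and
branch-point sequences, not by terminal dinucleotides: major AT-AC
introns exist and must not be called minor. `build_pwm()` estimates a
position weight matrix from an alignment of equal-length k-mers with a
pseudocount (default 0.25 per base; `N` spreads a quarter-count to each
base). `score_sequence()` reports a *normalized likelihood ratio*: the
product of per-position probabilities divided by the maximum attainable
product. This maps any sequence into (0, 1], with every per-position
consensus sequence scoring exactly 1. A bounded score is needed because
the classification thresholds — 0.07 for the 5' splice site and 0.14 for
the branch point — live on a bounded scale. The published matrices
behind those thresholds are not distributed with their source, so the
package ships small curated U12 consensus-variant training sets
(`u12_training_sets()`); both the training alignments and the thresholds
are user-replaceable, and the thresholds are deliberately configurable
because the score scale depends on the matrices used.

`scan_branch_point()` slides the branch-point matrix over every window
that lies wholly within transcribed positions −40..−3 upstream of the 3'
splice site (offset −1 is the last intronic base) and keeps the highest
score; ties resolve to the window nearest the 3' splice site. Windows
are enumerated exhaustively, and the test suite checks the scan against
an independent brute-force enumeration.

`classify_introns()` calls an intron minor when *both* scores reach
their thresholds, or when the intron is on a user-supplied allowlist
(curated minor introns with, typically, degenerate branch points).
Subtype is assigned from the donor dinucleotide alone: AT gives A-type,
GT or GC gives G-type, matching the field's grouping of GC-AG minor
introns with the G class.

## Retention quantification

`read_alignments()` parses SAM text; CIGAR `M/=/X/D` extend an aligned
block, `N` splits blocks, `I/S` consume no reference. Per intron and
sample, `count_intron_evidence()` tallies three read classes with an
anchor of `k` = 8 aligned nt (guarding against spurious 1-nt overlaps):

* **J** — junction reads, spliced exactly at the intron boundaries;
* **B** — exon–intron boundary crossings (a read can contribute at both
  boundaries);
* **R** — reads with at least `k` nt inside the intron that are not
  junction reads.

`compute_psi()` pools counts within a condition and estimates retention
as `psi = retained / (retained + spliced)`. In the default boundary mode
the retained evidence is `B / 2`, because one retained molecule presents
two boundaries while one spliced molecule presents a single junction;
without this correction psi would be biased upward. Body mode instead
rescales `R` by `read_length / intron_length` and is provided for
comparison. Reads are treated as unstranded single units; mates are
counted independently. The estimator is validated by parameter recovery
on simulated data: at a pooled coverage of about 200 informative units
and with pure counting noise, at least 95% of introns are recovered
within ±0.05 (the replicate-level biological overdispersion described
below adds deviation around the configured truth that no estimator can
remove, so the recovery property is assessed at `rho = 0`).

`filter_introns()` applies the two "at least 5" read-support filters
used in subtype-stratified retention analyses: total junction reads ≥ 5
across the samples of a comparison, or mean intron-body reads ≥ 5 per
sample; which filter applies is the caller's choice per analysis.

## Differential retention

For intron *i*, replicate *j* of condition *c*, the retained count is
modelled as beta-binomial:

$$r_{cj} \sim \mathrm{BetaBin}(n_{cj},\ \mu_c,\ \rho),$$

with condition means µ (the retention level) and intra-replicate
correlation ρ capturing biological replicate overdispersion. The test is
a likelihood-ratio of µ_control = µ_treatment against free means, with ρ
*shared* between the two models, referred to a χ²(1) distribution.
ΔΨ is reported as the difference of pooled-count retention fractions
(treatment − control), which is stabler than averaging per-replicate
fractions at low counts.

With three replicates per condition, per-intron maximum-likelihood
estimation of ρ is unreliable: the estimate is biased by the estimated
group means, and a free-ρ null model can absorb a genuine retention
shift into overdispersion. `test_differential_ir()` therefore defaults
to a *common* ρ estimated once across all introns of the comparison —
the same strategy dispersion-shrinking count frameworks use — with a
moment estimator that explicitly discounts the estimated group means:
for a replicate group with totals $n_j$, pooled mean $\bar p$ and $m$
replicates,
$E\!\left[\sum_j (r_j - n_j \bar p)^2 / n_j\right] =
\bar p (1-\bar p)\,(A + B\rho)$ with $A = m - 1$ and
$B = \sum (n_j - 1) - \sum n_j (n_j - 1) / n_\cdot$; numerators and
denominators are summed over all groups before solving for ρ. Under null
simulations (2,000 introns, 3 vs 3) the resulting test holds its size at
α = 0.05 for both ρ = 0 and ρ = 0.05. `betabin_test()` also exposes
per-pair estimation (`rho = "per_intron"`, coordinate ascent with
bounded 1-D maximizations, tolerance 1e-8, at most 200 sweeps,
method-of-moments initialization) and fixed values; `rho = 0` is the
closed-form binomial likelihood-ratio test, and a non-converged
beta-binomial fit falls back to it with a warning.

P-values are Benjamini–Hochberg adjusted (`adjust_bh()`). An intron is
`affected_ir` when `p_adj < 0.05` and `affected_strict` when
additionally ΔΨ > 0.1. Subtype comparisons use two-sided Mann–Whitney
rank-sum tests (`mann_whitney()`): exact null distribution when the
pooled sample has at most 20 observations and no ties, otherwise the
normal approximation with tie and continuity corrections; a pooled
sample with zero variance returns p = 1. Retention profiles are
clustered by average-linkage agglomeration on Euclidean distances
(`cluster_retention()`).

## Cryptic splice sites

When canonical minor splicing fails, nearby major splice sites can be
activated. `detect_cryptic()` screens observed junctions whose one
boundary lies within 50 nt of a canonical minor-intron boundary while
the other differs, quantifies alternative usage as
`J_alt / (J_alt + J_canonical)` and tests its shift with the same
beta-binomial machinery. An event is *activated* when `p_adj < 0.05` and
|ΔΨ_alt| > 0.1; the posterior-probability criterion used by some AS
tools is deliberately replaced by this frequentist cutoff so that one
testing framework covers both retention and alternative-splicing calls.
The 50 nt flank window is a package default; it trades sensitivity for
candidate-set size and is configurable.

## Phylogenetic co-occurrence

Genes functioning in one process tend to be lost and retained together
across species. `profile_correlation()` computes, for every gene's
binary presence/absence profile, the Pearson correlation with a query
profile — on binary vectors this equals the 2×2 phi coefficient.
Constant profiles have undefined correlation and rank last.
`select_cooccurring()` keeps genes with r strictly greater than 0.5
(default), excluding the query; `enrich_terms()` tests term
over-representation among the selected genes with the upper-tail
hypergeometric (one-sided Fisher) test and BH adjustment across terms.
Raw binary vectors are used without clade weighting or tree-aware
corrections, and ortholog assignment itself is an upstream input.

## Synthetic data

The generators exist so that every stage can be validated against known
truth without external downloads.

`simulate_genome()` builds a single-contig genome of alternating-strand
genes (three introns each; exons 100 nt, introns 120 nt). Four intron
classes are planted: minor A (AT..AC), minor G (GT..AG), major (GT..AG
with a major-consensus donor) and major AT-AC (AT..AC with random
internal sequence). Minor introns carry the U12 consensus donor and a
consensus branch point planted uniformly within the −40..−3 window;
consensus (rather than degenerate) motifs are planted because the
generator's contract is that planted minor introns are high-scoring —
motif degeneracy in real genomes is a classifier-threshold question, not
a generator one.

`simulate_counts()` draws per-replicate informative coverage from a
negative binomial (mean 70, size 8 — about 200 pooled over the default
three replicates per condition) and retained counts from a beta-binomial
with ρ = 0.02, a realistic level of biological replicate
overdispersion for cell-line experiments. Default retention levels are
0.10 for minor introns and 0.02 for majors (control-condition retention
of minor introns in human cells is of order 0.08–0.13), with treatment
shifts of +0.36 for A-type and +0.07 for G-type — the magnitudes that
motivate the subtype-asymmetry analyses. `simulate_sam()` realizes the
counts as SAM records with correct gapped-alignment strings (uniform
read starts under the anchor constraints, no sequencing error, no
paired-end structure). `simulate_profiles()` plants one shared
loss/retention pattern in a gene module (default 10 genes, 60 species)
and flips each entry with probability 0.05.

What the simulations do *not* emulate: GC and positional coverage bias,
paired-end inserts, mapping ambiguity, expression-level changes,
per-intron dispersion heterogeneity, and phylogenetic non-independence
of species. Passing tests therefore demonstrate correctness of the
algorithms and calibration under the stated model, not performance on
any particular real data set.

Problem sizes used by the validation suite — 250-intron genomes,
2,000-intron null calibrations, a 620-intron subtype comparison
(179 A-type, 441 G-type, the catalog sizes typical of the human minor
intron complement), and 100 replicate co-occurrence screens — were
chosen to make Monte-Carlo noise small relative to the tested margins.

## Pipeline

`run_pipeline()` chains the stages (simulate or load → catalog →
classify → quantify → filter → test → summarise → optionally co-occur),
writes each table as TSV plus a JSON manifest (package version, config
hash, seed, per-stage row counts), and is byte-reproducible for a fixed
configuration and seed: a single seed feeds every stochastic stage.

## Known limitations

* The bundled matrices are consensus-built, not organism-fitted; users
  reproducing a published minor-intron catalog must supply the original
  matrices and thresholds.
* The common-ρ default assumes exchangeable overdispersion across
  introns; strongly heterogeneous dispersion would call for per-intron
  or trended estimates.
* Mates of a pair are counted as independent reads, which can double-
  count a fragment spanning the same boundary twice.
* The cryptic-site screen considers only junctions near catalog minor
  introns; novel events elsewhere are out of scope.
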