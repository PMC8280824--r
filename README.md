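# minorlens

Analysis of minor (U12-dependent) intron splicing from RNA-seq-style
data, for researchers studying the minor spliceosome and the diseases
caused by its dysfunction.

Most human introns are excised by the major (U2-dependent) spliceosome;
roughly 700 "minor" introns depend on the low-abundance minor
spliceosome and are recognised by long conserved 5′ splice-site (5′ss)
and branch-point (BPS) sequences rather than by terminal dinucleotides
alone. Minor introns split into two subtypes: **A-type** (AT-AN terminal
dinucleotides: AT-AC, AT-AA, AT-AG, AT-AT) and **G-type** (GT-AG, GT-AT,
GT-TG, GC-AG). Loss of individual minor-spliceosome factors can affect
these subtypes very differently, which shows up as subtype-dependent
increases in intron retention (Ψ) and activation of nearby cryptic major
splice sites. minorlens implements the complete computational path for
such a study on desk-scale data:

1. **Catalog** — extract deduplicated introns from a genome (FASTA) and
   annotation (GTF), with strand-aware donor/branch-point windows.
2. **Classify** — score 5′ss and BPS with position weight matrices
   (normalized likelihood-ratio score in (0, 1]; the BPS is the best
   window within −40..−3 of the 3′ss) and call an intron *minor* when
   both scores pass their thresholds (defaults θ₅′ss = 0.07,
   θ_BPS = 0.14) or an allowlist entry forces it; subtype from the donor
   dinucleotide (AT → A; GT/GC → G).
3. **Quantify** — count junction (J), exon–intron boundary (B) and
   intron-body (R) reads per intron and sample from SAM alignments, and
   estimate Ψ = (B/2) / (B/2 + J) per condition.
4. **Test** — a replicate-aware beta-binomial likelihood-ratio test per
   intron, with a common overdispersion estimated across the comparison;
   Benjamini–Hochberg correction; affected = P_adj < 0.05, strictly
   affected additionally ΔΨ > 0.1; Mann–Whitney subtype comparisons;
   average-linkage clustering; cryptic-splice-site detection.
5. **Co-occurrence** — rank genes by the phi coefficient (Pearson
   correlation of binary phylogenetic profiles) against a query gene,
   select co-occurring genes at r > 0.5, and test term enrichment with
   the hypergeometric (Fisher) test.
6. **Simulate** — generators for toy genomes with planted minor introns,
   two-condition counts with known retention truth, and profile matrices
   with a planted co-occurring module, so every stage is testable
   end-to-end without downloads.

## Worked example

A synthetic two-condition experiment with 25 A-type, 25 G-type, 180
major and 20 major AT-AC introns, in which treatment shifts A-type
retention by +0.36 and G-type by +0.07:

```r
library(minorlens)
library(dplyr)

cfg     <- sim_config(seed = 7)
gen     <- simulate_genome(cfg)
introns <- extract_introns(gen$transcripts, gen$genome)
cl      <- classify_introns(introns)
count(cl, spliceosome_type, subtype)
#>   spliceosome_type subtype            n
#> 1 major            not_applicable   200
#> 2 minor            A                 25
#> 3 minor            G                 25

cts  <- simulate_counts(gen$truth, cfg)
res  <- test_differential_ir(filter_introns(cts$counts, "junction"),
                             cts$design)
summarize_by_subtype(res, cl, affected = "strict")
#>   subtype  n n_affected fraction_affected mean_delta_psi median_delta_psi  mw_U     mw_p
#> 1       A 25         25              1.00         0.3614            0.374   625 1.42e-09
#> 2       G 25          2              0.08         0.0758            0.074   625 1.42e-09
```

All 50 planted minor introns are recovered (none of the 20 major AT-AC
introns is called minor), every A-type intron but almost no G-type
intron is strictly affected, and the recovered mean retention shifts
(0.36 vs 0.08) match the planted effects — the subtype asymmetry the
package is built to detect. `plot_delta_psi(res, cl)` draws the
per-subtype ΔΨ densities; `run_pipeline()` chains all stages and writes
TSVs plus a reproducibility manifest.

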