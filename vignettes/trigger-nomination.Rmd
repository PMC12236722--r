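---
title: "Nominating TDMD trigger sites from chimeric interaction data"
author: "triggerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating TDMD trigger sites from chimeric interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triggerscan)
```

## Background

Target-directed microRNA degradation (TDMD) inverts the usual direction
of miRNA regulation: instead of the miRNA destabilizing its target, a
specialized *trigger* transcript binds the miRNA with extensive
complementarity and routes it to ZSWIM8-dependent decay. Validated
triggers share a recognizable duplex architecture: a perfect seed match
(miRNA positions 2--7/2--8), a modest central bulge, and an unusually long
stretch of pairing to the miRNA's 3' region. Chimeric AGO-CLASH
(chimeric eCLIP) libraries read out miRNA:target contacts directly --
each chimeric read joins a miRNA to the fragment it was bound to -- and
so provide the raw material for a genome-wide trigger search, but the
overwhelming majority of chimeras come from canonical, seed-only target
sites. `triggerscan` implements the discriminating filter cascade and
ranking, together with a fully synthetic test-bed.

## The filter cascade

Each clustered binding site is scanned for canonical seed matches and
every anchored site is evaluated against six criteria:

1. **Seed match** -- the site must pair the miRNA seed as a 6mer,
   7mer-A1, 7mer-m8 or 8mer. G:U wobbles do not count in the seed, so a
   single seed mismatch disqualifies a site.
2. **Noncoding location** -- the seed-match position must fall in a
   5'UTR, 3'UTR or noncoding-RNA exon. Translating ribosomes strip
   regulatory machinery from ORFs, so coding-sequence sites are excluded.
3. **Central bulge** -- no more than 7 consecutive unpaired miRNA
   positions after the seed (positions 9 to the 3' end). Both mismatched
   and bulged-out nucleotides count as unpaired.
4. **3' pairing run** -- at least 6 consecutive base pairs within the
   miRNA's 3' window, defined as its final 13 nucleotides. G:U pairs
   count here (hybridization semantics), unlike in the seed.
5. **Conservation** -- strictly positive mean per-base conservation
   (phyloP semantics) over the seed-binding nucleotides *and* over the
   site nucleotides predicted to pair the 3' window.
6. **3' MFE** -- the minimum free energy of the duplex between the
   miRNA's 3' window and the site region upstream of the seed match must
   be favorable (negative); passing candidates are *ranked* by this
   energy, most negative first.

A candidate passes only if all six verdicts hold; every evaluated site
is reported with its per-criterion verdicts so that attrition can be
audited.

## The duplex model

The published pipelines delegate hybridization energetics to an external
program. `triggerscan` instead ships a self-contained intermolecular
duplex model so that every energy in the output is reproducible from a
bundled parameter file:

* only inter-strand pairs, antiparallel and non-crossing; no
  intramolecular structure, no dangling ends;
* nearest-neighbor stacking energies for adjacent pairs, taken from the
  Turner 2004 RNA parameter set and frozen in
  `inst/extdata/turner2004_stack.tsv` (kcal/mol at 37 °C, G:U included);
* an affine penalty for interior loops and bulges,
  `3.20 + 0.40 × (unpaired nt)` kcal/mol, capped at 15 unpaired
  nucleotides per side -- beyond that a single duplex cannot bridge the
  gap;
* a terminal penalty of 0.45 kcal/mol for AU or GU pairs closing either
  helix end;
* the empty structure has energy 0; a structure is only reported if its
  energy is ≤ 0. Co-optimal structures resolve deterministically:
  more pairs first, then the 5'-most anchor on the first strand.

The affine loop penalty and terminal penalty are model constants of this
package (documented in the parameter file header); the stack table
carries its provenance in its `param_set` line. The dynamic program is
validated against an independent exhaustive enumeration of *all* valid
pairings for every sequence pair up to length 6 (≈30 million pairs) and
for 1,000 random pairs up to length 10 — zero discrepancies at
centi-kcal resolution.

Because isolated pairs carry no stacking energy, the model never adds a
lone long-distance contact to a structure (the loop penalty exceeds any
single-stack gain of ≤ 3.4 kcal/mol), which keeps the architecture
metrics stable under padding; the one deliberate consequence of the
"more pairs" tie-break is that a single zero-energy G:C contact can
appear when no negative-energy helix exists at all.

## Architecture metrics

`evaluateArchitecture()` anchors the classified seed pairs and co-folds
the miRNA remainder (positions 9..end, or 8..end for classes without an
m8 pair) against the site region upstream of the seed. From the
resulting map it reports the central mismatch run, the in-window 3'
pairing run (a run straddling the window boundary counts only its
in-window part), and the 3' MFE. "After the seed" is always positions
9..end regardless of seed class, matching the operational definition of
the central-bulge criterion. The 3' MFE is computed against the site
region upstream (5') of the seed match -- the only region reachable by
the miRNA 3' arm under antiparallel geometry; using the whole site would
double-count the seed helix.

## Annotation and conservation choices

Region classification uses the *seed-match position*, not majority
overlap of the cluster: the occlusion argument for criterion 2 concerns
the trigger site itself. When isoforms disagree, precedence is
`UTR3 > UTR5 > ncRNA_exon > CDS > intron > intergenic`, so any isoform
that places the site in a noncoding region lets it through -- the
permissive choice for a discovery pipeline. UTRs are derived by
exon-minus-CDS arithmetic when not annotated explicitly.

"Positive conservation" is interpreted as a strictly positive *mean* per
region (`conservationStats(..., rule = "mean")`); requiring every single
base to be positive (`rule = "all"`) is exposed as a switch but is close
to unsatisfiable on real tracks, where even deeply conserved elements
contain neutral positions. The boundary is strict: a mean of exactly 0
fails.

## Clustering

Upstream peak callers are out of scope; `clusterSites()` replaces them
with a strand-aware overlap merge of chimera target intervals per miRNA,
followed by the standard 10-nt extension at the cluster's 5' end (the
crosslink-induced truncation side), clipped at chromosome bounds, with a
configurable minimum read support (default 1). Externally called peaks
in BED-like form can be fed directly to `nominateTriggers()` as a
cluster table.

## The synthetic test-bed

`simulateTriggerStudy()` generates, from a single seed, a complete toy
study: 2 chromosomes × 100 kb of uniform-random sequence, 20 genes
(mRNAs with 200/900/900-nt UTR5/CDS/UTR3, a quarter with an intron, a
quarter ncRNA), 10 random 22-nt miRNAs, and 13 planted sites -- 3 full
trigger architectures (8mer seed, 8-nt 3' run, 4-nt bulge), 5
canonical seed-only sites, and 5 decoys each violating exactly one
criterion (seed mismatch, CDS placement, 8-nt bulge, 5-nt 3' run,
withheld conservation). Sites are built by writing reverse complements
of the relevant miRNA segments into the chosen region; spacers and pads
are rejection-sampled so they cannot form a ≥6-nt pairable run with the
miRNA remainder, cannot extend the planted helix by stacking, and
contain no stray seed hexamer. Each planted locus is then verified to
reproduce its intended metrics exactly — canonical sites additionally on
the cluster-cropped view the pipeline will actually evaluate — resampling
fillers if needed;
in the rare case where a miRNA's own 3' sequence makes a spec
unrealizable (e.g. it contains the seed hexamer), the generator
substitutes the next miRNA and records the substitution in the truth
table. Chimeras are 40-nt transcript-sense fragments at depth 5 per
site; conservation is +2 at planted functional positions of conserved
sites and −0.5 elsewhere.

What the generator does *not* emulate: sequencing error, UMI structure,
ligation biases, expression-weighted chimera sampling, overlapping
genes, alternative isoforms sharing exons, and realistic conservation
autocorrelation. Perfect recovery on this test-bed therefore
demonstrates the correctness of the decision logic and coordinate
arithmetic, not the expected sensitivity on real libraries.

## Worked example

```{r example}
sim <- simulateTriggerStudy(file.path(tempdir(), "demo"), seed = 1)
mirnas <- readMiRNAFasta(sim$paths$mirnas)
ann <- loadAnnotation(sim$paths$gtf)
cons <- readConservation(sim$paths$conservation)
chim <- readChimeras(sim$paths$chimeras, mirnas)
clusters <- clusterSites(chim, seqlens = sim$seqlens)
cand <- nominateTriggers(clusters, mirnas, ann, cons,
                         genome = sim$paths$genome)
cand[!is.na(cand$rank),
     c("mirna_id", "region_class", "seed_class",
       "three_prime_pair_run", "three_prime_mfe", "rank")]
evaluateRecovery(cand, sim$truth)[c("precision", "recall")]
```

## The repression statistic

`targetRepressionCdf()` compares log2 fold-changes of a target gene set
against a background set (genes above a CPM floor of 5 by default),
returning empirical CDFs and a one-sided Wilcoxon rank-sum p-value
(alternative: targets shifted toward lower fold-change). The normal
approximation uses tie correction and continuity correction; when both
groups have ≤ 10 tie-free values the exact distribution is used and
matches a full permutation enumeration to 10⁻¹².

```{r cdf, fig.width = 5, fig.height = 4}
set.seed(2)
tab <- data.frame(gene = sprintf("g%04d", 1:600),
                  log2fc = c(rnorm(100, -0.4), rnorm(500)))
res <- targetRepressionCdf(tab, tab$gene[1:100])
plotRepressionCdf(res)
res$p.value
```

## Numerical and scale choices

Energies are held internally in integer centi-kcal/mol, so energy ties
are exact and outputs are reproducible to 0.01 kcal/mol across
platforms. All generator randomness flows from explicit seeds through a
scoped RNG (the caller's RNG state is untouched). The default study
scale (2 × 100 kb, 20 genes, 13 sites, depth 5) runs the full
generate-plant-simulate-nominate-evaluate cycle in a few seconds, so the
20-seed recovery property and the 30-million-pair duplex sweep both run
routinely as part of the test suite.

## Known limitations

* The duplex model omits dangling ends, coaxial stacking and
  temperature dependence; energies are comparable within this package
  but not numerically identical to other hybridization tools.
* Whether the published criteria count G:U as pairing in the 3' run is
  not stated; `triggerscan` counts it (hybridization semantics). The
  seed, by contrast, is strictly Watson-Crick.
* Multi-isoform quantification, chimera abundance modelling and
  differential analysis between genotypes are out of scope; the
  repression stage consumes a precomputed fold-change table.
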