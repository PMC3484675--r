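---
title: "Dating a gene retrocopy from fixed and polymorphic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a gene retrocopy from fixed and polymorphic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodate)
```

## The inference problem

A young retrocopy and its parent gene differ at a handful of sites, but
those differences are of two kinds with opposite meaning for dating:
substitutions *fixed* on one lineage since the retrotransposition event
record elapsed time, while *modern polymorphisms* segregating in either
paralog record nothing about age. Reference assemblies are single sampled
haplotypes, so naive reference-vs-reference comparison cannot distinguish
the two. The package's core is therefore a classification stage fed by
population panels, with dating, read assignment, and insertion-hallmark
annotation built around it.

## The model and its assumptions

**Fixation.** A site is polymorphic within a paralog iff at least two
distinct alleles are observed in its panel, and a fixed difference iff
both paralogs are monomorphic with different alleles. Fixation is always
relative to the observed panel; every call carries its panel sizes so that
"evidently fixed" remains evidence-qualified. Missing data (`N`) is
ignored, never counted as an allele.

**Polarity.** Outgroup orthologs polarize variants by unanimity, not
majority: the ancestral state is the state of all non-missing outgroups,
and any disagreement yields `ambiguous`. At the scale of a few fixed
differences, one conflicting outgroup is enough to make a site unusable,
and a majority rule would quietly convert such sites into data.
Mononucleotide repeat-length sites are always ambiguous — copy numbers
vary within and among species.

**The parent allele at origin.** The parent's reference haplotypes are
merged by converting every inter-reference substitution to its ancestral
state (ambiguous positions become `N` and are counted; indel discordances
are flagged and their regions excluded). This reconstructs the allele the
retrocopy actually arose from.

**The clock.** With `k` fixed, *retrocopy-derived* substitutions over `L`
compared sites and rate `r` (substitutions/site/year), the age is
`t = k/(L r)`. Polarization matters: the parent gene is under purifying
selection while the retrocopy evolves neutrally at the retropseudogene
rate, so substitutions are counted on the retrocopy lineage against the
reconstructed parent allele. The estimator is linear, not Jukes-Cantor
corrected: at `d = k/L ~ 0.001` the correction is below 0.2% (a `jc69`
toggle exists for larger divergences). Rate uncertainty — the only
uncertainty the procedure propagates — maps the published rate range
`[0.5e-9, 1.35e-9]` to the age interval `[k/(L r_high), k/(L r_low)]`.
Substitution-count stochasticity is deliberately not propagated, matching
the procedure being reproduced; the recovery experiment (below) quantifies
what that omission costs.

**Phylogenetic bounds.** Presence in a sister lineage bounds the origin
from below by that divergence; absence bounds it from above. Published
divergence estimates conflict, so the envelope is configurable; the
default is `outer` (interval minimum for the lower bound, maximum for the
upper), the most permissive reading, because the package has no basis for
adjudicating between published estimates. `combine_evidence()` intersects
the clock interval with the bounds and flags inconsistency rather than
silently clipping.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| rate point / range | 1.25e-9; 0.5e-9–1.35e-9 /site/yr | published retropseudogene rates |
| alignment scoring | +2/−3, gap −5 −2/base | megablast-like; inputs are >99% identical so the scheme is non-critical but pinned for determinism |
| repeat-run threshold | 8 | shorter runs rarely show length polymorphism; longer runs are excluded from substitution counts |
| TSD scan | exact match, min 6, max 30 | recent insertions carry intact TSDs; shorter matches are chance |
| poly(A) | window 50, min 8, purity 0.8 | tuned to detect decayed remnants, not pristine tails |
| junction k-mer | k = 18 | 36-mers are locus-specific in a 10-kb context yet tolerate nearby substitutions |
| read margin | 1 mismatch | a read is conclusive when strictly closer to one paralog |
| read min overhang | 10 nt | junction "spanning" needs both sides anchored; the sources give no value, 10 is this package's choice |

Indels are left-aligned (shifted 5') before reporting. HGVS prescribes
3'-most normalization; the variant-ledger style this package reproduces
prints ancestral-first labels whose placement is ambiguous, and the 5'
convention reproduces those labels exactly. The rotation condition differs
by event type (deletions test the base before the event, insertions the
anchor base itself) — an asymmetry that the round-trip property test
(apply calls to the ancestral row, recover the derived row bit-exactly)
pins down.

## The synthetic world

`simulate_history()` emulates the study design the package targets: a
four-exon parent gene (197-nt 5' UTR, 918-nt reading frame including the
stop, 967-nt 3' UTR with two long poly(T) tracts), outgroups at
hominid-like divergence times (6, 8, 13 My), a retrocopy created 1.0 My
ago from the *deletion-carrying* parent allele (a segregating 22-nt 3'
UTR deletion at frequency 0.416), reverse-complemented with a 16-nt
poly(A) and inserted into a 3-kb host element with a 15-nt TSD, a GC-box
motif planted upstream in reverse orientation, and panels of 94 sequences
per paralog with 8 planted polymorphisms each (MAF 0.1–0.5).

Modeling choices, made once:

- **Uniform substitution model** (JC-like, no transition bias, no rate
  heterogeneity): the clock being validated is rate-only, so a richer
  generator would test robustness, not correctness.
- **Infinite sites**: mutation positions are drawn without replacement
  from a shared pool, so planted counts are exact at these divergences and
  outgroup unanimity holds by construction at focal sites.
- **Both branches diverge** after the retrotransposition: the generator
  plants `~2 L r t` parent-vs-retrocopy differences, of which only the
  retrocopy-derived half counts toward `k` after polarization. This is
  what makes `k/(L r)` unbiased for `t` and is exactly why polarization is
  part of the method rather than an optional refinement.
- **Deterministic hallmarks**: the generator guards its plantings — the
  TSD cannot extend by chance, the poly(A) cannot absorb adjacent A's
  under the purity rule, the motif has no chance occurrence in the scanned
  window — so hallmark recovery is exact, not approximate, and a failed
  recovery is a bug, not noise.

What the generator does *not* emulate: coalescent genealogies and linkage
(panel alleles are drawn i.i.d. at each site), recombination (the
recombinant haplotypes of real data are out of scope), selection,
sequencing error in panels, and alignment ambiguity from tandem repeats
longer than the planted tracts. A green end-to-end test therefore
establishes that the pipeline's logic is correct under its stated model,
not that real panels of this size always suffice — the false-fixation risk
from finite panels is quantified separately (<5% at MAF ≥ 0.2 with 20
sequences; ~5e-5 at the default 94).

## Numerical and degenerate-input choices

- Ages display as My rounded half-up to one decimal (0.9135 → 0.9,
  2.466 → 2.5); raw years are always retained.
- Frequencies display at four decimals, half-up; raw fractions retained.
- `k = 0` dates to age 0 with a zero-width interval — the data place no
  lower bound.
- Reads containing `N`: `N` matches nothing, adding one mismatch against
  every paralog (conservative toward `tied`).
- Ties in read assignment: a unique verdict requires a strictly minimal
  distance with the configured margin; equal minima are `tied`, never
  broken arbitrarily.
- Empty masks return `(k = 0, L = 0)`; empty panels are an input error.
- A contradictory presence table (present taxon older than an absent one)
  is flagged with both bounds returned, not an error: the contradiction is
  a finding.

## Validation

The test suite checks every operation against an independent oracle where
one exists: alignment scores against an exhaustive Gotoh DP on small
strings, read assignment against brute-force placement, fixation calls
against direct allele-set counting, motif scans against a regex scan,
coordinate conversions against exhaustive round-trips, and the clock
against its closed form. The acceptance suite reproduces the published
quantities (point age ≈ 1.0 My from k=2, L=1622; interval 0.9–2.5 My; the
prior 5.2 My estimate; 3 fixed differences, 2 in frame; allele frequencies
0.5840/0.4160; codons 253 and 82) and runs a 1000-replicate parameter
recovery at t = 1.0 My, asserting unbiasedness within 3 SE and interval
coverage equal, within binomial error, to the Poisson prediction of the
rate-interval construction (~54%: a reminder that the published interval
propagates rate uncertainty only, not counting noise).

## Known limitations

- Single-transcript gene models; no full HGVS grammar (no inversions,
  duplications, complex alleles).
- Pairwise alignment only; families are handled as pre-aligned column
  stacks.
- No statistical tests of neutrality or selection, no Hardy-Weinberg
  testing, no Bayesian dating — the package reproduces a specific
  rate-interval procedure and says so.
- Diagnostic-site read assignment is gapless by default (an edit-distance
  mode exists); paired-end logic and mapping-quality models are out of
  scope.
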