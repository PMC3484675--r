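# retrodate

Dating and annotation of gene retrocopies from fixed and polymorphic
variants.

## The problem

A retrocopy (processed pseudogene or retrogene) is an intronless genomic
copy of a gene created by reverse transcription of its mRNA. Because a
young retrocopy is nearly identical to its parent gene — and often to a
whole family of older retrocopies of the same parent — three questions that
sound simple are genuinely hard:

1. **How old is it?** Differences between parent and retrocopy mix truly
   fixed substitutions (which record time) with modern polymorphisms in
   either paralog (which do not). Counting polymorphisms as fixed inflates
   the age.
2. **Which paralog did a short read come from?** Reads mapped among
   near-identical paralogs are routinely misassigned; only reads covering
   *diagnostic sites* — positions where one paralog differs from every
   other family member — are conclusive.
3. **What does the insertion look like?** A genuine retrocopy carries
   hallmarks: a target-site duplication (TSD) flanking the insertion, a
   poly(A) remnant, loss of all parental introns, and (often) residence
   inside a host repeat element.

`retrodate` implements this analysis as a tested pipeline for population
geneticists and comparative genomicists, with a synthetic-data generator
that produces truth-annotated inputs so every stage can be validated
end to end.

## The model

Sites observed in panels of both paralogs are classified per site: a site
is *polymorphic* in a paralog if two or more alleles are observed,
a *fixed difference* if both paralogs are monomorphic for different
alleles. Outgroup orthologs polarize each variant (unanimity rule):
the ancestral allele is the state shared by all non-missing outgroups.
Merging the parent's reference haplotypes at their ancestral states
reconstructs the parent allele at retrotransposition time.

The age of the retrocopy under a neutral molecular clock is

    t = k / (L * r)

where `k` is the number of fixed, retrocopy-derived substitutions across
`L` compared sites and `r` is the per-site per-year substitution rate for
neutrally evolving retropseudogenes (point 1.25e-9, published range
0.5e-9 to 1.35e-9). The rate interval propagates to an age interval
`[k/(L*r_high), k/(L*r_low)]`, which is reconciled against phylogenetic
bounds from presence/absence of the retrocopy in related lineages (present
in a sister lineage = older than that divergence; absent = younger).

## Worked example

```r
library(retrodate)

# the published ledger of variants between a parent gene and its retrocopy
led <- read_variant_ledger(system.file("extdata",
        "nanog_nanogp8_ledger.tsv", package = "retrodate"))
calls <- classify_fixation(led$parent, led$retro)
calls$position[calls$status == "fixed_difference"]
#> [1] "*606" "144"  "759"

count_fixed_differences(calls, led$positions[led$in_reading_frame])$k
#> [1] 2

# molecular clock: 2 fixed differences over 1622 compared sites
age_interval(2, 1622, rate_model(1.25e-9, 0.5e-9, 1.35e-9))
#> <age_estimate> k=2 over L=1622 sites: 1.0 My (interval 0.9-2.5 My)

# allele frequencies of a polymorphic parent-allele deletion
tb <- read_genotype_table(system.file("extdata",
        "genotype_counts.tsv", package = "retrodate"))
allele_freqs(tb)$display
#> ancestral   derived
#>  "0.5840"  "0.4160"

# synthetic history with known truth (true age 1.0 My), dated end to end
b <- simulate_history(sim_config(seed = 42))
run_pipeline(b, presence = data.frame(
  taxon = c("neanderthal", "chimpanzee"),
  status = c("present", "absent"),
  div_low = c(2.7e5, 5.5e6), div_high = c(8.0e5, 7e6)))
#> <pipeline_summary> k=3 over L=2027 sites
#>   clock: 1.2 My (interval 1.1-3.0 My)
#>   bounds: 2.7e+05-7e+06 years (consistent)
#>   features: TSD 15 nt, poly(A) 16 nt, orientation reverse
```

The fixation filter reports exactly three fixed differences in the shipped
ledger, two of them in the reading frame; with the published rate range the
clock places the retrocopy's origin at roughly 0.9–2.5 million years, and
the synthetic pipeline recovers the planted insertion hallmarks (15-nt
TSD, 16-nt poly(A), reverse orientation) and the planted fixed-difference
count exactly.

## Command line

An executable wrapper is installed as `exec/retrodate` with subcommands
`simulate`, `run`, `align`, `variants`, `classify`, `date`, `features`,
`assign-reads`, `popfreq`, all honoring `--seed`, `--config`, `--verbose`,
`--out`. See `vignettes/retrocopy-dating.Rmd` for the methods account.
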