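# tailslip

Analysis of de novo SINE (Alu-type) insertions recovered from
culture-based rescue assays, centred on what a disruption-tagged A-tail
reveals about target-primed reverse transcription (TPRT).

In a rescue assay, a tagged SINE whose 3' polyA tail carries short non-A
"disruption" marker strings (e.g. the 82-nt A70D tail:
`A17-CATTAC-A18-G-A17-CACAC-A18`) is mobilized in trans by L1 ORF2p and
recovered from transfected cells together with its pre- and
post-insertion genomic flanks. Because the parental tail composition is
known exactly, every recovered insert reports on the insertion
machinery:

* **Hallmark recovery** — the target-site duplication (TSD, the direct
  repeat flanking a TPRT insert), the match of the cleavage site to the
  L1 endonuclease consensus 5'-TTTT/AA-3' (scored 0-6 on the nicked
  strand), 5' truncation of the element body, and a mismatch scan of the
  body (excluding its unstable A-rich middle). Events lacking these
  hallmarks are classed as chimeric recombination with a genomic Alu or
  as endonuclease-independent insertion.
* **A-tail segmentation** — each observed tail is parsed against its
  parental template: which disruptions survive locates the TPRT priming
  position (the insert retains the template *prefix* 5' of the priming
  point, because reverse transcription runs 3'→5' along the RNA), the
  last retained segment is the *terminal* segment, and per-segment
  length changes quantify expansion or contraction. Duplicated
  disruption strings are the direct signature of replication slippage.
* **Slippage simulator** — a generative model of slippage during
  reverse transcription of the homopolymeric tail: before each
  incorporated nucleotide the nascent cDNA dissociates with probability
  `p_dissoc0 * exp(-L / decay_scale)` (L = cDNA length) and re-anneals
  3'-ward (duplicating template positions, probability `p_duplicate`)
  or 5'-ward (deleting them). Stability grows with cDNA length, which
  reproduces the 3' bias of A-tail expansion.
* **Placement and enrichment** — a karyotype copy-number-weighted
  integer-space sampler for random-insertion null cohorts (flank G+C and
  repeat-class content summaries), and permutation-calibrated
  Mann-Whitney-Wilcoxon tests with Bonferroni correction contrasting
  genomic-feature distributions between insert-containing and
  insert-free windows.
* **Synthetic data** — an annotated multi-chromosome fixture genome
  (planted repeats, gene models, conserved elements, endonuclease
  consensus sites) and simulated insertion cohorts with full ground
  truth, so the entire pipeline runs and is testable with no external
  downloads.

## Worked example

```r
library(tailslip)

genome    <- generate_genome(chrom_sizes = c(chr1 = 80000L, chr2 = 60000L),
                             en_site_per_kb = 1, seed = 424242)
construct <- default_construct("A70D")
cohort    <- generate_cohort(genome, construct, n = 50, seed = 101)

chars <- characterize_cohort(cohort$records, construct,
                             repeats = genome$repeat_library["Alu"])
summ  <- summarize_characterization(chars)
summ$class_counts
#> TPRT_typical
#>           50
sprintf("DR mean %.1f (median %d, range %d-%d, n=%d)",
        summ$dr_mean, summ$dr_median, summ$dr_range[1],
        summ$dr_range[2], summ$dr_n)
#> "DR mean 15.6 (median 15, range 5-27, n=50)"
attr(summ$pfm, "consensus")
#> "TTTTAA"

parses <- lapply(chars$tail_seq[chars$insertion_class == "TPRT_typical"],
                 segment_tail, template = construct$tail)
summarize_tail_cohort(parses, construct$tail)
#> <tail_cohort_summary> n=50 | internal n=80 median=22.0 |
#>   terminal n=50 median=34.5 | contracted=11 | dup events=6
#>   internal vs terminal: U=1343.5 p=0.00168
#>   priming counts: 6/15/20/9 | GOF X2=9.71 p=0.0212
```

Reading the output: all 50 simulated events carry the TPRT hallmarks
(class `TPRT_typical`), their direct repeats average 15.6 bp, and the
pre-integration consensus recovered from the cleavage windows is the
canonical `TTTTAA`. The tail summary shows the 3' expansion bias: the 50
terminal segments (median 34.5 adenosines) are significantly longer than
the 80 internal segments (median 22.0; two-sided Mann-Whitney
p = 0.0017) against a parental segment length of 17-18, contraction
appears only in terminal segments (11 internally primed events), six
tails carry a duplicated disruption, and priming departs from the
uniform-over-tail null (chi-square goodness of fit p = 0.02).

A file-based pipeline (`pipeline_simulate()`, `pipeline_characterize()`,
`pipeline_tails()`, `pipeline_enrich()`, or `pipeline_all()`) writes the
same analyses as seed-stamped FASTA/BED/GFF3/TSV/JSON artifacts; a thin
command-line wrapper lives at `inst/cli/tailslip.R`. The methods
vignette (`vignettes/tail-slippage-analysis.Rmd`) documents the models,
conventions and parameter choices.

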