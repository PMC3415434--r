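---
title: "Disruption-tagged A-tails: hallmark recovery and slippage analysis of de novo SINE insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disruption-tagged A-tails: hallmark recovery and slippage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailslip)
```

## The measurement problem

Alu and other SINEs are mobilized in trans by the L1 ORF2 protein
through target-primed reverse transcription (TPRT): the endonuclease
nicks genomic DNA at a T-rich consensus (5'-TTTT/AA-3' on the nicked
strand, cut between the fourth T and the first A), the exposed
thymidines base-pair with the element RNA's 3' polyA tail, and reverse
transcription proceeds 3'→5' along the RNA. New inserts show a
characteristic set of hallmarks — a target-site duplication (TSD)
flanking the element, the endonuclease consensus at the pre-integration
site, an A-rich 3' tail — and, puzzlingly, tails that are much *longer*
than the parental source tail.

A homopolymeric tail is informationless: nothing in `AAAA...` records
where priming happened or where nucleotides were gained. The rescue
constructs modelled here solve this by tagging the parental tail with
short non-A *disruption* strings. `tailslip` implements the full
analysis that such tagged cohorts enable, plus generative simulators
that serve both as explicit models of the biology and as the source of
ground-truth test data.

## Tail templates and the construct reference

A `tail_template` is an ordered list of polyA segment lengths with the
disruption strings between them. Two built-ins mirror the published
construct variants:

```{r templates}
builtin_template("A70D")  # renders to 82 nt
builtin_template("A30D")  # renders to 35 nt
```

The A70D segment order is stated in the source material only as "17 or
18 adenosines" per segment with a 70-A total; the default order
17,18,17,18 satisfies both constraints and is configurable
(`a70d_order`). Disruptions may contain internal adenosines (CATTAC,
CACAC) but must not start or end with one — a flanking A would be
indistinguishable from segment adenosines, making the rendered sequence
ambiguous. Custom templates (e.g. for B2 or BC1 constructs) load from a
small YAML file via `read_tail_template()`.

A `construct_reference` joins a SINE body to a template and records the
body's A-rich middle, which mismatch scans exclude because its length is
unstable through cloning. The default body is a fixed synthetic 286-nt
pseudo-SINE — not a natural Alu — engineered to be free of terminal A's
and internal endonuclease consensus matches so that the body/tail and
junction boundaries in simulated data are exact.

## Parsing an observed tail

`segment_tail()` parses an observed tail against its template. Maximal
A-runs become segment observations; at each non-A position the scanner
tries, in order of preference:

1. an exact match of the next expected disruption,
2. an exact match of a *later* disruption (the intervening ones were
   lost; recorded in `skipped`),
3. a re-occurrence of an already-seen disruption — a *duplication*
   token, the sequence signature of slippage,
4. a fuzzy match of the next expected disruption (1 substitution for
   disruptions of 3+ nt; 1-2 nt disruptions must match exactly, since a
   single tolerated mismatch would make any stray base "match" the
   1-nt disruption G).

Anything else is an unparseable chunk; the parse continues. Matching is
substitution-only (no indels): the assay's point-mutation rate is of
order 1e-4, so one substitution of tolerance is enough, while indel
tolerance would blur the segment-length signal the whole analysis rests
on. Fuzzy lookahead is deliberately disallowed — a lost disruption
implies a deletion slip, which is rare, so a fuzzy lookahead would
mostly fire on slippage fragments.

Because cDNA synthesis runs 3'→5' on the RNA, an insert retains the
template *prefix* up to the priming position. The template index of the
last observed segment is therefore the TPRT priming segment; the insert
types follow from the highest retained disruption (with the
three-disruption template: A = all three, B = first two, C = first one,
D = homopolymer). A terminal segment shorter than its parental length
implies internal priming within that segment;
`priming_offset_estimate` converts this to a tail coordinate, exact when
no slippage altered the terminal segment and an estimate otherwise.

`reconstruct_tail()` re-concatenates the token stream and always equals
the input — the parse never loses sequence.

## Hallmark recovery from locus pairs

`characterize_insert()` consumes a pre-/post-insertion locus pair.

**Anchoring.** The construct body is located by its 3'-terminal 20-mer
(5' truncations never remove it; earlier 20-mers are fallbacks, and both
orientations are tried, so minus-strand integrants are handled by
working on the reverse complement). The body's 5' extent is then
recovered by a gap-free score walk (+1 match, -2 mismatch, argmax):
against random flanking sequence the score decays, so the argmax
separates body from flank robustly even with occasional point mutations,
and its distance from the body start is the 5' truncation.

**Tail/TSD boundary.** The region 3' of the body is tokenized with the
same scanner as `segment_tail()`. The tail cannot be delimited greedily:
target-site sequence can mimic a disruption token (a genomic `G`
followed by `A` reads exactly like the 1-nt disruption), and slippage
fragments can look unparseable. The boundary is therefore resolved
jointly with the duplication: every A-run token end is a candidate
junction, and the candidate whose following sequence forms the longest
direct repeat (at least `min_tsd`, default 5 nt) with the sequence
immediately 5' of the insert wins. Candidates stop accumulating once
cumulative unparseable content exceeds what slippage fragments produce
(12 nt or 4 chunks) — without that cap, homology between a genomic Alu
at the junction and Alu sequence deeper in the flank can masquerade as
a huge "duplication". When no candidate yields a qualifying repeat (the
atypical classes), the strict greedy end is used.

**Junction A's.** A TSD that begins with adenosines — forced at perfect
endonuclease sites, where the duplicated target starts `AAAA` — is
ambiguous against the tail end. Both conventions are implemented:
`a_policy = "tail"` (default) counts junction-adjacent A's into the
tail, shortening the reported TSD by its leading A-run;
`a_policy = "tsd"` gives trailing tail A's back to the duplication up to
the boundary that maximizes the anchored repeat. The choice shifts
TSD-length and terminal-segment-length accounting in opposite
directions; the simulator records ground truth under the same convention
so recovery is exact either way.

**Endonuclease score.** The 6 positions spanning the cleavage point are
scored against the consensus on the nicked strand, in both orientations,
better orientation reported. Under the tail-first policy the apparent
duplication start is displaced 3' by the absorbed A-run, so the score is
taken at the raw cleavage (duplication start minus the A-run immediately
5' of its recovered copy); for minus-strand elements the window is
evaluated in the original genomic orientation.

**Classification.** `TPRT_typical` requires a TSD of at least 5 nt and
an endonuclease score of at least 4/6; `chimeric_recombination` requires
no qualifying TSD and an insert 5' region matching an annotated genomic
Alu at 90% identity over 30 nt (local alignment); `endonuclease_independent`
requires no TSD, no chimerism and a sub-threshold score. Conflicting
evidence yields `ambiguous` with reasons. The numeric thresholds are
package choices — the source material describes these classes
qualitatively — and all are arguments.

## The slippage simulator

`reverse_transcribe_tail()` draws a priming position uniformly over the
tail's segment adenosines beyond `min_prime_offset` (default 20 nt; the
observation it encodes is reported variously as 20 and as 25 nt, and the
parameter is exposed). Copying proceeds one nucleotide at a time; before
each incorporation the complex dissociates with probability

  p_dissoc0 * exp(-L / decay_scale)

where L is the current cDNA length. The exponential form is a modelling
choice; the mechanism it encodes is only that duplex stability grows as
the cDNA lengthens. A dissociation re-anneals 3'-ward with probability
`p_duplicate` (re-copying template positions: expansion) or 5'-ward
(deletion), with a truncated-geometric span (mean 3, max 10 nt). A slip
whose span crosses a non-A template position completes only with
probability `p_cross_disruption` (default 0.05): re-annealing pairs the
nascent poly-T with the polyA tract, and a register shift across a
disruption requires fortuitous base pairing. This term is what
reconciles strong within-run expansion with the observed rarity of
duplicated disruptions.

Defaults (`p_dissoc0 = 0.7`, `decay_scale = 40`, `p_duplicate = 0.9`)
were calibrated once, by simulation against the published cohort-scale
observations for the long template — terminal segment median of roughly
40 adenosines versus low-20s for internal segments, contracted terminals
in a minority of inserts, duplicated disruptions in a few percent — and
then frozen. `replay_slippage()` deterministically replays a recorded
slip-event list; its output always equals the realized tail (slippage
conservation), which is the invariant the recovery tests lean on.

With `p_dissoc0 = 0` the realized tail is exactly the template prefix up
to the priming position. That regime defines the *recovery cohort* used
in the acceptance suite: without slippage noise, TSD length, truncation,
priming offset and class are all information-theoretically recoverable,
and the pipeline recovers them at 100%. With slippage active, TSD,
truncation and class remain exact, but a slip within the first few
copied nucleotides can garble the disruption adjacent to the priming
point, so priming-segment recovery is necessarily imperfect — a property
of the data, not the parser.

## Synthetic genome, placement and enrichment

`generate_genome()` builds background sequence at a target GC fraction
(default 0.41) and plants, largest-first into free gaps: diverged copies
of fixed per-class repeat consensi (Alu/L1/L2/MIR/MaLR at roughly
genomic densities), two-exon gene models with UTR/CDS/intron
substructure, conserved elements, and extra perfect endonuclease sites
at a controllable density. Planted intervals *are* the annotation truth
— repeats are planted, not discovered. Fixed seeds give byte-identical
genomes. The fixture default (two chromosomes of 350 kb total, 2-kb
feature windows) stands in for the genome-scale analysis (thousands of
1-Mb windows); all window logic is size-parameterized, and the tests'
problem sizes (cohorts of 500, 1000-template round trips, 6000 placement
draws) were chosen as the smallest at which the statistical assertions
are stable.

`build_integer_map()` maps the genome to consecutive integer space with
each region's allocation proportional to its karyotype copy number (the
copy number itself, not copy number/2 — only relative weights matter for
sampling). `sample_insertions()` draws integers uniformly and maps them
back to inter-base positions; `summarize_flanks()` reports cohort mean
percent G+C and percent repeat-class coverage over clipped flanks
(denominators use realized flank lengths).

`permutation_test()` contrasts a feature between insert-containing and
insert-free windows with the Mann-Whitney U statistic (authored here:
midranks, tie-corrected variance, continuity correction, exact
enumeration when the pooled size is at most 10 — cross-checked in the
tests against `wilcox.test` and a pairwise-enumeration oracle, which are
never the implementation). Labels are reshuffled preserving class sizes;
empirical p-values use add-one smoothing (b+1)/(B+1), with "as or more
extreme" defined on the U statistic centred at its null mean and ties
counted as extreme; two-, left- and right-sided values come from the
same null sample. `bonferroni_adjust()` is the capped product min(1, m p).
The recombination-hotspot 13-mer CCNCCNTNNCCNC is counted with
overlaps on both strands by default (the biology is strand-symmetric;
single-strand mode available).

## The synthetic supplementary stand-ins

The published per-insert tables are distributed as binary spreadsheet
attachments, so `synthetic_direct_repeats()`, `synthetic_insert_table()`
and `synthetic_tail_cohort()` provide deterministic reconstructions at
the printed marginal statistics (cohort sizes and class counts,
direct-repeat mean/median/range, priming histogram, segment-length
medians, contraction and expansion counts). They are synthetic:
individual rows are not the published inserts, and any analysis finer
than the pinned marginals reflects the reconstruction, not the data.
Two accounting conventions were forced by internal consistency:
the terminal expansion fraction is computed over end-primed terminals
only (95.9% is exactly 71/74; over all 91 terminals it cannot coexist
with 17 contracted terminals), and the internal fraction's printed 55.6%
is not representable with 143 internal segments, so the stand-in carries
the nearest attainable 80/143 = 55.9%.

`summarize_tail_cohort()` reports both expansion markers (net gain of at
least 4 adenosines, and the alternate "at least 40% longer than
parental"), both "complete tail" counts (all disruptions present, and
additionally all segments observed), and a chi-square goodness of fit of
priming-segment counts. The GOF null is priming uniform over the tail's
adenosines (expected counts proportional to parental segment lengths);
excluding the first `min_prime_offset` positions is available via
`prime_offset_excluded`, but is not the default because it assigns zero
eligible length to segment 1 of the long template while segment-1
priming is actually observed — the function falls back to the
unrestricted null with a warning if that happens.

## Known limitations

* The fixture genome has uniform random background: no isochore
  structure, CpG islands, tandem repeats or assembly gaps, so
  enrichment results on it validate machinery, not genome biology.
* Chimera detection matches the insert 5' region against a supplied
  repeat library rather than locally annotated flanking copies.
* Untemplated nucleotide addition at the RNA 3' end is not simulated.
* Junction conventions make simulated cohorts exactly recoverable;
  real recovered loci can present ambiguities (e.g. an A-rich flank)
  that the conventions resolve by fiat rather than evidence.
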