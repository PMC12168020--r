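---
title: "Scarless promoter-replacement library design and QC with promotune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scarless promoter-replacement library design and QC with promotune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotune)
```

## The problem

Tuning the expression of a chromosomal gene in yeast — for example a
transcription factor suspected to limit production of a metabolite, or to
gate a stress response — is most cleanly done by replacing its native
promoter with a characterized promoter of chosen strength, or deleting the
promoter outright, while leaving the coding sequence untouched.  Doing this
for dozens of targets at seven expression levels each calls for a pooled,
library-scale workflow: one synthesizable DNA element per target that
carries both the CRISPR guide and the repair template, a one-pot reaction
that combinatorially installs the promoter set, and a sequencing-based QC
step that confirms the pool really contains every intended construct.

`promotune` implements that workflow at the design desk: guide selection,
homology-arm extraction, element assembly, in silico Golden Gate, long-read
pool QC, and the downstream screening statistics.  Everything runs on plain
FASTA/GFF3/FASTQ/TSV files, and a fixtures module generates deterministic
toy inputs so the full pipeline is testable without any external data.

## The synthetic element

Each target gets one gene-block element with a fixed layout:

```
gibson_left(20) | spacer(20) | linker(80) | up_arm | SapI cassette(36) | down_arm | gibson_right(20)
```

The fixed regions total 2·20 + 20 + 80 + 36 = 176 bp, so an element is
`2·arm_len + 176` bp long: **500 bp with 162-bp arms, 300 bp with 62-bp
arms** — the two arm lengths worth considering, trading homologous
recombination efficiency against array-synthesis cost.

Coordinates are gene-relative: position 0 is the first base of the
annotated start codon, negative positions run upstream, and minus-strand
genes are reverse-complemented on load so that "upstream" always means 5′
of the CDS.  Within that frame:

* the **downstream arm** is fixed at `[0, arm_len − 1]` — it begins with
  the ATG itself, which is what makes the design scarless;
* the **upstream arm** starts at the distal end of the 500-bp design
  window, `[−500, −500 + arm_len − 1]`, maximizing the deleted span of
  native promoter.  If it contains a SapI recognition site it slides 1 bp
  toward the ATG until clean; the slide stops (and the target is flagged
  design-failed) if the deleted interval between the arms would become
  empty.  A SapI site in the fixed downstream arm fails the target
  immediately, since that arm cannot move.

The region between the arms — the interval the promoter replaces — is
reported as `deleted_interval` and re-used by guide selection.

### The SapI cassette and why the junction is scarless

SapI is a type IIS enzyme: it recognizes GCTCTTC, cuts 1 nt downstream on
the top strand and 4 nt on the bottom, and leaves a programmable 3-nt 5′
overhang.  The 36-bp cassette between the arms carries two sites in
opposite orientations, pointing outward, so digesting the cloned plasmid
excises the entire cassette and leaves the backbone with two fusion sites:
a configurable upstream site (`o_up`, default `AAT`) after the upstream
arm, and — the key trick — **the downstream arm's own ATG** on the CDS
side.  Any promoter part flanked to produce the matching (`o_up`, `ATG`)
overhangs ligates in with no scar at the CDS boundary: the edited locus
reads `…up_arm · o_up · promoter · ATG·CDS…`, and the ATG that ends the
junction *is* the original start codon.  An empty-core part gives the
promoter-deletion variant (`…up_arm · o_up · ATG·CDS…`), the seventh
expression level.

The exact stuffer interior is not biologically constrained; the shipped
default is an arbitrary fixed 17-mer chosen free of SapI sites.  `o_up`
must differ from `ATG` (otherwise backbone self-circularization and
promoter insertion would be indistinguishable) and defaults to the
non-palindromic `AAT`.

In the fragment model, every 3-nt 5′ overhang is recorded as the
top-strand sequence of the annealed junction, and two ends are compatible
when those strings are equal — string equality in this representation is
exactly Watson–Crick annealing of the two complementary protruding
strands.  Ligation fidelity is ideal (only exact pairs join); mismatch
ligation is out of scope.

## Guide selection

Candidates are every NGG-adjacent 20-mer, on either strand, whose
predicted blunt cut (between protospacer positions 17 and 18, i.e. 3 bp
5′ of the PAM — canonical SpCas9 geometry) falls in the window
`[−200, −1]`: cutting inside the replaced promoter region guarantees the
edited allele loses the protospacer and cannot be re-cut.  With the
default `require_cut_in_deletion`, the whole protospacer+PAM must in
addition lie inside the deleted interval.

Published screens typically filter guides on a black-box efficiency score
with a "greater than 60%" threshold.  Such scores are not reproducible
from their descriptions, so `promotune` ships a transparent rule-based
stand-in with the same threshold semantics: start at 100, −30 if spacer GC
is outside [0.40, 0.80], −40 if the spacer contains TTTT (a Pol III
terminator for the sgRNA), −20 per perfect-match genomic site beyond the
on-target one, floored at 0.  The threshold is a strict `> 60`.

Off-targets are counted genome-wide as PAM-adjacent matches within
Hamming distance ≤ 2 (no bulges), using a precomputed index of all NGG
sites.  Ranking is fully deterministic: fewest extra perfect hits, then
fewest 1-mismatch hits, then highest score, then smallest cut-to-ATG
distance, then lexicographic spacer.

## Library assembly and QC

`assemble_basic_plasmid()` clones each element into a backbone via its
20-bp terminal Gibson overlaps (checked exactly; the diagnostic reports
the longest matching terminal run when a junction fails).
`golden_gate()` then digests every basic plasmid, requires exactly one
backbone fragment with fusion sites (`ATG`, `o_up`), and enumerates every
compatible backbone × insert ligation.  Products are verified SapI-free —
correct assemblies are irreversible because both recognition sites leave
with the stuffer.  Library diversity is the count of distinct
(target, promoter-state) products: T targets × (P promoters + 1 deletion).

Pool QC assigns long reads to constructs by exact diagnostic tags instead
of alignment — appropriate at toy scale and fully deterministic:

* the 20-nt spacer (and reverse complement) identifies the target;
* promoter-specific 31-mers, majority-voted, identify the promoter state
  (k-mers shared between promoters are dropped from both sets);
* 31-mers crossing the `o_up`/ATG junction identify deletion variants.

A read is assigned only if exactly one spacer tag matches and the
promoter vote has a strict majority (or a same-target junction tag when no
promoter tag is present); everything else is unassigned with a reason
code.  Per construct the report gives mean depth, coverage rate (% of
positions seen ≥ 1×) and abundance.  **Abundance is defined as the
assigned-read fraction** (one reasonable choice among several; it is
stated in the report header).  The depth model places each read by
anchoring its first spacer-tag match and spreading
`min(read length, construct length)` covered bases — a simplification
that is exact for full-length reads.

## Screening statistics

* `normalized_betanin()` — nAb = A535/OD600, the plate-reader proxy for
  red-pigment titer per cell density; invariant under common rescaling of
  both channels.  Blank correction is the caller's responsibility.
* `percent_change()` — 100·(sample − control)/control.
* `max_growth_rate()` — µmax as the maximum least-squares slope of
  ln(OD) over a sliding window of consecutive time points (default 5),
  using only points above `od_floor` (suggested: 3× the blank SD).  The
  estimator is the package's own choice — window OLS on log OD is the
  standard batch-culture estimator; the window size trades noise
  suppression against resolution of the exponential phase.  On noisy
  curves the max-over-windows construction has a small upward bias that
  vanishes with the noise (verified in the test suite).
* `rank_hits()` — percent-change descending, ties broken by strain id.

## What the toy generators emulate — and what they do not

`make_toy_genome()` places genes on alternating strands, one per
1000-bp block, each with ≥ 540 bp of upstream sequence and a 240-bp CDS
beginning ATG.  Two interventions keep the study conditions well-posed by
construction: SapI recognition sites are scrubbed from each gene's design
window (so clean designs exist unless a site is deliberately implanted via
`implant_sapi` for negative tests), and one benign, genome-unique
protospacer with a TGG PAM is implanted at `[−80, −58]` of every promoter
(so a selectable guide exists).  Real promoters are not random DNA: they
carry repeats, homopolymers, shared motifs and occasional unavoidable SapI
sites, so real designs will see more slid arms, failed targets and guide
score attrition than the toy genome shows.  Passing tests demonstrate the
correctness of the machinery, not design success rates on a real genome.

`simulate_reads()` draws full-length (or uniformly truncated) reads with
i.i.d. substitution errors at constant Q20, both orientations equally.
There are no indels, no homopolymer artifacts and no chimeras — enough to
exercise exact-match tag voting, but a real long-read error profile would
lower assignment rates further; the tag approach would need
indel-tolerant matching (or alignment) at realistic error rates.

`simulate_plate()` uses pure exponentials over 0–10 h with multiplicative
Gaussian noise: no lag phase, no saturation.  µmax recovery results on
these curves are therefore best-case.

All generators are pure functions of (spec, seed) with private RNG
streams that restore the caller's RNG state.

## Numerical and design choices

* Internal coordinates are 0-based half-open at the string level; GFF3 is
  converted on load; all user-facing gene-relative intervals are
  inclusive.
* `N` bases are tolerated in a genome but any design or scan window
  containing `N` fails loudly — synthetic constructs must be fully
  specified.
* Sequences are uppercased on load; duplicate FASTA headers and duplicate
  contig names are errors.
* Site scanning on circular plasmids wraps the origin and is
  rotation-invariant; overlapping recognition heptamers are an error.
* Tie-breaks everywhere are deterministic (no RNG outside the fixtures
  module).
* Problem sizes in the shipped tests: a 6-gene shared toy design for most
  module tests, 56 genes for the library-diversity check, 10-kb genomes
  for oracle-equivalence, 2 000–10 000 simulated reads for the recovery
  properties.  These sizes were chosen as the smallest that exercise the
  combinatorics convincingly.

## A worked example

```{r example, eval = FALSE}
tg <- make_toy_genome(toy_genome_spec(n_genes = 6, seed = 42))
des <- design_constructs(tg$genome, tg$annotations, arm_len = 162)
pool <- assemble_library(des, toy_promoters(), toy_backbone())
pool$diversity            # 6 targets x (6 promoters + deletion) = 42

idx <- build_tag_index(pool)
fq <- tempfile(fileext = ".fastq")
simulate_reads(pool, read_sim_config(n_reads = 420, seed = 1), fq)
report <- coverage_report(assign_reads(fq, idx), pool)
report
```

## Known limitations

* The efficiency score is a documented stand-in, not a trained on-target
  model; scores are comparable within this package only.
* Off-target search is Hamming-distance, PAM-NGG only (≤ 3 mismatches);
  no bulges, no alternative PAMs.
* Golden Gate is simulated with ideal fidelity and exactly two-fragment
  assemblies (one backbone, one insert).
* Read assignment is exact-match tagging, not alignment; it degrades
  quickly beyond a few percent substitution error and does not handle
  indels.
* The toolkit is assembly-agnostic: it makes no assumption about which
  genome release supplied the annotation, beyond gene + CDS features with
  `ID=` attributes.
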