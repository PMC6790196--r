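---
title: "Methods: clone-based allele calling, phasing and splice-event analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based allele calling, phasing and splice-event analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicekin)
```

# The study design this package models

Small multigene families inside the extended MHC class I region — the
butyrophilin-3A (BTN3A) cluster is the motivating case — are typically
characterized by PCR-amplifying each gene's cDNA from pedigreed colony
animals, cloning the amplicons, and Sanger-sequencing a few dozen clones
per animal and gene. Three analytical problems follow:

1. distinguishing true alleles from PCR/sequencing artifacts when no
   chromatogram-level consensus is available (only clone sequences);
2. deducing which alleles of the linked genes travel together on one
   chromosome, using Mendelian co-segregation in families;
3. making sense of the many non-constitutive cDNA structures that
   clone-based sequencing surfaces: exon skips, alternative splice sites,
   and their protein consequences.

splicekin implements this chain end to end, together with a synthetic
cohort generator that reproduces the design's statistical structure so
every stage is testable against planted truth.

# Gene model and coordinate conventions

A `gene_model` stores the gene-strand genomic sequence, ordered exon
intervals in 0-based half-open coordinates, the translation start offset,
and a per-exon domain label (IgV, IgC, TM, heptad, B30.2, UTR, other).
GFF3 input is converted from its 1-based inclusive convention at the
boundary; minus-strand genes are reverse-complemented once at load time so
that all downstream logic reasons in transcript orientation. Translation
uses the standard nuclear code; codons containing `N` translate to `X` and
are never inferred to be stops.

Stop positions are reported in two conventions used side by side in this
field: the global codon index from the CDS start, and an exon-local
"triplet" index. The local numbering restarts at the first complete codon
whose first base lies in the exon. With 29 complete codons contributed by
exon 1 (the default architecture), the pseudogene stop at exon-2 triplet
65 is CDS codon 94 — the two numbers used interchangeably for the same
stop in descriptions of these pseudogenes, which is what fixed this
convention.

# The synthetic cohort

`cohort_config()` defaults define the reference study conditions:

* **Gene architecture.** Nine exons per gene: a 150-nt first exon with a
  63-nt 5' UTR (87 coding nt = 29 codons), a long IgV exon 2 (351 nt), an
  IgC exon 3 (330 nt), a transmembrane exon 4 (117 nt), four short heptad
  exons (24/27/36/21 nt), and a large terminal B30.2 exon (807 nt, 690
  coding). All exon lengths are multiples of 3 and boundaries are
  codon-aligned — the symmetry that makes single-exon skips
  frame-preserving, as in the real family. Splice sites carry the
  mammalian consensus (donor `...CAG|GTAAGT`, pyrimidine tract + `CAG|G`
  acceptor).
* **Engineered stops.** Gene 4 is a pseudogene with an in-frame stop at
  exon-2 triplet 65; gene 2 ends naturally in its exon 7 (no B30.2), as
  BTN3A2 does. A stop is additionally planted in the exon-2 reading frame
  that the 112-nt deletion event exposes (see below), positioned so it
  cannot collide with the main frame; a scrub pass removes all accidental
  main-frame stops without touching planted codons or splice consensus.
* **Population.** Eight founder haplotypes (distinct allele tuples over
  the four genes), four alleles per gene at SNP rate 0.002/site between
  alleles (exonic only, at least 10 nt from any junction or planted
  feature, never creating a premature stop). Two independent families of
  four generations and 13 animals each (2 founders, then three children
  per generation with a founder spouse), drawing from the same haplotype
  pool. Haplotypes transmit intact (`recombination_rate = 0`, the
  tight-linkage assumption; a nonzero rate plants crossovers recorded in
  the truth set).
* **Clone libraries.** 32 clones per animal and gene, split into two PCR
  batches so the evidence rule's "independent PCRs" arm is exercisable.
  Errors are substitutions only, at 5e-4/site by default, so every length
  change in a clone is a splice event (clone-consensus indels are
  negligible in this design). The planted splicing spectrum gives each
  clone at most one event: transmembrane-exon (exon 4) skipping at
  frequency 0.06 in genes 1 and 2 only — mirroring its observed absence
  from the third functional gene — and a 112-nt exon-2-internal deletion
  bounded by an alternative 3' and 5' splice site at frequency 0.04-0.05
  in all four genes. 112 is not a multiple of 3, so this event always
  shifts frame and terminates translation inside exon 2.

What the generator does **not** emulate: chromatogram noise and indel
errors, allele-specific expression imbalance, PCR recombination between
paralogs (chimeras), partial-length clones, and homology between the
paralogs themselves (the four genes are independent random sequences, so
inter-gene sequence distance is near saturation — relevant to the distance
model choice below). Passing tests on this cohort therefore demonstrate
the correctness of the algorithms under the stated error model, not
robustness to every artifact of real Sanger data.

# Allele calling

Clones classified as alternatively spliced (or rejected by the aligner)
are excluded; the rest are grouped by exact sequence within a gene. A
cluster is validated iff it contains at least two clones differing in
animal or in PCR batch. No consensus-polishing or near-duplicate merging
is applied: the evidence rule alone separates errors from alleles, which
keeps the procedure transparent and auditable. Validated alleles get
serial names `gene*NN` in first-observation order. Genotypes collect, per
animal and gene, the validated alleles supported by that animal's own
clones; more than two is reported as an error (contamination or collapsed
paralogs), never truncated.

A quantitative limitation follows from the rule itself: two clones that
independently acquire the *identical* substitution are indistinguishable
from a real allele. With error rate $e$ per site over length $L$, a pair
of single-error clones of the same allele collides with probability
$1/(3L)$; at the default $e = 5\times10^{-4}$, $L \approx 2.8$ kb and 832
clones per gene, several such coincidences are expected per cohort, each
validating a spurious allele (and potentially pushing an animal past two
validated alleles, which surfaces as the genotype error above). This is a
property of the evidence rule at this cohort size, not of the
implementation; at error 0 recovery is exact, and the acceptance script
reports the measured spurious count under the error model rather than
hiding it. Gene assignment (when clones are not pre-assigned) is a
31-mer vote against each gene's reference transcript, a computational
stand-in for gene-specific primers; ties are left unassigned with a
warning.

# Haplotype phasing

Phasing is an exact search, not a heuristic: families in this domain are
small (under ~20 animals), so completeness is affordable. Founder phase
assignments are enumerated (first heterozygous gene fixed to break the
chromosome-swap symmetry), transmissions are propagated in pedigree order,
and each child's genotype constrains which parental gamete it received.
Untyped animals hold haplotypes of wildcards that unify against what
their relatives require. Events extend the gamete space: a single
inter-gene crossover or a single de-novo mutation per gamete, each at cost
1. Iterative deepening on the total event count means zero-event
solutions are found without ever exploring event branches; among
minimal-event solutions the assignment minimising distinct haplotype
count is chosen, with remaining ties broken by the lexicographically
smallest label sequence and the tie count reported in the metadata. If no
assignment within `max_events` (default 4) exists, the error names the
first child at which the search fails — the offending trio.

Co-segregation with an external labelling (e.g. MHC haplotypes) is scored
per transmission: the transmitted cluster haplotype is paired with the
external label contributed by the same parent, the modal pairing per
parental haplotype is taken as the chromosomal phase, and deviations are
discordant. Transmissions from haplotype-homozygous parents are excluded
as uninformative (the transmitted chromosome cannot be identified from
the cluster side), as are children whose external labels cannot be
attributed to a unique parent. When both parents carry a copy of the same
haplotype, the parental origin of a child's copy is genuinely ambiguous
from genotypes alone; the phaser's deterministic tie-break then fixes one
orientation, and an occasional transmission can appear discordant for
this reason rather than through any crossover.

# Spliced alignment and event classification

Alignment seeds on 15-mers that are unique in the gene and shared with
the transcript, groups them by diagonal, and extends across isolated
substitutions (a run of two mismatches ends extension). Block edges are
required to be clean — no mismatch within 8 nt of an edge — so chance
matches beyond a junction cannot drag boundaries along; the flip side is
that a clone carrying a substitution within ~8 nt of a junction becomes
unclassifiable (it is reported, excluded, and — being an errored clone —
was never usable for allele calling anyway). Adjacent blocks must be
contiguous in the transcript; leftover transcript gaps or genomic-order
violations are reported as unalignable (possible chimera), and under 80%
anchored coverage is a wrong-gene rejection.

The very short heptad exons need one extra step: a substitution in the
middle of a 21-36-nt exon can destroy every anchor k-mer it contains,
leaving the whole exon unanchored. Such interior transcript gaps are
rescued by placing the full annotated exon over the gap — trimming
flanking blocks back where they overreached the junctions on chance
matches — at the split minimizing mismatches, provided the placement is
unique and its mismatch count small.

Junction placement inside runs of identical bases is ambiguous; gaps are
canonicalized maximally 5'-ward. Because annotated junctions share the
same ambiguity, classification compares each observed gap with the
annotation over the gap's entire placement range: a placement matching an
annotated intron is constitutive; annotated flanks spanning whole exons
is a (multi-)exon skip; one annotated side with the other boundary inside
an exon is an alternative 3'/5' splice site (signed `shift_nt`), inside
an intron a partial intron retention; both boundaries inside one exon is
the paired alt-3'SS+5'SS class (the exon-internal deletion); an annotated
intron wholly inside a block is an intron retention, and a block wholly
inside an intron a cryptic exon. The junction-offset tolerance is zero:
clone-consensus quality justifies calling any deviation from annotation an
alternative site.

Consequences are computed on the isoform rebuilt from the gene reference
through the block chain (clone errors thus do not leak into protein
predictions). In-frame means the summed event length change is 0 mod 3.
Premature termination is decided by genomic position: the isoform's first
stop is premature iff it does not map to the constitutive stop codon —
robust for frame-preserving isoforms that end at the natural stop.
Domain retention is derived from the events (an exon is intact unless an
excising event touches it; retention-type events add sequence without
removing exons), combined with the frame state upstream of the exon and
the position of any premature stop. The soluble flag requires in-frame,
no premature stop, and a lost transmembrane exon. Tallying pools clones
by compound event key — events co-occurring in one clone count as one
combination, a deliberate choice since per-mechanism recounting of
multi-event clones is ambiguous — and categorizes keys observed at least
`min_count` (default 4) times, i.e. more than three observations.

# Splice-site models

The PWM scores $\sum_i \log_2 f_i(w_i)/bg(w_i)$ with a 0.5 pseudocount by
default and a floor of −20 bits per position for zero-frequency cells
when trained without pseudocount. The maximum-entropy model matches
per-position marginals and, at order "2-adjacent", all adjacent-pair
marginals. Training uses generalized iterative scaling; the feature
expectations it needs are computed by forward–backward dynamic
programming over the position chain, so the $4^{23}$ acceptor space is
never enumerated. One subtlety: with pseudocounts, independently smoothed
single and pair marginals are mutually inconsistent and scaling cannot
converge; the single-position targets are therefore derived from the pair
tables, which are chain-consistent by construction. Convergence is
declared at a maximum marginal discrepancy below `tol` (default 1e-8);
non-convergence is an error carrying the final discrepancy. With order-1
constraints only, the fitted distribution is exactly the product of
marginals, so maxent and PWM scores coincide — a cross-check the tests
exploit, alongside the closed-form chain factorization as an independent
oracle. Window conventions are the common donor 9-mer (3 exonic + 6
intronic) and acceptor 23-mer (20 intronic + 3 exonic); both are
configurable since nothing downstream depends on the exact widths. Site
comparisons are emitted per event with an explicit note that scores carry
no threshold: only the actual-versus-alternative comparison of sites of
the same type under the same model is meaningful.

# Phylogenetics

Distances are p (mismatch fraction) or Kimura two-parameter, always with
pairwise deletion of non-ACGT positions, mirroring the per-pair removal
of ambiguous sites. K2P was chosen as the correcting model because the
clustering claims being tested (gene-wise monophyly of ortholog families)
are robust to the distance model, and more elaborate simultaneous
estimation adds nothing testable here. Neighbour joining is the canonical
Saitou–Nei agglomeration with a deterministic tie-break (smallest label
pair, clusters labelled by their smallest member) and negative branch
lengths clamped to zero with the deficit recorded. Bootstrap resamples
alignment columns, rebuilds NJ per replicate, and reports bipartition
percentages; replicate bipartitions are counted after rooting every
replicate at a fixed reference tip, so unrooted bipartitions are counted
correctly regardless of each replicate's basal arrangement.

Two caveats are documented rather than papered over. First, the allele
tree built by the pipeline uses p-distances: the synthetic paralogs are
unrelated sequences, so inter-gene K2P distances would saturate (real
paralogs, being homologous, would not). Second, NJ does not *guarantee*
that a zero-distance pair ends as a cherry in pathological
configurations; with well-separated neighbours the pair's Q value is
strictly minimal and the cherry is certain, which is the configuration
the test uses.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains all stages, writes standard formats (GFF3/FASTA,
TSV, JSON, Newick), and emits a report whose every number is recomputed
from the configuration and seed; two runs with the same configuration are
byte-identical. Its default configuration is the error-free reference
study (`clone_error_rate = 0`), which demonstrates exact recovery;
error-model studies pass a nonzero rate explicitly and must expect the
evidence-rule phenomena described above, including a genotype error when
a coincident-error allele pushes an animal past two.

Problem sizes used by the test suite were chosen to exercise every code
path at comfortable margins: unit tests run one family of 5–13 animals at
clone depths 4–16; the end-to-end checks run the full default cohort (2
families × 13 animals × 4 genes × depth 32 = 3,328 clones); the
classification round-trip covers 576 error-free clones; bootstrap checks
use 100–500 replicates on 500-nt alignments; minimum-evolution
cross-checks enumerate all topologies for 4–5 taxa. The acceptance script
reruns the full default cohort and 500 bootstrap replicates.

# Known limitations

* The evidence rule's coincident-error ceiling (quantified above) is
  inherent to exact-match validation at high clone counts; segregation
  analysis downstream would flag most spurious alleles, but that
  cross-check is deliberately not folded back into calling.
* Substitutions within ~8 nt of a junction make a clone unclassifiable
  rather than risking a misplaced junction call.
* The classifier assumes transcripts run the gene's full length (clone
  ends anchored); partial clones are rejected as unalignable.
* The phaser's event model allows one crossover or one mutation per
  gamete; two independent events in a single gamete are beyond the search
  space and surface as a Mendelian inconsistency.
* The generator's paralogs share no homology, so cross-gene analyses that
  depend on paralog similarity (e.g. chimera detection thresholds) are
  exercised only qualitatively.
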