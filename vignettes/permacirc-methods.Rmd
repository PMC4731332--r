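---
title: "Discovering a permuted circular ncRNA gene: models and methods"
author: "permacirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a permuted circular ncRNA gene: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permacirc)
```

## The biological problem

Some *Thermoproteus* species carry no annotated signal recognition particle
(SRP) RNA gene, although SRP19 and SRP54 proteins and signal peptides are
present.  The resolution is a *permuted* SRP RNA gene: the transcript's 5'
and 3' termini sit not in helix 1 but at the tip of helix 8, and the mature
molecule is a covalently closed circle.  The precursor carries a short
leader and trailer that fold together into a bulge-helix-bulge (BHB) motif
— the substrate of the tRNA splicing endonuclease — whose two bulge cuts
define the mature termini; RtcB-style ligation then circularizes the RNA.
The computational signature of such a gene in small RNA-Seq data is
threefold:

1. conserved sequence anchors (a GNAR tetraloop, the SRP54-binding motif of
   helix 8b) inside a strongly folding intergenic region;
2. reads that align with one arm at one terminus and carry the *distant*
   terminus as a soft clip — junction-spanning reads that all imply one
   identical ligation point;
3. a BHB at the junction flanks whose predicted cleavage positions coincide
   exactly with the observed termini.

`permacirc` implements this discovery procedure as a reusable pipeline, and
ships a synthetic-locus generator so every stage is testable without access
to the original sequencing data.

## Coordinates and containers

All coordinates are **1-based and closed** (the IRanges/GRanges idiom);
BED's 0-based half-open convention is produced only on export via
`rtracklayer`.  A junction stores `acceptor` (first mature base) and
`donor` (last mature base), so the circle length is
`donor - acceptor + 1`.  Cleavage positions are reported as the first
nucleotide 3' of the cut along the transcript, so a validated BHB satisfies
`cleavage1 == acceptor` and `cleavage2 == donor + 1` (mirrored on the
minus strand).  Sequences are held in `Biostrings` containers
(`DNAStringSet`, `QualityScaledDNAStringSet`); U is normalized to T on
input so a single alphabet serves the pairing and alignment code.

## The synthetic locus

`buildLocus()` assembles
`flank | TATA | gap | leader | circle | trailer | spacer | C/D box sRNA | flank`
over an i.i.d. background with configurable GC content.  The defaults *are*
the study conditions of the published locus: a 309-nt circle, a 23-nt
leader, and a `TTAATA` box separated from the TSS by 26 nt (the geometry
of the characterized *T. tenax* locus).  Three elements are planted:

* a **BHB cassette** at the circle boundaries.  Walking the leader/trailer
  duplex: a 5-bp outer helix (leader:trailer), a 3-nt bulge on the leader
  strand crossing the acceptor, the 4-bp central helix, a 3-nt bulge on the
  trailer strand crossing the donor, and a 4-bp outer helix formed by the
  mature 5' and 3' ends — the helix-8 stem that is restored on ligation.
  Cutting after the second nucleotide of each bulge lands exactly on the
  mature termini, so the generator and the detector share one cleavage
  convention (`cutOffset = 2`, configurable to 1; published
  secondary-structure diagrams of such junctions place the cut inside the
  bulge without fixing its exact position, so this is deliberately a
  configuration item, not an assertion).  Single `A`
  borders flank the cassette so that background bases cannot extend the
  planted helices, and the bulge letters are chosen so that the genome
  continuation differs from the circle continuation on both sides of the
  junction — local alignments of junction reads therefore stop exactly at
  the termini instead of absorbing a lucky matching base.
* a **GNAR tetraloop** as the loop of a constructed 5-bp hairpin, and an
  instantiation of the **helix-8b pattern**.  No exact consensus sequence
  is established for the SRP54-binding motif of helix 8b, so the default
  `"RGCGGCAGG"` is a documented placeholder: the generator plants whatever
  pattern the configuration specifies, keeping generator and detector
  symmetric rather than inventing biology.

Spurious `TTAATA` occurrences in the TSS-proximal search window are
scrubbed from the background so the planted box is the nearest match — on
real data a nearer spurious box would simply be reported.  Because a
"26 nt upstream" distance can be anchored at either end of the motif, the
TATA caller reports both offset conventions (from the motif's 3' and from
its 5' base).

### Read model

Circular reads are uniform substrings of the doubled circle string
restricted to start inside the circle, so a read crosses the junction at
most once (`readLen < C` is enforced; at the default 75-nt reads and 30x
depth about 24 reads span the junction with at least 8 nt on each side).
Precursor reads are substrings of `[TSS, trailer end]`; a configurable
fraction (default 0.6) starts *exactly* at the TSS.  This models how
small-RNA libraries work: adapters are ligated to intact molecule termini,
so primary 5' ends pile up at the TSS, which is precisely the evidence the
TSS caller uses.  A fully uniform fragment model would carry no TSS signal
at all and no caller could recover the leader from it.  Errors are i.i.d.
substitutions; indels, PCR duplicates and paired ends are out of scope.
What passing tests show is therefore recovery under substitution noise on
a compact locus with a unique background — not robustness to repeats,
structural variation or coverage biases of real libraries.

## Read processing

The standard small-RNA preprocessing settings are recast as explicit,
oracle-testable algorithms:

* **Quality trimming** (`qualityTrim`, limit 0.05): Mott-style maximum-sum
  trimming on error probabilities — each Phred Q becomes
  `p = 10^(-Q/10)` and the retained segment maximizes `sum(0.05 - p)`
  (ties: leftmost, then longest).  An exhaustive O(n^2) substring oracle
  checks it.  Reads with more than 2 ambiguous bases *after* trimming are
  discarded (the ordering is a choice; the source settings do not say).
* **Adapter trimming**: longest read suffix matching an adapter prefix with
  at least 3 nt overlap and at most 10% mismatches.
* **Length filter**: 15-nt cutoff.
* **Alignment** (`alignReads`): seed-and-extend with exact 12-mer seeds and
  full affine-gap Smith-Waterman (compiled) over seed-nominated windows,
  both strands.  Match +1 and mismatch -4 encode the stated "mismatch cost
  4"; gap costs (open 6, extend 1, a length-L gap costing `6 + L`) are the
  package's own choice and configurable.  All co-optimal placements are
  reported; the junction caller uses only reads with a unique best
  placement, which prevents false junctions from repeats without any
  tie-breaking inside the aligner.  Against full Smith-Waterman
  (`Biostrings::pairwiseAlignment`) the seed-and-extend score is exact
  whenever the optimal alignment contains an exact 12-mer; the test and
  acceptance fixtures therefore use reads of 51-60 nt with at most 3
  substitutions, where a 12-mer survivor is guaranteed by pigeonhole.

## Structure machinery

Folding potential is **maximum base pairing** (Nussinov DP, compiled), not
thermodynamics: it is dependency-free and exhaustively checkable by
enumeration of all non-crossing pair sets at small n.  An energy-model
backend could be substituted behind the same contract.  The pairing rule is
Watson-Crick plus G:U wobble by default (orthologous permuted SRP RNAs show
structure-preserving G-C to G-U exchanges); hairpin loops need at least 3
unpaired bases, which makes the GNAR tetraloop representable.  One caveat
discovered while testing: the pleasing symmetry "a sequence and its reverse
complement have the same maximum pairing" holds only for pure Watson-Crick
pairing — a G:U pair maps to A:C under reverse complement — so that
invariant is stated and tested with `allowGu = FALSE`.

## Candidate scanning

`scanCandidateLoci` slides 400-nt windows (step 50; sized to a ~300-nt
gene) and requires a same-strand co-occurrence of a GNAR hit and a
helix-8b hit plus a pairing fraction of at least 0.5.  GNAR alone is a weak
anchor (a random 400-mer contains a dozen matches); specificity comes from
the rarer helix-8b pattern and the fold score.  Overlapping qualifying
windows merge into one candidate; the combined score is the fold score
plus 0.5 per required motif.

## Junction, TSS and BHB calling

`detectCircularJunctions` re-places every soft clip of at least 8 nt
(expected random placements in a 1-kb radius at 8 nt: well below one at
zero mismatches) allowing at most 1 mismatch, using the fewest-mismatch
level and discarding placements that are ambiguous within it.  Each read
votes for an `(acceptor, donor)` pair; votes for non-identical pairs are
never merged — identical ligation points are the biological signature of
defined termini, so discordance is reported, not averaged away.

`findBhb` extracts `2 * flank` nt of transcript around each terminus
(default flank 18) and exhaustively enumerates outer-helix / 3-nt bulge /
4-bp central helix / 3-nt bulge / outer-helix configurations between the
two strands, in both bulge arrangements (which makes the enumeration
symmetric under swapping the strands).  Outer helices are maximal runs of
at least 2 bp.  Ranking is by total paired bases, ties by proximity of the
predicted cleavage to the observed termini.  On random strands bare
geometric configurations are common (~40% of shuffled flank pairs admit
one); the pipeline's detection event is therefore the **validated** motif —
`predictCleavage(bhb) == (acceptor, donor + 1)` — which occurs on none of
100 dinucleotide-shuffled flank pairs in the null test.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk run: recovery
sweeps use 20 random loci with circle lengths 80-400 nt and leaders
5-40 nt at 30x depth and 75-nt reads (about half a minute), oracle
equivalence uses 200 alignment pairs, 1000 trimming reads, 200 folds at
n <= 14 and 1000 scans, and the null test 100 shuffles.  Determinism is
end-to-end: every stochastic step derives from the configured seed through
an RNG-state-preserving wrapper, and rerunning `runPipeline` with the same
config yields a byte-identical `report.json`.  Floating-point ties in the
Mott trimmer are resolved with an epsilon of 1e-12; the Nussinov traceback
deterministically prefers pairing the interval ends over bifurcation.

## Known limitations

* The aligner is not a production short-read mapper: no spliced alignment,
  no quality recalibration, exact seeds only (a read whose every 12-mer is
  mutated will not seed).
* Maximum base pairing overestimates the pairedness of random sequence, so
  the fold score separates candidates weakly on its own; it is the motif
  co-occurrence that carries specificity.
* The C/D box sRNA neighbour is planted and counted but its boxes are not
  annotated; quantifying circular versus linear abundance is out of scope.
* Real-data accession-scale validation (the original GEO dataset against
  the *T. tenax* genome) requires downloads and is not part of the test
  suite; the synthetic defaults encode the same locus geometry instead.
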