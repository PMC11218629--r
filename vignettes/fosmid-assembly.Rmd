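---
title: "Assembling fosmid inserts from rolling-circle-amplified long reads"
author: "RCAssembly"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Assembling fosmid inserts from rolling-circle-amplified long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RCAssembly)
library(Biostrings)
```

# The problem

Functional metagenomic screens work with libraries of fosmid (or cosmid)
clones: circular molecules consisting of a vector backbone of roughly 8 kb
and a cloned environmental or genomic insert of roughly 30--40 kb ligated
into the vector's multiple-cloning site (MCS). Sequencing a clone of
interest means recovering the insert sequence de novo, because metagenomic
inserts usually have no usable reference.

A convenient way to get sequencing template directly from a colony is
rolling-circle amplification (RCA) with a phi29-family polymerase primed on
the backbone. RCA of a circle, however, produces long linear concatemers --
molecules that run around the circle several times -- and the polymerase's
strand-displacement activity additionally creates hyper-branched and
chimeric products. Long nanopore-style reads of this material therefore
contain (a) multiple tandem copies of the clone circle, (b) artifactual
junctions joining non-contiguous, sometimes inverted, template segments,
and (c) ordinary sequencing errors. A generic long-read assembler fed such
reads tends to produce multi-copy, vector-contaminated, or circularly
permuted contigs.

RCAssembly implements the pipeline that resolves this, plus the read
simulator needed to test it end to end without sequencing data.

# The pipeline

For each clone (reads are demultiplexed upstream):

1. **Vector model.** The vector backbone is rotated so the MCS occupies its
   final bases (`rotateVector()`). With the MCS at the 3' end, the insert
   begins immediately after the stored vector sequence in circular order;
   every later orientation decision is anchored on this convention.
2. **De-concatenation** (`processReadSet()`). Every read is aligned to the
   rotated vector with the package's native local aligner. Matching
   regions are trimmed out; the non-matching flanks are retained as
   independent fragments. Because one pass of the vector separates two
   consecutive insert copies in a concatemer, removing every vector match
   cuts a concatemeric read into single-copy insert fragments. Reads
   without any vector match are kept whole. Reads or fragments shorter
   than 150 nt are discarded.
3. **Assembly** (`assembleFragments()`). The fragments are assembled with
   a greedy overlap--layout--consensus assembler, gated on estimated input
   coverage (total fragment bases / expected molecule size): below 7x no
   assembly is attempted, and contigs whose mean layout depth is below the
   same value are dropped afterwards.
4. **Primary contig selection** (`selectPrimaryContig()`): the contig
   maximising length x mean depth.
5. **Finishing** (`trimContigVector()`). Residual vector in the selected
   contig is trimmed, and the flanks are re-joined so the insert reads 5'
   to 3' from the MCS junction: the flank downstream of the vector comes
   first. If the contig walked more than one full circle the two flanks
   overlap; the overlap is detected by alignment and merged. The result is
   a linear, vector-free insert that starts at the MCS.
6. **QC** (`qcReport()`): mean depth of coverage and the percentage of
   reads contributing at least one mapped fragment, from mapping the
   fragments back onto the finished insert. Optionally, inserts with more
   than 95% identity to a supplied host genome over more than 90% of their
   length are flagged as likely host contamination (both bounds strict).

# The native aligner

All alignment (vector detection, overlap detection, QC mapping,
truth evaluation) uses one native local aligner: exact k-mer anchors
(k = 15), windowed collinear chaining with a maximum anchor gap of 500 bp,
full dynamic programming across the short inter-anchor gaps, and gapped
free-end extension of the chain ends (windowed DP that stops at the
best-scoring cell). Identity is defined once and used everywhere: matching
columns / all alignment columns (gaps included) x 100.

Two properties of this design matter downstream. First, boundaries are
exact on error-free sequence and typically within a few bases under ~1%
error, so vector trimming leaves at most a few tens of residual vector
bases per junction at nanopore error rates. Second, the aligner is fully
deterministic. The test suite checks the aligner against
`Biostrings::pairwiseAlignment()` (a full dynamic-programming
implementation) on instances up to 2 kb, requiring interval agreement
within +-5 bp and identity within +-0.5 percentage points.

An adapter for an external mapper exists at the interface level: matches
can be imported and exported as PAF lines (`pafToMatches()` /
`matchesToPaf()`), so a production deployment can substitute a dedicated
aligner without touching the pipeline contracts.

# The assembler

The assembler is intentionally minimal -- a single-template, single-clone
greedy OLC, not a general-purpose assembler:

* The longest unused fragment seeds a draft. A seeded shuffle breaks ties
  between equal-length candidates, which is the only thing the assembler
  seed influences; given `(fragments, seed)` the output is byte-identical
  across runs.
* Each round, all unused fragments are aligned to the draft (both
  strands); an overlap qualifies at >= 500 bp and >= 80% identity.
  Fragments contained in the draft are laid onto it; the single best
  draft-extending overhang is applied per round.
* The consensus is a per-column majority vote over the layout, with
  deletions called only on strict majority, insertions on majority support
  at a junction, and base ties resolved alphabetically. Majority indel
  voting removes the draft backbone's private indels, so the consensus
  length is essentially independent of which fragment seeded the draft.
* Fragments whose parent read contained vector are carried in template
  orientation (their flanking vector match fixes the strand); after
  consensus, the contig is reverse-complemented if the majority of these
  orientation-known fragments aligned to it on the minus strand. This is
  what makes the finished insert equal to the template rather than its
  reverse complement even when no vector survives into the contig.

Because fragments are bounded by vector cuts, no fragment spans the
insert-end-to-insert-start junction, the layout over the insert is linear,
and the contig naturally terminates at the MCS junctions -- assembly of
de-concatenated fragments cannot re-create the concatemer.

The coverage gate is applied to *estimated input coverage* = total
fragment bases / `expectedMoleculeSize`. The default expected size is
40,000 bp, the scale of a typical fosmid; for substantially smaller
constructs the value should be set to the expected insert scale (it is a
config key), otherwise the gate under-estimates coverage because vector
bases have already been removed from the fragments.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `minMatchLen` | 100 | bp | minimum query span of a vector match |
| `minMatchIdentity` | 80 | % | minimum identity of a vector match |
| `mergeMaxGap` | 50 | bp | vector matches closer than this merge into one block |
| `minFragmentLen` | 150 | nt | fragments (and whole reads) below this are discarded |
| `minInputCoverage` | 7 | x | assembly gate, and post-assembly contig depth filter |
| `expectedMoleculeSize` | 40,000 | bp | denominator of the coverage estimate |
| `minOverlap` / `minOverlapIdentity` | 500 / 80 | bp / % | overlap acceptance in the assembler |
| `anchorK` | 15 | bp | aligner anchor size |
| `maxChainGap` | 500 | bp | maximum anchor chaining gap |

The 150 nt fragment filter, the coverage gate of 7, and the strict 95%/90%
host-contamination bounds are the pipeline's published operating points.
The remaining defaults are this package's choices: 100 bp/80% tolerates
nanopore-level error while never firing on random sequence; the 50 bp
merge gap absorbs the way indel noise splits one vector pass into several
local matches; 500 bp/80% overlaps are conservative for 3--30 kb
fragments at ~20x coverage; k = 15 with a 500 bp chain gap keeps anchor
seeding specific on 8--60 kb sequences. All are exposed in
`pipelineConfig()` and the flat key-value config file.

# The read simulator

`simulateRcaReads()` emulates what matters about phi29 RCA long reads:

* **Template structure.** A simulated clone (`makeFosmid()`) is the
  rotated vector followed by an i.i.d.-uniform random insert; reads start
  at a uniform position and strand on the circle and walk it circularly,
  so concatemers arise exactly when the drawn length exceeds the
  circumference.
* **Lengths.** Log-normal with median 11,500 bp (the read-length scale of
  the nanopore runs this pipeline targets) and sdlog 0.35, chosen so the
  upper tail (N50-type statistic) sits roughly a third above the median,
  as typical for size-selected long-read libraries.
* **Errors.** Independent per-base substitutions (0.5%), insertions
  (0.25%) and deletions (0.25%) -- about 1% total, the
  super-accuracy-basecalling regime of current nanopore chemistry.
* **Chimeras.** With probability 0.02 per read, one template switch at a
  uniform point, restarting at a new uniform position; half of the
  switches invert the strand. Inverted junctions are the read-level
  signature of hyper-branched RCA products; no branching graph is
  modelled. The rates are plausible placeholders for property testing,
  not calibrated estimates.
* **Truth.** Every read carries its error-free template walk (segment
  intervals on the circle, strands, junction flags, complete vector
  copies spanned), so tests can assert trimming and assembly against
  exact expectations.

What the simulator does **not** model: amplification bias and chimera
clustering near initiation sites, context-dependent (homopolymer) error,
quality-score variation, cross-clone chimeras (the unit of work is one
demultiplexed clone), and real vector sequence -- the bundled backbone is
a synthetic stand-in (`standInVector()`) with the pCC1 primer sites, one
SacI site and one XhoI site embedded. Passing tests therefore demonstrate
the pipeline's logic under a faithful structural model of RCA reads, not
performance on any particular real flow cell.

# Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open everywhere, including PAF output.
* Consensus ties go to the alphabetically first base; a deletion needs a
  strict majority; an insertion needs support from more than half of the
  fragments covering its junction. With two sequences these rules keep the
  first sequence's bases, which is also how the two finishing flanks are
  merged across their overlap.
* "Highest length and coverage" is operationalised as the maximum of
  length x mean depth, with ties broken by length and then contig id; the
  product prefers a long, well-supported insert contig over a short, very
  deep contamination contig.
* An empty fragment set estimates 0x coverage and returns the low-coverage
  status rather than an error; a pure-vector read set does the same.
  A contig that is pure vector finishes to an empty insert with a failure
  status. More than two separated vector blocks in a contig (a possible
  double-backbone clone) triggers a warning; all blocks are trimmed and
  the flanks are concatenated in MCS-consistent order.
* Degenerate bases other than N are rejected at vector load; N never
  matches an anchor.

# Known limitations

* The greedy assembler extends on single-fragment evidence, so a long
  chimeric fragment can carry a few spurious bases onto a contig end at
  low coverage; the paper-scale behaviour (contig length variation across
  repeated runs, a tail of over-long contigs) is reproduced but not
  eliminated. No repeat resolution, no polishing stage, no quality-aware
  consensus.
* Host-contamination flagging needs a user-supplied host genome and uses
  the native aligner; it is a desk-scale stand-in for a dedicated
  homology search.
* Dual-fosmid clones are flagged (warning) but not split into two inserts.

# Problem sizes used in the checks

The acceptance script and test suite run entirely on simulated data at
sizes chosen to exercise every code path at interactive speed: the
fragment-filter sweep uses 119 flank+vector+pad reads; the
reproducibility check assembles one ~35 kb clone (~58 reads, ~20x, 1%
error) five times; exact-reconstruction uses an error-free 30 kb insert
at ~10x; the de-concatenation property forces twelve reads each longer
than 1.5 circumferences of a 20 kb clone; and the coverage-gate sweep
tiles a 40 kb template at 1--12x. A batch of such clones corresponds to
the per-barcode unit of a real sequencing run.

# A worked example

```{r example, eval = FALSE}
library(RCAssembly)

vec <- standInVector()                       # or readVectorFasta(path, mcs)
fos <- makeFosmid(vec, insertLength = 30000, seed = 11, cloneId = "demo")
sim <- simulateRcaReads(fos, simulationConfig(
  seed = 5, nReads = 35, substitutionRate = 0, insertionRate = 0,
  deletionRate = 0, chimeraRate = 0))

ia <- runClone(sim$reads, vec, pipelineConfig(), cloneId = "demo")
ia
evaluateAgainstTruth(ia, fos)

identical(as.character(insertSequence(ia)),
          as.character(fosmidInsert(fos)))   # TRUE: exact, MCS-anchored
```
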