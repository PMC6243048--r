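---
title: "Seed-guided isoform assembly: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-guided isoform assembly: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isograph)
```

# The assembly model

`isograph` reconstructs transcript isoforms of a targeted locus from short
paired-end RNA-seq reads, anchored at a conserved *core region* whose
sequence is known (for a plant MIKC MADS-box gene, the stretch from the
first conserved intron/exon border after the DNA-binding domain to the last
border of the K-domain). The method makes three structural assumptions:

1. **The locus is expressed enough** that its k-mers and their adjacencies
   are sampled by reads: every true splice junction must be covered by at
   least one read spanning k + 1 bases across it.
2. **Isoforms differ by exon choice, not by cycles.** Candidate transcripts
   are simple paths, so tandem repeats traversed more than once and other
   cyclic structures cannot be represented (see *Limitations*).
3. **Isoforms run tip-to-tip.** Every isoform starts at a unitig with no
   predecessor and ends at one with no successor. Truncated transcripts
   nested inside longer ones are invisible to this construction; detecting
   them would require starting paths at coverage change-points, which this
   package deliberately does not do.

## Graph construction

Reads are decomposed into k-mers; each k-mer and its reverse complement are
one node, represented by the lexicographically smaller of the two strings.
k is restricted to odd values so no k-mer is its own reverse complement and
the canonical choice is always strict. Edges are stored as canonical
(k+1)-mers, which makes the graph strand-symmetric by construction:
assembling a library and its reverse complement yields identical graphs (a
property the test suite asserts).

Each data source is a *color*: colors share the node set but carry their own
coverage counts and edge sets. Merging graphs is a union over nodes that
leaves every color untouched; flattening colors sums coverages and unions
edges. Any window containing a non-ACGT symbol contributes neither node nor
edge, and reads shorter than k are skipped with a logged count.

## Cleaning

Maximal non-branching runs collapse into unitigs. Adjacency for collapsing
is taken over a *designated* subset of colors — in the pipeline, the
short-read sample color alone — so that seed sequences or long-read colors
can never fabricate junctions in the assembly graph. Two cleaning passes
follow:

* **Coverage filter.** A unitig is removed iff its mean k-mer coverage in
  the sample color is strictly below `min_unitig_mean_coverage`. Removal
  can merge formerly branching runs, so the graph is re-collapsed
  afterwards (configurable; re-collapsing is the default because it
  restores the unitig invariants the later stages rely on).
* **Tip pruning.** Within a seed subgraph, tips (unitigs with a free end)
  shorter than `tip_min_kmers` k-mers are removed. A removal can expose a
  new short tip, so pruning iterates to a fixpoint by default, with a
  configurable iteration cap; unitigs containing seed k-mers are exempt, so
  the region of interest can never prune itself away.

## Enumeration and aggregation

Seed subgraphs are connected components under *undirected* reachability,
because a transcript extends its core both 5′ and 3′. Candidates are all
simple tip-to-tip paths (depth-first traversal over oriented unitigs, with
a visited set at the unitig level). Since a traversal and its
reverse-complement traversal describe the same molecule, duplicate
orientations are merged; a candidate containing a seed sequence is reported
in the seed's orientation, all others on the lexicographically smaller
strand. The path count grows exponentially with the number of branchings,
so enumeration aborts with an error — never a silent truncation — beyond
`max_paths` (default 10,000) candidates.

Across samples, two candidates are duplicates when equal or
reverse-complementary; the retained representative is the lexicographically
smaller strand, with per-sample provenance kept as metadata.

## Support filtering

A read pair's equivalence class is the intersection, over all valid k-mers
of both mates (strand-agnostic), of the candidate sets containing each
k-mer; k-mers indexed by no candidate are skipped rather than forcing the
class empty. Abundances θ maximise the class multinomial likelihood
$\prod_c \left(\sum_{t \in c} \theta_t/\tilde\ell_t\right)^{y_c}$ by EM:
the E-step allocates each class count to members proportional to
$\theta_t/\tilde\ell_t$, the M-step renormalises. Estimated *counts* (not
TPM) are the allocated read counts, which sum to the pseudoaligned total in
every run — an invariant asserted throughout the tests.

The retention rule bootstraps the class counts (`n_bootstrap` multinomial
resamples of the class table — equivalent in distribution to resampling
reads, and orders of magnitude faster), reruns the EM on each replicate,
and keeps a candidate iff its estimated count reaches `min_count` (≥ 1) in
at least `min_support_samples` (≥ 95) replicates. Both thresholds are
inclusive; only the bootstrap rule gates retention, with the point estimate
reported alongside for transparency.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k` | 47 | bases | k-mer size; odd, large enough to be locus-specific in a conifer-sized transcriptome yet short enough for 125-base reads to contribute ~79 k-mers each |
| `min_unitig_mean_coverage` | 4 | mean k-mer count | removes sequencing-noise unitigs; strict (< 4 removed, 4.0 kept) |
| `tip_min_kmers` | 47 | k-mers | tips shorter than one full k-mer length of distinct sequence are error artifacts; strict (46 removed, 47 kept) |
| `n_bootstrap` / `min_support_samples` / `min_count` | 100 / 95 / 1 | replicates / replicates / reads | the retention rule: ≥ 1 estimated count in ≥ 95 of 100 replicates |
| `ccs_prune_coverage` | 2 | mean summed coverage | after joining long-read colors, prune unitigs below 2 in the joined (summed over colors) view |
| `em_tolerance` / `em_max_iter` | 1e-8 / 1000 | relative change / iterations | EM stop criterion (see below) |
| `fragment_mean` | 200 | bases | effective length $\tilde\ell = \max(1, \ell - 200 + 1)$; a plain-length mode is available |
| `max_paths` | 10,000 | paths | hard enumeration cap per subgraph |

# Numerical choices

* **EM initialisation and convergence.** θ starts uniform. Convergence is
  the maximum relative change of θ between iterations falling below
  `em_tolerance`, computed only over components above 1e-10: components
  decaying geometrically to zero never satisfy a pure relative criterion
  even though they no longer influence the allocation. Non-convergence at
  the iteration cap returns the current estimate with a warning.
* **Ties and determinism.** Unitig sequences are reported on the
  lexicographically smaller strand; candidate output is sorted by sequence
  then path; DFS successors are visited in sorted order; the bootstrap is
  seeded from `rng_seed` (the pipeline derives per-sample seeds from its
  global seed), and RNG state is restored after every seeded call. Two runs
  with the same configuration produce byte-identical primary outputs.
* **Degenerate inputs.** An all-too-short read set yields an empty graph
  plus a warning; an isolated k-mer is a one-k-mer unitig; a seed with no
  k-mer in the graph yields no subgraph (logged); an empty equivalence
  class table gives zero estimates and zero support; tip pruning that would
  empty a subgraph is an error naming the seed (unreachable in practice
  because seed unitigs are exempt).
* **Similarity direction.** The similarity of an assembled transcript to a
  reference is *match length divided by reference length* — matched bases
  are the summed M/`=` CIGAR operations minus substitution mismatches, so
  clips and indels contribute nothing, and NM-derived substitution counts
  subtract indel widths first (NM counts them, the match-length statistic
  must not). Values are rounded to two decimals at presentation only.
  Alignment-based evaluation tries both strands of each assembled
  transcript, since assemblies are strandless.
* **Long-read alignment roles.** The internal local aligner labels, per
  read, the alignment with the most matched bases `primary`; other
  surviving alignments covering a mostly disjoint read stretch (< 50%
  overlap with the primary span) are `supplementary` — the split-alignment
  situation when consecutive exon regions each align — and the rest
  `secondary`. Region grouping counts primary and supplementary alignments;
  unique-locus counting uses every surviving alignment. A text-SAM reader
  ingests external alignments (CIGAR and NM only) for users with their own
  mapper.

# The synthetic data generator

`make_mutually_exclusive_gene()` emulates the diamond topology of a locus
with mutually exclusive first and last exons: alternate 5′ exons (defaults:
two of 200 bases), a shared core (500 bases), alternate 3′ exons (250 and
300 bases). Exons are uniform random ACGT, rejected until (a) no two exons
share a 47-mer in either orientation and (b) no two alternate 5′ exons end
in, and no two alternate 3′ exons start with, the same base — a shared
terminal base would make junction k-mers coincide and blur the branch
point. Splicing concatenates one (or no) 5′ exon, the core, and one 3′
exon.

`simulate_read_pairs()` models the library at the molecule level: it draws
full-length transcript copies in proportion to abundance, fragments each
copy sequentially into pieces of roughly `fragment_mean = 300` (SD 25)
bases — the first piece length uniform, so cut phases are stationary along
the molecule — and sequences both ends (2 × 125 bases) of every piece at
least one read long. Fragmentation pieces are bounded by the molecule ends,
so transcript ends are covered like interior bases; this is what lets an
error-free 20× library reconstruct full-length isoforms, and it is how real
shotgun libraries behave. Pieces lost to size selection put the realised
depth slightly under the nominal target (about 7% in the default
configuration; the tests require agreement within 15%). Substitution errors
are i.i.d. per base. `simulate_ccs_reads()` emits full-length copies with
optional indel errors and an optional 5′ truncation emulating long-read
library 5′ loss.

**What the generator does not model:** GC and positional coverage bias,
quality-correlated errors, intron retention or alternative donor/acceptor
sites, chimeric fragments, and expression noise beyond multinomial
sampling. Passing tests on this generator therefore demonstrate the
correctness of the graph algebra, enumeration, and filtering logic under
the stated topology — not robustness to every artifact of real libraries.

# Known limitations

* **Cycles.** Simple paths cannot traverse a repeat twice; loci with
  internal repeats longer than k − 1 will collapse them.
* **Exponential candidate growth.** Heavily polymorphic or deeply
  alternatively spliced loci can exceed any practical path cap; the cap is
  a loud failure by design.
* **Truncated transcripts.** Isoforms properly contained in longer ones
  (e.g. short variants lacking the first exon) are not enumerated, because
  their 5′ end is not an incoming tip of the graph.
* **Identifiability.** When the shared core is longer than the fragment
  length, no read pair links a 5′ exon choice to a 3′ exon choice, and the
  class likelihood is flat along the "chimera ridge": the filter then
  cannot reject an unexpressed exon combination whose parts are each
  expressed. With fragments spanning the core the classes separate and the
  bootstrap filter rejects the chimeric paths — the test suite demonstrates
  both regimes. This is a property of the data, not of the estimator.

# Scale of the validation suite

The test and acceptance runs use deliberately desk-sized instances chosen
to exercise every code path while keeping the full suite in the minutes
range: diamond loci of ~1.4 kb total exon sequence at 20–30× simulated
coverage (roughly 330 read pairs per sample, ~1,400 graph nodes), chain
models of up to seven exon groups (≤ 12 unitigs, ≤ 27 paths) for the
enumeration oracle, equivalence-class systems of 2–5 transcripts for the
EM grid-search and Monte-Carlo bootstrap oracles (10⁴ replicates), and a
three-sample pipeline for end-to-end recovery and byte-identical
reproducibility checks.
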