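---
title: "Discovering divergent MHC class I alleles from RNA-Seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering divergent MHC class I alleles from RNA-Seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MHC class I genes are among the most polymorphic loci known: several genes
are co-expressed per haplotype, allele pairs can differ at 15% or more of
their nucleotides, and for many species (sheep among them) only a handful of
alleles have ever been curated. Standard RNA-Seq workflows fail on such loci
twice over. Alignment against a reference collapses reads from an unknown
allele onto whichever known allele is least dissimilar, producing mosaics
of mismatches and heterogeneous columns; pure de novo assembly, conversely,
happily merges reads across near-identical paralogues into chimeras.

`dinomfrs` implements a discovery loop that plays the two approaches against
each other. Reads are aligned permissively against a curated database of
exon2--exon3 allele sequences (the ~549 bp region encoding the
peptide-binding α1/α2 domains, where essentially all functional
polymorphism sits). Alleles whose alignment is complete and mismatch-free
are called directly. Alignments that are deep and long but mismatched or
heterogeneous are treated as shadows of alleles missing from the database:
their paired reads are extracted and reassembled de novo under stringent
overlap criteria, full-length contigs join the database as provisional
novel alleles, and the loop repeats until nothing new appears. A final
high-stringency mapping verifies every reported allele.

## The pipeline, stage by stage

### Reference database (`build_reference`, `augment`)

The database holds trimmed exon2--exon3 nucleotide sequences with unique
ids. Construction scans candidates in input order and drops any sequence
closer than `min_diff = 5` edit operations to an earlier entry, so curated
entries win ties against later additions. Full edit distance (not
substitution-only Hamming distance) is used so that length-variant
near-duplicates are also caught. Augmentation with novel contigs is
deliberately *not* redundancy-filtered — genuinely novel alleles may differ
from known ones by fewer than 5 bp — but exact duplicates are absorbed and
reported under the existing id. Each augmentation increments a version
counter. Where inputs are untrimmed, `trim_to_anchor()` cuts each sequence
to the span matching a designated anchor allele by local alignment,
replacing multiple-alignment-based trimming with an anchored-coordinate
rule.

### Read mapping (`map_reads`)

The mapper is a seed-and-extend banded local aligner: exact 19-mers anchor
diagonal windows (±`band`), which are scored by affine-gap dynamic
programming with a flat per-end soft-clip charge. Two presets mirror the
two scoring regimes of the discovery protocol:

| preset      | match | mismatch | band | clip | min score |
|-------------|-------|----------|------|------|-----------|
| `discovery` | 1     | 4        | 100  | 5    | 30        |
| `verify`    | 2     | 5        | 30   | 2    | 40        |

Gap penalties (open 6, extend 1), the unpaired-pair penalty (17) and the
seed length (19) are the conventional defaults of the short-read mapper
family this component emulates; the minimum reportable scores are set so
that random 100-mers essentially never produce a hit (they practically
never share an exact 19-mer with an unrelated reference, and their best
local alignments score far below the floor).

Pairing follows the protocol's use of an unpaired-read penalty: on each
allele where both mates align on opposite strands with an implied fragment
length between the read length and 1000 bp, the pair is proper and scores
the sum of its mates; otherwise the sum is docked by 17. Records are
emitted for **every allele tying the maximal pair score**. This multi-allele
co-mapping is intentional: reads from segments conserved between alleles
must count toward the per-position coverage of each tied allele, because
the downstream calls are per-allele pileup properties.

The seed-and-extend path is checked against an independent, unbanded
full-matrix dynamic program with identical scoring (`align_oracle_score`);
the test suite asserts score equality on over a thousand randomized cases
per preset.

### Allele calling (`compute_pileup`, `call_known`, `find_candidates`)

Pileups tally bases along cigar walks (soft-clipped bases excluded,
deletions tallied separately). A position counts as covered at depth
`min_depth = 5` — the protocol never quantifies "complete coverage", and 5
separates real coverage from stray noise at the depths involved. A position
is *heterogeneous* when its second-most-common base reaches count 10 and
frequency 0.05. These thresholds replace the visual alignment inspection
of the original workflow and are the pipeline's main calibration surface.
The frequency floor must sit *below* the smallest minority fraction a
co-mapped low-expression allele can present — with expression tiers
spanning <1000 to >5000 marker reads, a low-tier allele hiding under a
high-tier one contributes ≈ 500/6600 ≈ 0.08 of the bases at its
discriminating columns, which a 0.2 floor would silently absorb — and
*above* the frequency of error alternatives, which at 0.1--1% per-base
error is ≈ 0.001 per specific wrong base (the count floor of 10
additionally protects thin columns). An allele is **present** exactly when
its pileup is complete with no mismatched and no heterogeneous positions.

A pileup that is *not* a present call becomes a **candidate** for
reassembly when it has more than 500 aligned reads over a covered span
longer than 400 bp and shows at least one mismatched or heterogeneous
position. Both thresholds are strict inequalities, and the test suite
pins the boundary behaviour at (500, 450), (501, 401) and (2000, 380).

Expression is binned from the number of reads whose alignment covers one
allele-discriminating marker column (full-CDS position 260, i.e. trimmed
coordinate 187 under the 73 bp exon 1 offset): below 1000 reads is `low`,
1000--5000 inclusive `middle`, above 5000 `high`. The bin boundaries are
inclusive for the middle bin, matching the printed ranges literally.

### Micro-assembly (`assemble`)

Candidate read pairs are pooled into a single greedy
overlap-layout-consensus assembly. Admissible read-read overlaps need
length ≥ 40 bp, identity ≥ 0.99 and overlap score ≥ 120 (score =
matches·3 − mismatches·5); overlaps are located via a shared k-mer index
and evaluated ungapped at the k-mer-implied diagonal. Merging is
best-score-first with deterministic ties (longer overlap, then
lexicographic read id). The score gate's default deserves a note: a clean
overlap of the minimum length scores exactly 120, and the maximum possible
overlap score between 2×100 bp reads is 300, so a substantially higher
gate would forbid assembly of short-read data altogether; the identity and
length gates carry the stringency.

Two safeguards keep co-extracted alleles apart. First, a merge joining two
multi-read layouts must also agree at the identity gate over the full
implied consensus overlap, compared only at columns with depth ≥ 3 in both
layouts — deep columns give an error-robust majority, while thin staircase
tails (depth 1--2, occasionally shifted by a rare error indel) would
otherwise deadlock legitimate merges. Second, a final polish removes reads
below the identity gate against their own consensus and recomputes it.
Contigs need 20 supporting reads to be reported (candidates carry > 500
reads by construction, so this only suppresses spurious micro-contigs).

A contig is **full length** when its best local alignment to a database
allele covers ≥ 95% of that allele. Because candidate reads come from
whole transcripts, near-full-length contigs are first end-repaired by
clipped-read voting (`extend_contig_ends`: soft-clipped overhangs of
re-aligned reads vote per column while depth stays ≥ 5) and then cut back
to the allele frame of their closest database match
(`trim_contig_to_frame`), the package's analogue of exon2--exon3 trimming.
End repair is deliberately restricted to contigs already ≥ 90% of the
allele length: extending a short core from a pooled read set could walk
along a co-extracted allele's conserved sequence and fabricate a
recombinant.

### The per-individual loop (`run_individual`)

Each round maps all pairs under `discovery`, calls known alleles, finds
candidates, pools and caps their read pairs (1200 pairs per candidate,
taken evenly over the id-sorted reads — a deterministic subsample that
keeps minority alleles co-mapped onto a deep candidate at full depth while
bounding the quadratic overlap stage), assembles, and augments the
database with full-length contigs named `LfL` + counter. Non-full-length
contigs of at least 150 bp enter the working database as *provisional*
entries: the next round's mapping concentrates their reads in one place,
every pair with a mate aligned to a provisional entry is re-extracted, and
assembly extends it — the operational content of the iterative
align → extract → reassemble loop, whose hardest cases need two or three
rounds. Provisional entries are internal only: they are dropped before
verification and never reported. The loop stops when a round adds no novel
allele and no provisional contig grows, or after `max_rounds = 5`.

Finally all pairs are remapped under `verify` against the
individual-complete database. An allele enters the genotype only if its
pileup is a present call *and* each 30 bp terminal window is covered by at
least one mate of a proper pair, so both sequence ends are supported by
intact fragments rather than orphan mates — the guard against artificial
recombinants. Novel alleles failing verification are removed from the
returned database. Known alleles with reads but failing verification are
logged as insufficient evidence and excluded from the genotype.
Per-allele alignment results are cached across rounds (they do not depend
on the rest of the database), so later rounds only align against newly
added entries; the tie sets are recomputed from the cache.

### Annotation and genomic matching

`annotate_alleles` reports the closest database allele with percent
identity (equal-length pairs are compared position by position — the
direct-count convention of allele identity tables; length-variant pairs
are aligned end to end), the translated protein, and a
classical / putative non-classical call. Classification compares alleles
only at 31 antigen-contact positions (shipped in
`inst/extdata/contact_positions.tsv`, curated once from the class I
peptide-binding-groove literature; full-CDS residue numbering):
single-linkage clusters at Hamming distance ≤ 3 with at least 3 members
and within-cluster contact diversity ≤ 3 are labeled putative
non-classical. This converts a descriptive grouping — alleles
nearly invariant at the groove — into a reproducible rule. Group-specific
marker residues (p.D62H, p.M65L, p.A69T, p.T91I, p.Y122G, p.Q161R,
p.E170L, p.L180F, p.E186N; p.K88N, p.E181V) are reported as supporting
evidence when present.

`detect_gene_conversion` screens equal-length allele pairs for the
signature of gene conversion — identical flanks of ≥ 200 bp around a
divergent core (≥ 50 bp, ≥ 10% divergence). `diversity_stats` computes
all-pairs substitution counts over a CDS window (the classic contrast
window is 474--593, 120 bp). `match_to_genome` locates an RNA-derived
allele in genomic contigs as two separately aligned exon hits (both
strands) that are colinear in transcript order with an inter-exon gap of
50--5000 bp; reverse-orientation hits are printed transcript-wise with
start > end. `intron_len` is the number of contig bases strictly between
the exon hits (published tables sometimes print the coordinate difference,
which is one larger).

## The synthetic-data generator

`simulate_allele_set` derives known and novel alleles from one random
549 bp ancestor. `divergence_range` (default 0.05--0.15) is the target
*pairwise* divergence: each allele receives substitutions at half a rate
drawn from the range, concentrated threefold inside two hypervariable
windows, so two alleles differ at approximately a rate inside the range —
matching both the 5--20% pairwise divergence of real allele panels and
what a permissive mapping regime can still align (at 4 penalty units per
mismatch, a 100 bp read stops mapping beyond ~14 differences). One novel
allele optionally carries a 9 bp divergent motif at full-CDS 256--264
(kept ancestral in all other alleles, so it differs there from every
neighbour), emulating the hardest published discovery case. All pairwise
distances are guaranteed ≥ 5.

`simulate_reads` embeds each allele in an allele-specific random
transcript flank (100 bp per side) and draws 300 ± 50 bp fragments from
the padded transcript until the number of mate alignments covering the
marker column reaches the allele's expression tier. This flank matters:
real RNA-Seq fragments extend beyond the exon2--exon3 region, so its
terminal positions are covered as deeply as its interior — without it, a
low-expression allele could never satisfy complete coverage at depth 5.
Errors are i.i.d. substitutions at 0.3% per base plus 1 bp indels at a
tenth of that rate (to exercise cigar handling); qualities are constant
Phred 35. Everything flows from one integer seed through R's RNG, so
equal seeds give byte-identical FASTQ output. The generator does **not**
model positional coverage bias, PCR duplicates, quality decay or
splice-junction reads; passing tests therefore demonstrate correctness of
the method's logic under idealised error, not robustness to every
real-library artefact.

`simulate_genomic_contig` builds genomic fixtures — flanks + exon 2 + a
GT...AG intron + exon 3 — with planted coordinates for the exon-matching
logic.

## Problem sizes used by the test suite

The end-to-end recovery check runs 20 seeded individuals with 4--6 alleles
each (1--3 novel, one carrying the planted motif), 2×100 bp reads at 0.3%
error and expression tiers 800 / 2000 / 6100 marker reads (one high-tier
allele per individual — the realistic pattern in published allele tables;
the low-bin exemplar sits at 800 because the candidate rule's
more-than-500-aligned-reads floor makes substantially shallower divergent
alleles undetectable by construction).
The mapper oracle covers 1100 random cases per preset; the assembler
oracle exhaustively enumerates merge orders on 4--6-read instances and
checks 20 two-allele mixtures at 30× for chimera-free separation. On one
CPU the complete suite runs in roughly ten minutes.

## Known limitations

* The aligner has no FM-index; it is built for kilobase-scale reference
  collections (hundreds of ~549 bp alleles), not genomes.
* Spliced alignment is out of scope; transcript reads overlapping the
  region boundaries are handled by soft-clipping.
* Candidate detection is calibrated for the coverage regime of the study
  design (hundreds to thousands of reads per allele); very shallow
  libraries will under-call novel alleles before they ever reach the
  candidate thresholds.
* Haplotype phasing across alleles and statistical genotype likelihoods
  are not attempted; the caller is deliberately rule-based so every call
  can be traced to coverage, mismatch and pairing facts.
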