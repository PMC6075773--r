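---
title: "Curating a plant alternative oxidase gene family with aoxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a plant alternative oxidase gene family with aoxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoxkit)
```

## The problem

Alternative oxidase (AOX) is a mitochondrial terminal oxidase that bypasses
the cytochrome pathway; in plants the Type 1 subfamily splits into the
AOX1a, AOX1c, AOX1e and AOX1d clades. Curating an AOX gene family from a
newly assembled genome is a sequence of small, well-defined desk analyses:
delineate each gene's exon/intron structure from its transcript, classify
every protein isoform from its signature motifs and diagnostic residues,
name isoforms with a systematic grammar, transfer residue numbering onto
the *Trypanosoma brucei* AOX (TbAOX) crystal-structure reference to profile
the diiron center, dimer interface and hydrophobic (quinol-binding) cavity,
scan 1500 bp promoters for degenerate regulator motifs such as the
mitochondrial dysfunction motif (MDM), detect CpG islands, and tabulate
protein properties and expression ratios. aoxkit packages each of these
steps as a tested, reusable function with explicit parameters, plus a
synthetic-data generator so that every step can be audited against known
ground truth.

## Gene structure: spliced exact matching

`delineate_structure()` places a transcript (or CDS) on its genomic
sequence as a chain of exact exon matches. Because transcript and gene come
from the same assembly, a full dynamic-programming spliced aligner is
unnecessary; the implementation anchors the next exon with an exact seed
(default `anchor = 12`) and extends maximally. When junction-adjacent bases
are identical on both sides, the boundary can slide without changing the
spliced product; the documented tie-break is **GT..AG introns first, then
the leftmost donor**, and any residual tie sets an `ambiguous` flag.
Introns must be at least `min_intron = 20` bp (the source analyses state no
minimum; 20 bp is below any credible plant intron, so it only guards
against degenerate placements). `max_mismatch` defaults to 0 — exons must
reconstruct the transcript exactly — and can be raised for material from a
different cultivar. A pruned exhaustive placement search over all exon
chains serves as the test oracle.

`classify_splice_events()` compares two structures on the same gene: each
maximal interval exonic in exactly one structure is emitted once, labeled
`intron_retention` when it lies inside the other structure's intron,
`alt_5utr`/`alt_3utr` when it lies outside the other's exon span, `other`
otherwise.

## Isoform classification and naming

Four signature motifs (LETVAA, ERMHLMT, LEEEA, RADEAHH) carry the
glutamate/histidine residues that coordinate the diiron center. A motif is
`present` on an exact hit and `variant` when the best window differs at a
single position **and** every catalytic-flagged position is preserved; this
tolerance is what lets a LEMVAA-type modification still count toward "all
motifs present", which the published family requires, and `strict = TRUE`
disables it. Knocking a motif out makes the isoform a "-like" protein;
losing all four marks a putative regulator ("reg").

Diagnostic typing aligns the query to a reference protein and reads the
residues at the scheme positions (five Type 1 vs Type 2 positions; six
subtype a-c/e vs d positions). A class is called only when its allowed set
contains every observed residue; conflicting positions give `mixed`, and
more than half the positions unaligned gives `unresolved`. Because the
published allowed sets are conveyed by table colours that do not survive
text extraction, the shipped sets are synthetic defaults (flagged
`synthetic_default` in the catalog) that are internally consistent with the
package's synthetic references; real analyses should supply their own
catalog.

Clade assignment substitutes nearest-reference percent identity for the
original maximum-likelihood/Bayesian phylogeny, which is out of scope: a
decisive subtype call first restricts the candidates (d vs a/c/e), then the
highest global-alignment identity picks the clade, with a 25% identity
floor below which the clade is `unknown`. Each call records which rule
fired. Mixed diagnostic calls defer to identity rather than failing.

The naming grammar concatenates, deterministically:
`[put.][reg|ne.]<species>AOX<clade|•>[-like][-<arm>][.<paralog>][.sv<n>]`,
where "put." marks low-confidence gene models, "ne." non-expressed ones,
"reg" motif-free putative regulators (never combined with a clade or
-like), and the bullet stands in for an unresolved clade of a non-expressed
model. `parse_name()` inverts `assign_name()` exactly; chromosome arms,
paralog and splice-variant indices come from input metadata and are never
inferred.

## Residue-number transfer and domain profiles

`global_align()` is Needleman–Wunsch under BLOSUM62 with affine gaps (open
10, extend 0.5 — the common default of web alignment tools; the original
analysis names the algorithm but not the matrix, so both are configurable).
Percent identity is **matches / alignment columns including gaps**,
reported to 0.1%; the denominator is stated explicitly because the source
does not define one. `map_to_reference()` converts the alignment into a
reference-position → query-position map (identity below a 20% floor emits
the map with a warning flag), `extract_domain_profile()` reads the residues
at the cataloged diiron / dimer-interface / cavity positions ("-" for
unaligned), and `conservation_summary()` partitions a domain's positions
into identical-to-reference, uniform substitutions and mixed — the
partition is exact by construction. `chemistry_ratios()` classifies
side chains as hydrophobic {A,V,L,I,M,C}, polar {S,T,N,Q,D,E,K,R}, cyclic
{F,W,Y,H,P} or glycine, the four-way scheme used by the published cavity
table; the assignment lives in the catalog so it can be re-binned.

The exact TbAOX sequence variant behind the published numbering is not
identifiable, so the package ships a **synthetic scaffold**
(`tbaox_reference()`): the residue letters at every cataloged position are
the transcribed table letters, everything between them is deterministic
filler. Profile extraction and conservation arithmetic on the cataloged
positions behave exactly as on the real protein; alignments *between*
cataloged positions are meaningless, which is why the published
conservation counts are reproduced from the transcribed table fixtures
(`load_domain_fixtures()`) rather than from scaffold alignments. Any
user-supplied replacement reference must pass
`check_reference_consistency()` (catalog letters at catalog positions).

## Promoter scanning and CpG islands

`scan_iupac()` matches a degenerate IUPAC pattern against every window: a
non-N pattern position is violated when its base set excludes the subject
base; subject ambiguity codes match by set intersection; N never counts as
a mismatch. Both strands are scanned by default (minus-strand hits are
reverse-complement pattern matches reported in plus coordinates) because
regulator binding sites are orientation-ambiguous and the original counts
do not state a convention; `strands` is a flag. All overlapping hits are
reported; hit counts are non-decreasing in `max_mismatch` and the scanner
is property-tested against a naive per-window oracle.
`classify_deviation()` annotates hits of the relaxed MDM pattern
(YTTGNNNNNVAMV) with their deviation count and site relative to the
stringent CTTGNNNNNCAMG, instead of guessing whether published counts
include the subset overlap.

`find_cpg_islands()` follows the windowed observed/expected semantics of
the classic EMBOSS tool: a 100 bp window steps by 1; per window,
GC% = 100·(C+G)/w and O/E = (#CG·w)/(#C·#G); each window's values are
attributed to its midpoint (start + ⌊w/2⌋); islands are maximal runs of
midpoints strictly exceeding both thresholds (defaults O/E > 0.6,
GC > 50) spanning at least 200 bp, reported with run means. The midpoint
attribution and strict inequalities are the package's documented
convention; exact edge behaviour of the original tool cannot be validated
here (no machine-readable input sequences), so reported coordinates should
be treated as tool-convention-dependent within about one window.

## Protein properties

Molecular weight is the sum of average residue masses plus one water,
reported in kDa to one decimal (round-half-even). Net charge at pH follows
Henderson–Hasselbalch: positive groups (N-terminus, K, R, H) contribute
1/(1+10^(pH−pKa)), negative groups (C-terminus, D, E, C, Y) contribute
−1/(1+10^(pKa−pH)); cysteines are treated as free. The isoelectric point
is the bisection root of the net charge on [0, 14] to 0.001 pH, reported
to two decimals, and always tagged with the pKa set: the tool behind the
published table does not document its pKas, so `emboss` is the default and
`lehninger`/`sillero` are selectable; swapping sets moves pI by a bounded,
reported amount, which is why the published pI values carry a ±0.3 band.

## Expression ratios

`ratio_matrix()` computes log2((treatment + c)/(control + c)) per declared
pair with pseudocount c = 0.01; the published methods say "expression
ratio" without transform details, so both the log2 scale and the
pseudocount are flags, and swapping treatment with control negates every
value exactly. Reproducing the published heat-map magnitudes would require
the external expression database and is out of scope.

## The synthetic world, and what a green test establishes

`make_family()` generates a family whose stated world mirrors the curated
one: clade-dependent intron plans (AOX1a three introns, AOX1c three to
five, AOX1d intronless or single-intron), GT..AG introns 60–120 bp with
junction bases constrained so planted boundaries are not silently
slidable, proteins built from the synthetic clade backbones with ~3%
substitution at unconstrained positions, optional motif knockouts and
single-substitution variants, 1500 bp promoters at 45% GC with planted
motif realizations at non-overlapping loci, CG-rich blocks planted inside
long introns, and expression tables with lognormal noise around planted
folds. The 45% GC background deliberately permits spurious degenerate-motif
matches; the manifest therefore stores both the planted loci and a
post-assembly audit count, and recovery tests compare against the audit.
Every planted feature is recorded in a manifest and regenerating with the
same seed is byte-identical.

What the generator does **not** emulate: indel evolution, codon-usage
bias, UTR splice sites, overlapping genes, heteroplasmy of real
assemblies, or the sequence context of the real wheat family. A green
recovery test therefore establishes that the algorithms invert the
generator's stated world exactly — not that the published family's values
are reproduced. The published values that are reproducible from printed
tables (domain conservation counts 9/8/6, the full naming grammar) are
asserted in the acceptance suite; the ones requiring the study's
PDF-only sequences are left as explicit red tests rather than being
approximated.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere, with "(start..end)"
  display columns in reports.
* Empty FASTA records and duplicate ids are errors; softmasked bases are
  uppercased before any scan.
* `delineate_structure` reports the first unplaceable transcript offset on
  failure; a transcript shorter than the seed anchor falls back to the
  full transcript as seed.
* `conservation_summary` sends any position with an unaligned ("-")
  included isoform to `mixed`; exclusion lists are the caller's.
* `chemistry_ratios` on an all-gap profile returns zero counts and NA
  ratios with an `undefined` flag rather than dividing by zero.
* `compute_pi` refuses sequences whose charge does not bracket zero on
  [0, 14].
* Catalog files are validated on load: IUPAC legality (error names the
  pattern), strictly increasing position lists, unique names, disjoint
  chemistry classes.

## Known limitations

* Clade assignment by nearest-reference identity can disagree with a
  phylogenetic placement for deeply diverged regulators; the rule that
  fired is recorded in the output for exactly this reason.
* The synthetic diagnostic scheme and TbAOX scaffold make classification
  and mapping testable, but real-data runs should supply a real reference
  and a transcribed diagnostic catalog.
* CpG island coordinates are convention-dependent within about one window
  of the original tool's output.
* The spliced matcher targets same-assembly transcript/gene pairs; it is
  not a cross-species spliced aligner.
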