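---
title: "Methods: a genome-wide WRKY family census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide WRKY family census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkycensus)
```

## The problem

WRKY proteins are one of the larger plant transcription-factor families.
Each member carries one or two ~60-residue DNA-binding domains built from
a conserved heptapeptide (canonically `WRKYGQK`) followed by a
zinc-finger structure, and the family divides into groups I, II (a–e),
III and, in some species, a small divergent group IV. A genome-wide
census of the family — who the members are, how they classify, what
their proteins look like, how their genes are organized on chromosomes
and when they are expressed — is a standard first step toward functional
work in a new species. `wrkycensus` packages that census as a reusable,
testable pipeline.

## Domain detection

`find_cores()` matches a configurable list of core heptapeptides. The
default list is `WRKYGQK`, `WRKYGKK` and `WEKYGQK`. Divergent families
replace only the first four residues of the motif (`WKKY`, `WKRY`,
`WSKY`, `WIKY`, `WRIC`, `WRMC`, `WRRY`, `WVKY`); since nothing
constrains the remaining three positions, these are matched as a 4-mer
followed by any three residues and are disabled by default
(`core_variants(four_letter = TRUE)` enables them). Matching is exact
substring search with overlaps allowed; the ambiguity code `X` never
matches a motif position.

`parse_finger()` searches up to `window = 120` residues downstream of a
core (the domain is ~60 aa, so 120 leaves generous margin) for the first
arrangement `C-X{m}-C-X{n}-H-X-[H|C]` with `m` in {4, 5, 7} and `n` in
{22, 23} — the spacings observed across the family, both configurable.
"First" means the smallest first-cysteine position; ties on the same
cysteine resolve toward the smaller `m`, then the smaller `n`. A
terminal histidine gives a C2H2 finger, a terminal cysteine C2HC.
Spacers are stored so that `m = c2 − c1 − 1` and `n = h1 − c2 − 1`
always hold; windows below 40 residues are rejected because the shortest
legal finger (4 + 22 spacers) cannot fit.

## Group classification

The spacing rule is total:

* two or more complete C2H2 domains → group I;
* a single complete C2H2 domain with `m = 4` → IIc;
* a single complete C2H2 domain with `m = 5` → II, subgroup unresolved;
* a single complete C2HC domain → group III candidate;
* no complete domain → NG (no group).

Subgroups IIa/IIb/IId/IIe all share `C-X5-C-X23-H-X-H` and cannot be
separated by spacing; they are resolved by placement in a
neighbor-joining tree of domain sequences against a labeled reference
set (in practice the Arabidopsis WRKY domains; the test suite uses
synthetic references). A query takes the label of the smallest clade
containing it whose labeled reference leaves are unanimous, falling back
to the nearest reference by patristic distance when no unanimous clade
exists.

Group III versus IV needs care. The divergence test is anchored on the
clade *spanned* by the group-III references (all leaves under their most
recent common ancestor on the midpoint-rooted tree), which requires at
least two group-III exemplars. A C2HC query inside that span is III. A
query outside it is IV when its protein exceeds the divergence length
threshold (default 800 aa — the two known group-IV proteins are
1,333–1,348 aa against ≤ 734 aa for every group-III member), and is
otherwise still III when its placement or nearest reference is III (a
short member may legitimately attach sister to the reference span). We
deliberately do not use the unanimous-clade walk alone for this
decision: a divergent C2HC pair attaches to the tree at a node whose
reference leaves are unanimously III, so the walk alone would absorb
group IV into group III.

Named motifs are scanned as regular expressions: HARF
(`RTGHARFRR[A/G]P`, diagnostic of subgroup IId), the `LxxLL`
co-activator motif, the EAR-like `LxLxLx` repressor motif (trailing
residue required by default; `lxlxlx_trailing = FALSE` switches to the
5-residue convention), and a leucine zipper defined — since no formal
definition is standard — as at least four leucines at exact heptad
spacing (configurable count).

## Physicochemical profile

Per protein: length, molecular weight (sum of ExPASy average residue
masses plus one water; `X` contributes the mean residue mass),
Kyte–Doolittle GRAVY, aliphatic index
(`X(Ala) + 2.9·X(Val) + 3.9·(X(Ile)+X(Leu))` on mole percents),
isoelectric point and instability index (Guruprasad dipeptide weights,
shipped as a CSV). `X` residues are excluded from the GRAVY, aliphatic
and instability denominators.

The pI is the root of the Henderson–Hasselbalch net-charge sum over the
termini and the D, E, C, Y, H, K, R side chains, found by bisection on
pH 0–14 to a tolerance of 1e-4 and reported to two decimals. The pKa
set defaults to the ExPASy-style ("bjellqvist") values with fixed
terminal pKas; the EMBOSS set is selectable. We do not apply
residue-specific terminal pKa corrections, so third-decimal differences
from web calculators are expected.

## Gene structure

GFF3 models (1-based inclusive) are converted to 0-based half-open
coordinates; one model is kept per gene (the mRNA with the longest total
CDS — the data this pipeline targets are single-isoform annotations, and
the choice is stated rather than hidden). Introns are the genomic gaps
between consecutive CDS segments in transcription order; intron phase is
the upstream CDS length modulo 3.

An intron inside the WRKY domain is typed by the residue immediately 3′
of the junction, defined for all phases as the residue whose codon
contains the first nucleotide after the intron: `R` if that residue is
arginine (the classical R-type domain intron), `V` if it is valine *and*
sits exactly six residues after the zinc finger's second cysteine (the
V-type intron of subgroups IIa/IIb; an inclusive-counting ±1 tolerance
is available via `v_tolerance`), `other` for any other in-domain intron,
`none` outside the domain.

## Chromosomal organization

Family naming follows chromosome order: placed loci are numbered by
(chromosome in natural sort order, start); unplaced loci get the highest
numbers. Gene clusters use single-linkage chaining with a start-to-start
gap threshold, 200 kb by default — the classical "gene cluster"
definition gives no number, and 200 kb is the conventional figure;
start-to-start distance keeps the measure insensitive to gene length.
Tandem duplications are same-chromosome pairs with at most one
intervening gene (configurable) and global-alignment protein identity of
at least 70% (BLOSUM62, gap open 10 / extend 0.5); both defaults are
package choices since no published criteria accompany the calls they
emulate.

## Phylogeny

Domain sequences are aligned progressively: all pairwise global
alignments (BLOSUM62, gap open 10 / extend 0.5) give percent-identity
distances, a UPGMA guide tree orders the merges, and profiles are merged
by affine-gap profile–profile dynamic programming with the expected
BLOSUM62 column score (gap–residue pairs score 0). Tie-breaks in the
dynamic program prefer match over gap states, making the alignment
deterministic. Distances are p-distances by default (columns with a gap
in either row excluded); a Poisson correction is selectable since the
underlying reports rarely state which was used.

Trees are built by Saitou–Nei neighbor joining; negative branch lengths
are clamped to zero with a warning. On additive matrices NJ recovers the
generating topology and branch lengths exactly, and the package carries
an exhaustive least-squares topology search (`ls_tree_search()`, all
unrooted topologies for up to 7 taxa, OLS branch lengths on the
path-indicator design matrix) purely as an independent check of that
property. Bootstrap support resamples alignment columns with
replacement, rebuilds the NJ tree per replicate, and reports for each
internal bipartition of the full-data tree the percentage of replicates
containing it; `nj_bootstrap()` defaults to 1,000 replicates, while
`run_census()` uses 100 by default to keep an orchestrated desk-scale
run snappy (configurable). During bootstrap, a resampled pair with no
comparable columns receives the maximal p-distance 1 instead of
erroring.

## Expression calls

The module consumes already-quantified nonnegative matrices with sample
metadata (tissue, stage in days after flowering, treatment, paired
control). Three qualitative calls mirror how such surveys report
results:

* **expressed per tissue** — maximum over the tissue's untreated samples
  exceeds a detection threshold (default 1 on abundance scales; use 0
  for presence/absence matrices);
* **developmental trend** — per-stage means classify as `up` when
  last/first reaches the fold threshold (default 2) and the series is
  non-decreasing within a fractional tolerance (default 0.25, absorbing
  measurement noise without admitting real reversals), `down`
  symmetrically, `flat` when max/min stays under the fold, else
  `mixed`; a zero first stage with later signal counts as an infinite
  fold and is logged;
* **treatment response** — per treated/control pair: `induced` at
  treated/control ≥ fold, `repressed` at control/treated ≥ fold,
  `undetected` when both sit below detection, else `unchanged`.

No differential-expression statistics are attempted; the paired-fold
rules deliberately match the qualitative language of the reports this
census style produces. A `2^-ddCt` helper converts qPCR Ct matrices.

## The synthetic-data generators

Every stage is exercised by a generator that plants its ground truth and
is itself first-class, tested code.

`sim_proteins()` builds proteins as flank – domain – flank (group I: two
domains with a linker), with flanks i.i.d. uniform over the 20 residues
and rejection-sampled so no core heptapeptide arises by accident; zinc
finger spacers exclude C and H so the planted finger is the only legal
parse. Each group uses its observed signature (I: two C2H2 domains with
n = 22/23; IIa/b/d/e: `C-X5-C-X23-H-X-H`; IIc: `C-X4`; III/IV:
`C-X7-...-C`). Subgroup spacers act as barcodes: a fixed template per
subgroup with two random substitutions per protein, so reference-tree
placement separates subgroups cleanly at zero noise. Group IV proteins
combine a deliberately divergent low-complexity spacer with long flanks
(proteins well above the 800 aa threshold). HARF is planted into IId
members by default. Assembled sequences are re-scanned and rebuilt in
the (astronomically rare) event a junction creates a spurious core.

`sim_genome()` encodes one IIb-style domain protein per gene (that
signature carries both an arginine in the core and a valine at
second-cysteine + 6, so R-, V-, `other` and `none` introns all have
targets), reverse-translates with a fixed codon per residue, splits the
CDS at phase-0 junctions for R/V introns, a codon-splitting phase-2
junction for `other` and a phase-1 flank junction for `none`, and
interleaves `GT...AG` introns of 80–200 bp. Genes alternate strands.
Chromosomes default to 1 Mb; clusters are planted by spacing members
within the chaining threshold, singletons at 1.5 × the threshold, and
tandem pairs are near-identical copies (two flank substitutions, ~99%
identity) planted as the first two members of a cluster — as real tandem
pairs are cluster co-members. Flanks are 60 aa so that unrelated genes
share only the ~65 aa domain (~35% global identity, far below the 70%
tandem threshold).

`sim_expression()` emulates a four-organ panel, a five-stage fruit
series (18–42 DAF) and paired treatment/control samples at two stages.
Planted labels map to well-separated values: expressed tissues at 8 vs a
detection threshold of 1; trends as geometric series with fold 16 (`up`
1→16, `down` reversed, `flat` constant, `mixed` zig-zag); responses at
four-fold separation (8 vs 2). Noise is additive Gaussian on the log2
scale (multiplicative on the raw scale), leaving exact zeros untouched.
At the default design, noise_sd = 0.1 leaves every decision margin ≥ 7
standard deviations, so ≥ 95% recovery is expected with room to spare —
and 100% at zero noise.

What the generators do *not* emulate: homology between flanks,
compositional bias, alternative isoforms, UTRs, missing data, read-count
noise models, or any nucleotide-level evolution. Passing the round-trip
tests therefore demonstrates the pipeline's internal correctness — that
each stage recovers exactly what its contract promises — not robustness
to the full messiness of real annotations.

## Numerical and degenerate-input choices

* Overlapping core hits are all reported; classification uses complete
  domains only, and mixed C2H2/C2HC proteins are labeled by the
  C-terminal complete domain with a warning.
* A CDS length not divisible by 3 warns but does not fail; zero-intron
  genes are reported as such.
* NJ agglomeration ties resolve to the lowest index pair (inherited
  determinism); identical inputs always give identical outputs, and
  every generator is byte-deterministic under a fixed seed.
* Problem sizes in the shipped tests and acceptance script (desk scale):
  families of 16–59 proteins, genomes of up to 59 genes on up to 7
  chromosomes of 1–3.5 Mb, expression studies of 30–59 genes, 1,000
  random sequences for the scanner oracle and 100 random additive
  matrices (4–5 taxa) for the NJ oracle — sizes chosen so the whole
  suite exercises every code path in about a minute.

## Known limitations

* No profile-HMM domain search; detection is exact-motif based, so
  cores outside the configured variant list are missed (real censuses
  typically cross-check with an HMM — out of scope here).
* Subgroup resolution quality is bounded by the reference set; with a
  single group-III exemplar the III/IV divergence test degrades to
  placement-plus-length.
* The progressive aligner is a compact reimplementation for ~60-residue
  domains, not a general MSA engine; column counts and exact gap
  placement may differ from Clustal-family tools even where both are
  reasonable.
* Tandem calling counts intervening genes among supplied loci unless a
  full gene list is provided; segmental/collinearity duplication
  analysis is deliberately not implemented.
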