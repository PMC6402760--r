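---
title: "Characterizing alternative UTRs: models, rules and design choices"
author: "utrlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing alternative UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrlens)
```

# The problem

Untranslated regions concentrate much of a gene's post-transcriptional
control: upstream open reading frames (uORFs) and structured 5′ UTRs
repress initiation, polyadenylation signals (PAS) set 3′-end choice and
transcript stability, and 3′ UTRs carry miRNA target sites whose
efficacy depends on how easily the site can be unpaired from the
mRNA's own fold. Gene families with alternative UTR variants — the
mammalian lipocalins are the motivating case, with early-diverging
members carrying long, conserved, uORF-rich 5′ UTRs and late-diverging
members carrying short permissive ones — need all of these features
computed uniformly across many variants and species. `utrlens`
implements that feature extraction as a set of small, testable rules
around a keyed sequence catalog (`UtrCatalog`, a `DNAStringSet` with
gene/variant/species/region metadata).

Coordinates are 0-based internally only in arithmetic; everything
user-visible is 1-based inclusive, matching how positions are reported
in the field's tables. RNA input is accepted everywhere (U is mapped
to T on entry).

# Rules and parameters

## Composition

G+C content is (G+C)/(A+C+G+T); N bases are excluded from the
denominator so ambiguity characters in database sequences do not
depress the estimate, and an all-N sequence is an error rather than a
silent 0. The UTR–CDS correlation uses Pearson's r with a two-sided
p-value and an OLS line with a pointwise 95 % confidence band; zero
variance on either axis is an error because r is undefined there.

## uORFs and translation classes

Every ATG is a uAUG; each is walked in frame to the first in-frame
stop inside the UTR. By default ORFs that run into the CDS are
excluded (`requireStopInUtr = TRUE`): published per-variant counts
satisfy n_uORF ≤ n_uAUG with strict inequality in some variants, which
is what stop-contained counting produces. The minimum peptide length
is 1 codon (start plus stop), the smallest value consistent with those
counts; both are configurable.

Initiation context uses only the −3 and +4 positions (the two most
informative Kozak positions): optimal when −3 ∈ {A,G} and +4 = G,
adequate when exactly one holds, weak otherwise. A uORF closer than
3 nt to the cap has no −3 base, which counts as failing the −3
condition. Cap distance is classed optimal above 19 nt and weak below
12 nt; the 12–19 nt band is undefined in the published two-letter
scheme, so it is kept as an explicit `intermediate` class internally
and collapsed into `O` (together with `adequate` contexts) when the
two-letter `"O2/W1"`-style summary strings are emitted.

The translation-efficiency classes I (low) and III (efficient) come
from a classification-tree scheme whose fitted tree is not public. We
therefore expose a deliberately simple surrogate rule with tunable
thresholds (`cartThresholds()`): class III iff no uORF, length ≤ 100
nt, and (when a folding energy is available) MFE ≥ −0.45 kcal/mol/nt.
Against the printed classes of the bundled lipocalin table the
surrogate agrees on 38/40 variants; the two misses are a pair of mouse
Rbp4 variants that the printed table itself classes inconsistently
with any length/uORF rule (one 61-nt variant with a uORF printed III,
one 89-nt uORF-free variant printed I). We document rather than fit
these: no rule stated in terms of the printed features separates them.

## Polyadenylation signals

AAUAAA is canonical (C), AUUAAA non-canonical (NC), and ten further
single-base variants (TATAAA, AGTAAA, AAGAAA, AATATA, AATACA, CATAAA,
GATAAA, AATGAA, TTTAAA, ACTAAA, AATAGA) form the default NC\* set, the
variant list reported by genome-wide polyadenylation surveys; the set
is a plain argument. Scanning is sense-strand only (PAS function is
strand-specific) and overlap-tolerant. Efficiency uses one window:
a hexamer whose start lies 10–45 nt from the 3′ end is VE (canonical)
or E (non-canonical); outside, LE. The window was chosen to cover the
distances (17–45 nt) at which canonical signals are annotated very
efficient in the bundled reference table; with it the rule reproduces
40/42 printed labels, and both misses are annotations the source
itself prints in parentheses (flagged `parenthesized` in
`inst/extdata/lipocalin_pas_reference.tsv`). Candidate alternative 3′
ends are placed 20 nt downstream of each non-LE hexamer end, capped at
the UTR end — a nominal cleavage offset, not a cleavage-site model.

## Oligonucleotide enrichment

Counting is overlapping and, by default, two-strand: a word is pooled
with its reverse complement under the lexicographically smaller key,
because regulatory-motif reports pool such pairs (e.g. CTGGCA/TGCCAG
as one count). Expected counts come from a Markov background of order
0–2 estimated from the input set itself with a 0.01 pseudo-count;
input-training is the reproducible choice when no published background
table exists. Significance is the exact binomial upper tail at the
per-position probability, Bonferroni-corrected over the number of
distinct observed words (configurable to 4^k); the significance index
is −log10 of that E-value, so positive values mean less than one such
word expected by chance. Published significance indices depend on the
original tool's internal test count and are treated as comparison
points, never asserted.

## miRNA site accessibility

Seed matching pairs miRNA positions 1..8 (configurable ≥ 6)
antiparallel against the UTR with at most one G:U and one mismatch;
position 1 must be Watson–Crick, a stricter reading of "not both at
position 1" that keeps the anchor pair unambiguous. Scoring follows
the accessibility idea: ΔGopen = E(window, unconstrained) −
E(window, site forced unpaired) ≤ 0 by construction, ΔΔG = ΔGduplex −
ΔGopen, computed over a ±70 nt window (the published accessibility
default). Thresholds: ΔΔG < −10 kcal/mol ⇒ accessible; additionally
ΔGopen > −10 ⇒ very accessible, hence very-accessible ⊆ accessible
always.

Thermodynamics are a pluggable engine contract because exact energies
depend on parameter sets that are not pinned anywhere: a constant
`stubEnergyEngine()` isolates the arithmetic in tests, a
self-contained `toyEnergyEngine()` (pair energies GC −3, AU −2, G:U
−1; minimum-energy fold as ensemble proxy) gives deterministic
engine-like behaviour without external tools, and
`viennaEnergyEngine()` binds the RNAduplex/RNAfold command-line tools
with partition-function ensembles when present. Absolute site counts
against real miRNA catalogs depend on the catalog snapshot and engine
and are deliberately not asserted anywhere.

## Secondary-structure censuses

The toy folding engine scores −1 per pair (canonical plus G:U) with a
3-nt minimum hairpin loop — the standard steric constraint, and the
value the exhaustive test oracle must share for exact agreement. All
structures within the energy window (default +5 kcal/mol, the
conventional native-structure band) are enumerated by bound-pruned
recursion over the dynamic-programming table, so the ensemble is exact,
not sampled; ordering is deterministic (energy, then lexicographic
dot-bracket, MFE first, ties broken lexicographically). The abstract
shape drops unpaired positions, collapses each helix chain (helices
separated only by bulges/internal loops) and keeps only branching:
`((...))` → `[]`, `..((..))..((...))..` → `[][]`, open chain → `_`.
Conserved elements are the maximal MFE-structure helices whose entire
pair set occurs in at least 60 % (configurable) of the suboptimal
structures — a helix-sharing measure, intentionally simpler than
tree-edit structure alignment, which is out of scope. The toy engine
is exponential in the worst case and intended for short sequences and
oracle tests; quantitative energies should use the ViennaRNA engine,
whose MFE values are parameter-version-dependent and only ever
compared within ±10 %.

## Conservation and Ka/Ks

Percent identity uses global alignment (match +1, mismatch −1, gap
open 10, gap extend 0.5 — generic alignment defaults, since the
original comparisons were made with unspecified tool settings, making
published identities ±-a-few-points comparison values). Columns in
terminal gap runs are excluded so length-variable UTR variants are
compared over their aligned core; internal gaps count as mismatches.
Homology calls use an inclusive ≥ 60 % threshold. Codon-partitioned
identity excludes whole codons containing gaps or Ns pairwise and
reports positions 1+2 versus 3 separately. Multiple alignment itself
is delegated (pre-aligned input in `msa_columns` mode); only
column-wise identity is computed here.

Ka/Ks is Nei–Gojobori 1986: per-codon synonymous site fractions
(mutations to stops count as nonsynonymous) averaged over the two
sequences; substitution counts averaged over all shortest mutational
pathways, discarding pathways through stop codons when any
stop-free pathway exists; Jukes–Cantor correction d = −3/4 ln(1 −
4p/3), with p ≥ 3/4 flagged undefined rather than thrown, and the
ratio flagged undefined when Ks = 0.

# The synthetic-data generator

The generator exists so every scanner can be validated against a known
truth without downloads. It emulates: gene families with lettered UTR
variants; uORFs planted at chosen cap distances with chosen −3/+4
context classes; PAS hexamers at chosen distances from the 3′ end;
enriched k-mers over a background of target G+C; miRNA seed sites; and
ortholog families diverged with per-codon-position rates (third
position fastest).

Exact recovery is engineered, not hoped for: 5′ backgrounds are
scrubbed of every spurious ATG (and planted-k-mer occurrence, forward
and reverse complement, since counting is two-strand), 3′ backgrounds
of every PAS hexamer and of every *near*-match to a planted seed
(within the 1-G:U/1-mismatch tolerance, broken preferentially at the
position-1 pair). Scrub replacements are drawn from the target base
distribution so they do not bias G+C. uORF peptide codons are drawn
from T-free codons, which excludes internal stops and internal ATGs by
construction (this is also why an optimal-context uORF needs peptide
length ≥ 2: a stop codon starts with T, so the +4 base of a
start-plus-stop ORF can never be G). When a spurious motif falls
entirely inside protected planted bases — rare but possible — the gene
is regenerated from a fresh deterministic substream; output is still
byte-identical for a given plan and seed. Defaults (300 nt UTRs, 100
codons, G+C 0.5, ≥ 5 nt between planted features) are ordinary
mammalian-scale values.

What the generator does *not* emulate: isochore structure, indels
(substitutions only), repeat elements, splicing, and any correlation
between features. Passing recovery tests therefore shows the scanners
are exact on clean signal-plus-background sequence, not that they are
robust to every property of real UTRs.

Divergence uses independent per-site substitution (Jukes–Cantor style;
a substituted base becomes one of the other three uniformly), with
position-1/2 CDS substitutions reverted if they would create an
internal stop, and rejects rates above 0.75 where identity saturates.
Under rate r per lineage the expected leaf–leaf identity is
(1−r)² + r²/3, the closed form the tests and the acceptance script
compare against.

# Numerical and testing choices

Tests freeze seeds and compare against independent oracles: an
exhaustive no-DP structure enumerator, a graph-reduction shape
abstraction, a hard-coded codon table with DFS pathway enumeration for
Ka/Ks, naive sliding-window counters, and closed-form expectations.
Problem sizes were chosen so each oracle stays exact and fast: ≤ 3
codons for the 500 Ka/Ks pairs (pathway count ≤ 3! per codon), a
50-sequence panel of 8–25 nt for structure enumeration (tens of
thousands of structures at most), 25 genes × 8 planted features for
the 200-feature recovery check, and 100 replicates for the
divergence-ordering rate. The G+C-tracking check averages over eight
600-nt genes because a single 600-nt draw has a sampling standard
deviation (~2 points) comparable to the bias being tested.

`scripts/acceptance.R` recomputes the same quantities from scratch at
an arbitrary seed. Checks that require the original published UTR
*sequences* (exact per-variant lengths, G+C, oligo pair counts, MFE
values) cannot run without that catalog, which is not redistributable
here; they look for a user-supplied copy under
`inst/extdata/lipocalin/` and fail visibly when absent, rather than
being skipped. The printed annotation tables that *are* reproducible
from the source's text ship as plain TSVs under `inst/extdata/` and
back the rule-agreement checks.

# Known limitations

- The translation-class rule is a surrogate; it reproduces the printed
  classes only as well as any length/uORF rule can (38/40 here).
- PAS efficiency is a pure distance rule; downstream U/GU-rich
  elements and cleavage evidence are out of scope.
- The toy energy model ranks structures by pair count only; use the
  ViennaRNA engine for anything quantitative.
- Identity values depend on alignment scoring; treat small differences
  (a few points) as noise.
- miRNA site counts depend on the miRNA catalog supplied; none is
  bundled.
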