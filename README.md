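# utrlens

Characterization of 5′ and 3′ untranslated regions (UTRs) for
post-transcriptional regulation analysis.

Genes with alternative UTR variants — such as the mammalian lipocalins,
where early-diverging members (APOD, RBP4, PTGDS, APOM) carry long,
uORF-laden, highly conserved 5′ UTRs while late-diverging members carry
short permissive ones — encode much of their expression control outside
the CDS. `utrlens` turns a FASTA catalog of UTR variants (keyed
`gene|variant|species`) into the feature tables a regulatory analysis
needs:

- **Composition** — length, G+C content (Ns excluded from the
  denominator), per-codon-position G+C of the CDS, and the Pearson
  correlation of UTR G+C with third-codon-position G+C, with OLS line
  and 95 % confidence band.
- **Upstream ORFs** — every uAUG and uORF (frame walk to the first
  in-frame stop), Kozak-style context from the −3/+4 bases
  (optimal = −3 ∈ {A,G} ∧ +4 = G), cap-distance classes
  (optimal > 19 nt, weak < 12 nt), and a transparent surrogate for the
  published CART translation classes: class III (efficient) iff no
  uORF, length ≤ 100 nt and folding energy ≥ −0.45 kcal/mol/nt.
- **Polyadenylation signals** — all AAUAAA (C), AUUAAA (NC) and
  rare-variant (NC\*) hexamers; a signal within 10–45 nt of the 3′ end
  is very efficient (VE, canonical) or efficient (E, non-canonical),
  otherwise low efficiency (LE); candidate alternative 3′ ends follow
  from the non-LE sites.
- **Oligo enrichment** — overlapping k-mer counts (two-strand,
  reverse-complement pairs merged), expected counts under an
  input-trained Markov background, exact binomial upper-tail p-values
  and a Bonferroni significance index, sig = −log10(nTests · p).
- **miRNA accessibility** — seed matches (≥ 8 nt, ≤ 1 G:U, ≤ 1
  mismatch, position 1 Watson–Crick) scored PITA-style:
  ΔΔG = ΔGduplex − ΔGopen, where ΔGopen is the ensemble-energy cost of
  unpairing the site in a ±70 nt window; ΔΔG < −10 ⇒ accessible,
  additionally ΔGopen > −10 ⇒ very accessible. Energies come from a
  pluggable engine (deterministic stub, self-contained toy model, or
  the ViennaRNA command-line tools).
- **Structure censuses** — MFE plus all suboptimal structures within
  +5 kcal/mol, collapsed to level-5-style abstract shapes, and the MFE
  helices present in ≥ 60 % of the suboptimal set.
- **Conservation** — global-alignment percent identity (terminal gaps
  excluded), codon-position-partitioned identity, identity matrices,
  ≥ 60 % homology calls, and Nei–Gojobori (1986) Ka/Ks with pathway
  averaging and Jukes–Cantor correction.
- **Synthetic data** — a generator that plants uORFs, PAS hexamers,
  k-mers and miRNA seed sites at exact, recorded coordinates in
  motif-scrubbed backgrounds, and diverges ortholog families with
  per-codon-position substitution rates.

## Worked example

```r
library(utrlens)

utr5 <- "CCATGGCGTAACCCCCCCCCCCCCCCCCCCCCCCCCATGAAATAACC"
prof <- translationProfile(utr5)
prof[c("n_uaug", "n_uorf", "efficiency_string", "cart_class")]
#> $n_uaug
#> [1] 2
#> $n_uorf
#> [1] 2
#> $efficiency_string
#> [1] "O1/W1"
#> $cart_class
#> [1] "I"
```

Two uORFs are found; one sits more than 19 nt from the cap (`O`), one
closer than 12 nt (`W`), so the summary string is `"O1/W1"` and the
variant is classed `I` (low translation). On the 3′ side:

```r
scanPas("CCAATAAACCCCCCCCCCCCCCCCCCCCCCCCCCC")
#> DataFrame with 1 row and 5 columns
#>    position     hexamer    pas_type distance_to_end  efficiency
#>   <integer> <character> <character>       <integer> <character>
#> 1         3      AATAAA           C              32          VE
```

A full run over FASTA catalogs (`runCharacterization(runConfig(...))`)
writes `table1_like.tsv`, `table4_like.tsv`, `enrichment.tsv`,
`conservation.tsv` and a run log;
`inst/scripts/utrlens.R` wraps the same calls for shell use.

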