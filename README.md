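# karyodelim

Integrative species delimitation for taxa that differ by Robertsonian
chromosome fusions and fissions — built for the "anomalous blue"
butterflies (*Polyommatus* subgenus *Agrodiaetus*), whose species are
externally cryptic but karyotypically distinct, and whose hybrids can be
recognised from chromosome counts alone.

## Who this is for

Systematists and evolutionary biologists working on chromosomally
polymorphic groups who need to answer, specimen by specimen: is this a
pure member of species A or B, an F1 hybrid, or a backcross? The package
combines three marker systems:

1. **A meiotic pairing model** (the core). A haploid karyotype is a
   partition of a shared universe of chromosome arms into chromosomes; a
   diploid is two such partitions. At metaphase I, the homology graph —
   one node per chromosome, one edge per arm joining its two carriers —
   decomposes into connected components: bivalents (2 chromosomes),
   trivalents (3, fusion heterozygotes), quadrivalents and higher chains.
   The component count is the number of **visible elements** n counted
   under the microscope. Balanced gametes are exact covers of each
   element's arms, so crosses and pedigrees (F1, BC1, F2) can be
   enumerated exhaustively and every scenario's achievable-count set
   derived exactly.
2. **COI barcode haplogroups**: haplotype collapsing, a minimum-spanning
   (TCS-style) haplotype network with reticulations and inferred
   intermediate haplotypes, and haplogroup assignment by cutting long
   edges.
3. **Wing-colour morphometrics**: per-specimen RGB/HSV profiles from disc
   measurements, NMDS ordination (Kruskal stress-1) and a from-scratch
   one-way PERMANOVA — pseudo-F = (SS_B/(k−1))/(SS_W/(N−k)) over a
   distance matrix, with SS_T = Σ_{i<j} d²_ij/N and an add-one permutation
   p-value.

In the focal two-species system (haploid counts n = 41–42 vs 42–43, one
fixed fusion difference, each species polymorphic for a fusion in a
different pair), the model predicts that **every F1 combination shows
exactly 41 visible elements**, while first-generation backcrosses span
{41, 42, 43}. A contact-zone specimen with the O-side mitochondrion and
n = 43 is therefore a backcross, not an F1 — evidence that reproductive
isolation is incomplete.

A synthetic-study generator (`simulation_config()`,
`simulate_specimen_table()`) produces sequences, karyotypes, colours and
localities with planted truth, so the whole pipeline is testable offline.

## Worked example

```r
library(karyodelim)

m <- build_two_species_model()
m
#> Two-species fusion/fission model over 44 arms
#> Species karyotype spec 'species-O': 2 fixed fusion(s), 1 polymorphic fusion(s); haploid n in {41, 42}
#> Species karyotype spec 'species-L': 1 fixed fusion(s), 1 polymorphic fusion(s); haploid n in {42, 43}
#> Haplogroup map: orph1->O, orph2->O, aroa3->L
```

A fusion heterozygote of the L species (one fused chromosome facing two
unfused homologues over 43 arms) pairs into 41 bivalents plus one
trivalent — 42 visible elements:

```r
u <- arm_universe(as.character(1:43))
het <- diploid_genotype(
  haploid_karyotype(c(list(c("1", "2")), as.list(as.character(3:43))), u),
  unfused_karyotype(u))
pair_meiosis(het)
#> Metaphase-I configuration: 42 visible elements ( 41 bivalent + 1 trivalent )
```

Exhaustive pedigree enumeration and the per-specimen consistency call:

```r
achievable_visible_counts(pedigree_scenario("BC1", m))
#>   visible_count probability
#> 1            41      0.4375
#> 2            42      0.5000
#> 3            43      0.0625

classify_karyotype_consistency(43, "orph2", m)
#> n = 43 with haplogroup orph2 -> backcross-consistent
#>   scenarios containing the count: BC1
```

The BC1 table reads: a backcross of an F1 to species L has a 6.25% chance
of the diagnostic count 43 (and is otherwise indistinguishable from a
pure parent by count alone). The full pipeline on a synthetic study —
haplogroup assignment from the sequences, karyotype consistency, colour
ordination and PERMANOVA, contact-zone detection, integrative calls:

```r
report <- run_pipeline(list(simulation = list(seed = 11), seed = 2,
                            n_permutations = 999))
report
#> Integrative delimitation report
#>   calls: putative-hybrid=2, species-A=12, species-B=13
#>   contact zones flagged: contact-zone
#>   PERMANOVA (call groups): F = 61.728, P = 0.001
#>   NMDS stress: 0.0137
```

Here two of the four planted backcrosses drew a diagnostic karyotype and
were recalled as hybrids; the others drew counts inside the pure species'
achievable sets and are — irreducibly — called species A. All planted
pure specimens are called correctly, and the colour PERMANOVA separates
the call groups decisively.

See `vignettes/integrative-delimitation.Rmd` for the model's assumptions,
parameter defaults and limitations.

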