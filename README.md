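# orphanscan

Annotation and comparison of motif-demarcated toxin/immunity modules in
bacterial contact-dependent growth inhibition (CDI) and rearrangement-hotspot
(Rhs) loci.

## The problem

CDI systems deliver the toxic C-terminal domain (CdiA-CT) of the cell-surface
exoprotein CdiA into neighbouring bacteria; a small CdiI immunity protein
encoded immediately downstream neutralizes the cognate toxin. The CdiA-CT is
polymorphic and begins immediately after a conserved Val-Glu-Asn-Asn (VENN)
peptide motif; Rhs proteins carry an analogous polymorphic C-terminus (Rhs-CT)
demarcated by the PxxxxDPxGL motif. Downstream of many *cdiBAI* and *rhs*
clusters lie **orphan** *cdiA-CT/cdiI* gene pairs: CT-encoding fragments that
generally lack a translation initiation codon and Shine-Dalgarno sequence but
still encode the demarcation motif, each paired with a small, expressible
immunity ORF. Orphan modules can be swapped onto the full-length gene by
deletion at the motif junction, and near-identical modules appear at different
positions in different strains (module interchange).

`orphanscan` turns that comparative-genomics procedure into a tested pipeline
for user-supplied loci:

- **Six-frame motif scanning** — every occurrence of a peptide pattern
  (uppercase residues exact, `x`/`.` any residue) in all six reading frames,
  mapped to exact nucleotide coordinates; the CT region starts at the first
  nucleotide after the motif span and runs to the first in-frame stop.
- **ORF calling with initiation signals** — stop-to-stop ORFs annotated with
  the most upstream start codon (ATG/GTG/TTG) and a Shine-Dalgarno score: the
  best match to the anti-SD consensus `AGGAGG` within a 4-20 nt pre-start
  window; an ORF is *expressible* iff it has a start and an SD score ≥ 4/6,
  otherwise a *fragment*.
- **Module assembly** — each motif hit is paired with the nearest same-strand
  downstream ORF of 150-900 nt within 300 nt; a module is *main* when ≥ 3,000
  nt of uninterrupted in-frame coding sequence lie upstream of the motif and
  that frame is expressible, *orphan* otherwise; orphans are labelled
  o1, o2, ... in positional order.
- **Locus comparison** — ACT-style gap-free identity blocks from exact shared
  21-mers (both strands), divergence breakpoints at motif junctions,
  deletion-fusion events (deleted length recovered exactly from diagonal
  arithmetic, A-gap minus B-gap) and module interchange (Needleman-Wunsch
  global identity ≥ 90% over ≥ 500 nt between module spans).
- **Synthetic loci with planted ground truth** for end-to-end validation, and
  the efficiency-corrected qPCR expression ratio
  *e* = E_target^(−Ct_target) / E_ref^(−Ct_ref) with mean ± SEM replicate
  summaries.

## Worked example

```r
library(orphanscan)

# a synthetic cdiBAI-like locus: full-length gene + 3 orphan modules
sim <- generate_locus(synthetic_locus_spec(n_orphans = 3, seed = 42))
map <- scan_locus(sim$sequence, motif = "VENN")
map
```

```
<locus_map> synthetic_locus_seed42 (12536 nt), motif VENN
  full-length gene: [163, 9163) +
 label  class strand ct_start ct_end immunity_start immunity_end gap_nt
  main   main      +     8755   9160           9175         9538     15
    o1 orphan      +     9608   9974           9989        10523     15
    o2 orphan      +    10591  10915          10930        11320     15
    o3 orphan      +    11463  11898          11913        12426     15
 immunity_expressible ct_truncated upstream_coding_nt
                 TRUE        FALSE               8592
                 TRUE        FALSE                  0
                 TRUE        FALSE                  0
                 TRUE        FALSE                  0
```

The full-length gene's CT begins right after its VENN-encoding span
(`ct_start` 8755) with 8,592 nt of in-frame coding sequence upstream; the
three orphan CT fragments have none (`upstream_coding_nt` 0, no start codon),
yet each is followed at a 15 nt gap by an expressible immunity ORF —
the architecture that defines orphan toxin/immunity modules.

Deletion-fusion between motif junctions:

```r
del <- apply_rearrangement(sim$sequence, sim$truth, "deletion_fusion",
                           list(orphan = 1, deletion_len = 3557))
# (requires a locus geometry whose main CT-to-orphan junction distance
#  exceeds the deletion; see ?synthetic_locus_spec)
cmp <- compare_loci(sim$sequence, del$sequence)
events_table(cmp)
```

For a locus generated with `ct_len_range = c(1800, 1800)`,
`immunity_len_range = c(600, 600)`, `gap_range = c(1200, 1200)` this prints
one `deletion_fusion` event with `deletion_len_nt = 3557` and
`label_a = "o1", label_b = "main"`: the orphan module now fused onto the
full-length gene, recovered exactly from the block diagonals.

From a shell, the same stages are available as subcommands:

```sh
inst/scripts/orphanscan simulate --spec inst/extdata/simulate_example.yaml --out sim/
inst/scripts/orphanscan scan     --fasta sim/locus.fasta --out scan/
inst/scripts/orphanscan compare  --a locusA.fa --b locusB.fa --out cmp/
inst/scripts/orphanscan qpcr     --csv inst/extdata/qpcr_example.csv --out expr.csv
```

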