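# mitoclover

Comparative analysis of annotated insect mitochondrial genomes, centered on
the detection of **tRNA-like structures** in mitochondrial control regions.

Insect mitogenomes are circular 15–16 kb molecules with 13 protein-coding
genes, 22 tRNAs, two rRNAs and one A+T-rich non-coding control region.
Beyond the standard comparative statistics, their control regions can carry
cloverleaf-folding segments whose anticodon is identical to one of the
genome's own tRNAs — tRNA-like sequences, whose census, conservation and
origin are of interest in insect molecular evolution. `mitoclover` is for
researchers who have annotated mitogenome records (GenBank flat files or
FASTA plus a feature table) and want a reproducible, scriptable pipeline
for:

- **Composition**: base counts, A+T content, strand asymmetry
  (AT-skew = (A − T)/(A + T), GC-skew = (G − C)/(G + C)), per-codon-position
  composition (GC3, GC12).
- **Codon-usage bias** under the invertebrate mitochondrial code (table 5,
  62 sense codons): RSCU, Wright's effective number of codons (ENC)
  generalized to the code's 2/4/6/8-fold family structure, Bennetzen–Hall
  codon bias index (CBI), and the ENC-plot expectation
  ENC\* = 2 + GC3 + 29/(GC3² + (1 − GC3)²).
- **Selection**: pairwise Ka/Ks per gene by Nei–Gojobori (1986) counting
  with Jukes–Cantor correction, pathway-averaged over multi-hit codons.
- **Control-region architecture**: tandem repeats (deterministic
  self-offset scanner with fractional copy numbers), poly-T tracts, TA
  repeats, G+C-rich windows, and conserved intergenic spacer motifs.
- **tRNA-like detection**: constrained cloverleaf folding (acceptor 7 bp,
  D 3–4 bp, anticodon stem 5 bp + 7-nt loop, T 4–5 bp, G–U allowed) with
  the anticodon-identity criterion, percent-identity scoring against the
  same-anticodon conventional tRNA, and a 65% tier.
- **Phylogenetic export**: concatenated P123 / P123AA / P123RNA
  supermatrices with per-gene and per-codon-position charsets
  (PHYLIP-relaxed and NEXUS).
- **Synthetic data**: a deterministic mitogenome generator with planted
  tandem repeats and tRNA-like copies, providing ground truth for every
  stage.

## Worked example

```r
library(mitoclover)

cfg <- simulation_config(
  seed = 42,
  planted_trnas = list(list(family = "trnL2", mutation_rate = 0.05,
                            position = 400)))
rec <- generate_mitogenome(cfg)
rec
#> <mito_record> SYN0000042 (synthetic tenebrionid mitogenome): 15888 bp,
#>   38 features (1 control_region, 13 PCG, 2 rRNA, 22 tRNA)

cs <- summarize_composition(rec$sequence)
u  <- usage_stats(rec)
cr <- extract_control_region(rec)
hits <- scan_control_region(cr, trna_references(rec))
```

The record reproduces the hallmarks of a darkling-beetle mitogenome —
`A+T 71.1%, AT-skew 0.107, GC-skew -0.220` on the J strand, and
`ENC 51.24, CBI 0.304, GC3 27.9%` with the observed ENC close to the
composition-only expectation `ENC* 50.82`, as expected for selection-free
codon sampling. The control region is `1000 bp at 86.0% A+T`, and the scan
recovers the planted, 5%-mutated leucine-tRNA copy:

```r
hits[, c("start", "end", "strand", "family", "anticodon",
         "match_percent", "tier", "p_dist")]
#>   start end  strand     family anticodon match_percent tier     p_dist
#> 1   400 472 forward trnL2-like       TAA      97.22222 high 0.02777778
cat(hits$dot_bracket[1])
#> (((((((..((.(........).)).(((((.......)))))....(((((.......)))))))))))).
```

`match_percent` is the global-alignment identity against the genome's own
conventional trnL2 (97.2% here: the plant was mutated at 5% per base), the
`high` tier marks hits at or above 65%, and the dot-bracket string shows
the folded cloverleaf with its four stems.

For real data, replace the generator with `parse_genbank("file.gb")` (or
`parse_feature_table()` for FASTA + TSV) and drive everything at once with
`run_pipeline(paths, out_dir = "out")`, which writes the per-record summary,
codon usage, Ka/Ks, repeat and tRNA-like tables as TSV/JSON. A thin CLI
wrapper with `summarize`, `simulate` and `supermatrix` subcommands is
installed at `inst/scripts/mitoclover`.

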