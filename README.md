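# crisprko

Design everything needed for a seamless, marker-free CRISPR/Cas9 deletion in
a small genome (written for fission-yeast-style workflows): the single guide
RNAs (sgRNAs) and the three PCR primer sets that take a deletion from plasmid
cloning to verification.

## Who this is for

Labs deleting genes or arbitrary genomic regions with S. pyogenes Cas9 plus a
co-transformed repair template, where the workflow is:

1. express an sgRNA and Cas9 from one plasmid (the spacer is cloned into the
   plasmid by inverse PCR),
2. let the cell repair the Cas9 double-strand break from a short synthetic
   homologous-recombination (HR) template that fuses the deletion flanks, and
3. confirm the deletion by junction PCR.

Given a genome FASTA and a target region — a gene name resolved through a
GFF3 annotation, or explicit `chromosome:start-end` coordinates — the package
produces a complete, deterministic design report.

## The method

**sgRNA enumeration and ranking.** Cas9 requires a 5'-NGG-3' protospacer
adjacent motif (PAM); the 20 nt immediately 5' of the PAM on the same strand
form the spacer. The package scans every chromosome on both strands and
builds a database of all PAM-adjacent spacers. For a spacer *s*, its
**similarity profile** is the 7-tuple

&nbsp;&nbsp;&nbsp;&nbsp;*c(k)* = number of PAM-adjacent spacers genome-wide whose last *k* nt
(PAM-proximal suffix) equal those of *s*, for *k* = 20, 18, 16, 14, 12, 10, 8.

Only spacers with *c(20)* = 1 (unique in the spacer database) are reported,
ranked by ascending lexicographic order of the tuple — the fewer genomic
near-matches at long shared suffixes, the lower the off-target risk, and the
better the rank. A `seed_unique` flag marks spacers whose 12-nt seed
(the PAM-proximal region where mismatches abolish Cas9 activity) is itself
unique. Each candidate is annotated with the blunt cut site (3 bp upstream of
the PAM) and the 10-nt PAM-proximal window where point mutations can be
placed in other editing applications.

**Primer sets.**

| Set | Construction |
|---|---|
| sgRNA cloning | Inverse-PCR primers around the plasmid insertion point; the spacer rides on primer 5' tails. *Ligation* method: spacer on the forward primer only, blunt product is phosphorylated/ligated. *Ligation-free*: both primers carry the full spacer in opposite orientation; bacteria recircularise via the 20-nt terminal homology. |
| HR template | The 80 nt upstream + 80 nt downstream of the region are fused into a 160-nt template; `HRfw` = its first 100 nt, `HRrv` = reverse complement of its last 100 nt (40-nt overlap; >= 20 nt suffices for the PCR). |
| Checking primers | The post-deletion junction is simulated as 250 + 250 nt of flank; one primer is picked per flank (length 18–25, Tm 57–63 °C optimum 60, GC 20–80 %, pair ΔTm <= 3 °C) minimising \|Tm−60\| per primer plus the pair Tm difference. Reported with nearest-neighbor Tm and predicted product sizes: deletion product, and wild-type product = deletion product + deleted length. |

Melting temperatures use unified SantaLucia/Allawi nearest-neighbor
thermodynamics at 50 mM monovalent salt and 50 nM oligo.

## Worked example

Using the shipped synthetic demo fixtures (a 2 × 3 kb genome and a matching
GFF3; the demo plasmid is a labelled synthetic stand-in, not a real vector):

```r
library(crisprko)
genome     <- read_genome(system.file("extdata", "genome.fa", package = "crisprko"))
annotation <- read_annotation(system.file("extdata", "annotation.gff3", package = "crisprko"))
index      <- build_index(scan_pams(genome), genome)

region <- resolve_gene("SPNCRNA.01", annotation, genome)  # II:901-1500
design <- design_deletion(genome, region, index = index)
design
```

```
deletion design for SPNCRNA.01 (600 nt)
  76 genome-unique sgRNA candidate(s); top 2 with cloning primers
 rank strand               spacer pam spacer_start cut_position seed_unique k20
    1      + CCGACATTGCGGTAGCTAAC CGG          902          918        TRUE   1
    2      - CCGGTTAGCTACCGCAATGT CGG          905          908        TRUE   1
 k18 k16 k14 k12 k10 k8
   1   1   1   1   1  1
   1   1   1   1   1  1
  HR template: 160 nt; HR primers 100 nt each, 40 nt overlap
deletion-checking design
check_fw  5'-TCCGTGAGCAAAGTAGGACGGGAG-3'  (24 nt, Tm 60.0 C)
check_rv  5'-ATTCCCGACTGGAGGAACGGGAAG-3'  (24 nt, Tm 60.0 C)
  product if deleted: 160 nt; wild-type: 760 nt; junction template: 500 nt
```

Reading the output: 76 spacers inside the region are unique genome-wide; the
two top-ranked ones share no PAM-proximal suffix of 8 nt or more with any
other genomic spacer (all profile counts are 1 — only their own occurrence),
so they are the least likely to cut elsewhere. Cas9 guided by the rank-1
spacer cuts between positions 918 and 919. A colony PCR with the two checking
primers yields a 160-nt band if the 600-nt region was deleted and a 760-nt
band from wild-type cells. `write_design_json()` / `write_design_tsv()` save
the full report including cloning primers and an order sheet.

The same design runs from the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "crisprko.R", package="crisprko"))')" \
  design --genome inst/extdata/genome.fa \
  --gff inst/extdata/annotation.gff3 --gene SPNCRNA.01 --out design
```

Subcommands: `design`, `sgrna` (candidate table only), `index build`
(persist the spacer index with a genome checksum), `primers check`
(checking primers only). Every flag can also come from a key=value or YAML
`--config` file.

## Limitations

- Uniqueness and similarity are exact-suffix counts over PAM-adjacent
  spacers: no mismatch/bulge off-target search and no MIT/CFD-style scores.
- The wet-lab protocol around these primers (PCR programs, transformation,
  colony selection) is out of scope.
- Real plasmid cloning requires the user's own plasmid sequence and insertion
  point; the built-in plasmid is a synthetic demo stand-in.
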