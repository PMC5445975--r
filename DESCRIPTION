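Package: crisprko
Title: CRISPR/Cas9 Knockout Design for Fission Yeast: Genome-Unique
    sgRNAs and Seamless-Deletion Primers
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Given a genome and a target region (gene name or coordinates),
    enumerates all Cas9 single-guide RNAs (20-nt spacers next to 5'-NGG-3'
    PAM sites) on both strands, keeps only spacers that are unique among all
    PAM-adjacent spacers genome-wide, and ranks them by a PAM-proximal
    suffix-similarity profile (shared suffixes of 8 to 20 nt, step 2) to
    minimise off-target risk. Designs every primer needed for a seamless
    marker-free deletion: inverse-PCR plasmid cloning primers for the sgRNA
    (ligation and ligation-free methods), 100-nt primers that synthesise a
    160-nt homologous-recombination template from 80-nt flanks, and
    junction-checking primers picked by melting temperature from 250-nt
    flanks with predicted product sizes for deleted and wild-type alleles.
    Includes a seeded synthetic-genome generator and brute-force oracles so
    the whole pipeline is testable without downloads, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    digest,
    optparse,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
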