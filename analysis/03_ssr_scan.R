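#!/usr/bin/env Rscript
# Microsatellite survey of the non-redundant sequences: perfect 1-6 nt
# repeats (>= 12 nt for units 1-3, >= 4 units for 4-6), canonical motif
# classes, length bins and density.

suppressMessages(library(beskit))
nr <- read_fasta("results/nonredundant.fa")
loci <- scan_ssrs(nr)
write.table(loci, "results/ssr_loci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sm <- summarize_ssrs(loci, sum(nchar(nr$sequence)))
print(sm)
write.table(sm$motif_counts, "results/ssr_motif_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# ground truth: how many planted loci survived into the non-redundant set
led <- read.delim("results/ledger_ssrs.tsv")
cat(sprintf("planted motif classes recovered: %d of %d classes present\n",
            length(intersect(loci$canonical_motif, led$canonical_motif)),
            length(unique(led$canonical_motif))))
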