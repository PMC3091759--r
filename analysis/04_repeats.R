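#!/usr/bin/env Rscript
# Repeat summary and masking: classify the planted repeat annotations into
# the TE taxonomy, compute the class ratios, and hard-mask the repeat spans
# of the genome ahead of the homology analyses.

suppressMessages(library(beskit))
led <- read.delim("results/ledger_repeats.tsv")
ann <- led[, c("seq_id", "start", "end", "strand", "family_label",
               "class_label")]
cls <- classify_repeats(ann)
genome <- read_fasta("results/genome.fa")
sm <- summarize_repeats(cls, sum(nchar(genome$sequence)))
print(sm)
write.table(sm$counts, "results/repeat_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

masked <- mask_sequences(genome, cls, mode = "hard")
write_fasta(masked$seqs, "results/genome_masked.fa")
cat(sprintf("masked %d bp (%.1f%% of the genome)\n", masked$masked_bp,
            100 * masked$masked_bp / sum(nchar(genome$sequence))))
cat(sprintf("classification recovered the planted classes: %s\n",
            all(cls$class == led$class) && all(cls$element == led$element)))
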