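#!/usr/bin/env Rscript
# Build the synthetic study system: a genome with planted microsatellites,
# repeat fragments and genes, plus two BAC libraries that mirror the two
# survey designs -- one restriction-biased, one randomly sheared. Writes the
# genome, reads and ground-truth ledgers under results/.

suppressMessages(library(beskit))
dir.create("results", showWarnings = FALSE)

genome <- simulate_genome(
  n_chrom = 2, chrom_len = 150000,
  features = feature_request(n_ssrs = 60, n_repeats = 40, n_genes = 25),
  seed = 1001)
print(genome)
write_fasta(genome$sequences, "results/genome.fa")
write.table(genome$ledger$ssrs, "results/ledger_ssrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(genome$ledger$repeats, "results/ledger_repeats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(genome$ledger$genes, "results/ledger_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# restriction-biased library (BamHI-style boundaries from ledger sites)
bcm <- simulate_library(genome, library_spec(
  n_clones = 120, mean_insert = 13900, insert_sd = 1200,
  method = "restriction", empty_fraction = 0.20, seed = 1002), "BCM")
# random-shear library
rcm <- simulate_library(genome, library_spec(
  n_clones = 160, mean_insert = 12000, insert_sd = 1200,
  method = "random_shear", empty_fraction = 0.23, seed = 1003), "RCM")

for (nm in c("bcm", "rcm")) {
  lib <- get(nm)
  reads <- library_reads(lib)
  write_fasta(reads[, c("id", "sequence")], sprintf("results/%s_reads.fa", nm))
  write.table(lib, sprintf("results/%s_clones.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  st <- total_length_stats(nchar(reads$sequence),
                           genome_mb = sum(nchar(genome$sequences$sequence)) / 1e6)
  cat(sprintf("%s: %d clones, %d reads, mean %.0f bp (range %d-%d)\n",
              toupper(nm), nrow(lib), st$count, st$mean, st$min, st$max))
}
cat("Insert sizes are scaled ~1:10 against a real BAC library so the\n")
cat("150 kb pseudomolecules carry many clones; read geometry is unscaled.\n")
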