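#!/usr/bin/env Rscript
# Stage 5 -- marker-gene abundance.
#
# Downstream count arithmetic on the (already identity-filtered) gene
# count table: length-normalized TPM per representative sequence and the
# phnJ relative abundance as a percentage of genomes, normalizing to the
# single-copy gene recA.

suppressMessages(library(mpnmethane))

counts <- read_gene_counts("results/gene_counts.tsv")
with_tpm <- tpm(counts)
phnj <- phnj_relative_abundance(counts)

write_tsv(with_tpm, "results/genes_tpm.tsv")
write_tsv(data.frame(phnj_percent_of_genomes = phnj),
          "results/genes_phnj.tsv")

top <- with_tpm[order(-with_tpm$tpm), c("gene_id", "gene_family", "tpm")]
cat("TPM total:", round(sum(with_tpm$tpm)), "(by construction 1e6)\n")
cat("top sequences:\n")
print(head(top, 5), row.names = FALSE)
cat(sprintf("phnJ relative abundance: %.2f%% of genomes (recA-normalized)\n",
            phnj))
cat("wrote results/genes_{tpm,phnj}.tsv\n")
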