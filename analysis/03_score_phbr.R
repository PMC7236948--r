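#!/usr/bin/env Rscript
# Step 3: PHBR scoring.
#
# For each mutation, every genotype slot takes its best (minimum) rank
# percentile over the mutation's peptide windows; the six best ranks are
# aggregated by harmonic mean into the PHBR score (homozygous loci count
# twice). Each patient is then summarised by the minimum PHBR across
# mutations -- the best-presented mutation.

suppressPackageStartupMessages(library(phbrtmb))

peptides <- utils::read.delim("results/peptides.tsv", stringsAsFactors = FALSE)
genotypes <- read_genotype_table("results/cohort/genotypes.tsv")
oracle <- load_rank_table("results/cohort/ranks.tsv")

scores <- score_cohort_phbr(peptides, genotypes, oracle)
write_tsv(scores$mutations, "results/phbr_mutations.tsv")
write_tsv(scores$patients, "results/phbr_patients.tsv")

message(sprintf("scored %d mutations across %d patients",
                nrow(scores$mutations), nrow(scores$patients)))
message(sprintf("min-PHBR < 0.5 (strong presentation): %d/%d patients (%.0f%%)",
                sum(scores$patients$min_phbr < 0.5), nrow(scores$patients),
                100 * mean(scores$patients$min_phbr < 0.5)))
message("PHBR tables written to results/phbr_mutations.tsv, results/phbr_patients.tsv")
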