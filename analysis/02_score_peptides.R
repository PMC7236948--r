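#!/usr/bin/env Rscript
# Step 2: map somatic variants to mutant 8-11-mer peptide windows.
#
# Missense mutations substitute one residue and every window covering it is
# kept (38 for an interior site); in-frame indels edit the CDS, the edited
# sequence is re-translated, and only peptides absent from the wild-type
# protein are retained. Unsupported classes (frameshift, splice, ...) are
# counted and set aside, mirroring the analysis exclusions.

suppressPackageStartupMessages(library(phbrtmb))

variants <- read_variant_table("results/cohort/variants.tsv")
transcripts <- read_transcript_fasta("results/cohort/transcripts.fasta")

excl <- attr(variants, "excluded_counts")
message(sprintf("scoreable variants: %d; excluded by class: %s",
                nrow(variants),
                paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))

peptides <- score_variant_peptides(variants, transcripts)
write_tsv(peptides, "results/peptides.tsv")

per_var <- table(paste(peptides$patient_id, peptides$variant))
message(sprintf("%d candidate peptides over %d mutations (median %d windows/mutation)",
                nrow(peptides), length(per_var), stats::median(per_var)))
message("peptide windows written to results/peptides.tsv")
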