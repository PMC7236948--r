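AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# fixed table-backed oracle from parallel vectors
toy_oracle <- function(alleles, peptides, ranks) {
  rank_table_oracle(data.frame(allele = alleles, peptide = peptides,
                               rank_percentile = ranks,
                               stringsAsFactors = FALSE))
}

constant_oracle <- function(r) {
  rank_oracle(function(allele, peptides) rep(r, length(peptides)),
              sprintf("constant %g", r))
}

toy_genotype <- function() {
  hla_genotype(c("A*02:01", "A*01:01", "B*07:02", "B*08:01",
                 "C*07:01", "C*04:01"))
}

random_genotype <- function() {
  pool <- default_allele_pool()
  hla_genotype(unlist(lapply(pool, function(p) sample(p$allele, 2L, replace = TRUE))))
}

random_peptides <- function(n, len = 9L) {
  vapply(seq_len(n), function(i) random_protein(len), character(1L))
}
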