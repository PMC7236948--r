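# Readers and writers for the interchange formats. All tables are
# tab-separated UTF-8 with a header row; '#' comment lines are permitted;
# missing values are empty cells; coordinates are 1-based inclusive.

read_tsv <- function(path, what = "table") {
  if (!file.exists(path)) {
    pkg_error(sprintf("%s not found: %s", what, path), "missing_input")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a transcript FASTA into transcript records
#'
#' Header = transcript id, body = CDS nucleotides.
#'
#' @param path FASTA path.
#' @return Named list of [transcript_record()]s.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) {
    pkg_error(sprintf("transcript FASTA not found: %s", path), "missing_input")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    pkg_error("duplicate transcript id in FASTA", "parse_error")
  }
  recs <- lapply(seq_along(seqs), function(i) {
    transcript_record(ids[i], as.character(seqs[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write transcript records as FASTA
#'
#' @param transcripts Named list of [transcript_record()]s.
#' @param path Output path.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, character(1L), "cds"))
  names(seqs) <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read and validate a variant table
#'
#' Required columns: `patient_id`, `gene`, `transcript_id`,
#' `variant_class`, `protein_change`, `cds_effect`. Rows with variant
#' classes outside {missense, inframe_ins, inframe_del} are not scoreable;
#' they are counted and kept in the `excluded` attribute rather than
#' silently dropped. Missense rows must carry a parseable protein change
#' and indel rows a parseable CDS effect.
#'
#' @param path Table path.
#' @return Data frame of scoreable rows; attributes `excluded` (data
#'   frame) and `excluded_counts` (named integer vector by class).
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv(path, "variant table")
  needed <- c("patient_id", "gene", "transcript_id", "variant_class",
              "protein_change", "cds_effect")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    pkg_error(sprintf("variant table %s: missing column(s) %s", path,
                      paste(missing_cols, collapse = ", ")), "schema_error")
  }
  for (col in c("protein_change", "cds_effect")) {
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  scoreable <- tab$variant_class %in% c("missense", "inframe_ins", "inframe_del")
  excluded <- tab[!scoreable, , drop = FALSE]
  kept <- tab[scoreable, , drop = FALSE]
  for (i in seq_len(nrow(kept))) {
    line <- as.integer(rownames(kept)[i]) + 1L  # +1 for the header line
    if (kept$variant_class[i] == "missense") {
      if (!grepl("^[A-Z][0-9]+[A-Z]$", kept$protein_change[i])) {
        pkg_error(sprintf("variant table %s line %d: bad protein_change '%s'",
                          path, line, kept$protein_change[i]), "row_error")
      }
    } else if (!nzchar(kept$cds_effect[i])) {
      pkg_error(sprintf("variant table %s line %d: indel row without cds_effect",
                        path, line), "row_error")
    }
  }
  attr(kept, "excluded") <- excluded
  attr(kept, "excluded_counts") <- table(excluded$variant_class)
  kept
}

#' Read a patient HLA genotype table
#'
#' Columns `patient_id`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2` (six allele
#' slots at 4-digit resolution; homozygous loci repeat the allele).
#'
#' @param path Table path.
#' @return Named list of [hla_genotype()]s keyed by patient id.
#' @export
read_genotype_table <- function(path) {
  tab <- read_tsv(path, "genotype table")
  needed <- c("patient_id", "A1", "A2", "B1", "B2", "C1", "C2")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    pkg_error(sprintf("genotype table %s: missing column(s) %s", path,
                      paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (anyDuplicated(tab$patient_id)) {
    pkg_error(sprintf("genotype table %s: duplicate patient id %s", path,
                      tab$patient_id[duplicated(tab$patient_id)][1L]),
              "conflict_error")
  }
  slots <- c("A1", "A2", "B1", "B2", "C1", "C2")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    alleles <- unlist(tab[i, slots], use.names = FALSE)
    if (anyNA(alleles)) {
      pkg_error(sprintf("genotype table %s: patient %s has fewer than 6 alleles",
                        path, tab$patient_id[i]), "arity_error")
    }
    tryCatch(hla_genotype(alleles), phbrtmb_error = function(e) {
      pkg_error(sprintf("genotype table %s: patient %s: %s", path,
                        tab$patient_id[i], conditionMessage(e)),
                class(e)[1L])
    })
  })
  names(out) <- tab$patient_id
  out
}

#' Read the clinical outcome table
#'
#' Columns: `patient_id`, `tumor_type`, `sex`, `ethnicity`,
#' `age_at_treatment`, `therapy`, `msi_status`, `tmb`, `response`,
#' `pfs_months`, `pfs_event`, `os_months`, `os_event`,
#' `followup_months`. Missing TMB is an empty cell.
#'
#' @param path Table path.
#' @return Validated data frame.
#' @export
read_clinical_table <- function(path) {
  tab <- read_tsv(path, "clinical table")
  needed <- c("patient_id", "tmb", "response", "pfs_months", "pfs_event",
              "os_months", "os_event")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    pkg_error(sprintf("clinical table %s: missing column(s) %s", path,
                      paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (any(tab$pfs_months < 0 | tab$os_months < 0, na.rm = TRUE)) {
    pkg_error("clinical table: negative follow-up time", "row_error")
  }
  if (any(tab$tmb < 0, na.rm = TRUE)) {
    pkg_error("clinical table: negative TMB", "row_error")
  }
  if (!all(tab$pfs_event %in% 0:1) || !all(tab$os_event %in% 0:1)) {
    pkg_error("clinical table: event flags must be 0/1", "row_error")
  }
  tab
}

#' Write all generated cohort inputs to a directory
#'
#' Emits `transcripts.fasta`, `variants.tsv`, `genotypes.tsv`,
#' `clinical.tsv`, `ranks.tsv` and `ground_truth.tsv` plus a `seed.txt`
#' provenance stamp.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Target directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcript_fasta(cohort$transcripts, file.path(dir, "transcripts.fasta"))
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(cohort$rank_table, file.path(dir, "ranks.tsv"))
  write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  writeLines(sprintf("seed\t%d", cohort$config$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
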