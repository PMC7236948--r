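# Mutant protein construction and 8-11-mer peptide window enumeration.
#
# Coordinates are 1-based and inclusive throughout: protein positions index
# amino acids of the translated CDS, CDS positions index nucleotides.

#' Translate a coding sequence with the standard genetic code
#'
#' Translation proceeds codon by codon and stops at (and excludes) the first
#' stop codon; if the sequence contains no stop codon, all complete codons
#' are translated and any trailing partial codon is ignored.
#'
#' @param cds A single nucleotide string over the alphabet A/C/G/T.
#' @return The amino-acid string (single-letter code, no stop symbol).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  if (!is_scalar_string(cds)) {
    pkg_error("`cds` must be a single nucleotide string", "invalid_sequence")
  }
  cds <- toupper(cds)
  if (nchar(cds) < 3L) {
    pkg_error("CDS shorter than one codon", "invalid_sequence")
  }
  if (grepl("[^ACGT]", cds)) {
    pkg_error("CDS contains a character outside A/C/G/T (ambiguity codes are rejected)",
              "invalid_sequence")
  }
  n_codon <- nchar(cds) %/% 3L
  idx <- seq_len(n_codon)
  codons <- substring(cds, 3L * idx - 2L, 3L * idx)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Transcript record: a CDS and its translation
#'
#' The protein is derived from the CDS at construction time and the CDS is
#' required to be cleanly translatable: any stop codon must be terminal.
#'
#' @param transcript_id Transcript identifier (e.g. an Ensembl transcript id).
#' @param cds Coding nucleotide sequence, A/C/G/T.
#' @return An object of class `transcript_record` with fields
#'   `transcript_id`, `cds` and `protein`.
#' @export
transcript_record <- function(transcript_id, cds) {
  if (!is_scalar_string(transcript_id) || !nzchar(transcript_id)) {
    pkg_error("`transcript_id` must be a nonempty string", "invalid_input")
  }
  protein <- translate_cds(cds)
  cds <- toupper(cds)
  # internal stop check: the first stop codon, if present, must terminate the CDS
  n_codon <- nchar(cds) %/% 3L
  if (nchar(protein) < n_codon - 1L) {
    pkg_error(sprintf("transcript %s: internal stop codon in CDS", transcript_id),
              "invalid_sequence")
  }
  if (nchar(protein) == 0L) {
    pkg_error(sprintf("transcript %s: CDS translates to an empty protein", transcript_id),
              "invalid_sequence")
  }
  structure(list(transcript_id = transcript_id, cds = cds, protein = protein),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s: %d nt CDS, %d aa protein\n",
              x$transcript_id, nchar(x$cds), nchar(x$protein)))
  invisible(x)
}

#' Missense variant
#'
#' @param transcript_id Transcript the protein position refers to.
#' @param protein_position 1-based amino-acid position.
#' @param ref_aa,alt_aa Reference and alternate residues (single letters,
#'   must differ).
#' @export
missense_variant <- function(transcript_id, protein_position, ref_aa, alt_aa) {
  if (!is_scalar_number(protein_position) || protein_position < 1 ||
      protein_position != round(protein_position)) {
    pkg_error("`protein_position` must be a positive integer", "invalid_input")
  }
  if (!is_scalar_string(ref_aa) || nchar(ref_aa) != 1L ||
      !is_scalar_string(alt_aa) || nchar(alt_aa) != 1L) {
    pkg_error("`ref_aa` and `alt_aa` must be single amino-acid letters", "invalid_input")
  }
  if (ref_aa == alt_aa) {
    pkg_error("`ref_aa` and `alt_aa` must differ", "invalid_input")
  }
  structure(list(transcript_id = transcript_id,
                 protein_position = as.integer(protein_position),
                 ref_aa = ref_aa, alt_aa = alt_aa),
            class = "missense_variant")
}

#' In-frame insertion/deletion on the CDS
#'
#' `cds_position` is the first affected base: for a deletion, the first
#' deleted base; for a pure insertion, the base before which the new bases
#' are inserted. The net length change must be a multiple of 3; frameshifts
#' are rejected with an `unsupported_variant` error.
#'
#' @param transcript_id Transcript id.
#' @param cds_position 1-based position of the first affected base.
#' @param deleted Deleted bases (possibly empty). May be left empty with
#'   `deleted_length` set, in which case the bases are taken from the CDS
#'   when the variant is applied (no reference check possible).
#' @param inserted Inserted bases (possibly empty).
#' @param deleted_length Number of deleted bases when `deleted` is not given.
#' @export
inframe_indel <- function(transcript_id, cds_position, deleted = "",
                          inserted = "", deleted_length = nchar(deleted)) {
  if (!is_scalar_number(cds_position) || cds_position < 1) {
    pkg_error("`cds_position` must be a positive integer", "invalid_input")
  }
  if (nzchar(deleted) && grepl("[^ACGT]", toupper(deleted))) {
    pkg_error("`deleted` must be over A/C/G/T", "invalid_input")
  }
  if (nzchar(inserted) && grepl("[^ACGT]", toupper(inserted))) {
    pkg_error("`inserted` must be over A/C/G/T", "invalid_input")
  }
  if (deleted_length == 0L && !nzchar(inserted)) {
    pkg_error("indel with neither inserted nor deleted bases", "invalid_input")
  }
  if ((nchar(inserted) - deleted_length) %% 3L != 0L) {
    pkg_error("frame-shifting edit: |inserted| - |deleted| not divisible by 3",
              "unsupported_variant")
  }
  structure(list(transcript_id = transcript_id,
                 cds_position = as.integer(cds_position),
                 deleted = toupper(deleted), inserted = toupper(inserted),
                 deleted_length = as.integer(deleted_length)),
            class = "inframe_indel")
}

#' Apply a missense variant to a transcript's protein
#'
#' @param t A [transcript_record()] (or a plain protein string).
#' @param v A [missense_variant()].
#' @return The mutant protein string, differing from the wild type at
#'   exactly `v$protein_position`.
#' @export
apply_missense <- function(t, v) {
  protein <- if (inherits(t, "transcript_record")) t$protein else t
  if (!inherits(v, "missense_variant")) {
    pkg_error("`v` must be a missense_variant", "invalid_input")
  }
  pos <- v$protein_position
  if (pos > nchar(protein)) {
    pkg_error(sprintf("protein position %d beyond protein length %d",
                      pos, nchar(protein)), "invalid_input")
  }
  found <- substr(protein, pos, pos)
  if (found != v$ref_aa) {
    pkg_error(sprintf("reference mismatch at position %d: expected %s, CDS translates to %s (stale transcript mapping?)",
                      pos, v$ref_aa, found), "reference_mismatch")
  }
  paste0(substr(protein, 1L, pos - 1L), v$alt_aa,
         substr(protein, pos + 1L, nchar(protein)))
}

#' Apply an in-frame indel to a transcript's CDS and translate
#'
#' The edit is made on the nucleotide sequence and the edited CDS is then
#' translated; translation stops at the first stop codon, so edits that
#' introduce an early stop yield a truncated protein.
#'
#' @param t A [transcript_record()].
#' @param v An [inframe_indel()].
#' @return The mutant protein string.
#' @export
apply_cds_indel <- function(t, v) {
  if (!inherits(t, "transcript_record")) {
    pkg_error("`t` must be a transcript_record", "invalid_input")
  }
  if (!inherits(v, "inframe_indel")) {
    pkg_error("`v` must be an inframe_indel", "invalid_input")
  }
  cds <- t$cds
  pos <- v$cds_position
  del_len <- v$deleted_length
  if (pos + max(del_len - 1L, 0L) > nchar(cds)) {
    pkg_error("indel extends beyond the CDS", "invalid_input")
  }
  if (del_len > 0L) {
    in_cds <- substr(cds, pos, pos + del_len - 1L)
    if (nzchar(v$deleted) && in_cds != v$deleted) {
      pkg_error(sprintf("deleted bases %s do not match CDS (%s) at position %d",
                        v$deleted, in_cds, pos), "reference_mismatch")
    }
  }
  mutant_cds <- paste0(substr(cds, 1L, pos - 1L), v$inserted,
                       substr(cds, pos + del_len, nchar(cds)))
  translate_cds(mutant_cds)
}

#' Enumerate 8-11-mer windows covering mutated residues
#'
#' Returns every window of each requested length that lies fully inside the
#' mutant protein and contains at least one mutated position. For one
#' interior mutation with at least 10 flanking residues on each side this
#' yields exactly 38 windows (8 + 9 + 10 + 11). Near the protein termini
#' fewer windows exist and all valid ones are returned; no padding is
#' fabricated.
#'
#' @param mutant_protein Mutant protein string.
#' @param mutated_positions Integer vector of 1-based mutated positions.
#' @param lengths Window lengths, default `8:11`.
#' @return A data frame with columns `peptide`, `start`, `length`, unique
#'   over (`peptide`, `start`).
#' @export
enumerate_mutant_windows <- function(mutant_protein, mutated_positions,
                                     lengths = 8:11) {
  if (!is_scalar_string(mutant_protein) || !nzchar(mutant_protein)) {
    pkg_error("empty mutant protein", "invalid_input")
  }
  n <- nchar(mutant_protein)
  mutated_positions <- unique(as.integer(mutated_positions))
  if (length(mutated_positions) == 0L ||
      any(mutated_positions < 1L | mutated_positions > n)) {
    pkg_error("mutated positions must be nonempty and within the protein",
              "invalid_input")
  }
  out <- lapply(as.integer(lengths), function(L) {
    if (L > n) return(NULL)
    starts <- seq_len(n - L + 1L)
    keep <- vapply(starts, function(s) {
      any(mutated_positions >= s & mutated_positions <= s + L - 1L)
    }, logical(1L))
    starts <- starts[keep]
    if (!length(starts)) return(NULL)
    data.frame(peptide = substring(mutant_protein, starts, starts + L - 1L),
               start = starts, length = L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(peptide = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  }
  out[!duplicated(out[c("peptide", "start")]), , drop = FALSE]
}

#' Restrict candidate peptides to those absent from the wild-type protein
#'
#' "Novel" means the peptide sequence does not occur anywhere as a substring
#' of the same transcript's wild-type protein (proteome-wide uniqueness is
#' out of scope). Used for indel-derived peptides; missense windows covering
#' the substituted residue are retained without this filter.
#'
#' @param candidates Data frame from [enumerate_mutant_windows()].
#' @param wildtype_protein Wild-type protein string.
#' @export
novel_peptides <- function(candidates, wildtype_protein) {
  if (!nrow(candidates)) return(candidates)
  hit <- vapply(candidates$peptide, function(p) {
    grepl(p, wildtype_protein, fixed = TRUE)
  }, logical(1L), USE.NAMES = FALSE)
  candidates[!hit, , drop = FALSE]
}

#' Positions in the mutant protein altered by an edit
#'
#' Compares wild-type and mutant proteins and returns the mutated span in
#' mutant coordinates: everything between the longest common prefix and the
#' longest common suffix. For a clean deletion whose junction locally
#' recreates wild-type sequence the span can be empty; the junction-flanking
#' positions are returned instead so window enumeration still anchors on the
#' edit (the novelty filter removes any wild-type-identical windows).
#'
#' @param wildtype,mutant Protein strings.
#' @return Integer vector of 1-based positions in `mutant`.
#' @export
mutated_span <- function(wildtype, mutant) {
  la <- nchar(wildtype); lb <- nchar(mutant)
  if (lb == 0L) pkg_error("empty mutant protein", "invalid_input")
  a <- utf8ToInt(wildtype); b <- utf8ToInt(mutant)
  nmin <- min(la, lb)
  pre <- 0L
  while (pre < nmin && a[pre + 1L] == b[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre && a[la - suf] == b[lb - suf]) suf <- suf + 1L
  if (lb - suf >= pre + 1L) {
    seq.int(pre + 1L, lb - suf)
  } else {
    sort(unique(pmin(pmax(c(pre, pre + 1L), 1L), lb)))
  }
}

#' Mutant peptide set for a variant
#'
#' End-to-end per-variant peptide enumeration: applies the variant to the
#' transcript, determines the mutated span, enumerates 8-11-mer windows
#' covering it, and for indels keeps only peptides novel with respect to the
#' wild-type protein.
#'
#' @param t A [transcript_record()].
#' @param v A [missense_variant()] or [inframe_indel()].
#' @param lengths Window lengths, default `8:11`.
#' @return Data frame with columns `peptide`, `start`, `length`.
#' @export
mutant_peptides <- function(t, v, lengths = 8:11) {
  if (inherits(v, "missense_variant")) {
    mut <- apply_missense(t, v)
    enumerate_mutant_windows(mut, v$protein_position, lengths)
  } else if (inherits(v, "inframe_indel")) {
    mut <- apply_cds_indel(t, v)
    span <- mutated_span(t$protein, mut)
    windows <- enumerate_mutant_windows(mut, span, lengths)
    novel_peptides(windows, t$protein)
  } else {
    pkg_error("unsupported variant class (only missense and in-frame indels are scored)",
              "unsupported_variant")
  }
}

#' Parse a protein-change string like "A2V"
#'
#' @param x Protein change in single-letter ref/position/alt form.
#' @return List with `ref_aa`, `protein_position`, `alt_aa`.
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))[[1L]]
  if (length(m) != 4L) {
    pkg_error(sprintf("cannot parse protein change '%s' (expected e.g. 'A2V')", x),
              "parse_error")
  }
  list(ref_aa = m[2L], protein_position = as.integer(m[3L]), alt_aa = m[4L])
}

#' Parse a CDS-effect string like "6_7insGGG" or "4_6del"
#'
#' Insertions are written `<i>_<i+1>ins<bases>` (bases inserted between
#' positions i and i+1); deletions `<i>_<j>del` or `<i>_<j>del<bases>`
#' (bases i..j removed, inclusive), with a single-position form `<i>del`.
#'
#' @param x CDS-effect string.
#' @return List with `cds_position`, `deleted`, `inserted`,
#'   `deleted_length`, suitable for [inframe_indel()].
#' @export
parse_cds_effect <- function(x) {
  ins <- regmatches(x, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", x))[[1L]]
  if (length(ins) == 4L) {
    i <- as.integer(ins[2L]); j <- as.integer(ins[3L])
    if (j != i + 1L) {
      pkg_error(sprintf("insertion '%s': positions must be adjacent", x), "parse_error")
    }
    return(list(cds_position = j, deleted = "", inserted = ins[4L],
                deleted_length = 0L))
  }
  del <- regmatches(x, regexec("^([0-9]+)(_([0-9]+))?del([ACGT]*)$", x))[[1L]]
  if (length(del) == 5L) {
    i <- as.integer(del[2L])
    j <- if (nzchar(del[4L])) as.integer(del[4L]) else i
    if (j < i) pkg_error(sprintf("deletion '%s': end before start", x), "parse_error")
    bases <- del[5L]
    len <- j - i + 1L
    if (nzchar(bases) && nchar(bases) != len) {
      pkg_error(sprintf("deletion '%s': stated bases disagree with the range", x),
                "parse_error")
    }
    return(list(cds_position = i, deleted = bases, inserted = "",
                deleted_length = len))
  }
  pkg_error(sprintf("cannot parse cds effect '%s'", x), "parse_error")
}
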