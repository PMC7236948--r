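# PHBR scoring: per-allele best binding-rank percentiles over a mutation's
# peptide windows, aggregated with a harmonic mean over the patient's six
# HLA class-I allele slots. Low PHBR = good presentation; the conventional
# rank thresholds are < 2 (weak binder) and < 0.5 (strong binder).

RANK_FLOOR <- 1e-6  # ranks are clamped above this before reciprocals

#' Validate an HLA class-I allele name
#'
#' Alleles use 4-digit resolution, e.g. `"A*02:01"`; locus must be A, B or C.
#'
#' @param x Character vector of allele names.
#' @return `x`, invisibly, after validation.
#' @export
validate_hla_allele <- function(x) {
  ok <- grepl("^[ABC]\\*[0-9]{2,3}:[0-9]{2,3}$", x)
  if (!all(ok)) {
    pkg_error(sprintf("malformed HLA allele name(s): %s",
                      paste(x[!ok], collapse = ", ")), "parse_error")
  }
  invisible(x)
}

#' Six-slot HLA class-I genotype
#'
#' Exactly two slots per locus in A, A, B, B, C, C order; homozygous loci
#' repeat the allele, and the repeated allele is counted twice in the PHBR
#' harmonic mean (six slots always).
#'
#' @param alleles Character vector of exactly six allele names.
#' @return Character vector of class `hla_genotype`.
#' @export
hla_genotype <- function(alleles) {
  if (length(alleles) != 6L) {
    pkg_error(sprintf("an HLA genotype has exactly 6 allele slots, got %d",
                      length(alleles)), "arity_error")
  }
  validate_hla_allele(alleles)
  loci <- substr(alleles, 1L, 1L)
  counts <- table(factor(loci, levels = c("A", "B", "C")))
  if (any(counts != 2L)) {
    pkg_error("an HLA genotype needs exactly two alleles per locus (A, B, C)",
              "arity_error")
  }
  structure(alleles[order(loci)], class = "hla_genotype")
}

#' Rank oracle contract
#'
#' A rank oracle maps (allele, peptide) pairs to binding-rank percentiles in
#' (0, 100]. It stands in for an external binding predictor; any
#' deterministic mapping satisfying the contract can be plugged in.
#'
#' @param rank_fun Function `(allele, peptides)` returning one positive rank
#'   per peptide.
#' @param description Short human-readable description.
#' @return An object of class `rank_oracle`.
#' @export
rank_oracle <- function(rank_fun, description = "rank oracle") {
  stopifnot(is.function(rank_fun))
  structure(list(rank_fun = rank_fun, description = description),
            class = "rank_oracle")
}

#' @export
print.rank_oracle <- function(x, ...) {
  cat("<rank_oracle>", x$description, "\n")
  invisible(x)
}

#' Query a rank oracle
#'
#' @param oracle A [rank_oracle()].
#' @param allele Single allele name.
#' @param peptides Character vector of peptides (length 8-11).
#' @return Numeric vector of percentile ranks, one per peptide.
#' @export
oracle_rank <- function(oracle, allele, peptides) {
  if (!inherits(oracle, "rank_oracle")) {
    pkg_error("`oracle` must be a rank_oracle", "invalid_input")
  }
  r <- oracle$rank_fun(allele, peptides)
  if (length(r) != length(peptides) || any(!is.finite(r)) || any(r <= 0)) {
    pkg_error("rank oracle returned a non-positive or non-finite rank",
              "domain_error")
  }
  r
}

# 32-bit FNV-1a over a string, in double arithmetic (no 64-bit integers in
# base R; the multiply is split into 16-bit halves to stay exact).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

#' Deterministic synthetic rank oracle
#'
#' A hash of (seed, allele, peptide) is mapped to a percentile rank such
#' that a configurable fraction of peptides rank below 0.5 (the strong-binder
#' threshold); the remainder are spread over [0.5, 100]. Repeated calls with
#' the same inputs return identical ranks, making the oracle usable as a
#' reproducible stand-in for an external predictor.
#'
#' @param seed Integer seed mixed into the hash.
#' @param strong_binder_fraction Fraction of (allele, peptide) pairs ranked
#'   below 0.5; default 0.1.
#' @param allele_effects Optional named numeric vector of per-allele shifts
#'   added to `strong_binder_fraction` for the named alleles.
#' @return A [rank_oracle()].
#' @export
synthetic_rank_oracle <- function(seed, strong_binder_fraction = 0.1,
                                  allele_effects = NULL) {
  if (!is_scalar_number(strong_binder_fraction) ||
      strong_binder_fraction < 0 || strong_binder_fraction > 1) {
    pkg_error("`strong_binder_fraction` must be in [0, 1]", "domain_error")
  }
  seed <- as.integer(seed)
  force(allele_effects)
  rank_fun <- function(allele, peptides) {
    f <- strong_binder_fraction
    if (!is.null(allele_effects) && allele %in% names(allele_effects)) {
      f <- min(max(f + allele_effects[[allele]], 0), 1)
    }
    vapply(peptides, function(p) {
      u <- (fnv1a32(paste(seed, allele, p, sep = "|")) + 0.5) / 4294967296
      if (u < f) {
        max(0.5 * u / f, RANK_FLOOR)
      } else {
        if (f >= 1) return(0.5 - RANK_FLOOR)
        0.5 + 99.5 * (u - f) / (1 - f)
      }
    }, numeric(1L), USE.NAMES = FALSE)
  }
  rank_oracle(rank_fun,
              sprintf("synthetic hash oracle (seed %d, strong-binder fraction %.3g)",
                      seed, strong_binder_fraction))
}

#' Rank oracle backed by a precomputed rank table
#'
#' @param ranks Data frame with columns `allele`, `peptide`,
#'   `rank_percentile`. Duplicate (allele, peptide) pairs with differing
#'   ranks are rejected as ambiguous; lookups of absent pairs raise a
#'   `missing_prediction` error.
#' @return A [rank_oracle()].
#' @export
rank_table_oracle <- function(ranks) {
  needed <- c("allele", "peptide", "rank_percentile")
  if (!all(needed %in% names(ranks))) {
    pkg_error("rank table needs columns allele, peptide, rank_percentile",
              "parse_error")
  }
  key <- paste(ranks$allele, ranks$peptide, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(ranks$rank_percentile[dup] != ranks$rank_percentile[first])) {
      pkg_error("duplicate (allele, peptide) pairs with differing ranks",
                "parse_error")
    }
    ranks <- ranks[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  if (any(ranks$rank_percentile <= 0)) {
    pkg_error("rank percentiles must be strictly positive", "domain_error")
  }
  lookup <- new.env(parent = emptyenv(), size = nrow(ranks))
  for (i in seq_len(nrow(ranks))) assign(key[i], ranks$rank_percentile[i], lookup)
  rank_fun <- function(allele, peptides) {
    vapply(peptides, function(p) {
      k <- paste(allele, p, sep = "\r")
      if (!exists(k, lookup, inherits = FALSE)) {
        pkg_error(sprintf("no rank prediction for allele %s, peptide %s",
                          allele, p), "missing_prediction")
      }
      get(k, lookup, inherits = FALSE)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  rank_oracle(rank_fun, sprintf("rank table oracle (%d entries)", nrow(ranks)))
}

#' Load a rank table file into an oracle
#'
#' Tab-separated with header columns `allele`, `peptide`,
#' `rank_percentile`; `#` comment lines permitted.
#'
#' @param path Path to the table.
#' @return A [rank_oracle()].
#' @export
load_rank_table <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) pkg_error(sprintf("cannot read rank table %s: %s",
                                          path, conditionMessage(e)), "parse_error"))
  needed <- c("allele", "peptide", "rank_percentile")
  if (!all(needed %in% names(tab))) {
    pkg_error(sprintf("rank table %s: missing column(s) %s", path,
                      paste(setdiff(needed, names(tab)), collapse = ", ")),
              "parse_error")
  }
  if (!is.numeric(tab$rank_percentile)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$rank_percentile))))[1L]
    pkg_error(sprintf("rank table %s: non-numeric rank at data row %d",
                      path, bad), "parse_error")
  }
  rank_table_oracle(tab)
}

#' Best rank of an allele over a peptide set
#'
#' The minimum oracle rank over the unique peptide sequences (identical
#' sequences arising at different starts are scored once), clamped above a
#' small floor before any reciprocal is taken.
#'
#' @param oracle A [rank_oracle()].
#' @param allele Single allele name.
#' @param peptides Character vector of peptides, or a data frame with a
#'   `peptide` column.
#' @return The best (minimum) rank percentile.
#' @export
best_rank <- function(oracle, allele, peptides) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(peptides)
  if (!length(peptides)) {
    pkg_error("empty peptide set", "empty_input")
  }
  max(min(oracle_rank(oracle, allele, peptides)), RANK_FLOOR)
}

#' Harmonic-mean aggregation of six per-allele best ranks
#'
#' PHBR = 6 / sum(1 / BR_i). High values indicate poor presentation.
#'
#' @param best_ranks Numeric vector of exactly six positive best ranks.
#' @return The PHBR score.
#' @export
phbr <- function(best_ranks) {
  if (length(best_ranks) != 6L) {
    pkg_error(sprintf("PHBR aggregates exactly 6 per-allele best ranks, got %d",
                      length(best_ranks)), "arity_error")
  }
  if (any(!is.finite(best_ranks)) || any(best_ranks <= 0)) {
    pkg_error("best ranks must be positive", "domain_error")
  }
  6 / sum(1 / best_ranks)
}

#' PHBR score of one mutation for one patient
#'
#' Composes [best_rank()] per genotype slot and [phbr()]: homozygous loci
#' contribute their allele twice.
#'
#' @param oracle A [rank_oracle()].
#' @param genotype An [hla_genotype()].
#' @param peptides Peptide windows for the mutation ([mutant_peptides()]
#'   output or a character vector).
#' @return Object of class `phbr_score` with fields `value`,
#'   `per_allele_best_ranks` (named by slot) and `n_peptides`.
#' @export
mutation_phbr <- function(oracle, genotype, peptides) {
  if (!inherits(genotype, "hla_genotype")) genotype <- hla_genotype(genotype)
  br <- vapply(unclass(genotype), function(a) best_rank(oracle, a, peptides),
               numeric(1L))
  names(br) <- paste0(c("A1", "A2", "B1", "B2", "C1", "C2"), ":",
                      unclass(genotype))
  n_pep <- if (is.data.frame(peptides)) length(unique(peptides$peptide)) else length(unique(peptides))
  structure(list(value = phbr(br), per_allele_best_ranks = br,
                 n_peptides = n_pep),
            class = "phbr_score")
}

#' @export
print.phbr_score <- function(x, ...) {
  cat(sprintf("<phbr_score> PHBR = %.4g over %d peptides\n", x$value, x$n_peptides))
  invisible(x)
}

#' Patient minimum PHBR across mutations
#'
#' Selects the best-presented mutation: the minimum PHBR value, ties broken
#' by first occurrence in input order. Patients with no scored mutation are
#' not evaluable (they are excluded from the cohort upstream).
#'
#' @param values Numeric vector of PHBR values (or list of `phbr_score`).
#' @param variants Optional vector of variant labels parallel to `values`.
#' @return List with `value`, `index` and `variant`.
#' @export
patient_min_phbr <- function(values, variants = NULL) {
  if (is.list(values) && length(values) && inherits(values[[1L]], "phbr_score")) {
    values <- vapply(values, `[[`, numeric(1L), "value")
  }
  if (!length(values)) {
    pkg_error("patient has no scored mutation: not evaluable for PHBR",
              "patient_not_evaluable")
  }
  i <- which.min(values)  # which.min takes the first of tied minima
  list(value = values[[i]], index = i,
       variant = if (!is.null(variants)) variants[[i]] else NA_character_)
}

#' Binder class of a rank percentile
#'
#' Conventional thresholds: rank < 0.5 strong binder, < 2 weak binder,
#' otherwise non-binder.
#'
#' @param rank Numeric vector of rank percentiles.
#' @return Character vector in {"strong", "weak", "non-binder"}.
#' @export
binder_class <- function(rank) {
  ifelse(rank < 0.5, "strong", ifelse(rank < 2, "weak", "non-binder"))
}
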