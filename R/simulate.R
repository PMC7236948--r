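# Synthetic cohort generator: fully synthetic inputs with the statistical
# structure the analysis assumes (long-tailed panel TMB, six-slot HLA
# genotypes with occasional homozygosity, a rank table inducing a
# configurable fraction of patients with min-PHBR < 0.5, stratum-dependent
# benefit probabilities and survival hazards with administrative
# censoring), plus ground truth for recovery tests.

#' Default HLA class-I allele pool
#'
#' A small pool per locus with frequencies summing to 1. The alleles are
#' common allele names; population-realistic frequencies are a non-goal.
#'
#' @return Named list of data frames (`A`, `B`, `C`) with columns `allele`,
#'   `freq`.
#' @export
default_allele_pool <- function() {
  list(
    A = data.frame(allele = c("A*02:01", "A*01:01", "A*03:01", "A*24:02",
                              "A*11:01", "A*26:01"),
                   freq = c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10)),
    B = data.frame(allele = c("B*07:02", "B*08:01", "B*44:02", "B*35:01",
                              "B*15:01", "B*40:01"),
                   freq = c(0.25, 0.20, 0.20, 0.15, 0.10, 0.10)),
    C = data.frame(allele = c("C*07:01", "C*07:02", "C*04:01", "C*03:04",
                              "C*06:02"),
                   freq = c(0.25, 0.25, 0.20, 0.15, 0.15)))
}

STRATA <- c("TMB-low/PHBR-low", "TMB-low/PHBR-high",
            "TMB-high/PHBR-low", "TMB-high/PHBR-high")

#' Synthetic cohort configuration
#'
#' Defaults mirror the headline shape of an 83-patient pan-cancer
#' checkpoint-blockade cohort: min-PHBR < 0.5 prevalence ~ 32/83, TMB >= 10
#' prevalence ~ half of measured patients, benefit probabilities
#' (0.18, 0.33, 0.78, 0.43) and progression medians (4.2, 3.5, 26.8, 5.8)
#' months for the four TMB/PHBR strata.
#'
#' @param n_patients Cohort size, default 83.
#' @param seed RNG seed used by [generate_cohort()].
#' @param allele_pool Per-locus allele frequencies, see
#'   [default_allele_pool()].
#' @param homozygosity_rate Per-locus probability that the second allele
#'   copies the first (named A/B/C or a single number).
#' @param tmb_meanlog,tmb_sdlog Log-normal parameters of the latent TMB
#'   distribution (mutations/Mb).
#' @param tmb_missing_rate Probability that the reported TMB is missing.
#' @param panel_mb Panel footprint in Mb, default 1.2.
#' @param scored_missense_rate Poisson mean for scored missense mutations
#'   per patient beyond the guaranteed one.
#' @param indel_fraction Fraction of scored mutations that are in-frame
#'   indels rather than missense.
#' @param phbr_low_prevalence Target fraction of patients with
#'   min-PHBR < 0.5, default 32/83.
#' @param benefit_prob Named per-stratum benefit probabilities.
#' @param pfs_median,os_median Named per-stratum survival medians (months)
#'   of the exponential event-time distributions.
#' @param censor_window Administrative censoring drawn uniformly on this
#'   interval (months).
#' @param tmb_threshold,phbr_threshold Dichotomization cutoffs used for the
#'   latent stratum assignment.
#' @param n_transcripts,transcript_len_codons Size of the synthetic
#'   transcript pool and the codon-length range of its CDSs.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 83,
                          seed = 1L,
                          allele_pool = default_allele_pool(),
                          homozygosity_rate = c(A = 0.15, B = 0.10, C = 0.15),
                          tmb_meanlog = 2.3,
                          tmb_sdlog = 1.6,
                          tmb_missing_rate = 6 / 83,
                          panel_mb = 1.2,
                          scored_missense_rate = 2,
                          indel_fraction = 0.05,
                          phbr_low_prevalence = 32 / 83,
                          benefit_prob = c("TMB-low/PHBR-low" = 0.18,
                                           "TMB-low/PHBR-high" = 0.33,
                                           "TMB-high/PHBR-low" = 0.78,
                                           "TMB-high/PHBR-high" = 0.43),
                          pfs_median = c("TMB-low/PHBR-low" = 4.2,
                                         "TMB-low/PHBR-high" = 3.5,
                                         "TMB-high/PHBR-low" = 26.8,
                                         "TMB-high/PHBR-high" = 5.8),
                          os_median = c("TMB-low/PHBR-low" = 12.0,
                                        "TMB-low/PHBR-high" = 10.1,
                                        "TMB-high/PHBR-low" = 40.0,
                                        "TMB-high/PHBR-high" = 17.2),
                          censor_window = c(12, 36),
                          tmb_threshold = 10,
                          phbr_threshold = 0.5,
                          n_transcripts = 20,
                          transcript_len_codons = c(120, 400)) {
  if (length(homozygosity_rate) == 1L) {
    homozygosity_rate <- c(A = homozygosity_rate, B = homozygosity_rate,
                           C = homozygosity_rate)
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              allele_pool = allele_pool, homozygosity_rate = homozygosity_rate,
              tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
              tmb_missing_rate = tmb_missing_rate, panel_mb = panel_mb,
              scored_missense_rate = scored_missense_rate,
              indel_fraction = indel_fraction,
              phbr_low_prevalence = phbr_low_prevalence,
              benefit_prob = benefit_prob, pfs_median = pfs_median,
              os_median = os_median, censor_window = censor_window,
              tmb_threshold = tmb_threshold, phbr_threshold = phbr_threshold,
              n_transcripts = as.integer(n_transcripts),
              transcript_len_codons = as.integer(transcript_len_codons))
  probs <- c(cfg$tmb_missing_rate, cfg$indel_fraction,
             cfg$phbr_low_prevalence, cfg$benefit_prob,
             unname(cfg$homozygosity_rate))
  if (any(probs < 0 | probs > 1)) {
    pkg_error("probabilities must lie in [0, 1]", "config_error")
  }
  if (any(c(cfg$pfs_median, cfg$os_median) <= 0) || cfg$panel_mb <= 0) {
    pkg_error("survival medians and panel footprint must be positive", "config_error")
  }
  if (!setequal(names(cfg$benefit_prob), STRATA) ||
      !setequal(names(cfg$pfs_median), STRATA) ||
      !setequal(names(cfg$os_median), STRATA)) {
    pkg_error("benefit_prob, pfs_median and os_median must be named by the four TMB/PHBR strata",
              "config_error")
  }
  for (loc in c("A", "B", "C")) {
    f <- cfg$allele_pool[[loc]]$freq
    if (!length(f) || abs(sum(f) - 1) > 1e-8) {
      pkg_error(sprintf("allele frequencies at locus %s must sum to 1", loc),
                "config_error")
    }
  }
  structure(cfg, class = "cohort_config")
}

#' Sample one HLA genotype from the configured pool
#'
#' Two draws per locus; with probability `homozygosity_rate` the second
#' draw copies the first. Uses the current RNG state.
#'
#' @param config A [cohort_config()].
#' @return An [hla_genotype()].
#' @export
sample_genotype <- function(config) {
  slots <- unlist(lapply(c("A", "B", "C"), function(loc) {
    pool <- config$allele_pool[[loc]]
    a1 <- sample(pool$allele, 1L, prob = pool$freq)
    a2 <- if (stats::runif(1) < config$homozygosity_rate[[loc]]) a1
          else sample(pool$allele, 1L, prob = pool$freq)
    c(a1, a2)
  }))
  hla_genotype(slots)
}

non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

#' Generate a pool of synthetic transcripts
#'
#' Each CDS starts with ATG, continues with random non-stop codons and ends
#' with a terminal stop codon, so every transcript satisfies the
#' clean-translation invariant.
#'
#' @param config A [cohort_config()].
#' @return Named list of [transcript_record()]s.
#' @export
sample_transcript_pool <- function(config) {
  codons <- non_stop_codons()
  lens <- config$transcript_len_codons
  pool <- lapply(seq_len(config$n_transcripts), function(i) {
    n_codon <- sample(seq(lens[1L], lens[2L]), 1L)
    body <- paste(sample(codons, n_codon - 1L, replace = TRUE), collapse = "")
    transcript_record(sprintf("TX%04d", i), paste0("ATG", body, "TAA"))
  })
  names(pool) <- vapply(pool, `[[`, character(1L), "transcript_id")
  pool
}

AA_LETTERS <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL)

#' Sample the somatic mutations of one patient
#'
#' The panel mutation count is Poisson(tmb x panel_mb). A small subset of
#' mutations is scorable (missense or in-frame indel); the rest are emitted
#' as unsupported classes (frameshift, splice, synonymous), mirroring panel
#' reports in which only part of the alterations can be mapped to peptides.
#' A patient whose count is zero carries no missense mutation and is
#' returned as an empty table (the exclusion rule upstream removes such
#' patients); otherwise at least one missense mutation is guaranteed.
#'
#' @param patient_id Patient identifier.
#' @param tmb Latent TMB in mutations/Mb.
#' @param config A [cohort_config()].
#' @param transcripts Transcript pool from [sample_transcript_pool()].
#' @return Data frame with columns `patient_id`, `gene`, `transcript_id`,
#'   `variant_class`, `protein_change`, `cds_effect`; attribute
#'   `mutation_count` holds the panel count.
#' @export
sample_patient_variants <- function(patient_id, tmb, config, transcripts) {
  count <- stats::rpois(1L, max(tmb, 0) * config$panel_mb)
  empty <- data.frame(patient_id = character(), gene = character(),
                      transcript_id = character(), variant_class = character(),
                      protein_change = character(), cds_effect = character(),
                      stringsAsFactors = FALSE)
  if (count == 0L) {
    attr(empty, "mutation_count") <- 0L
    return(empty)
  }
  n_scored <- min(count, 1L + stats::rpois(1L, config$scored_missense_rate))
  is_indel <- stats::runif(n_scored) < config$indel_fraction
  is_indel[1L] <- FALSE  # guarantee >= 1 missense
  rows <- lapply(seq_len(n_scored), function(k) {
    t <- transcripts[[sample(length(transcripts), 1L)]]
    if (is_indel[k]) {
      # one whole codon inserted or deleted at a codon boundary
      n_codon <- nchar(t$protein)
      codon_i <- sample(2:(n_codon - 1L), 1L)
      if (stats::runif(1) < 0.5) {
        eff <- sprintf("%d_%dins%s", 3L * (codon_i - 1L), 3L * (codon_i - 1L) + 1L,
                       paste(sample(non_stop_codons(), 1L), collapse = ""))
        cls <- "inframe_ins"
      } else {
        eff <- sprintf("%d_%ddel", 3L * (codon_i - 1L) + 1L, 3L * codon_i)
        cls <- "inframe_del"
      }
      data.frame(patient_id = patient_id,
                 gene = sub("TX", "GENE", t$transcript_id),
                 transcript_id = t$transcript_id, variant_class = cls,
                 protein_change = "", cds_effect = eff,
                 stringsAsFactors = FALSE)
    } else {
      pos <- sample(2:(nchar(t$protein) - 1L), 1L)
      ref <- substr(t$protein, pos, pos)
      alt <- sample(setdiff(AA_LETTERS, ref), 1L)
      data.frame(patient_id = patient_id,
                 gene = sub("TX", "GENE", t$transcript_id),
                 transcript_id = t$transcript_id, variant_class = "missense",
                 protein_change = sprintf("%s%d%s", ref, pos, alt),
                 cds_effect = "", stringsAsFactors = FALSE)
    }
  })
  n_other <- count - n_scored
  if (n_other > 0L) {
    other_cls <- sample(c("frameshift", "splice", "synonymous"), n_other,
                        replace = TRUE, prob = c(0.4, 0.2, 0.4))
    tx <- vapply(sample(length(transcripts), n_other, replace = TRUE),
                 function(i) transcripts[[i]]$transcript_id, character(1L))
    rows <- c(rows, list(data.frame(
      patient_id = patient_id, gene = sub("TX", "GENE", tx),
      transcript_id = tx, variant_class = other_cls,
      protein_change = "", cds_effect = "", stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  attr(out, "mutation_count") <- count
  out
}

#' Sample clinical outcomes for given strata
#'
#' Benefit is Bernoulli with the stratum's probability; progression and
#' survival times are exponential with the stratum's median, censored at a
#' uniform administrative time. Benefit and survival are coupled through
#' the stratum only.
#'
#' @param stratum Character/factor vector of the four TMB/PHBR stratum
#'   labels.
#' @param config A [cohort_config()].
#' @return Data frame with `response`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`, `followup_months`.
#' @export
sample_outcomes <- function(stratum, config) {
  stratum <- as.character(stratum)
  if (any(!stratum %in% STRATA)) {
    pkg_error(sprintf("unknown stratum: %s",
                      paste(setdiff(stratum, STRATA), collapse = ", ")),
              "config_error")
  }
  n <- length(stratum)
  benefit <- stats::runif(n) < config$benefit_prob[stratum]
  cens <- stats::runif(n, config$censor_window[1L], config$censor_window[2L])
  pfs_t <- stats::rexp(n, log(2) / config$pfs_median[stratum])
  os_t <- stats::rexp(n, log(2) / config$os_median[stratum])
  response <- ifelse(benefit,
                     sample(c("CR", "PR", "SD>=6mo"), n, replace = TRUE,
                            prob = c(0.05, 0.55, 0.40)),
                     sample(c("PD", "SD<6mo"), n, replace = TRUE,
                            prob = c(0.80, 0.20)))
  # ongoing stable disease that has not yet reached 6 months of follow-up
  response[response == "SD>=6mo" & cens < 6] <- "SD<6mo-ongoing"
  data.frame(response = response,
             pfs_months = pmin(pfs_t, cens),
             pfs_event = as.integer(pfs_t <= cens),
             os_months = pmin(os_t, cens),
             os_event = as.integer(os_t <= cens),
             followup_months = cens,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Produces every input the pipeline consumes - transcript FASTA, variant
#' table, genotype table, clinical table and a rank table - together with
#' the latent ground truth. The rank table is constructed from the latent
#' per-patient PHBR class: for patients latently below the threshold, one
#' mutation receives a strong rank (uniform on 0.1-0.45) for each genotype
#' allele; all other (allele, peptide) pairs rank at or above 0.5, so
#' scoring the emitted inputs end-to-end reproduces the configured
#' min-PHBR < 0.5 prevalence (up to rare peptide collisions between
#' patients). Deterministic per `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory; when given, all tables are written there
#'   in the package's interchange formats.
#' @return List with `variants`, `transcripts`, `genotypes` (data frame),
#'   `clinical`, `rank_table`, `oracle`, `ground_truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  set.seed(config$seed)
  transcripts <- sample_transcript_pool(config)
  n <- config$n_patients
  patients <- sprintf("PT%03d", seq_len(n))

  genotypes <- vector("list", n)
  variant_tabs <- vector("list", n)
  truth <- vector("list", n)
  clin_rows <- vector("list", n)

  i <- 0L
  attempts <- 0L
  while (i < n) {
    attempts <- attempts + 1L
    if (attempts > 50L * n) {
      pkg_error("could not retain enough patients with a missense mutation", "config_error")
    }
    tmb_true <- stats::rlnorm(1L, config$tmb_meanlog, config$tmb_sdlog)
    vt_try <- sample_patient_variants("tmp", tmb_true, config, transcripts)
    if (!nrow(vt_try)) next  # no missense mutation: excluded from the cohort
    i <- i + 1L
    pid <- patients[i]
    vt_try$patient_id <- pid
    variant_tabs[[i]] <- vt_try
    genotypes[[i]] <- sample_genotype(config)

    count <- attr(vt_try, "mutation_count")
    tmb_reported <- tmb_from_panel(count, config$panel_mb)
    if (stats::runif(1) < config$tmb_missing_rate) tmb_reported <- NA_real_
    tmb_class <- dichotomize_tmb(tmb_reported, config$tmb_threshold)
    phbr_low <- stats::runif(1) < config$phbr_low_prevalence
    stratum <- assign_stratum(as.character(tmb_class),
                              if (phbr_low) "low" else "high")
    outcome <- sample_outcomes(as.character(stratum), config)

    clin_rows[[i]] <- data.frame(
      patient_id = pid,
      tumor_type = sample(c("NSCLC", "Cutaneous SCC", "Head and neck SCC", "Other"),
                          1L, prob = c(0.31, 0.12, 0.11, 0.46)),
      sex = sample(c("male", "female"), 1L, prob = c(0.55, 0.45)),
      ethnicity = sample(c("Caucasian", "Other"), 1L, prob = c(0.86, 0.14)),
      age_at_treatment = round(min(max(stats::rnorm(1L, 66, 12), 25), 92)),
      therapy = sample(c("monotherapy", "combination"), 1L, prob = c(0.8, 0.2)),
      msi_status = sample(c("stable", "high", "unknown"), 1L,
                          prob = c(0.8, 0.05, 0.15)),
      tmb = tmb_reported,
      outcome, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = pid, tmb_true = tmb_true, mutation_count = count,
      tmb_reported = tmb_reported, phbr_low = phbr_low,
      tmb_class = as.character(tmb_class), stratum = as.character(stratum),
      p_benefit = unname(config$benefit_prob[as.character(stratum)]),
      pfs_median_true = unname(config$pfs_median[as.character(stratum)]),
      os_median_true = unname(config$os_median[as.character(stratum)]),
      stringsAsFactors = FALSE)
  }

  variants <- do.call(rbind, variant_tabs)
  clinical <- do.call(rbind, clin_rows)
  ground_truth <- do.call(rbind, truth)
  names(genotypes) <- patients
  genotype_tab <- data.frame(patient_id = patients,
                             t(vapply(genotypes, unclass, character(6L))),
                             stringsAsFactors = FALSE, row.names = NULL)
  names(genotype_tab)[-1L] <- c("A1", "A2", "B1", "B2", "C1", "C2")

  rank_table <- build_cohort_rank_table(variants, transcripts, genotypes,
                                        ground_truth$phbr_low)
  list(variants = variants, transcripts = transcripts,
       genotypes = genotype_tab, clinical = clinical,
       rank_table = rank_table, oracle = rank_table_oracle(rank_table),
       ground_truth = ground_truth, config = config) -> out
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# Assign a rank to every (allele, peptide) pair the cohort can query.
# Default ranks are uniform on [0.5, 100]; for each latently PHBR-low
# patient, one peptide of their first scored mutation gets a strong rank
# (uniform 0.1-0.45) under each of their genotype alleles.
build_cohort_rank_table <- function(variants, transcripts, genotypes, phbr_low) {
  patients <- names(genotypes)
  scored <- variants[variants$variant_class %in%
                       c("missense", "inframe_ins", "inframe_del"), , drop = FALSE]
  pep_by_variant <- lapply(seq_len(nrow(scored)), function(k) {
    row <- scored[k, ]
    t <- transcripts[[row$transcript_id]]
    v <- variant_from_row(row)
    unique(mutant_peptides(t, v)$peptide)
  })
  alle <- character(0); pept <- character(0)
  strong_alle <- character(0); strong_pept <- character(0)
  for (j in seq_along(patients)) {
    pid <- patients[j]
    rows_j <- which(scored$patient_id == pid)
    peps_j <- unique(unlist(pep_by_variant[rows_j]))
    alleles_j <- unique(unclass(genotypes[[pid]]))
    alle <- c(alle, rep(alleles_j, each = length(peps_j)))
    pept <- c(pept, rep(peps_j, times = length(alleles_j)))
    if (phbr_low[j]) {
      first_mis <- rows_j[scored$variant_class[rows_j] == "missense"][1L]
      peps_v <- pep_by_variant[[first_mis]]
      chosen <- sample(peps_v, 1L)
      strong_alle <- c(strong_alle, alleles_j)
      strong_pept <- c(strong_pept, rep(chosen, length(alleles_j)))
    }
  }
  key <- paste(alle, pept, sep = "\r")
  keep <- !duplicated(key)
  tab <- data.frame(allele = alle[keep], peptide = pept[keep],
                    rank_percentile = stats::runif(sum(keep), 0.5, 100),
                    stringsAsFactors = FALSE)
  skey <- unique(paste(strong_alle, strong_pept, sep = "\r"))
  hit <- match(skey, paste(tab$allele, tab$peptide, sep = "\r"))
  tab$rank_percentile[hit[!is.na(hit)]] <-
    stats::runif(sum(!is.na(hit)), 0.1, 0.45)
  tab
}

# Build a variant object from one (scored) variant-table row.
variant_from_row <- function(row) {
  if (row$variant_class == "missense") {
    pc <- parse_protein_change(row$protein_change)
    missense_variant(row$transcript_id, pc$protein_position, pc$ref_aa, pc$alt_aa)
  } else if (row$variant_class %in% c("inframe_ins", "inframe_del")) {
    ce <- parse_cds_effect(row$cds_effect)
    inframe_indel(row$transcript_id, ce$cds_position, ce$deleted, ce$inserted,
                  ce$deleted_length)
  } else {
    pkg_error(sprintf("unsupported variant class '%s'", row$variant_class),
              "unsupported_variant")
  }
}

#' Fast stratified survival simulator for statistics checks
#'
#' Generates only what the stratified Cox / log-rank machinery needs:
#' TMB stratum, PHBR class, and an exponential progression time whose
#' hazard within each TMB stratum is multiplied by `hr` for PHBR-low
#' patients, censored at a uniform administrative time. Used for parameter
#' recovery and null-calibration simulations.
#'
#' @param n Number of patients.
#' @param hr True within-stratum hazard ratio of PHBR-low vs PHBR-high.
#' @param baseline_median Named medians (months) of the PHBR-high event
#'   time per TMB stratum, `c(low = ..., high = ...)`.
#' @param p_tmb_high,p_phbr_low Marginal class probabilities.
#' @param censor_window Uniform administrative censoring interval.
#' @return Data frame with `tmb_class`, `phbr_class`, `time`, `event`.
#' @export
simulate_stratified_survival <- function(n, hr = 0.39,
                                         baseline_median = c(low = 4, high = 6),
                                         p_tmb_high = 0.5, p_phbr_low = 0.4,
                                         censor_window = c(12, 36)) {
  tmb_class <- ifelse(stats::runif(n) < p_tmb_high, "high", "low")
  phbr_low <- stats::runif(n) < p_phbr_low
  rate <- log(2) / baseline_median[tmb_class] * ifelse(phbr_low, hr, 1)
  t_event <- stats::rexp(n, rate)
  cens <- stats::runif(n, censor_window[1L], censor_window[2L])
  data.frame(tmb_class = factor(tmb_class, levels = c("low", "high")),
             phbr_class = factor(ifelse(phbr_low, "low", "high"),
                                 levels = c("high", "low")),
             time = pmin(t_event, cens),
             event = as.integer(t_event <= cens))
}
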