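# End-to-end pipeline: variant table -> mutant peptides -> per-mutation
# PHBR -> per-patient min-PHBR -> merged patient records -> outcome
# analysis tables.

#' Enumerate mutant peptides for every scoreable variant
#'
#' @param variants Variant table ([read_variant_table()] output or an
#'   equivalent data frame restricted to missense / in-frame rows).
#' @param transcripts Named list of [transcript_record()]s covering every
#'   transcript id in `variants`.
#' @param lengths Window lengths, default `8:11`.
#' @return Data frame with `patient_id`, `transcript_id`, `variant`,
#'   `peptide`, `start`, `length`.
#' @export
score_variant_peptides <- function(variants, transcripts, lengths = 8:11) {
  missing_tx <- setdiff(unique(variants$transcript_id), names(transcripts))
  if (length(missing_tx)) {
    pkg_error(sprintf("no CDS for transcript(s): %s",
                      paste(missing_tx, collapse = ", ")), "missing_input")
  }
  out <- lapply(seq_len(nrow(variants)), function(k) {
    row <- variants[k, ]
    v <- variant_from_row(row)
    label <- paste0(row$transcript_id, ":",
                    if (nzchar(row$protein_change)) row$protein_change
                    else row$cds_effect)
    pep <- mutant_peptides(transcripts[[row$transcript_id]], v, lengths)
    if (!nrow(pep)) return(NULL)
    data.frame(patient_id = row$patient_id, transcript_id = row$transcript_id,
               variant = label, pep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), transcript_id = character(),
                      variant = character(), peptide = character(),
                      start = integer(), length = integer())
  }
  out
}

#' Score per-mutation PHBR and per-patient minimum PHBR
#'
#' @param peptides Output of [score_variant_peptides()].
#' @param genotypes Named list of [hla_genotype()]s keyed by patient id.
#' @param oracle A [rank_oracle()].
#' @return List with `mutations` (patient_id, variant, phbr, the six
#'   per-slot best ranks, selected_flag) and `patients` (patient_id,
#'   min_phbr, selected_variant, n_mutations).
#' @export
score_cohort_phbr <- function(peptides, genotypes, oracle) {
  miss <- setdiff(unique(peptides$patient_id), names(genotypes))
  if (length(miss)) {
    pkg_error(sprintf("no HLA genotype for patient(s): %s",
                      paste(miss, collapse = ", ")), "missing_input")
  }
  key <- interaction(peptides$patient_id, peptides$variant, drop = TRUE)
  groups <- split(peptides, key)
  mut_rows <- lapply(groups, function(g) {
    score <- mutation_phbr(oracle, genotypes[[g$patient_id[1L]]], g)
    br <- score$per_allele_best_ranks
    data.frame(patient_id = g$patient_id[1L], variant = g$variant[1L],
               phbr = score$value,
               best_rank_A1 = br[[1L]], best_rank_A2 = br[[2L]],
               best_rank_B1 = br[[3L]], best_rank_B2 = br[[4L]],
               best_rank_C1 = br[[5L]], best_rank_C2 = br[[6L]],
               stringsAsFactors = FALSE)
  })
  mutations <- do.call(rbind, c(mut_rows, list(make.row.names = FALSE)))
  # order by patient then first appearance so the documented first-wins tie
  # rule is reproducible from the input order
  mutations <- mutations[order(match(mutations$patient_id, unique(peptides$patient_id)),
                               match(mutations$variant, unique(peptides$variant))), ]
  pat_rows <- lapply(split(mutations, mutations$patient_id), function(m) {
    sel <- patient_min_phbr(m$phbr, m$variant)
    data.frame(patient_id = m$patient_id[1L], min_phbr = sel$value,
               selected_variant = sel$variant, n_mutations = nrow(m),
               stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, c(pat_rows, list(make.row.names = FALSE)))
  mutations$selected_flag <- paste(mutations$patient_id, mutations$variant) %in%
    paste(patients$patient_id, patients$selected_variant)
  list(mutations = mutations, patients = patients)
}

#' Merge clinical data with per-patient PHBR into analysis records
#'
#' Patients without a scored mutation are excluded (mirroring the cohort
#' exclusion rule); derived columns `benefit`, `phbr_class`, `tmb_class`
#' and `stratum` are added using the supplied thresholds.
#'
#' @param clinical Clinical table ([read_clinical_table()] output).
#' @param phbr_patients `patients` element of [score_cohort_phbr()].
#' @param tmb_threshold TMB cutoff (mutations/Mb), default 10.
#' @param phbr_threshold PHBR cutoff, default 0.5.
#' @return Patient-level analysis data frame.
#' @export
build_patient_records <- function(clinical, phbr_patients, tmb_threshold = 10,
                                  phbr_threshold = 0.5) {
  rec <- merge(clinical, phbr_patients, by = "patient_id")
  rec$benefit <- overall_benefit(rec$response, rec$followup_months)
  rec$phbr_class <- dichotomize_phbr(rec$min_phbr, phbr_threshold)
  rec$tmb_class <- dichotomize_tmb(rec$tmb, tmb_threshold)
  rec$stratum <- assign_stratum(rec$tmb_class, rec$phbr_class)
  rec
}

# OBR numerator/denominator: not-evaluable patients leave the denominator.
obr_counts <- function(benefit) {
  evaluable <- benefit != "not_evaluable"
  c(benefit = sum(benefit == "benefit"), evaluable = sum(evaluable))
}

# One association row: 2x2 of exposure vs PHBR class, RR for PHBR < 0.5
# in the exposed group, Fisher p.
phbr_association_row <- function(records, exposed, variable, group_label) {
  low <- records$phbr_class == "low"
  a <- sum(exposed & low); b <- sum(exposed & !low)
  cc <- sum(!exposed & low); d <- sum(!exposed & !low)
  rr <- tryCatch(risk_ratio(a, b, cc, d),
                 phbrtmb_error = function(e) list(rr = NA_real_, ci_low = NA_real_,
                                                  ci_high = NA_real_))
  ft <- fisher_exact(a, b, cc, d)
  data.frame(variable = variable, group = group_label,
             n_exposed = a + b, phbr_low_exposed = a,
             n_reference = cc + d, phbr_low_reference = cc,
             rr = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
             fisher_p = ft$p, stringsAsFactors = FALSE)
}

# PFS/OS medians, unadjusted Cox HR (first level vs second) and log-rank p
# for a two-level split.
two_group_survival <- function(times, events, cls, endpoint) {
  cls <- droplevels(as.factor(cls))
  lv <- levels(cls)
  km <- lapply(lv, function(l) km_fit(times[cls == l], events[cls == l]))
  names(km) <- lv
  lr <- log_rank(times, events, cls)
  data.frame(endpoint = endpoint,
             group = paste(lv[1L], "vs", lv[2L]),
             median_1 = km[[1L]]$median, median_2 = km[[2L]]$median,
             median_followup_1 = km[[1L]]$median_followup,
             median_followup_2 = km[[2L]]$median_followup,
             hr = 1 / lr$hr, hr_ci_low = 1 / lr$hr_ci_high,
             hr_ci_high = 1 / lr$hr_ci_low, logrank_p = lr$p,
             stringsAsFactors = FALSE)
}

#' Outcome analysis of a scored cohort
#'
#' Produces the analysis tables the scored cohort supports: PHBR-class
#' association rows (risk ratios with Wald CIs and Fisher p), univariate
#' outcome comparisons (overall-benefit rate, Kaplan-Meier medians,
#' unadjusted hazard ratios, log-rank p) for the PHBR and TMB
#' dichotomizations, pairwise comparisons of the four TMB x PHBR strata,
#' the TMB-stratified Cox model quantifying the PHBR effect on
#' progression, and the Spearman correlation between (pseudocounted) TMB
#' and min-PHBR.
#'
#' @param records Output of [build_patient_records()].
#' @param tmb_threshold TMB cutoff used for strata, default 10.
#' @return List of tables; see details.
#' @export
analyze_cohort <- function(records, tmb_threshold = 10) {
  records$tmb_class <- dichotomize_tmb(records$tmb, tmb_threshold)
  records$stratum <- assign_stratum(records$tmb_class, records$phbr_class)
  ev <- records[records$benefit != "not_evaluable", ]

  assoc <- rbind(
    phbr_association_row(records, records$sex == "male", "sex", "male vs female"),
    phbr_association_row(records, records$ethnicity == "Caucasian",
                         "ethnicity", "Caucasian vs others"),
    phbr_association_row(records, records$therapy == "monotherapy",
                         "therapy", "monotherapy vs combination"),
    phbr_association_row(records, as.character(records$tmb_class) == "low",
                         sprintf("TMB (cutoff %g)", tmb_threshold),
                         sprintf("< %g vs >= %g", tmb_threshold, tmb_threshold)),
    phbr_association_row(ev, ev$benefit == "benefit", "overall benefit",
                         "SD>=6mo/PR/CR vs others"),
    phbr_association_row(ev, ev$response == "PD", "progressive disease",
                         "PD vs others"))

  obr_row <- function(dat, cls, variable) {
    cls <- droplevels(as.factor(cls))
    lv <- levels(cls)
    n1 <- obr_counts(dat$benefit[cls == lv[1L]])
    n2 <- obr_counts(dat$benefit[cls == lv[2L]])
    ft <- fisher_exact(n1["benefit"], n1["evaluable"] - n1["benefit"],
                       n2["benefit"], n2["evaluable"] - n2["benefit"])
    data.frame(variable = variable, group = paste(lv[1L], "vs", lv[2L]),
               obr_1 = unname(n1["benefit"] / n1["evaluable"]),
               obr_2 = unname(n2["benefit"] / n2["evaluable"]),
               fisher_p = ft$p, stringsAsFactors = FALSE)
  }
  univariate <- list(
    obr = rbind(obr_row(ev, ev$phbr_class, "PHBR"),
                obr_row(ev, ev$tmb_class, "TMB")),
    pfs = rbind(
      cbind(variable = "PHBR",
            two_group_survival(records$pfs_months, records$pfs_event,
                               records$phbr_class, "PFS")),
      cbind(variable = "TMB",
            two_group_survival(records$pfs_months, records$pfs_event,
                               records$tmb_class, "PFS"))),
    os = rbind(
      cbind(variable = "PHBR",
            two_group_survival(records$os_months, records$os_event,
                               records$phbr_class, "OS")),
      cbind(variable = "TMB",
            two_group_survival(records$os_months, records$os_event,
                               records$tmb_class, "OS"))))

  # four-stratum comparison (overall log-rank) and all pairwise contrasts
  four_way <- list(
    pfs = log_rank(records$pfs_months, records$pfs_event, records$stratum),
    os = log_rank(records$os_months, records$os_event, records$stratum))
  pairs <- utils::combn(levels(records$stratum), 2L, simplify = FALSE)
  stratum_pairs <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- records$stratum %in% pr
    dat <- records[sel, ]
    dat$stratum <- droplevels(dat$stratum)
    evd <- dat[dat$benefit != "not_evaluable", ]
    n1 <- obr_counts(evd$benefit[evd$stratum == pr[1L]])
    n2 <- obr_counts(evd$benefit[evd$stratum == pr[2L]])
    ft <- fisher_exact(n1["benefit"], n1["evaluable"] - n1["benefit"],
                       n2["benefit"], n2["evaluable"] - n2["benefit"])
    pfs <- two_group_survival(dat$pfs_months, dat$pfs_event, dat$stratum, "PFS")
    os <- two_group_survival(dat$os_months, dat$os_event, dat$stratum, "OS")
    data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
               n_1 = sum(dat$stratum == pr[1L]), n_2 = sum(dat$stratum == pr[2L]),
               obr_1 = unname(n1["benefit"] / max(n1["evaluable"], 1L)),
               obr_2 = unname(n2["benefit"] / max(n2["evaluable"], 1L)),
               obr_fisher_p = ft$p,
               pfs_median_1 = pfs$median_1, pfs_median_2 = pfs$median_2,
               pfs_hr = pfs$hr, pfs_logrank_p = pfs$logrank_p,
               os_median_1 = os$median_1, os_median_2 = os$median_2,
               os_hr = os$hr, os_logrank_p = os$logrank_p,
               stringsAsFactors = FALSE)
  }))

  # PHBR effect on PFS with a separate baseline hazard per TMB stratum
  strat_cox <- cox_ph(records$pfs_months, records$pfs_event,
                      data.frame(phbr_low = records$phbr_class == "low"),
                      strata = records$tmb_class)
  within <- lapply(split(records, records$tmb_class), function(d) {
    if (sum(d$pfs_event) == 0L || length(unique(d$phbr_class)) < 2L) return(NULL)
    cox_ph(d$pfs_months, d$pfs_event,
           data.frame(phbr_low = d$phbr_class == "low"))$coefficients
  })

  sp <- spearman_cor(add_pseudocount(records$tmb[!is.na(records$tmb)]),
                     records$min_phbr[!is.na(records$tmb)])

  list(n = nrow(records), association = assoc, univariate = univariate,
       four_way = four_way, stratum_pairs = stratum_pairs,
       stratified_cox = strat_cox$coefficients,
       within_stratum_cox = within,
       spearman_tmb_phbr = sp,
       tmb_threshold = tmb_threshold)
}

#' Write analysis tables to a directory
#'
#' @param analysis Output of [analyze_cohort()].
#' @param dir Target directory.
#' @export
write_analysis_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(analysis$association, file.path(dir, "association.tsv"))
  write_tsv(analysis$univariate$obr, file.path(dir, "univariate_obr.tsv"))
  write_tsv(rbind(analysis$univariate$pfs, analysis$univariate$os),
            file.path(dir, "univariate_survival.tsv"))
  write_tsv(analysis$stratum_pairs, file.path(dir, "stratum_comparisons.tsv"))
  write_tsv(analysis$stratified_cox, file.path(dir, "stratified_cox.tsv"))
  invisible(dir)
}
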