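member_class_masks <- function(members) {
  list(all = rep(TRUE, nrow(members)),
       anthracycline = members$anthracycline,
       her2 = members$her2,
       neither = !members$anthracycline & !members$her2)
}

#' LVEF assessment summary by exposure class
#'
#' Counts and rates of pre- and post-treatment LVEF assessment for the whole
#' cohort and for the anthracycline, HER2-antibody and neither strata (the
#' surveillance-pattern figure of a cardio-oncology registry).
#'
#' @param members Phenotyped member tibble from [phenotype_cohort()].
#' @param decimals Display rounding for the rate columns (half-up).
#' @return A tibble: `class`, `n`, `pre_n`, `pre_pct`, `post_n`, `post_pct`.
#' @export
assessment_summary <- function(members, decimals = 2) {
  masks <- member_class_masks(members)
  dplyr::bind_rows(lapply(names(masks), function(cl) {
    m <- members[masks[[cl]], , drop = FALSE]
    n <- nrow(m)
    tibble::tibble(
      class = cl, n = n,
      pre_n = sum(m$pre_assessed),
      pre_pct = if (n > 0) proportion_pct(sum(m$pre_assessed), n, decimals) else NA_real_,
      post_n = sum(m$post_assessed),
      post_pct = if (n > 0) proportion_pct(sum(m$post_assessed), n, decimals) else NA_real_
    )
  }))
}

#' Post-treatment cardiomyopathy prevalence by exposure class
#'
#' LVD prevalence among post-assessed members (only screened patients are at
#' risk of an LVEF-based diagnosis) and Problem-List HFrEF prevalence among
#' all members, for the whole cohort and the anthracycline / HER2 / neither
#' strata.
#'
#' @param members Phenotyped member tibble from [phenotype_cohort()].
#' @param decimals Display rounding (half-up).
#' @return A tibble: `class`, `lvef_assessed_n`, `lvd_n`, `lvd_pct`,
#'   `documented_n`, `hfref_n`, `hfref_pct`.
#' @export
prevalence_table <- function(members, decimals = 1) {
  masks <- member_class_masks(members)
  dplyr::bind_rows(lapply(names(masks), function(cl) {
    m <- members[masks[[cl]], , drop = FALSE]
    at_risk <- sum(m$post_assessed)
    tibble::tibble(
      class = cl,
      lvef_assessed_n = at_risk,
      lvd_n = sum(m$lvd),
      lvd_pct = if (at_risk > 0) proportion_pct(sum(m$lvd), at_risk, decimals) else NA_real_,
      documented_n = nrow(m),
      hfref_n = sum(m$hfref),
      hfref_pct = if (nrow(m) > 0) proportion_pct(sum(m$hfref), nrow(m), decimals) else NA_real_
    )
  }))
}

#' Care-gap report
#'
#' Actionable gaps in guideline-directed care: members with no baseline
#' (pre-treatment) LVEF assessment; outcome patients (post-treatment LVD or
#' HFrEF) without an active prescription in each GDMT class; and GDMT
#' prescription rates stratified by cardiology referral, with a chi-squared
#' comparison per drug class (continuity correction off).
#'
#' @param members Phenotyped member tibble from [phenotype_cohort()].
#' @return An object of class `care_gap_report`: `missing_baseline_lvef`
#'   (ids), `outcome_patients` (ids), `off_gdmt` (named list of id vectors
#'   per drug class), and `referral_stratified_gdmt` (tibble: `drug_class`,
#'   `n_referred`, `on_gdmt_referred`, `rate_referred`, `n_not_referred`,
#'   `on_gdmt_not_referred`, `rate_not_referred`, `p_value`).
#' @export
care_gap_report <- function(members) {
  outcome <- members$lvd | members$hfref
  out_m <- members[outcome, , drop = FALSE]
  classes <- c(beta_blocker = "beta_blocker", acei_or_arb = "acei_or_arb",
               mra = "mra")
  off_gdmt <- lapply(classes, function(cl) out_m$patient_id[!out_m[[cl]]])

  strat <- dplyr::bind_rows(lapply(names(classes), function(cl) {
    on_drug <- out_m[[cl]]
    ref <- out_m$referred
    n_ref <- sum(ref)
    n_not <- sum(!ref)
    p <- if (n_ref > 0 && n_not > 0 && (sum(on_drug) > 0 && sum(!on_drug) > 0)) {
      chisq_2x2(matrix(c(sum(on_drug & ref), sum(!on_drug & ref),
                         sum(on_drug & !ref), sum(!on_drug & !ref)),
                       nrow = 2, byrow = TRUE))$p_value
    } else NA_real_
    tibble::tibble(
      drug_class = cl,
      n_referred = n_ref,
      on_gdmt_referred = sum(on_drug & ref),
      rate_referred = if (n_ref > 0) proportion_pct(sum(on_drug & ref), n_ref, 1) else NA_real_,
      n_not_referred = n_not,
      on_gdmt_not_referred = sum(on_drug & !ref),
      rate_not_referred = if (n_not > 0) proportion_pct(sum(on_drug & !ref), n_not, 1) else NA_real_,
      p_value = p
    )
  }))

  structure(list(
    missing_baseline_lvef = members$patient_id[!members$pre_assessed],
    outcome_patients = out_m$patient_id,
    n_referred = sum(out_m$referred),
    referred_pct = if (nrow(out_m) > 0)
      proportion_pct(sum(out_m$referred), nrow(out_m), 1) else NA_real_,
    off_gdmt = off_gdmt,
    referral_stratified_gdmt = strat
  ), class = "care_gap_report")
}

#' @export
print.care_gap_report <- function(x, ...) {
  cat("<care_gap_report>\n",
      "  missing baseline LVEF : ", length(x$missing_baseline_lvef), " patients\n",
      "  outcome patients      : ", length(x$outcome_patients),
      " (", x$n_referred, " referred to cardiology, ", x$referred_pct, "%)\n",
      sep = "")
  print(x$referral_stratified_gdmt)
  invisible(x)
}

#' Write a care-gap report to JSON and Markdown
#'
#' @param report A [care_gap_report()].
#' @param json_path Output path for the machine-readable JSON; `NULL` to
#'   skip.
#' @param md_path Output path for the human-readable Markdown; `NULL` to
#'   skip.
#' @return The report, invisibly.
#' @export
write_care_gap_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "care_gap_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(md_path)) {
    s <- report$referral_stratified_gdmt
    lines <- c(
      "# Care-gap report", "",
      sprintf("- Members without baseline LVEF assessment: %d",
              length(report$missing_baseline_lvef)),
      sprintf("- Post-treatment LVD/HFrEF patients: %d (%s%% referred to cardiology)",
              length(report$outcome_patients), report$referred_pct),
      "", "| GDMT class | referred n | referred on-GDMT (%) | not referred n | not referred on-GDMT (%) | p |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %d | %d (%s) | %d | %d (%s) | %s |",
              s$drug_class, s$n_referred, s$on_gdmt_referred, s$rate_referred,
              s$n_not_referred, s$on_gdmt_not_referred, s$rate_not_referred,
              ifelse(is.na(s$p_value), "NA", formatC(s$p_value, format = "g", digits = 3)))
    )
    writeLines(lines, md_path)
  }
  invisible(report)
}
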