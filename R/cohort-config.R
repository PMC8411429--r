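#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published structure of an institutional
#' cardio-oncology registry (N = 8275 treated cancer patients, 2011-2017):
#' exposure mix, per-class pre/post LVEF screening probabilities, per-class
#' LVD risk among the screened and HFrEF prevalence, the imperfect
#' Problem-List documentation channel for HFrEF (sensitivity 0.953,
#' specificity 0.835), baseline cardiac dysfunction prior to treatment
#' (372/8275), cardiology referral among outcome patients (0.639), and
#' referral-stratified GDMT prescription probabilities. Exposure classes are
#' `anthracycline`, `her2` (HER2 antibodies), `tki` (tyrosine kinase
#' inhibitors), `ici` (immune checkpoint inhibitors) and `other`; per-class
#' probability vectors must be named with exactly these classes.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Integer seed; together with the config it fully determines
#'   the generated dataset.
#' @param treatment_window Length-2 Date vector, closed interval for episode
#'   start dates.
#' @param exposure_probs Named probabilities of each (mutually exclusive)
#'   treatment class; must sum to 1.
#' @param pre_screen_prob,post_screen_prob Named per-class probabilities of
#'   a pre-treatment / post-treatment LVEF assessment.
#' @param lvd_risk Named per-class probability of true post-treatment LVD
#'   given a post-treatment assessment.
#' @param hfref_prev Named per-class probability of true post-treatment
#'   HFrEF.
#' @param baseline_dysfunction_prob Probability of cardiac dysfunction
#'   predating treatment (these patients are the registry's baseline
#'   exclusions).
#' @param hfref_doc_sensitivity,hfref_doc_specificity The Bernoulli
#'   documentation channel: probability a true HFrEF patient carries a
#'   qualifying Problem-List entry, and probability a non-HFrEF patient does
#'   not.
#' @param referral_prob_given_outcome,referral_prob_no_outcome Probability
#'   of a cardiology referral for patients with / without a detected
#'   post-treatment outcome.
#' @param gdmt_probs 3 x 2 numeric matrix, rows `beta_blocker`, `acei_arb`,
#'   `mra`, columns `referred`, `not_referred`: probability an outcome
#'   patient has an active prescription of that class.
#' @param cancer_prob Probability a simulated patient truly has cancer (the
#'   registry context implies 1; lower it to exercise the population
#'   filter).
#' @param female_frac,alive_frac,age_median,age_sd,htn_prob,dm_prob
#'   Demographic targets.
#' @param lvef_lvd_mean,lvef_lvd_sd,lvef_normal_mean,lvef_normal_sd LVEF
#'   generating distributions (truncated normal, %): below-50 regime for
#'   true LVD, at-or-above-50 regime otherwise, clipped to \[5, 80\].
#' @param extraction_date Date the active medication list and demographics
#'   are "as of".
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 8275,
    seed = 1L,
    treatment_window = as.Date(c("2011-01-01", "2017-06-30")),
    exposure_probs = c(anthracycline = 0.1778, her2 = 0.0495,
                       tki = 0.0882, ici = 0.0031, other = 0.6814),
    pre_screen_prob = c(anthracycline = 0.2588, her2 = 0.2780,
                        tki = 0.1785, ici = 0.1785, other = 0.1785),
    post_screen_prob = c(anthracycline = 0.691, her2 = 0.851,
                         tki = 0.320, ici = 0.320, other = 0.320),
    lvd_risk = c(anthracycline = 0.042, her2 = 0.049,
                 tki = 0.126, ici = 0.126, other = 0.126),
    hfref_prev = c(anthracycline = 0.0357, her2 = 0.0902,
                   tki = 0.0198, ici = 0.0198, other = 0.0198),
    baseline_dysfunction_prob = 372 / 8275,
    hfref_doc_sensitivity = 0.953,
    hfref_doc_specificity = 0.835,
    referral_prob_given_outcome = 0.639,
    referral_prob_no_outcome = 0.02,
    gdmt_probs = matrix(c(0.441, 0.188,
                          0.474, 0.306,
                          0.118, 0.024),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("beta_blocker", "acei_arb", "mra"),
                                        c("referred", "not_referred"))),
    cancer_prob = 1,
    female_frac = 0.5457,
    alive_frac = 0.6738,
    age_median = 63,
    age_sd = 14,
    htn_prob = 0.258,
    dm_prob = 0.1524,
    lvef_lvd_mean = 40, lvef_lvd_sd = 6,
    lvef_normal_mean = 60, lvef_normal_sd = 5,
    extraction_date = as.Date("2018-01-01")) {

  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    treatment_window = as.Date(treatment_window),
    exposure_probs = exposure_probs,
    pre_screen_prob = per_class(pre_screen_prob),
    post_screen_prob = per_class(post_screen_prob),
    lvd_risk = per_class(lvd_risk),
    hfref_prev = per_class(hfref_prev),
    baseline_dysfunction_prob = baseline_dysfunction_prob,
    hfref_doc_sensitivity = hfref_doc_sensitivity,
    hfref_doc_specificity = hfref_doc_specificity,
    referral_prob_given_outcome = referral_prob_given_outcome,
    referral_prob_no_outcome = referral_prob_no_outcome,
    gdmt_probs = gdmt_probs,
    cancer_prob = cancer_prob,
    female_frac = female_frac, alive_frac = alive_frac,
    age_median = age_median, age_sd = age_sd,
    htn_prob = htn_prob, dm_prob = dm_prob,
    lvef_lvd_mean = lvef_lvd_mean, lvef_lvd_sd = lvef_lvd_sd,
    lvef_normal_mean = lvef_normal_mean, lvef_normal_sd = lvef_normal_sd,
    extraction_date = as.Date(extraction_date)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

exposure_classes <- c("anthracycline", "her2", "tki", "ici", "other")

# recycle a scalar probability across the five exposure classes
per_class <- function(p) {
  if (length(p) == 1 && is.null(names(p))) {
    p <- stats::setNames(rep(p, length(exposure_classes)), exposure_classes)
  }
  p
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  if (cfg$treatment_window[1] >= cfg$treatment_window[2]) {
    stop("treatment window start must precede its end", call. = FALSE)
  }
  probs <- c(cfg$exposure_probs, cfg$pre_screen_prob, cfg$post_screen_prob,
             cfg$lvd_risk, cfg$hfref_prev, cfg$baseline_dysfunction_prob,
             cfg$hfref_doc_sensitivity, cfg$hfref_doc_specificity,
             cfg$referral_prob_given_outcome, cfg$referral_prob_no_outcome,
             as.vector(cfg$gdmt_probs), cfg$cancer_prob,
             cfg$female_frac, cfg$alive_frac, cfg$htn_prob, cfg$dm_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$exposure_probs) - 1) > 1e-8) {
    stop("exposure_probs must sum to 1", call. = FALSE)
  }
  for (nm in c("pre_screen_prob", "post_screen_prob", "lvd_risk", "hfref_prev")) {
    if (!setequal(names(cfg[[nm]]), exposure_classes)) {
      stop(nm, " must be named with the exposure classes: ",
           paste(exposure_classes, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_patients, " seed =", x$seed, "\n")
  cat("  window:", format(x$treatment_window[1]), "to",
      format(x$treatment_window[2]), "\n")
  cat("  exposure:", paste(sprintf("%s %.4f", names(x$exposure_probs),
                                   x$exposure_probs), collapse = ", "), "\n")
  invisible(x)
}
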