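#' Bundle EHR-style tables into a dataset
#'
#' Validates referential integrity (every patient id referenced by a child
#' table exists in `patients`) and LVEF plausibility bounds, then returns an
#' `ehr_dataset`: the record bundle every downstream stage (cohort
#' construction, phenotyping, reporting) consumes.
#'
#' @param patients Tibble: `patient_id`, `birth_date`, `sex`, `vital_status`.
#' @param problem_list Tibble: `patient_id`, `code`, `onset_date`.
#' @param treatment_episodes Tibble: `patient_id`, `drug_name`, `drug_class`,
#'   `start_date`.
#' @param imaging_studies Tibble: `patient_id`, `modality` (one of `echo`,
#'   `muga`, `cardiac_mri`), `study_date`, `lvef` (percent, in \[5, 80\]).
#' @param medication_orders Tibble: `patient_id`, `drug_name`,
#'   `pharmaceutical_class`, `pharmaceutical_subclass`, `active`,
#'   `as_of_date`.
#' @param referrals Tibble: `patient_id`, `specialty`, `referral_date`.
#' @return An object of class `ehr_dataset` (a named list of tibbles).
#' @export
ehr_dataset <- function(patients, problem_list, treatment_episodes,
                        imaging_studies, medication_orders, referrals) {
  d <- list(patients = tibble::as_tibble(patients),
            problem_list = tibble::as_tibble(problem_list),
            treatment_episodes = tibble::as_tibble(treatment_episodes),
            imaging_studies = tibble::as_tibble(imaging_studies),
            medication_orders = tibble::as_tibble(medication_orders),
            referrals = tibble::as_tibble(referrals))
  for (nm in setdiff(names(d), "patients")) {
    orphans <- setdiff(d[[nm]]$patient_id, d$patients$patient_id)
    if (length(orphans) > 0) {
      stop("table '", nm, "' references unknown patient id(s): ",
           paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
    }
  }
  lvef <- d$imaging_studies$lvef
  if (length(lvef) > 0 && (any(lvef < 5) || any(lvef > 80))) {
    stop("imaging LVEF values must lie in [5, 80]", call. = FALSE)
  }
  structure(d, class = "ehr_dataset")
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

rbern <- function(n, p) stats::runif(n) < p

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates an EHR extract with the statistical structure configured in
#' [cohort_config()]: coded cancer diagnoses on the Problem List, one
#' treatment episode per patient with an exposure class, pre/post-treatment
#' LVEF imaging with class-specific screening probabilities, true
#' post-treatment LVD expressed as a below-50 LVEF, true HFrEF pushed
#' through a noisy Problem-List documentation channel (configured
#' sensitivity/specificity), pre-treatment cardiac dysfunction for the
#' baseline-exclusion arm, cardiology referrals concentrated in outcome
#' patients, and referral-stratified GDMT prescriptions on the active
#' medication list. The result is fully determined by `(config, seed)`; the
#' caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `dataset` (an [ehr_dataset()]) and `truth`
#'   (one row per patient: `true_cancer`, `exposure_class`,
#'   `baseline_dysfunction`, `pre_assessed`, `post_assessed`, `true_lvd`,
#'   `true_hfref`, `hfref_documented`, `referred`, `gdmt_beta_blocker`,
#'   `gdmt_acei_arb`, `gdmt_mra`).
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 200, seed = 42))
#' sim$dataset
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  window <- config$treatment_window

  # --- demographics -------------------------------------------------------
  age <- rtrunc_norm(n, config$age_median, config$age_sd, 18, 95)
  birth_date <- config$extraction_date - round(age * 365.25)
  sex <- ifelse(rbern(n, config$female_frac), "F", "M")
  vital <- ifelse(rbern(n, config$alive_frac), "alive", "deceased")
  patients <- tibble::tibble(patient_id = ids, birth_date = birth_date,
                             sex = sex, vital_status = vital)

  # --- cancer status and treatment episode -------------------------------
  true_cancer <- rbern(n, config$cancer_prob)
  exposure_class <- sample(exposure_classes, n, replace = TRUE,
                           prob = config$exposure_probs)
  exposure_class[!true_cancer] <- NA_character_
  treated <- true_cancer  # registry context: every cancer patient has an episode

  span <- as.integer(window[2] - window[1])
  exposure_date <- window[1] + floor(stats::runif(n, 0, span + 1))
  exposure_date[!treated] <- as.Date(NA)

  drug_for_class <- c(anthracycline = "Doxorubicin", her2 = "Trastuzumab",
                      tki = "Imatinib", ici = "Pembrolizumab",
                      other = "Paclitaxel")
  treatment_episodes <- tibble::tibble(
    patient_id = ids[treated],
    drug_name = unname(drug_for_class[exposure_class[treated]]),
    drug_class = exposure_class[treated],
    start_date = exposure_date[treated]
  )

  # --- problem list: cancer, comorbidities, decoys ------------------------
  cancer_codes <- c("254837009", "363358000", "93143009", "118600007",
                    "702391001", "363406005", "93727008", "92695006",
                    "99741000119100")
  cancer_wts <- c(0.35, 0.12, 0.12, 0.12, 0.08, 0.08, 0.05, 0.04, 0.04)
  n_cancer <- sum(true_cancer)
  pl <- list(tibble::tibble(
    patient_id = ids[true_cancer],
    code = sample(cancer_codes, n_cancer, replace = TRUE, prob = cancer_wts),
    onset_date = exposure_date[true_cancer] - floor(stats::runif(n_cancer, 10, 400))
  ))
  # non-cancer patients may still carry codes the exclusion bracket removes
  decoy <- !true_cancer & rbern(n, 0.6)
  if (any(decoy)) {
    pl <- c(pl, list(tibble::tibble(
      patient_id = ids[decoy],
      code = sample(c("92030004", "92186001", "275937001", "418304008"),
                    sum(decoy), replace = TRUE),
      onset_date = window[1] + floor(stats::runif(sum(decoy), 0, span))
    )))
  }
  for (com in list(c("38341003", "htn_prob"), c("73211009", "dm_prob"))) {
    has <- rbern(n, config[[com[2]]])
    if (any(has)) {
      pl <- c(pl, list(tibble::tibble(
        patient_id = ids[has], code = com[1],
        onset_date = config$extraction_date - floor(stats::runif(sum(has), 100, 4000))
      )))
    }
  }

  # --- baseline (pre-treatment) cardiac dysfunction -----------------------
  baseline <- treated & rbern(n, config$baseline_dysfunction_prob)
  mode <- stats::runif(n)  # <0.5 low pre-LVEF, <0.8 HF problem entry, else both
  base_echo <- baseline & (mode < 0.5 | mode >= 0.8)
  base_hf <- baseline & mode >= 0.5
  img <- list()
  if (any(base_echo)) {
    k <- sum(base_echo)
    img <- c(img, list(tibble::tibble(
      patient_id = ids[base_echo], modality = "echo",
      study_date = exposure_date[base_echo] - floor(stats::runif(k, 30, 365)),
      lvef = rtrunc_norm(k, config$lvef_lvd_mean, config$lvef_lvd_sd, 5, 49.5)
    )))
  }
  if (any(base_hf)) {
    k <- sum(base_hf)
    pl <- c(pl, list(tibble::tibble(
      patient_id = ids[base_hf],
      code = sample(c("417996009", "195021004"), k, replace = TRUE),
      onset_date = exposure_date[base_hf] - floor(stats::runif(k, 30, 800))
    )))
  }

  # --- pre/post LVEF screening -------------------------------------------
  cls <- exposure_class
  cls[is.na(cls)] <- "other"
  modal_wts <- c(echo = 0.975, muga = 0.015, cardiac_mri = 0.010)
  pre_assessed <- treated & rbern(n, unname(config$pre_screen_prob[cls]))
  if (any(pre_assessed)) {
    k <- sum(pre_assessed)
    img <- c(img, list(tibble::tibble(
      patient_id = ids[pre_assessed],
      modality = sample(names(modal_wts), k, replace = TRUE, prob = modal_wts),
      study_date = exposure_date[pre_assessed] - floor(stats::runif(k, 1, 365)),
      lvef = rtrunc_norm(k, config$lvef_normal_mean, config$lvef_normal_sd, 50, 80)
    )))
  }
  post_assessed <- treated & rbern(n, unname(config$post_screen_prob[cls]))
  true_lvd <- post_assessed & rbern(n, unname(config$lvd_risk[cls]))
  if (any(post_assessed)) {
    k <- sum(post_assessed)
    lvef <- ifelse(true_lvd[post_assessed],
                   rtrunc_norm(k, config$lvef_lvd_mean, config$lvef_lvd_sd, 5, 49.5),
                   rtrunc_norm(k, config$lvef_normal_mean, config$lvef_normal_sd, 50, 80))
    img <- c(img, list(tibble::tibble(
      patient_id = ids[post_assessed],
      modality = sample(names(modal_wts), k, replace = TRUE, prob = modal_wts),
      study_date = exposure_date[post_assessed] + floor(stats::runif(k, 0, 700)),
      lvef = lvef
    )))
    # occasional second post-treatment study (multi-modality overlap)
    second <- post_assessed & rbern(n, 0.15)
    if (any(second)) {
      k2 <- sum(second)
      img <- c(img, list(tibble::tibble(
        patient_id = ids[second],
        modality = sample(names(modal_wts), k2, replace = TRUE, prob = modal_wts),
        study_date = exposure_date[second] + floor(stats::runif(k2, 0, 700)),
        lvef = rtrunc_norm(k2, config$lvef_normal_mean, config$lvef_normal_sd, 50, 80)
      )))
    }
  }

  # --- HFrEF truth and its Problem-List documentation channel -------------
  true_hfref <- treated & rbern(n, unname(config$hfref_prev[cls]))
  doc_p <- ifelse(true_hfref, config$hfref_doc_sensitivity,
                  1 - config$hfref_doc_specificity)
  hfref_documented <- treated & rbern(n, doc_p)
  if (any(hfref_documented)) {
    k <- sum(hfref_documented)
    pl <- c(pl, list(tibble::tibble(
      patient_id = ids[hfref_documented],
      code = sample(c("417996009", "441530006", "195021004"), k, replace = TRUE),
      onset_date = exposure_date[hfref_documented] + floor(stats::runif(k, 60, 730))
    )))
  }

  # --- referrals ----------------------------------------------------------
  outcome <- true_lvd | hfref_documented
  referred <- treated & rbern(n, ifelse(outcome, config$referral_prob_given_outcome,
                                        config$referral_prob_no_outcome))
  referrals <- tibble::tibble(
    patient_id = ids[referred], specialty = "cardiology",
    referral_date = exposure_date[referred] + floor(stats::runif(sum(referred), 60, 800))
  )

  # --- active medication list --------------------------------------------
  gp <- config$gdmt_probs
  col <- ifelse(referred, "referred", "not_referred")
  gdmt_bb <- outcome & rbern(n, unname(gp["beta_blocker", ][col]))
  gdmt_ra <- outcome & rbern(n, unname(gp["acei_arb", ][col]))
  gdmt_mra <- outcome & rbern(n, unname(gp["mra", ][col]))

  meds <- list()
  med_row <- function(sel, name, class, subclass) {
    tibble::tibble(patient_id = ids[sel], drug_name = name,
                   pharmaceutical_class = class, pharmaceutical_subclass = subclass,
                   active = TRUE, as_of_date = config$extraction_date)
  }
  if (any(gdmt_bb)) {
    bb_names <- sample(c("Carvedilol 12.5 mg tablet",
                         "Metoprolol Succinate ER 50 mg tablet",
                         "Bisoprolol Fumarate 5 mg tablet"), sum(gdmt_bb), replace = TRUE)
    meds <- c(meds, list(med_row(gdmt_bb, bb_names,
                                 "Beta-Adrenergic Blocking Agents",
                                 "Beta-Blockers, Cardioselective")))
  }
  if (any(gdmt_ra)) {
    kind <- stats::runif(n)  # acei vs arb split, plus edge-case products
    is_acei <- gdmt_ra & kind < 0.5
    acei_combo <- is_acei & kind < 0.125
    acei_plain <- is_acei & !acei_combo
    is_arb <- gdmt_ra & !is_acei
    arb_ali <- is_arb & kind > 0.93
    arb_plain <- is_arb & !arb_ali
    combos <- c("Lisinopril-Hydrochlorothiazide 20-25 mg tablet",
                "Benazepril-Amlodipine 10-5 mg capsule",
                "Trandolapril-Verapamil ER 2-180 mg tablet")
    if (any(acei_plain)) {
      meds <- c(meds, list(med_row(acei_plain, "Lisinopril 10 mg tablet",
                                   "ACE Inhibitors", "ACE Inhibitors")))
    }
    if (any(acei_combo)) {
      # combination products: class title lacks the ACE-Inhibitor phrase,
      # detection must come from the named-combination list
      meds <- c(meds, list(med_row(acei_combo,
                                   sample(combos, sum(acei_combo), replace = TRUE),
                                   "Antihypertensive Combinations",
                                   "Antihypertensive Combinations")))
    }
    if (any(arb_plain)) {
      meds <- c(meds, list(med_row(arb_plain, "Losartan Potassium 50 mg tablet",
                                   "Angiotensin II Receptor Blockers (ARBs)",
                                   "Angiotensin II Receptor Blockers (ARBs)")))
    }
    if (any(arb_ali)) {
      meds <- c(meds, list(med_row(arb_ali, "Aliskiren-Valsartan 150-160 mg tablet",
                                   "Renin Inhibitor Combinations",
                                   "Renin Inhibitor Combinations")))
    }
  }
  if (any(gdmt_mra)) {
    meds <- c(meds, list(med_row(gdmt_mra, "Spironolactone 25 mg tablet",
                                 "Diuretics, Potassium-Sparing",
                                 "Aldosterone Receptor Antagonists")))
  }
  # distractor medications; none may trip a GDMT rule (metoprolol tartrate
  # and the barbiturate class are deliberate near-misses)
  distract <- rbern(n, 0.4)
  if (any(distract)) {
    k <- sum(distract)
    pick <- sample(5, k, replace = TRUE)
    dnames <- c("Atorvastatin 40 mg tablet", "Metformin 500 mg tablet",
                "Phenobarbital 30 mg tablet", "Metoprolol Tartrate 25 mg tablet",
                "Amlodipine 5 mg tablet")[pick]
    dclass <- c("HMG-CoA Reductase Inhibitors", "Biguanides", "Barbiturates",
                "Beta-Adrenergic Blocking Agents", "Calcium Channel Blockers")[pick]
    meds <- c(meds, list(med_row(distract, dnames, dclass, dclass)))
  }
  # non-outcome hypertensives may be on an ACE inhibitor for blood pressure
  htn_acei <- !outcome & treated & rbern(n, 0.10)
  if (any(htn_acei)) {
    meds <- c(meds, list(med_row(htn_acei, "Lisinopril 10 mg tablet",
                                 "ACE Inhibitors", "ACE Inhibitors")))
  }

  empty_pl <- tibble::tibble(patient_id = character(), code = character(),
                             onset_date = as.Date(character()))
  empty_img <- tibble::tibble(patient_id = character(), modality = character(),
                              study_date = as.Date(character()), lvef = numeric())
  empty_med <- tibble::tibble(patient_id = character(), drug_name = character(),
                              pharmaceutical_class = character(),
                              pharmaceutical_subclass = character(),
                              active = logical(), as_of_date = as.Date(character()))
  problem_list <- dplyr::arrange(dplyr::bind_rows(empty_pl, pl),
                                 .data$patient_id, .data$onset_date, .data$code)
  imaging <- dplyr::arrange(dplyr::bind_rows(empty_img, img),
                            .data$patient_id, .data$study_date, .data$modality)
  medication_orders <- dplyr::arrange(dplyr::bind_rows(empty_med, meds),
                                      .data$patient_id, .data$drug_name)

  truth <- tibble::tibble(
    patient_id = ids, true_cancer = true_cancer,
    exposure_class = exposure_class,
    baseline_dysfunction = baseline,
    pre_assessed = pre_assessed, post_assessed = post_assessed,
    true_lvd = true_lvd, true_hfref = true_hfref,
    hfref_documented = hfref_documented, referred = referred,
    gdmt_beta_blocker = gdmt_bb, gdmt_acei_arb = gdmt_ra, gdmt_mra = gdmt_mra
  )

  list(
    dataset = ehr_dataset(patients, problem_list, treatment_episodes,
                          imaging, medication_orders, referrals),
    truth = truth
  )
}
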