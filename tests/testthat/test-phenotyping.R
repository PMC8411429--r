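ep_row <- function(class, date, drug = "x") {
  tibble::tibble(patient_id = "P", drug_name = drug, drug_class = class,
                 start_date = as.Date(date))
}
img_row <- function(date, lvef, modality = "echo") {
  tibble::tibble(patient_id = "P", modality = modality,
                 study_date = as.Date(date), lvef = lvef)
}
med_row <- function(name, class = "", subclass = "", active = TRUE) {
  tibble::tibble(patient_id = "P", drug_name = name,
                 pharmaceutical_class = class, pharmaceutical_subclass = subclass,
                 active = active, as_of_date = as.Date("2018-01-01"))
}

test_that("exposure profiles aggregate drug classes over all episodes", {
  one <- classify_exposure(ep_row("anthracycline", "2012-03-01"))
  expect_true(one$anthracycline)
  expect_false(one$her2_antibody || one$tki || one$ici)
  expect_equal(one$initial_exposure_date, as.Date("2012-03-01"))

  two <- classify_exposure(dplyr::bind_rows(ep_row("anthracycline", "2012-03-01"),
                                            ep_row("her2", "2013-01-15")))
  expect_true(two$anthracycline && two$her2_antibody)
  expect_equal(two$initial_exposure_date, as.Date("2012-03-01"))

  expect_error(classify_exposure(ep_row("x", "2012-01-01")[0, ]), "episode")
})

test_that("LVEF summaries split studies around the exposure date", {
  exposure <- as.Date("2012-06-01")
  s <- summarize_lvef(img_row("2012-05-31", 62), exposure)
  expect_true(s$pre_assessed)
  expect_false(s$post_assessed)
  expect_true(is.na(s$min_post_lvef))

  same_day <- summarize_lvef(img_row("2012-06-01", 62), exposure)
  expect_false(same_day$pre_assessed)
  expect_true(same_day$post_assessed)

  flipped <- summarize_lvef(img_row("2012-06-01", 62), exposure,
                            same_day_is_post = FALSE)
  expect_true(flipped$pre_assessed)

  multi <- summarize_lvef(dplyr::bind_rows(img_row("2012-08-01", 55),
                                           img_row("2013-01-01", 44, "muga")),
                          exposure)
  expect_equal(multi$min_post_lvef, 44)
  expect_setequal(multi$post_modalities, c("echo", "muga"))

  expect_error(summarize_lvef(img_row("2012-08-01", 0.5), exposure), "LVEF")
})

test_that("LVD detection is strictly below the 50% threshold", {
  exposure <- as.Date("2012-06-01")
  at <- summarize_lvef(img_row("2012-08-01", 50), exposure)
  just_below <- summarize_lvef(img_row("2012-08-01", 49.9), exposure)
  none <- summarize_lvef(img_row("2012-08-01", 50)[0, ], exposure)
  expect_false(detect_lvd(at))
  expect_true(detect_lvd(just_below))
  expect_false(detect_lvd(none))
  # threshold flip is exactly at the strict boundary
  for (eps in c(-0.1, -1e-6)) {
    s <- summarize_lvef(img_row("2012-08-01", 50 + eps), exposure)
    expect_true(detect_lvd(s))
  }
  expect_false(detect_lvd(summarize_lvef(img_row("2012-08-01", 50 + 1e-6), exposure)))
})

test_that("HFrEF detection matches systolic HF and/or dilated cardiomyopathy", {
  h <- demo_concept_hierarchy()
  vs <- expand_value_set(h, hf_value_set_rule())
  pl <- function(code, onset) tibble::tibble(patient_id = "P", code = code,
                                             onset_date = as.Date(onset))
  expect_false(detect_hfref(pl("x", "2013-01-01")[0, ], vs))
  expect_true(detect_hfref(pl("195021004", "2013-01-01"), vs))   # DCM alone
  expect_true(detect_hfref(pl("441530006", "2013-01-01"), vs))   # descendant
  expect_false(detect_hfref(pl("418304008", "2013-01-01"), vs))  # diastolic HF
  # onset before exposure is baseline, not a post-treatment outcome
  expect_false(detect_hfref(pl("195021004", "2011-01-01"), vs,
                            exposure_date = as.Date("2012-06-01")))
  expect_true(detect_hfref(pl("195021004", "2013-01-01"), vs,
                           exposure_date = as.Date("2012-06-01")))
})

test_that("GDMT beta-blocker matching is ingredient-specific", {
  vocab <- gdmt_vocabulary()
  expect_true(classify_gdmt(med_row("Carvedilol 12.5 mg tablet"), vocab)$beta_blocker)
  expect_true(classify_gdmt(med_row("METOPROLOL   SUCCINATE ER 100 mg"), vocab)$beta_blocker)
  expect_true(classify_gdmt(med_row("bisoprolol fumarate 10 mg"), vocab)$beta_blocker)
  # tartrate formulations do not qualify
  expect_false(classify_gdmt(med_row("Metoprolol Tartrate 25 mg tablet"), vocab)$beta_blocker)
})

test_that("GDMT ACE-inhibitor matching uses title phrases and combinations", {
  vocab <- gdmt_vocabulary()
  expect_true(classify_gdmt(med_row("Lisinopril", class = "ACE Inhibitors"),
                            vocab)$acei)
  # phrase containment, not exact title equality
  expect_true(classify_gdmt(med_row("FixedDose", class = "ACE Inhibitors & Calcium Blockers"),
                            vocab)$acei)
  expect_true(classify_gdmt(med_row("x", subclass = "ace inhibitor & thiazide diuretic combinations"),
                            vocab)$acei)
  # combination product whose class title lacks the phrase
  combo <- classify_gdmt(med_row("Benazepril-Amlodipine 10-5 mg capsule",
                                 class = "Antihypertensive Combinations"), vocab)
  expect_true(combo$acei)
  expect_false(classify_gdmt(med_row("Amlodipine", class = "Calcium Channel Blockers"),
                             vocab)$acei)
})

test_that("GDMT ARB matching is phrase- or token-based with word boundaries", {
  vocab <- gdmt_vocabulary()
  expect_true(classify_gdmt(med_row("Losartan", class = "Angiotensin II Receptor Blockers (ARBs)"),
                            vocab)$arb)
  expect_true(classify_gdmt(med_row("Valsartan", class = "Angiotensin Receptor Antagonists"),
                            vocab)$arb)
  expect_true(classify_gdmt(med_row("Olmesartan", class = "ARB-Diuretic Combinations"),
                            vocab)$arb)
  # 'ARB' must be a standalone token: barbiturates never match
  expect_false(classify_gdmt(med_row("Phenobarbital", class = "Barbiturates"),
                             vocab)$arb)
  expect_true(classify_gdmt(med_row("Aliskiren-Valsartan 150-160 mg tablet",
                                    class = "Renin Inhibitor Combinations"),
                            vocab)$arb)
})

test_that("GDMT MRA and composite flags behave as defined", {
  vocab <- gdmt_vocabulary()
  mra <- classify_gdmt(med_row("Spironolactone", subclass = "Aldosterone Receptor Antagonists"),
                       vocab)
  expect_true(mra$mra)
  expect_false(mra$acei_or_arb)

  both <- classify_gdmt(dplyr::bind_rows(
    med_row("Lisinopril", class = "ACE Inhibitors"),
    med_row("Losartan", class = "Angiotensin Receptor Blockers")), vocab)
  expect_true(both$acei && both$arb && both$acei_or_arb)

  # inactive orders are ignored; empty list is all-false
  inactive <- classify_gdmt(med_row("Carvedilol", active = FALSE), vocab)
  expect_false(inactive$beta_blocker)
  none <- classify_gdmt(med_row("x")[0, ], vocab)
  expect_false(any(unlist(none)))
})

test_that("adding unrelated medications never switches a GDMT flag off", {
  vocab <- gdmt_vocabulary()
  base <- dplyr::bind_rows(med_row("Carvedilol"),
                           med_row("Losartan", class = "Angiotensin Receptor Blockers"))
  before <- classify_gdmt(base, vocab)
  grown <- dplyr::bind_rows(base, med_row("Atorvastatin", class = "HMG-CoA Reductase Inhibitors"),
                            med_row("Phenobarbital", class = "Barbiturates"))
  after <- classify_gdmt(grown, vocab)
  for (flag in names(before)) {
    expect_true(!before[[flag]] || after[[flag]], label = flag)
  }
})

test_that("cardiology referral flag requires the cardiology specialty", {
  ref <- function(spec) tibble::tibble(patient_id = "P", specialty = spec,
                                       referral_date = as.Date("2015-01-01"))
  expect_false(referred_to_cardiology(ref("x")[0, ]))
  expect_false(referred_to_cardiology(ref("oncology")))
  expect_true(referred_to_cardiology(ref("Cardiology")))
})

test_that("table-wise phenotyping agrees with the per-patient functions", {
  h <- demo_concept_hierarchy()
  sim <- generate_cohort(cohort_config(n_patients = 300, seed = 55))
  res <- build_cohort(sim$dataset, h, registry_criteria(cancer_value_set_rule()))
  members <- phenotype_cohort(sim$dataset, res$ids, h)
  expect_setequal(members$patient_id, res$ids)

  vs <- expand_value_set(h, hf_value_set_rule())
  vocab <- gdmt_vocabulary()
  d <- sim$dataset
  for (pid in sample(members$patient_id, 40)) {
    row <- members[members$patient_id == pid, ]
    ep <- d$treatment_episodes[d$treatment_episodes$patient_id == pid, ]
    exp_prof <- classify_exposure(ep)
    expect_equal(row$initial_exposure_date, exp_prof$initial_exposure_date)
    expect_equal(row$anthracycline, exp_prof$anthracycline)

    s <- summarize_lvef(d$imaging_studies[d$imaging_studies$patient_id == pid, ],
                        exp_prof$initial_exposure_date)
    expect_equal(row$pre_assessed, s$pre_assessed)
    expect_equal(row$post_assessed, s$post_assessed)
    expect_equal(row$min_post_lvef, s$min_post_lvef)
    expect_equal(row$lvd, detect_lvd(s))

    expect_equal(row$hfref,
                 detect_hfref(d$problem_list[d$problem_list$patient_id == pid, ],
                              vs, exp_prof$initial_exposure_date))
    g <- classify_gdmt(d$medication_orders[d$medication_orders$patient_id == pid, ],
                       vocab)
    expect_equal(row$beta_blocker, g$beta_blocker)
    expect_equal(row$acei_or_arb, g$acei_or_arb)
    expect_equal(row$mra, g$mra)
    expect_equal(row$referred,
                 referred_to_cardiology(d$referrals[d$referrals$patient_id == pid, ]))
  }
})

test_that("phenotyping recovers the generator's per-patient truth", {
  h <- demo_concept_hierarchy()
  sim <- generate_cohort(cohort_config(n_patients = 2000, seed = 56,
                                       baseline_dysfunction_prob = 0))
  res <- build_cohort(sim$dataset, h, registry_criteria(cancer_value_set_rule()))
  members <- phenotype_cohort(sim$dataset, res$ids, h)
  tr <- sim$truth[match(members$patient_id, sim$truth$patient_id), ]
  expect_identical(members$lvd, tr$true_lvd)
  expect_identical(members$hfref, tr$hfref_documented)
  expect_identical(members$referred, tr$referred)
  expect_identical(members$pre_assessed, tr$pre_assessed)
  expect_identical(members$post_assessed, tr$post_assessed)
  outcome <- members$lvd | members$hfref
  expect_identical(members$beta_blocker[outcome], tr$gdmt_beta_blocker[outcome])
  expect_identical(members$mra[outcome], tr$gdmt_mra[outcome])
})
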