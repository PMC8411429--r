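mini_dataset <- function(problem_codes = list(), episodes = list(),
                         imaging = list()) {
  ids <- unique(c(names(problem_codes), names(episodes), names(imaging), "P1"))
  ehr_dataset(
    patients = tibble::tibble(patient_id = ids,
                              birth_date = as.Date("1960-01-01"),
                              sex = "F", vital_status = "alive"),
    problem_list = dplyr::bind_rows(
      tibble::tibble(patient_id = character(), code = character(),
                     onset_date = as.Date(character())),
      lapply(names(problem_codes), function(id)
        tibble::tibble(patient_id = id, code = problem_codes[[id]]$code,
                       onset_date = as.Date(problem_codes[[id]]$onset)))),
    treatment_episodes = dplyr::bind_rows(
      tibble::tibble(patient_id = character(), drug_name = character(),
                     drug_class = character(), start_date = as.Date(character())),
      lapply(names(episodes), function(id)
        tibble::tibble(patient_id = id, drug_name = "Doxorubicin",
                       drug_class = "anthracycline",
                       start_date = as.Date(episodes[[id]])))),
    imaging_studies = dplyr::bind_rows(
      tibble::tibble(patient_id = character(), modality = character(),
                     study_date = as.Date(character()), lvef = numeric()),
      lapply(names(imaging), function(id)
        tibble::tibble(patient_id = id, modality = "echo",
                       study_date = as.Date(imaging[[id]]$date),
                       lvef = imaging[[id]]$lvef))),
    medication_orders = tibble::tibble(
      patient_id = character(), drug_name = character(),
      pharmaceutical_class = character(), pharmaceutical_subclass = character(),
      active = logical(), as_of_date = as.Date(character())),
    referrals = tibble::tibble(patient_id = character(), specialty = character(),
                               referral_date = as.Date(character()))
  )
}

test_that("cancer population selection follows the value-set rule", {
  h <- demo_concept_hierarchy()
  rule <- cancer_value_set_rule()
  empty <- mini_dataset()
  expect_identical(build_cancer_population(empty, h, rule), character(0))

  d <- mini_dataset(problem_codes = list(
    A = list(code = "254837009", onset = "2012-01-01"),  # breast cancer
    B = list(code = "92030004", onset = "2012-01-01"),   # benign brain only
    C = list(code = "275937001", onset = "2012-01-01")   # family history only
  ))
  expect_identical(build_cancer_population(d, h, rule), "A")
})

test_that("the treatment window is a closed interval", {
  h <- demo_concept_hierarchy()
  crit <- registry_criteria(cancer_value_set_rule(),
                            treatment_window = as.Date(c("2011-01-01", "2017-06-30")))
  d <- mini_dataset(
    problem_codes = list(A = list(code = "254837009", onset = "2010-06-01"),
                         B = list(code = "254837009", onset = "2010-06-01"),
                         C = list(code = "254837009", onset = "2010-06-01")),
    episodes = list(A = "2011-01-01",   # on the start boundary: in
                    B = "2017-07-01",   # one day past the end: out
                    C = "2017-06-30"))  # on the end boundary: in
  pop <- build_cancer_population(d, h, crit$cancer_rule)
  expect_identical(build_registry(pop, d, crit), c("A", "C"))
})

test_that("baseline dysfunction exclusion is strict about 'predated'", {
  h <- demo_concept_hierarchy()
  d <- mini_dataset(
    problem_codes = list(
      A = list(code = "254837009", onset = "2011-06-01"),
      B = list(code = c("254837009", "417996009"),
               onset = c("2011-06-01", "2011-12-31")),  # HF before exposure
      C = list(code = "254837009", onset = "2011-06-01"),
      D = list(code = "254837009", onset = "2011-06-01")),
    episodes = list(A = "2012-01-01", B = "2012-01-01", C = "2012-01-01",
                    D = "2012-01-01"),
    imaging = list(
      C = list(date = "2011-11-01", lvef = 42),  # low LVEF before exposure
      D = list(date = "2012-01-01", lvef = 42))  # low LVEF ON exposure day
  )
  res <- exclude_baseline_dysfunction(c("A", "B", "C", "D"), d, h,
                                      hf_value_set_rule())
  # B (pre-onset HF) and C (pre low LVEF) go; D's same-day study is post
  expect_setequal(res$ids, c("A", "D"))
  expect_equal(res$attrition$n_excluded_baseline, 2L)
  expect_equal(res$attrition$n_final, 2L)
})

test_that("attrition accounting conserves counts and rejects impossible flows", {
  rep <- attrition_report(8275, 8275, 372)
  expect_equal(rep$n_final, 7903L)
  expect_error(attrition_report(100, 200, 0), "exceed")
  expect_error(attrition_report(100, 50, 60), "exclude")
  expect_error(attrition_report(-1, 0, 0), "non-negative")
})

test_that("a registry patient without any treatment episode cannot be anchored", {
  h <- demo_concept_hierarchy()
  d <- mini_dataset(problem_codes = list(A = list(code = "254837009",
                                                  onset = "2012-01-01")))
  expect_error(exclude_baseline_dysfunction("A", d, h, hf_value_set_rule()),
               "without any treatment episode")
})

test_that("cohort construction recovers the generator's ground truth", {
  h <- demo_concept_hierarchy()
  sim <- generate_cohort(cohort_config(n_patients = 2000, seed = 31,
                                       cancer_prob = 0.6))
  pop <- build_cancer_population(sim$dataset, h, cancer_value_set_rule())
  expect_setequal(pop, sim$truth$patient_id[sim$truth$true_cancer])
  expect_within_3se(length(pop), 2000, 0.6)

  crit <- registry_criteria(cancer_value_set_rule())
  reg <- build_registry(pop, sim$dataset, crit)
  expect_setequal(reg, pop)  # all generated episodes start in-window

  res <- exclude_baseline_dysfunction(reg, sim$dataset, h, hf_value_set_rule(),
                                      n_cancer_population = length(pop))
  expect_setequal(res$ids,
                  sim$truth$patient_id[sim$truth$true_cancer &
                                         !sim$truth$baseline_dysfunction])
  expect_equal(res$attrition$n_final,
               res$attrition$n_treated_registry - res$attrition$n_excluded_baseline)
})

test_that("baseline exclusions scale with the configured dysfunction rate", {
  h <- demo_concept_hierarchy()
  sim <- generate_cohort(cohort_config(n_patients = 8275, seed = 32))
  res <- build_cohort(sim$dataset, h, registry_criteria(cancer_value_set_rule()))
  expect_within_3se(res$attrition$n_excluded_baseline, 8275, 372 / 8275)
})

test_that("a dataset with no baseline dysfunction excludes nobody", {
  h <- demo_concept_hierarchy()
  sim <- generate_cohort(cohort_config(n_patients = 400, seed = 33,
                                       baseline_dysfunction_prob = 0))
  res <- build_cohort(sim$dataset, h, registry_criteria(cancer_value_set_rule()))
  expect_equal(res$attrition$n_excluded_baseline, 0L)
  expect_equal(res$attrition$n_final, res$attrition$n_treated_registry)
})
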