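#' Criteria defining the treated registry
#'
#' @param cancer_rule A [value_set_rule()] selecting the cancer population.
#' @param treatment_window Length-2 Date vector; treatment episode start
#'   dates are filtered to this closed interval.
#' @param require_treatment_episode Must a registry member have at least one
#'   treatment episode? (Stands in for the EHR oncology-module filter.)
#' @return An object of class `registry_criteria`.
#' @export
registry_criteria <- function(cancer_rule,
                              treatment_window = as.Date(c("2011-01-01", "2017-06-30")),
                              require_treatment_episode = TRUE) {
  treatment_window <- as.Date(treatment_window)
  if (treatment_window[1] >= treatment_window[2]) {
    stop("treatment window start must precede its end", call. = FALSE)
  }
  structure(list(cancer_rule = cancer_rule, treatment_window = treatment_window,
                 require_treatment_episode = require_treatment_episode),
            class = "registry_criteria")
}

#' Attrition accounting for nested cohort construction
#'
#' Records the counts at each filter of the cohort flow: broad cancer
#' population, treated registry, baseline-dysfunction exclusions, and the
#' final analysis population. Conservation (`n_final = n_treated_registry -
#' n_excluded_baseline`) is enforced at construction.
#'
#' @param n_cancer_population,n_treated_registry,n_excluded_baseline
#'   Non-negative counts; the treated registry cannot exceed the cancer
#'   population.
#' @return An object of class `attrition_report` with the three counts plus
#'   `n_final`.
#' @export
attrition_report <- function(n_cancer_population, n_treated_registry,
                             n_excluded_baseline) {
  counts <- c(n_cancer_population, n_treated_registry, n_excluded_baseline)
  if (any(counts < 0)) stop("attrition counts must be non-negative", call. = FALSE)
  if (n_treated_registry > n_cancer_population) {
    stop("treated registry cannot exceed the cancer population", call. = FALSE)
  }
  if (n_excluded_baseline > n_treated_registry) {
    stop("cannot exclude more patients than the registry holds", call. = FALSE)
  }
  structure(list(n_cancer_population = as.integer(n_cancer_population),
                 n_treated_registry = as.integer(n_treated_registry),
                 n_excluded_baseline = as.integer(n_excluded_baseline),
                 n_final = as.integer(n_treated_registry - n_excluded_baseline)),
            class = "attrition_report")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("<attrition_report>\n",
      "  cancer population : ", x$n_cancer_population, "\n",
      "  treated registry  : ", x$n_treated_registry, "\n",
      "  baseline excluded : ", x$n_excluded_baseline, "\n",
      "  final population  : ", x$n_final, "\n", sep = "")
  invisible(x)
}

#' Broad cancer population from Problem-List value-set matching
#'
#' A patient belongs to the cancer population iff any diagnosis on their
#' Problem List falls in the expansion of the cancer value-set rule.
#'
#' @param dataset An [ehr_dataset()].
#' @param hierarchy A [concept_hierarchy()].
#' @param rule A [value_set_rule()] (e.g. [cancer_value_set_rule()]).
#' @return Sorted character vector of patient ids.
#' @export
build_cancer_population <- function(dataset, hierarchy, rule) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  vs <- expand_value_set(hierarchy, rule)
  pl <- dataset$problem_list
  sort(unique(pl$patient_id[pl$code %in% vs$codes]))
}

#' Treated registry: population members with an in-window treatment episode
#'
#' Filters the cancer population to patients having at least one treatment
#' episode whose start date lies inside the closed treatment window.
#'
#' @param population Character vector of patient ids (from
#'   [build_cancer_population()]).
#' @param dataset An [ehr_dataset()].
#' @param criteria A [registry_criteria()].
#' @return Sorted character vector of patient ids.
#' @export
build_registry <- function(population, dataset, criteria) {
  stopifnot(inherits(dataset, "ehr_dataset"),
            inherits(criteria, "registry_criteria"))
  missing <- setdiff(population, dataset$patients$patient_id)
  if (length(missing) > 0) {
    stop("population contains id(s) absent from the dataset: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!criteria$require_treatment_episode) return(sort(unique(population)))
  ep <- dataset$treatment_episodes
  w <- criteria$treatment_window
  in_window <- ep$start_date >= w[1] & ep$start_date <= w[2]
  sort(intersect(population, unique(ep$patient_id[in_window])))
}

initial_exposure_dates <- function(dataset, ids) {
  ep <- dplyr::filter(dataset$treatment_episodes, .data$patient_id %in% ids)
  no_episode <- setdiff(ids, unique(ep$patient_id))
  if (length(no_episode) > 0) {
    stop("registry patient(s) without any treatment episode (cannot anchor ",
         "pre-treatment timing): ",
         paste(utils::head(no_episode, 5), collapse = ", "), call. = FALSE)
  }
  ex <- dplyr::summarise(dplyr::group_by(ep, .data$patient_id),
                         exposure_date = min(.data$start_date), .groups = "drop")
  stats::setNames(ex$exposure_date, ex$patient_id)[ids]
}

#' Exclude patients with cardiac dysfunction predating treatment
#'
#' Removes registry members with a below-threshold LVEF strictly before the
#' initial exposure date, or a heart-failure / dilated-cardiomyopathy
#' Problem-List entry with onset strictly before it. Same-day events count
#' as post-treatment; Problem-List entries without an onset date predate
#' nothing and are kept.
#'
#' @param registry Character vector of registry patient ids.
#' @param dataset An [ehr_dataset()].
#' @param hierarchy A [concept_hierarchy()].
#' @param hf_rule A [value_set_rule()] for systolic HF / dilated
#'   cardiomyopathy (e.g. [hf_value_set_rule()]).
#' @param lvef_threshold LVD threshold in percent, strict (`< threshold`).
#' @param n_cancer_population Optional upstream population size for the
#'   attrition report; defaults to the registry size.
#' @return A list: `ids` (final population, sorted) and `attrition` (an
#'   [attrition_report()]).
#' @export
exclude_baseline_dysfunction <- function(registry, dataset, hierarchy, hf_rule,
                                         lvef_threshold = 50,
                                         n_cancer_population = length(registry)) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (lvef_threshold <= 0 || lvef_threshold >= 100) {
    stop("lvef_threshold must lie in (0, 100)", call. = FALSE)
  }
  registry <- sort(unique(registry))
  exposure <- initial_exposure_dates(dataset, registry)

  img <- dplyr::filter(dataset$imaging_studies, .data$patient_id %in% registry)
  low_pre <- img$lvef < lvef_threshold &
    img$study_date < exposure[img$patient_id]
  lvd_baseline <- unique(img$patient_id[low_pre])

  hf_vs <- expand_value_set(hierarchy, hf_rule)
  pl <- dplyr::filter(dataset$problem_list,
                      .data$patient_id %in% registry,
                      .data$code %in% hf_vs$codes,
                      !is.na(.data$onset_date))
  hf_baseline <- unique(pl$patient_id[pl$onset_date < exposure[pl$patient_id]])

  excluded <- union(lvd_baseline, hf_baseline)
  final <- setdiff(registry, excluded)
  list(ids = final,
       attrition = attrition_report(n_cancer_population, length(registry),
                                    length(excluded)))
}

#' End-to-end cohort construction
#'
#' Convenience wrapper chaining [build_cancer_population()],
#' [build_registry()] and [exclude_baseline_dysfunction()].
#'
#' @param dataset An [ehr_dataset()].
#' @param hierarchy A [concept_hierarchy()].
#' @param criteria A [registry_criteria()].
#' @param hf_rule A [value_set_rule()] for baseline HF exclusion.
#' @param lvef_threshold Strict LVD threshold in percent.
#' @return A list: `ids` (final analysis population) and `attrition`.
#' @export
build_cohort <- function(dataset, hierarchy, criteria,
                         hf_rule = hf_value_set_rule(), lvef_threshold = 50) {
  population <- build_cancer_population(dataset, hierarchy, criteria$cancer_rule)
  registry <- build_registry(population, dataset, criteria)
  exclude_baseline_dysfunction(registry, dataset, hierarchy, hf_rule,
                               lvef_threshold,
                               n_cancer_population = length(population))
}
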