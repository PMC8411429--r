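#' Demonstration concept hierarchy
#'
#' A small SNOMED-style polyhierarchy covering the concepts the registry
#' rules reference: malignant neoplastic disease and common cancer
#' descendants, carcinoma in situ, neoplasm of brain (with both malignant and
#' benign children — the benign child also sits under benign neoplastic
#' disease, exercising the DAG case), family-history situation codes, heart
#' failure with systolic/diastolic children, dilated cardiomyopathy, and the
#' comorbidities tabulated in the registry demographics. Codes use SNOMED CT
#' identifiers where the concept has a well-known one; the hierarchy itself
#' is a hand-built miniature, not a terminology release.
#'
#' @return A [concept_hierarchy()].
#' @export
demo_concept_hierarchy <- function() {
  concepts <- tibble::tribble(
    ~code, ~display,
    "404684003", "Clinical finding (finding)",
    "55342001",  "Neoplastic disease (disorder)",
    "363346000", "Malignant neoplastic disease (disorder)",
    "254837009", "Malignant neoplasm of breast (disorder)",
    "363358000", "Malignant neoplasm of lung (disorder)",
    "93143009",  "Leukemia (disorder)",
    "118600007", "Malignant lymphoma (disorder)",
    "702391001", "Renal cell carcinoma (disorder)",
    "363406005", "Malignant neoplasm of colon (disorder)",
    "109355002", "Carcinoma in situ (disorder)",
    "92695006",  "Carcinoma in situ of bronchus (disorder)",
    "99741000119100", "Adenocarcinoma in situ in villous adenoma (disorder)",
    "126952004", "Neoplasm of brain (disorder)",
    "93727008",  "Primary malignant neoplasm of brain (disorder)",
    "92030004",  "Benign neoplasm of brain (disorder)",
    "92186001",  "Benign neoplasm of cerebral meninges (disorder)",
    "20376005",  "Benign neoplastic disease (disorder)",
    "416471007", "Family history of clinical finding (situation)",
    "275937001", "Family history of cancer (situation)",
    "84114007",  "Heart failure (disorder)",
    "417996009", "Systolic heart failure (disorder)",
    "441530006", "Chronic systolic heart failure (disorder)",
    "418304008", "Diastolic heart failure (disorder)",
    "85898001",  "Cardiomyopathy (disorder)",
    "195021004", "Dilated cardiomyopathy (disorder)",
    "38341003",  "Hypertensive disorder (disorder)",
    "73211009",  "Diabetes mellitus (disorder)"
  )
  edges <- tibble::tribble(
    ~child_code, ~parent_code,
    "55342001",  "404684003",
    "363346000", "55342001",
    "254837009", "363346000",
    "363358000", "363346000",
    "93143009",  "363346000",
    "118600007", "363346000",
    "702391001", "363346000",
    "363406005", "363346000",
    "109355002", "55342001",
    "92695006",  "109355002",
    "99741000119100", "109355002",
    "126952004", "55342001",
    "93727008",  "126952004",
    "93727008",  "363346000",   # malignant brain tumor: child of both
    "92030004",  "126952004",
    "92030004",  "20376005",    # benign brain neoplasm: polyhierarchical
    "92186001",  "92030004",
    "20376005",  "55342001",
    "275937001", "416471007",
    "84114007",  "404684003",
    "417996009", "84114007",
    "441530006", "417996009",
    "418304008", "84114007",
    "85898001",  "404684003",
    "195021004", "85898001",
    "38341003",  "404684003",
    "73211009",  "404684003"
  )
  concept_hierarchy(concepts, edges)
}

#' Value-set rule for the broad cancer population
#'
#' Include malignant neoplastic disease, carcinoma in situ, adenocarcinoma in
#' situ in villous adenoma and neoplasm of brain, each with descendants; AND
#' NOT benign neoplasm of brain or family history of clinical finding, each
#' with descendants. Any Problem-List diagnosis matching the expansion places
#' the patient in the cancer population.
#'
#' @return A [value_set_rule()].
#' @export
cancer_value_set_rule <- function() {
  value_set_rule(
    includes = c("363346000", "109355002", "99741000119100", "126952004"),
    excludes = c("92030004", "416471007")
  )
}

#' Value-set rule for HFrEF Problem-List detection
#'
#' Systolic heart failure and/or dilated cardiomyopathy, with descendants.
#'
#' @return A [value_set_rule()].
#' @export
hf_value_set_rule <- function() {
  value_set_rule(includes = c("417996009", "195021004"))
}
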