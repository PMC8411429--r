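#' Classify a patient's treatment exposure profile
#'
#' Exposure flags are set from drug-class membership across all of the
#' patient's treatment episodes; a patient may carry several flags. The
#' initial exposure date is the earliest episode start — the anchor for
#' every pre/post split downstream.
#'
#' @param episodes Tibble of one patient's treatment episodes (`drug_class`,
#'   `start_date`); at least one row.
#' @return A list: `initial_exposure_date`, and logical `anthracycline`,
#'   `her2_antibody`, `tki`, `ici`.
#' @export
classify_exposure <- function(episodes) {
  if (nrow(episodes) == 0) {
    stop("cannot classify exposure without any treatment episode", call. = FALSE)
  }
  cls <- episodes$drug_class
  list(initial_exposure_date = min(episodes$start_date),
       anthracycline = "anthracycline" %in% cls,
       her2_antibody = "her2" %in% cls,
       tki = "tki" %in% cls,
       ici = "ici" %in% cls)
}

#' Summarize LVEF assessment timing relative to treatment
#'
#' A patient has a pre-treatment assessment iff any LVEF study predates the
#' initial exposure date strictly; any study on or after that date counts as
#' post-treatment (`same_day_is_post`). The minimum post-treatment LVEF
#' drives LVD detection: any qualifying measure below threshold flags the
#' patient.
#'
#' @param imaging Tibble of one patient's imaging studies (`modality`,
#'   `study_date`, `lvef`); may be empty.
#' @param exposure_date Initial exposure date.
#' @param same_day_is_post Should a study on the exposure date count as
#'   post-treatment? Default `TRUE`.
#' @return A list: `pre_assessed`, `post_assessed`, `pre_modalities`,
#'   `post_modalities`, `min_post_lvef` (`NA` unless post-assessed).
#' @export
summarize_lvef <- function(imaging, exposure_date, same_day_is_post = TRUE) {
  stopifnot(length(exposure_date) == 1, !is.na(exposure_date))
  if (nrow(imaging) > 0 && (any(imaging$lvef < 1) || any(imaging$lvef > 99))) {
    stop("implausible LVEF value(s) outside [1, 99]", call. = FALSE)
  }
  is_post <- if (same_day_is_post) imaging$study_date >= exposure_date
             else imaging$study_date > exposure_date
  pre <- imaging[!is_post, , drop = FALSE]
  post <- imaging[is_post, , drop = FALSE]
  list(pre_assessed = nrow(pre) > 0,
       post_assessed = nrow(post) > 0,
       pre_modalities = sort(unique(pre$modality)),
       post_modalities = sort(unique(post$modality)),
       min_post_lvef = if (nrow(post) > 0) min(post$lvef) else NA_real_)
}

#' Detect post-treatment left ventricular dysfunction
#'
#' LVD is a minimum post-treatment LVEF strictly below the threshold (50%
#' by definition); a patient with no post-treatment assessment cannot be
#' flagged.
#'
#' @param summary Output of [summarize_lvef()].
#' @param threshold Strict threshold in percent.
#' @return Logical flag.
#' @export
detect_lvd <- function(summary, threshold = 50) {
  isTRUE(summary$post_assessed) && summary$min_post_lvef < threshold
}

#' Detect HFrEF from Problem-List documentation
#'
#' True iff any Problem-List entry matches the systolic-HF / dilated-
#' cardiomyopathy value set with onset on or after the exposure date
#' (entries predating treatment belong to the baseline exclusion, handled
#' upstream). Entries without an onset date count as post-treatment when no
#' exposure date is supplied, and are kept when one is.
#'
#' @param problems Tibble of one patient's Problem-List entries (`code`,
#'   `onset_date`); may be empty.
#' @param hf_value_set A `value_set` expanded from systolic-HF and
#'   dilated-cardiomyopathy codes.
#' @param exposure_date Optional initial exposure date restricting matches
#'   to onsets on/after it.
#' @return Logical flag.
#' @export
detect_hfref <- function(problems, hf_value_set, exposure_date = NULL) {
  stopifnot(inherits(hf_value_set, "value_set"))
  hit <- problems$code %in% hf_value_set$codes
  if (!is.null(exposure_date)) {
    hit <- hit & (is.na(problems$onset_date) | problems$onset_date >= exposure_date)
  }
  any(hit)
}

# shared matching primitives: case-insensitive, whitespace-normalized
norm_ws <- function(x) {
  x[is.na(x)] <- ""
  gsub("\\s+", " ", trimws(tolower(x)))
}

title_contains <- function(titles, phrases) {
  titles <- norm_ws(titles)
  hit <- rep(FALSE, length(titles))
  for (p in norm_ws(phrases)) hit <- hit | grepl(p, titles, fixed = TRUE)
  hit
}

#' Classify GDMT status from an active medication list
#'
#' Applies the drug rules for reduced-EF cardiomyopathy therapy:
#' beta-blockers by ingredient name (carvedilol, metoprolol succinate,
#' bisoprolol — metoprolol tartrate does not qualify); ACE inhibitors by
#' pharmaceutical class or subclass title containing "ACE Inhibitor", or by
#' membership in the named combination-product list; ARBs by class title
#' containing an angiotensin-receptor-blocker phrase or the standalone token
#' "ARB"/"ARBs" (word-bounded, so barbiturates never match), or
#' aliskiren/valsartan by drug name; MRAs by subclass title containing
#' "Aldosterone Receptor Antagonist". All matching is case-insensitive and
#' whitespace-robust. Only rows with `active = TRUE` are considered.
#'
#' @param meds Tibble of one patient's medication orders (`drug_name`,
#'   `pharmaceutical_class`, `pharmaceutical_subclass`, `active`); may be
#'   empty.
#' @param vocab A [gdmt_vocabulary()].
#' @return A list of logical flags: `beta_blocker`, `acei`, `arb`,
#'   `acei_or_arb`, `mra`.
#' @export
classify_gdmt <- function(meds, vocab = gdmt_vocabulary()) {
  stopifnot(inherits(vocab, "gdmt_vocabulary"))
  if (nrow(meds) > 0 && "active" %in% names(meds)) {
    meds <- meds[meds$active %in% TRUE, , drop = FALSE]
  }
  if (nrow(meds) == 0) {
    return(list(beta_blocker = FALSE, acei = FALSE, arb = FALSE,
                acei_or_arb = FALSE, mra = FALSE))
  }
  name <- norm_ws(meds$drug_name)
  class_title <- norm_ws(meds$pharmaceutical_class)

  bb <- Reduce(`|`, lapply(norm_ws(vocab$beta_blocker_ingredients),
                           function(ing) grepl(ing, name, fixed = TRUE)))

  acei <- title_contains(meds$pharmaceutical_class, vocab$acei_phrases) |
    title_contains(meds$pharmaceutical_subclass, vocab$acei_phrases) |
    Reduce(`|`, lapply(norm_ws(vocab$acei_combinations),
                       function(cmb) grepl(cmb, name, fixed = TRUE)))

  arb <- title_contains(meds$pharmaceutical_class, vocab$arb_phrases) |
    grepl("\\barbs?\\b", class_title) |
    grepl("aliskiren[-/ ]valsartan", name)

  mra <- title_contains(meds$pharmaceutical_subclass, vocab$mra_phrases)

  list(beta_blocker = any(bb), acei = any(acei), arb = any(arb),
       acei_or_arb = any(acei) || any(arb), mra = any(mra))
}

#' Any cardiology referral on record?
#'
#' @param referrals Tibble of one patient's referrals (`specialty`); may be
#'   empty.
#' @return Logical flag.
#' @export
referred_to_cardiology <- function(referrals) {
  nrow(referrals) > 0 && any(norm_ws(referrals$specialty) == "cardiology")
}

#' Phenotype every member of a cohort
#'
#' Derives one record per patient — exposure profile, LVEF assessment
#' summary, LVD and HFrEF outcome flags, GDMT status and cardiology-referral
#' flag — using the same rules as the per-patient functions
#' ([classify_exposure()], [summarize_lvef()], [detect_lvd()],
#' [detect_hfref()], [classify_gdmt()], [referred_to_cardiology()]) but
#' computed table-wise.
#'
#' @param dataset An [ehr_dataset()].
#' @param ids Character vector of cohort patient ids (each must have at
#'   least one treatment episode).
#' @param hierarchy A [concept_hierarchy()].
#' @param hf_rule A [value_set_rule()] for HFrEF detection.
#' @param vocab A [gdmt_vocabulary()].
#' @param lvef_threshold Strict LVD threshold in percent.
#' @param same_day_is_post Same-day imaging convention, see
#'   [summarize_lvef()].
#' @return A tibble with one row per id: exposure flags and date,
#'   `pre_assessed`, `post_assessed`, `min_post_lvef`, `lvd`, `hfref`,
#'   `beta_blocker`, `acei`, `arb`, `acei_or_arb`, `mra`, `referred`.
#' @export
phenotype_cohort <- function(dataset, ids, hierarchy,
                             hf_rule = hf_value_set_rule(),
                             vocab = gdmt_vocabulary(),
                             lvef_threshold = 50, same_day_is_post = TRUE) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  ids <- sort(unique(ids))
  exposure <- initial_exposure_dates(dataset, ids)
  members <- tibble::tibble(patient_id = ids,
                            initial_exposure_date = unname(exposure))

  ep <- dplyr::filter(dataset$treatment_episodes, .data$patient_id %in% ids)
  flags <- dplyr::summarise(
    dplyr::group_by(ep, .data$patient_id),
    anthracycline = "anthracycline" %in% .data$drug_class,
    her2 = "her2" %in% .data$drug_class,
    tki = "tki" %in% .data$drug_class,
    ici = "ici" %in% .data$drug_class,
    .groups = "drop"
  )
  members <- dplyr::left_join(members, flags, by = "patient_id")

  img <- dplyr::filter(dataset$imaging_studies, .data$patient_id %in% ids)
  if (nrow(img) > 0 && (any(img$lvef < 1) || any(img$lvef > 99))) {
    stop("implausible LVEF value(s) outside [1, 99]", call. = FALSE)
  }
  img$exposure_date <- exposure[img$patient_id]
  img$is_post <- if (same_day_is_post) img$study_date >= img$exposure_date
                 else img$study_date > img$exposure_date
  lvef_sum <- dplyr::summarise(
    dplyr::group_by(img, .data$patient_id),
    pre_assessed = any(!.data$is_post),
    post_assessed = any(.data$is_post),
    min_post_lvef = ifelse(any(.data$is_post),
                           suppressWarnings(min(.data$lvef[.data$is_post])),
                           NA_real_),
    .groups = "drop"
  )
  members <- dplyr::left_join(members, lvef_sum, by = "patient_id")
  members$pre_assessed[is.na(members$pre_assessed)] <- FALSE
  members$post_assessed[is.na(members$post_assessed)] <- FALSE
  members$lvd <- members$post_assessed &
    !is.na(members$min_post_lvef) & members$min_post_lvef < lvef_threshold

  hf_vs <- expand_value_set(hierarchy, hf_rule)
  pl <- dplyr::filter(dataset$problem_list, .data$patient_id %in% ids,
                      .data$code %in% hf_vs$codes)
  pl$exposure_date <- exposure[pl$patient_id]
  hf_hit <- pl$patient_id[is.na(pl$onset_date) | pl$onset_date >= pl$exposure_date]
  members$hfref <- members$patient_id %in% hf_hit

  meds <- dplyr::filter(dataset$medication_orders, .data$patient_id %in% ids,
                        .data$active %in% TRUE)
  gdmt_hit <- function(sel) unique(meds$patient_id[sel])
  if (nrow(meds) > 0) {
    name <- norm_ws(meds$drug_name)
    class_raw <- norm_ws(meds$pharmaceutical_class)
    bb_ids <- gdmt_hit(Reduce(`|`, lapply(norm_ws(vocab$beta_blocker_ingredients),
                                          function(i) grepl(i, name, fixed = TRUE))))
    acei_ids <- gdmt_hit(
      title_contains(meds$pharmaceutical_class, vocab$acei_phrases) |
        title_contains(meds$pharmaceutical_subclass, vocab$acei_phrases) |
        Reduce(`|`, lapply(norm_ws(vocab$acei_combinations),
                           function(cmb) grepl(cmb, name, fixed = TRUE))))
    arb_ids <- gdmt_hit(
      title_contains(meds$pharmaceutical_class, vocab$arb_phrases) |
        grepl("\\barbs?\\b", class_raw) |
        grepl("aliskiren[-/ ]valsartan", name))
    mra_ids <- gdmt_hit(title_contains(meds$pharmaceutical_subclass, vocab$mra_phrases))
  } else {
    bb_ids <- acei_ids <- arb_ids <- mra_ids <- character(0)
  }
  members$beta_blocker <- members$patient_id %in% bb_ids
  members$acei <- members$patient_id %in% acei_ids
  members$arb <- members$patient_id %in% arb_ids
  members$acei_or_arb <- members$acei | members$arb
  members$mra <- members$patient_id %in% mra_ids

  ref <- dplyr::filter(dataset$referrals, .data$patient_id %in% ids)
  cardio_ids <- unique(ref$patient_id[norm_ws(ref$specialty) == "cardiology"])
  members$referred <- members$patient_id %in% cardio_ids

  members
}
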