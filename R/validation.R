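#' Stratified sampling of charts for manual review
#'
#' Draws a uniform without-replacement sample from the flagged-positive
#' stratum and another from the flagged-negative stratum, reproducibly under
#' a seed — the design used to validate registry-detected outcomes against
#' manual chart review (e.g. 50 + 50 charts for LVD, 100 + 100 for HFrEF).
#'
#' @param flags Named logical vector: detected outcome flag per patient id.
#' @param n_pos,n_neg Stratum sample sizes; each stratum must hold at least
#'   that many patients.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return An object of class `review_sample`: `positives`, `negatives`
#'   (character vectors of ids), `seed`.
#' @export
sample_for_review <- function(flags, n_pos, n_neg, seed) {
  stopifnot(is.logical(flags), !is.null(names(flags)))
  pos <- names(flags)[flags]
  neg <- names(flags)[!flags]
  if (length(pos) < n_pos || length(neg) < n_neg) {
    stop(sprintf(paste0("stratum too small: %d flagged positive (need %d), ",
                        "%d flagged negative (need %d)"),
                 length(pos), n_pos, length(neg), n_neg), call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  structure(list(positives = sort(sample(pos, n_pos)),
                 negatives = sort(sample(neg, n_neg)),
                 seed = as.integer(seed)),
            class = "review_sample")
}

check_same_ids <- function(a, b) {
  if (!setequal(names(a), names(b))) {
    stop("rating sets cover different ids", call. = FALSE)
  }
}

#' Interrater percent agreement
#'
#' @param ratings_a,ratings_b Named vectors of labels over the same ids.
#' @return The fraction of ids on which the two raters agree.
#' @export
percent_agreement <- function(ratings_a, ratings_b) {
  check_same_ids(ratings_a, ratings_b)
  ids <- names(ratings_a)
  mean(ratings_a[ids] == ratings_b[ids])
}

#' Third-reviewer adjudication of disagreements
#'
#' Where the two primary raters agree, their shared label stands; where they
#' disagree, the third reviewer's label is final. The adjudicator must cover
#' every disagreement.
#'
#' @param ratings_a,ratings_b Named label vectors over the same ids.
#' @param ratings_c Named label vector covering (at least) all disagreement
#'   ids.
#' @return Named label vector over the same ids.
#' @export
adjudicate <- function(ratings_a, ratings_b, ratings_c) {
  check_same_ids(ratings_a, ratings_b)
  ids <- names(ratings_a)
  out <- ratings_a[ids]
  disagree <- ids[ratings_a[ids] != ratings_b[ids]]
  uncovered <- setdiff(disagree, names(ratings_c))
  if (length(uncovered) > 0) {
    stop("no adjudication for disagreement id(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  }
  out[disagree] <- ratings_c[disagree]
  out
}

#' Confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts (true/false positive/negative).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> tp =", x$tp, " fp =", x$fp,
      " fn =", x$fn, " tn =", x$tn, "\n")
  invisible(x)
}

#' Cross-tabulate detection flags against adjudicated review labels
#'
#' @param flags Named logical vector of registry-detected flags.
#' @param labels Named logical vector of adjudicated chart-review truth,
#'   covering every flagged id.
#' @return A [confusion_matrix()] with `tp + fp + fn + tn` equal to the
#'   number of ids.
#' @export
confusion_from_review <- function(flags, labels) {
  uncovered <- setdiff(names(flags), names(labels))
  if (length(uncovered) > 0) {
    stop("review labels missing for id(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  }
  lab <- labels[names(flags)]
  confusion_matrix(tp = sum(flags & lab), fp = sum(flags & !lab),
                   fn = sum(!flags & lab), tn = sum(!flags & !lab))
}

#' Reconstruct a confusion matrix from predictive values
#'
#' Back-solves the review counts from the published stratum sizes and
#' predictive values: `tp = ppv * n_flagged_pos`, `tn = npv *
#' n_flagged_neg`. Both products must be integral (to within 1e-6), so that
#' no counts are silently invented from incompatible rounded inputs.
#'
#' @param n_flagged_pos,n_flagged_neg Stratum sizes of the review sample.
#' @param ppv,npv Positive and negative predictive values as proportions.
#' @return A [confusion_matrix()].
#' @examples
#' confusion_from_predictive_values(50, 50, 0.80, 1.00)  # tp 40, fp 10, fn 0, tn 50
#' @export
confusion_from_predictive_values <- function(n_flagged_pos, n_flagged_neg,
                                             ppv, npv) {
  stopifnot(n_flagged_pos >= 1, n_flagged_neg >= 1,
            ppv >= 0, ppv <= 1, npv >= 0, npv <= 1)
  tp_raw <- ppv * n_flagged_pos
  tn_raw <- npv * n_flagged_neg
  if (abs(tp_raw - round(tp_raw)) > 1e-6 || abs(tn_raw - round(tn_raw)) > 1e-6) {
    stop(sprintf("predictive values do not yield integral counts (tp = %g, tn = %g)",
                 tp_raw, tn_raw), call. = FALSE)
  }
  tp <- round(tp_raw)
  tn <- round(tn_raw)
  confusion_matrix(tp = tp, fp = n_flagged_pos - tp,
                   fn = n_flagged_neg - tn, tn = tn)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval obtained by inverting the binomial tails (beta
#' quantile form). The lower bound is exactly 0 when there are no successes
#' and the upper bound exactly 1 when every trial succeeds.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`, both in \[0, 1\].
#' @examples
#' clopper_pearson(40, 40)  # lower bound 0.912
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("interval undefined for zero trials", call. = FALSE)
  stopifnot(successes >= 0, successes <= trials, level > 0, level < 1)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(ci_low = low, ci_high = high)
}

#' Diagnostic performance with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a Clopper-Pearson interval at `level`. A metric whose denominator is zero
#' is flagged undefined rather than reported as a sentinel.
#'
#' @param cm A [confusion_matrix()] with positive total.
#' @param level Confidence level.
#' @return A tibble with columns `metric`, `numerator`, `denominator`,
#'   `estimate`, `ci_low`, `ci_high`, `defined`.
#' @export
diagnostic_performance <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp + cm$fn + cm$tn == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  pieces <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn)
  )
  rows <- lapply(names(pieces), function(m) {
    num <- pieces[[m]][1]
    den <- pieces[[m]][2]
    if (den == 0) {
      tibble::tibble(metric = m, numerator = num, denominator = den,
                     estimate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, defined = FALSE)
    } else {
      ci <- clopper_pearson(num, den, level)
      tibble::tibble(metric = m, numerator = num, denominator = den,
                     estimate = num / den, ci_low = ci[["ci_low"]],
                     ci_high = ci[["ci_high"]], defined = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}
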