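#' Classify a single NPT response
#'
#' The test is a forced face/no-face judgement. Crossing the stimulus truth
#' with the report gives the four categories: a face correctly identified is
#' `Face`; a face missed on a face image is `Missed`; a face reported on a
#' faceless image is `Pareidolia`; a correctly rejected noise image is
#' `Noise`.
#'
#' @param face_present Logical; does the stimulus contain an embedded face?
#' @param reported_face Logical; did the participant report a face?
#' @return One of `"Face"`, `"Missed"`, `"Pareidolia"`, `"Noise"`.
#' @export
classify_response <- function(face_present, reported_face) {
  stopifnot(is.logical(face_present), is.logical(reported_face),
            !is.na(face_present), !is.na(reported_face))
  if (face_present) {
    if (reported_face) "Face" else "Missed"
  } else {
    if (reported_face) "Pareidolia" else "Noise"
  }
}

#' Score a subject's NPT session
#'
#' Counts responses per category and derives the signal-detection rates:
#' hit rate H = Face / (Face + Missed), false-alarm rate
#' F = Pareidolia / (Pareidolia + Noise). Partial sessions are scored on
#' the trials present, without imputation. d-prime is computed from the
#' counts with a log-linear correction (see [dprime()]).
#'
#' @param trials Data.frame with a `category` column (and optionally
#'   `stimulus` etc.), one row per administered trial.
#' @param variance_ratio_s Noise/signal SD ratio passed to [dprime()].
#' @return A list of class `subject_score`: `counts` (named integer vector
#'   over the four categories), `hit_rate`, `fa_rate` (NA when undefined),
#'   `d_prime`.
#' @export
score_subject <- function(trials, variance_ratio_s = 1) {
  cats <- c("Face", "Missed", "Pareidolia", "Noise")
  counts <- vapply(cats, function(k) sum(trials$category == k), integer(1))
  n_sig <- counts["Face"] + counts["Missed"]
  n_noise <- counts["Pareidolia"] + counts["Noise"]
  H <- if (n_sig > 0) unname(counts["Face"] / n_sig) else NA_real_
  F <- if (n_noise > 0) unname(counts["Pareidolia"] / n_noise) else NA_real_
  d <- if (n_sig > 0 && n_noise > 0)
    dprime_from_counts(counts["Face"], counts["Missed"],
                       counts["Pareidolia"], counts["Noise"],
                       variance_ratio_s)
  else NA_real_
  structure(list(counts = counts, hit_rate = H, fa_rate = F, d_prime = d),
            class = "subject_score")
}

#' Signal-detection d-prime with unequal-variance adjustment
#'
#' Classical d' is z(H) - z(F). When the noise and signal distributions have
#' unequal spread (SD ratio `s` = noise/signal), the adjusted index
#' \deqn{d_a = \sqrt{2/(1+s^2)}\,\bigl(z(H) - s\,z(F)\bigr)}
#' is used; `s = 1` recovers the classical d'. Rates of exactly 0 or 1 give
#' infinite z-scores, so [dprime_from_counts()] applies the log-linear
#' correction (add 0.5 to every cell, 1 to every denominator) before
#' converting to rates.
#'
#' @param H Hit rate in \[0, 1\].
#' @param F False-alarm rate in \[0, 1\].
#' @param s Noise/signal SD ratio; must be positive. Default 1.
#' @return Unitless sensitivity.
#' @export
dprime <- function(H, F, s = 1) {
  if (s <= 0) stop("variance ratio s must be positive")
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1)
  sqrt(2 / (1 + s^2)) * (qnorm(H) - s * qnorm(F))
}

#' @rdname dprime
#' @param n_face,n_missed,n_pareidolia,n_noise Category counts.
#' @export
dprime_from_counts <- function(n_face, n_missed, n_pareidolia, n_noise,
                               s = 1) {
  H <- (n_face + 0.5) / (n_face + n_missed + 1)
  F <- (n_pareidolia + 0.5) / (n_pareidolia + n_noise + 1)
  dprime(H, F, s)
}

#' Dichotomise a patient by original-NPT pareidolia count
#'
#' Patients are split on the original paper-based NPT score: 0-1 pareidolias
#' is non-pareidolic (`PDnP`), 2 or more is pareidolic (`PDP`). The
#' modified-test score is never used for grouping.
#'
#' @param original_npt_pareidolia_count Non-negative integer count.
#' @return `"PDnP"` or `"PDP"`.
#' @export
dichotomize <- function(original_npt_pareidolia_count) {
  stopifnot(original_npt_pareidolia_count >= 0)
  ifelse(original_npt_pareidolia_count >= 2, "PDP", "PDnP")
}
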