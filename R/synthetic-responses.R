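#' Behavioural profile of a subject group
#'
#' Bundles the response-rate and gaze-behaviour parameters the generator
#' uses for one group. Within face images hit + miss = 1 and within noise
#' images correct-rejection + pareidolia = 1, so the two free rates are the
#' hit rate and the pareidolia (false-alarm) rate.
#'
#' Defaults for the three study groups are provided by
#' [default_group_profiles()]: healthy controls respond accurately with few
#' pareidolias; non-pareidolic patients (PDnP) miss slightly more faces;
#' pareidolic patients (PDP) report faces on a large fraction of noise
#' images and dwell longer on AOIs.
#'
#' @param group Group label (e.g. `"HC"`, `"PDnP"`, `"PDP"`).
#' @param hit_rate Probability of reporting a face on a face image.
#' @param pareidolia_rate Probability of reporting a face on a noise image.
#' @param fixation_mean_ms,fixation_sd_ms Fixation-duration distribution.
#' @param response_median_s Median per-image viewing time, s; per-trial
#'   response times are drawn log-normally around it.
#' @param blink_rate_hz Blink events per second of viewing.
#' @param long_saccade_prob Mixture weight of long (>= 4 deg) saccades.
#' @param original_npt_pareidolias Pareidolia count on the original
#'   paper-based NPT used for dichotomisation (PDP/PDnP assignment draws
#'   around this).
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(group, hit_rate, pareidolia_rate,
                          fixation_mean_ms = 400, fixation_sd_ms = 80,
                          response_median_s = 9, blink_rate_hz = 0.1,
                          long_saccade_prob = 0.4,
                          original_npt_pareidolias = 0) {
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            pareidolia_rate >= 0, pareidolia_rate <= 1,
            fixation_mean_ms > 0, fixation_sd_ms >= 0,
            response_median_s > 0, blink_rate_hz >= 0,
            long_saccade_prob >= 0, long_saccade_prob <= 1)
  structure(list(group = group, hit_rate = hit_rate,
                 pareidolia_rate = pareidolia_rate,
                 fixation_mean_ms = fixation_mean_ms,
                 fixation_sd_ms = fixation_sd_ms,
                 response_median_s = response_median_s,
                 blink_rate_hz = blink_rate_hz,
                 long_saccade_prob = long_saccade_prob,
                 original_npt_pareidolias = original_npt_pareidolias),
            class = "group_profile")
}

#' @rdname group_profile
#' @export
default_group_profiles <- function() {
  list(
    HC   = group_profile("HC",   hit_rate = 0.85, pareidolia_rate = 0.02,
                         fixation_mean_ms = 350, response_median_s = 8.9,
                         original_npt_pareidolias = 0),
    PDnP = group_profile("PDnP", hit_rate = 0.80, pareidolia_rate = 0.02,
                         fixation_mean_ms = 420, response_median_s = 9.2,
                         original_npt_pareidolias = 1),
    PDP  = group_profile("PDP",  hit_rate = 0.80, pareidolia_rate = 0.40,
                         fixation_mean_ms = 450, response_median_s = 9.2,
                         original_npt_pareidolias = 24)
  )
}

#' Simulate forced-choice responses for one subject
#'
#' Draws one reported answer per stimulus from the group's hit and
#' pareidolia rates and classifies it against the face-present flag with
#' [classify_response()]. Response times are log-normal with the group's
#' median and a 0.25 log-SD, truncated to the 30-s deadline.
#'
#' @param profile A [group_profile()].
#' @param stimulus_set A [generate_stimulus_set()] result.
#' @param seed Integer RNG seed.
#' @return A data.frame of trial records: `stimulus`, `face_present`,
#'   `reported_face`, `category`, `response_time_ms`.
#' @export
simulate_responses <- function(profile, stimulus_set, seed = 1L) {
  stopifnot(inherits(profile, "group_profile"))
  local_rng(seed)
  n <- length(stimulus_set)
  face <- vapply(stimulus_set, `[[`, logical(1), "face_present")
  p_report <- ifelse(face, profile$hit_rate, profile$pareidolia_rate)
  reported <- runif(n) < p_report
  rt <- pmin(30000, 1000 * rlnorm(n, log(profile$response_median_s), 0.25))
  rt <- pmax(rt, 1500)
  data.frame(
    stimulus = vapply(stimulus_set, `[[`, character(1), "id"),
    face_present = face,
    reported_face = reported,
    category = mapply(classify_response, face, reported),
    response_time_ms = rt,
    stringsAsFactors = FALSE
  )
}
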