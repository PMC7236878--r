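# Clinical outcome catalogue for the synthetic LGMD2I cohort.
#
# lo/hi span the published baseline ranges of the trial cohort this package
# emulates (e.g. two-minute walk distance 17-233 m, intramuscular fat fraction
# 36.2-90.3%). direction is the monotone association with the latent disease
# severity: +1 increases with severity (timed tests, fat fraction), -1
# decreases (walk distance, strength, pulmonary function, lean mass), 0 is
# unassociated (total body fat, which tracked severity only weakly in the
# trial). skew > 1 concentrates values at the mild end with a long severe
# tail, as timed function tests show. repeatable marks the five outcomes
# re-tested on a second consecutive day.
outcome_catalog <- function() {
  oc <- rbind(
    data.frame(outcome = "2MWD",      lo = 17,   hi = 233,  direction = -1, skew = 1, noise_frac = 0.05, repeatable = TRUE),
    data.frame(outcome = "10MWR",     lo = 2.8,  hi = 40.4, direction =  1, skew = 3, noise_frac = 0.05, repeatable = TRUE),
    data.frame(outcome = "4SC",       lo = 1.7,  hi = 49.8, direction =  1, skew = 3, noise_frac = 0.05, repeatable = TRUE),
    data.frame(outcome = "TUG",       lo = 6,    hi = 80,   direction =  1, skew = 3, noise_frac = 0.05, repeatable = TRUE),
    data.frame(outcome = "PUL",       lo = 30,   hi = 42,   direction = -1, skew = 2, noise_frac = 0.05, repeatable = TRUE),
    data.frame(outcome = "MMT",       lo = 145,  hi = 262,  direction = -1, skew = 1, noise_frac = 0.05, repeatable = FALSE),
    data.frame(outcome = "FVC",       lo = 1.98, hi = 5.94, direction = -1, skew = 1, noise_frac = 0.05, repeatable = FALSE),
    data.frame(outcome = "FEV1",      lo = 1.53, hi = 4.72, direction = -1, skew = 1, noise_frac = 0.05, repeatable = FALSE),
    data.frame(outcome = "MIP",       lo = 26,   hi = 124,  direction = -1, skew = 1, noise_frac = 0.08, repeatable = FALSE),
    data.frame(outcome = "MEP",       lo = 31,   hi = 154,  direction = -1, skew = 1, noise_frac = 0.08, repeatable = FALSE),
    data.frame(outcome = "DEXA_lean", lo = 22.7, hi = 50.5, direction = -1, skew = 1, noise_frac = 0.10, repeatable = FALSE),
    data.frame(outcome = "DEXA_fat",  lo = 15.7, hi = 45.8, direction =  0, skew = 1, noise_frac = 0.25, repeatable = FALSE),
    data.frame(outcome = "MRI_FF",    lo = 36.2, hi = 90.3, direction =  1, skew = 1, noise_frac = 0.04, repeatable = FALSE))
  oc
}

#' Effect specification for the synthetic cohort
#'
#' Controls the association structure and noise of [generate_cohort()]. All
#' noise parameters are fractions of each outcome's plausible range.
#'
#' @param directions optional named integer vector overriding the monotone
#'   direction (severity association) of individual outcomes; values must be
#'   -1, 0 or 1.
#' @param noise_scale multiplier on the per-outcome between-subject noise SD.
#' @param retest_frac_base,retest_frac_gain day-2 test-retest noise SD as a
#'   fraction of range: `base + gain * severity`, so retest spread grows with
#'   disease severity (heteroscedastic, as the severe end of timed tests
#'   shows).
#' @param drift_frac systematic follow-up drift as a fraction of range
#'   (positive = toward the severe end); 0 emulates a stable 4-month lead-in.
#' @param followup_frac visit-to-visit noise SD as a fraction of range.
#' @return An `effect_spec` list.
#' @export
cohort_effect_spec <- function(directions = NULL, noise_scale = 1,
                               retest_frac_base = 0.02, retest_frac_gain = 0.06,
                               drift_frac = 0, followup_frac = 0.02) {
  oc <- outcome_catalog()
  dir <- stats::setNames(oc$direction, oc$outcome)
  if (!is.null(directions)) {
    if (is.null(names(directions)) || !all(names(directions) %in% oc$outcome))
      stop("directions must be named by outcome")
    if (!all(directions %in% c(-1, 0, 1)))
      stop("invalid direction flags: each must be -1, 0 or 1 (monotone or null)")
    dir[names(directions)] <- directions
  }
  if (noise_scale < 0 || retest_frac_base < 0 || retest_frac_gain < 0 ||
      followup_frac < 0)
    stop("noise fractions must be nonnegative")
  structure(list(directions = dir, noise_scale = noise_scale,
                 retest_frac_base = retest_frac_base,
                 retest_frac_gain = retest_frac_gain,
                 drift_frac = drift_frac, followup_frac = followup_frac),
            class = "effect_spec")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic clinical cohort
#'
#' Draws a latent per-participant disease severity and produces a long-format
#' outcome table shaped like a two-visit trial lead-in: baseline and follow-up
#' visits, with the five ambulatory/upper-limb outcomes repeated on a second
#' consecutive day at follow-up for repeatability analysis. Outcome values
#' move monotonically with severity per the effect specification, day-2
#' repeats add heteroscedastic test-retest noise, and everything is clipped to
#' the plausible published ranges.
#'
#' @param n_participants number of participants (>= 3).
#' @param effect_spec a [cohort_effect_spec()].
#' @param seed integer RNG seed.
#' @return A `cohort_table` data frame with columns `participant_id`, `visit`
#'   (`baseline`/`followup`), `day` (1 or 2), `sex`, `age_years`, `bmi`,
#'   `ck_UL`, `genotype_class`, `outcome`, `value`. The latent severities and
#'   the effect spec are attached as attribute `truth`.
#' @export
generate_cohort <- function(n_participants,
                            effect_spec = cohort_effect_spec(),
                            seed = 1L) {
  if (!inherits(effect_spec, "effect_spec"))
    stop("effect_spec must come from cohort_effect_spec()")
  if (length(n_participants) != 1L || n_participants < 3)
    stop("n_participants must be at least 3")
  n <- as.integer(n_participants)
  es <- effect_spec
  oc <- outcome_catalog()
  set.seed(as.integer(seed))

  sev <- stats::runif(n)
  demo <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(12, 7) / 19),
    age_years = round(stats::runif(n, 19, 67)),
    bmi = round(stats::runif(n, 15.0, 30.3), 1),
    ck_UL = round(exp(stats::runif(n, log(202), log(5668)))),
    genotype_class = sample(c("homozygous", "compound-het"), n,
                            replace = TRUE, prob = c(15, 4) / 19))

  rows <- vector("list", nrow(oc))
  for (i in seq_len(nrow(oc))) {
    o <- oc[i, ]
    rng <- o$hi - o$lo
    dirn <- es$directions[[o$outcome]]
    u <- switch(as.character(dirn),
                "1" = sev, "-1" = 1 - sev, "0" = stats::runif(n))
    base <- o$lo + rng * u^o$skew
    sd_b <- o$noise_frac * rng * es$noise_scale
    b1 <- clip(base + stats::rnorm(n, sd = sd_b), o$lo, o$hi)
    f1 <- clip(b1 + es$drift_frac * rng * ifelse(dirn == 0, 1, dirn) +
                 stats::rnorm(n, sd = es$followup_frac * rng), o$lo, o$hi)
    out <- list(
      data.frame(participant_id = demo$participant_id, visit = "baseline",
                 day = 1L, outcome = o$outcome, value = b1),
      data.frame(participant_id = demo$participant_id, visit = "followup",
                 day = 1L, outcome = o$outcome, value = f1))
    if (o$repeatable) {
      sd_r <- (es$retest_frac_base + es$retest_frac_gain * sev) * rng
      f2 <- clip(f1 + stats::rnorm(n, sd = sd_r), o$lo, o$hi)
      out <- c(out, list(
        data.frame(participant_id = demo$participant_id, visit = "followup",
                   day = 2L, outcome = o$outcome, value = f2)))
    }
    rows[[i]] <- do.call(rbind, out)
  }
  tab <- do.call(rbind, rows)
  tab <- merge(tab, demo, by = "participant_id", sort = FALSE)
  tab <- tab[order(tab$participant_id, tab$outcome, tab$visit, tab$day),
             c("participant_id", "visit", "day", "sex", "age_years", "bmi",
               "ck_UL", "genotype_class", "outcome", "value")]
  rownames(tab) <- NULL
  attr(tab, "truth") <- list(severity = stats::setNames(sev, demo$participant_id),
                             effect_spec = es, seed = as.integer(seed))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Manual muscle testing sum score
#'
#' Sums adapted 12-point MRC strength grades over the tested muscle groups.
#' The standard protocol grades 22 muscle groups from 1 to 12, so the maximum
#' possible sum score is 264 and the minimum 22.
#'
#' @param grades numeric vector of per-muscle-group grades.
#' @param max_grade maximum grade of the scale (default 12).
#' @return The integer sum score.
#' @export
mmt_sum <- function(grades, max_grade = 12) {
  if (length(grades) == 0) stop("no grades supplied")
  if (any(!is.finite(grades)) || any(grades < 1) || any(grades > max_grade))
    stop("each grade must lie in [1, ", max_grade, "]")
  sum(grades)
}

#' Demographic summary of the 19-participant LGMD2I trial cohort
#'
#' Per-participant sex, age, body-mass index, age at symptom onset, the two
#' FKRP pathogenic variants, and serum creatine kinase, as published in the
#' trial's demographic summary. Used as a transcription fixture and to scale
#' the synthetic cohort.
#'
#' @return data frame with 19 rows and columns `participant`, `sex`,
#'   `age_years`, `bmi`, `onset_age_years`, `allele1`, `allele2`, `ck_UL`.
#' @export
lgmd2i_demographics <- function() {
  path <- system.file("extdata", "lgmd2i_demographics.csv",
                      package = "dixonmuscle", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
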