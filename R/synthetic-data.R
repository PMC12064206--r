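#' Define a simulation profile for one well-being group
#'
#' A group profile describes how one respondent group uses its leisure time:
#' how many respondents it has, the per-activity probability that a
#' respondent records that activity on a given diary day, the lognormal
#' duration scale, and a per-day-type multiplier that shifts participation
#' between weekdays and weekends.
#'
#' @param group_label `"high_swb"` or `"low_swb"`.
#' @param n_respondents Number of respondents in the group (>= 0).
#' @param activity_probs Named or unnamed numeric vector of participation
#'   probabilities in `[0, 1]`, one per activity.
#' @param minutes_mean,minutes_sd Mean and standard deviation (minutes, on
#'   the natural scale) of the lognormal duration draw; `minutes_mean > 0`.
#' @param day_type_shift Named numeric vector `c(weekday = , weekend = )` of
#'   multiplicative adjustments applied to `activity_probs`; shifted
#'   probabilities are clipped to `[0, 1]`.
#'
#' @return A `group_profile` list.
#' @examples
#' group_profile("high_swb", 10, activity_probs = rep(0.5, 5))
#' @export
group_profile <- function(group_label,
                          n_respondents,
                          activity_probs,
                          minutes_mean = 60,
                          minutes_sd = 45,
                          day_type_shift = c(weekday = 1, weekend = 1)) {
  group_label <- match.arg(group_label, c("high_swb", "low_swb"))
  if (length(activity_probs) == 0L) {
    abort("`activity_probs` must be non-empty (field: activity_probs).")
  }
  if (!is.numeric(activity_probs) || anyNA(activity_probs) ||
      any(activity_probs < 0 | activity_probs > 1)) {
    abort("`activity_probs` must lie in [0, 1] (field: activity_probs).")
  }
  assert_scalar_number(n_respondents, "n_respondents", lower = 0)
  assert_scalar_number(minutes_mean, "minutes_mean", lower = 1e-9)
  assert_scalar_number(minutes_sd, "minutes_sd", lower = 0)
  if (!all(c("weekday", "weekend") %in% names(day_type_shift))) {
    abort("`day_type_shift` needs named entries for weekday and weekend (field: day_type_shift).")
  }
  structure(
    list(
      group_label = group_label,
      n_respondents = as.integer(n_respondents),
      activity_probs = activity_probs,
      minutes_mean = minutes_mean,
      minutes_sd = minutes_sd,
      day_type_shift = day_type_shift[c("weekday", "weekend")]
    ),
    class = "group_profile"
  )
}

default_score_rules <- function() {
  list(
    high_swb = list(swb = c(1L, 4L), health = c(1L, 2L)),
    low_swb = list(swb = c(5L, 7L), health = c(3L, 5L))
  )
}

#' Configure the synthetic diary generator
#'
#' Assembles a full simulation configuration: the two group profiles, the
#' activity universe, the well-being/health score ranges used to label each
#' group, and the seed. The defaults emulate the study conditions the
#' package is designed around: 241 respondents per group over a 49-activity
#' leisure universe, with the high well-being group participating broadly
#' (higher-entropy profile, weekend participation boost) and the low
#' well-being group concentrating on a few mostly solitary activities.
#'
#' @param n_high,n_low Respondents per group (defaults 241 each).
#' @param seed Integer seed stored with the configuration and used by
#'   [simulate_diaries()] unless overridden.
#' @param profiles Optional list of two [group_profile()]s (one
#'   `"high_swb"`, one `"low_swb"`); defaults are derived from
#'   [default_activities()].
#' @param score_rules Per-group inclusive `(swb, health)` score ranges; the
#'   high group must sit within SWB 1-4 and health 1-2, the low group
#'   within SWB 5-7 and health 3-5 (on both scales higher = worse).
#'
#' @return A `leisure_sim_config` list.
#' @examples
#' cfg <- leisure_sim_config(n_high = 20, n_low = 20, seed = 1)
#' cfg$n_activities
#' @export
leisure_sim_config <- function(n_high = 241,
                               n_low = 241,
                               seed = 1L,
                               profiles = NULL,
                               score_rules = default_score_rules()) {
  if (is.null(profiles)) {
    acts <- default_activities()
    profiles <- list(
      high_swb = group_profile(
        "high_swb", n_high,
        activity_probs = setNames(acts$p_high, acts$activity_code),
        day_type_shift = c(weekday = 1, weekend = 1.15)
      ),
      low_swb = group_profile(
        "low_swb", n_low,
        activity_probs = setNames(acts$p_low, acts$activity_code),
        day_type_shift = c(weekday = 1, weekend = 0.95)
      )
    )
  } else {
    labels <- vapply(profiles, function(p) p$group_label, character(1))
    if (!setequal(labels, c("high_swb", "low_swb"))) {
      abort("`profiles` must contain one high_swb and one low_swb profile.")
    }
    names(profiles) <- labels
  }
  n_act <- length(profiles$high_swb$activity_probs)
  if (n_act < 2L) {
    abort("The activity universe must contain at least 2 activities (field: activity_probs).")
  }
  if (length(profiles$low_swb$activity_probs) != n_act) {
    abort("Both profiles must cover the same number of activities (field: activity_probs).")
  }

  sr <- score_rules
  ok_high <- sr$high_swb$swb[1] >= 1 && sr$high_swb$swb[2] <= 4 &&
    sr$high_swb$health[1] >= 1 && sr$high_swb$health[2] <= 2
  ok_low <- sr$low_swb$swb[1] >= 5 && sr$low_swb$swb[2] <= 7 &&
    sr$low_swb$health[1] >= 3 && sr$low_swb$health[2] <= 5
  if (!ok_high || !ok_low) {
    abort(paste0(
      "`score_rules` must keep the high group within SWB 1-4 / health 1-2 ",
      "and the low group within SWB 5-7 / health 3-5 (field: score_rules)."
    ))
  }

  structure(
    list(
      n_activities = n_act,
      profiles = profiles,
      seed = as.integer(seed),
      score_rules = score_rules
    ),
    class = "leisure_sim_config"
  )
}

activity_labels <- function(config) {
  nm <- names(config$profiles$high_swb$activity_probs)
  if (is.null(nm)) sprintf("activity_%02d", seq_len(config$n_activities)) else nm
}

# Lognormal parameters matched to a natural-scale mean and sd.
lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

simulate_group <- function(profile, config, prefix) {
  n <- profile$n_respondents
  acts <- activity_labels(config)
  n_act <- length(acts)
  empty <- tibble(
    person_id = character(), age = integer(), sex = character(),
    education = character(), swb_score = integer(), health_score = integer(),
    leisure_satisfaction = integer(), day_type = character(),
    activity_code = character(), minutes = double()
  )
  if (n == 0L) {
    return(empty)
  }
  rule <- config$score_rules[[profile$group_label]]
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  age <- sample(10:19, n, replace = TRUE)
  respondents <- tibble(
    person_id = ids,
    age = age,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.45, 0.55)),
    education = dplyr::case_when(
      age <= 12 ~ "elementary",
      age <= 15 ~ "middle",
      TRUE ~ "high"
    ),
    swb_score = sample(seq(rule$swb[1], rule$swb[2]), n, replace = TRUE),
    health_score = sample(seq(rule$health[1], rule$health[2]), n, replace = TRUE),
    leisure_satisfaction = sample(1:5, n, replace = TRUE,
                                  prob = c(0.11, 0.21, 0.32, 0.25, 0.11))
  )
  ln <- lnorm_params(profile$minutes_mean, profile$minutes_sd)
  days <- purrr::map(c("weekday", "weekend"), function(day) {
    p_day <- pmin(1, pmax(0, profile$activity_probs * profile$day_type_shift[[day]]))
    inc <- matrix(runif(n * n_act) < rep(p_day, each = n), nrow = n)
    idx <- which(inc, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(empty)
    }
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    minutes <- pmax(5, 5 * round(rlnorm(nrow(idx), ln$meanlog, ln$sdlog) / 5))
    dplyr::bind_cols(
      respondents[idx[, 1L], ],
      tibble(day_type = day, activity_code = acts[idx[, 2L]], minutes = minutes)
    )
  })
  bind_rows(days) %>%
    arrange(.data$person_id, .data$day_type, match(.data$activity_code, acts))
}

#' Generate synthetic time-use diaries
#'
#' Draws one weekday and one weekend diary per respondent. Each activity is
#' included independently with its profile probability (adjusted by the
#' day-type shift); durations are lognormal, rounded to 5-minute slots;
#' well-being and health scores are uniform within the group's score range.
#' The result is deterministic given the seed.
#'
#' @param config A [leisure_sim_config()].
#' @param seed Seed for the draw; defaults to `config$seed`.
#'
#' @return A tibble of diary records with columns `person_id`, `age`, `sex`,
#'   `education`, `swb_score`, `health_score`, `leisure_satisfaction`,
#'   `day_type`, `activity_code`, `minutes`.
#' @examples
#' cfg <- leisure_sim_config(n_high = 5, n_low = 5, seed = 42)
#' simulate_diaries(cfg)
#' @export
simulate_diaries <- function(config, seed = NULL) {
  if (!inherits(config, "leisure_sim_config")) {
    abort("`config` must be created by leisure_sim_config().")
  }
  seed <- seed %||% config$seed
  with_seed(seed, {
    bind_rows(
      simulate_group(config$profiles$high_swb, config, "H"),
      simulate_group(config$profiles$low_swb, config, "L")
    )
  })
}

#' Inject data-quality defects into diary records
#'
#' Corrupts a clean record set with one named defect so that the ingestion
#' filters can be exercised: duplicated rows, missing well-being scores, or
#' respondents outside the 10-19 age range.
#'
#' @param records A diary tibble as produced by [simulate_diaries()].
#' @param kind One of `"duplicates"`, `"missing_scores"`,
#'   `"out_of_age_range"`.
#' @param rate Fraction of rows to corrupt; `round(rate * nrow)` rows are
#'   affected (at least one when `rate > 0`). `rate = 0` returns the input
#'   unchanged.
#' @param seed Optional seed for the row sample.
#'
#' @return The corrupted records tibble.
#' @export
inject_pathologies <- function(records, kind, rate = 0.05, seed = NULL) {
  kind <- match.arg(kind, c("duplicates", "missing_scores", "out_of_age_range"))
  assert_scalar_number(rate, "rate", lower = 0, upper = 1)
  n <- nrow(records)
  if (rate == 0 || n == 0L) {
    return(records)
  }
  k <- max(1L, as.integer(round(rate * n)))
  with_seed(seed, {
    rows <- sample.int(n, k)
    switch(kind,
      duplicates = bind_rows(records, records[rows, ]),
      missing_scores = {
        records$swb_score[rows] <- NA_integer_
        records
      },
      out_of_age_range = {
        records$age[rows] <- sample(c(5:9, 20:24), k, replace = TRUE)
        records
      }
    )
  })
}

#' Write diary records to the canonical CSV schema
#'
#' @param records Diary tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
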