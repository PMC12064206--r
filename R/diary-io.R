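diary_schema <- c(
  "person_id", "age", "sex", "education", "swb_score", "health_score",
  "leisure_satisfaction", "day_type", "activity_code", "minutes"
)

#' Read a long-format time-use diary CSV
#'
#' Reads the canonical diary schema (`person_id, age, sex, education,
#' swb_score, health_score, leisure_satisfaction, day_type, activity_code,
#' minutes`). Malformed rows are not silently dropped: they are collected
#' into a rejects report retrievable with [diary_rejects()], each with a
#' reason. Score fields may be empty (they become `NA` and are handled at
#' grouping time); structurally broken rows (non-numeric minutes or age,
#' invalid day type, missing identifiers) are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble of typed diary records, with a `rejects` attribute.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read diary file: '%s' does not exist.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(diary_schema, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Diary file is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[diary_schema]

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  minutes <- num_or_na(raw$minutes)
  age <- num_or_na(raw$age)
  reason <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(raw$person_id) | raw$person_id == "", "missing person_id")
  reason <- bad(is.na(raw$activity_code) | raw$activity_code == "", "missing activity_code")
  reason <- bad(!is.na(raw$minutes) & raw$minutes != "" & is.na(minutes), "non-numeric minutes")
  reason <- bad(is.na(minutes), "missing minutes")
  reason <- bad(minutes < 0, "negative minutes")
  reason <- bad(!is.na(raw$age) & raw$age != "" & is.na(age), "non-numeric age")
  reason <- bad(is.na(age), "missing age")
  reason <- bad(!raw$day_type %in% c("weekday", "weekend"), "invalid day_type")

  keep <- is.na(reason)
  int_or_na <- function(x) suppressWarnings(as.integer(round(as.numeric(x))))
  records <- tibble(
    person_id = raw$person_id[keep],
    age = as.integer(round(age[keep])),
    sex = raw$sex[keep],
    education = raw$education[keep],
    swb_score = int_or_na(raw$swb_score[keep]),
    health_score = int_or_na(raw$health_score[keep]),
    leisure_satisfaction = int_or_na(raw$leisure_satisfaction[keep]),
    day_type = raw$day_type[keep],
    activity_code = raw$activity_code[keep],
    minutes = minutes[keep]
  )
  rejects <- dplyr::bind_cols(raw[!keep, ], tibble(reason = reason[!keep]))
  if (nrow(rejects) > 0L) {
    warn(sprintf("%d malformed diary row(s) moved to the rejects report.", nrow(rejects)))
  }
  attr(records, "rejects") <- rejects
  records
}

#' Retrieve the rejects report attached by [read_diary()]
#'
#' @param records Tibble returned by [read_diary()].
#' @return A tibble of rejected raw rows with a `reason` column.
#' @export
diary_rejects <- function(records) {
  attr(records, "rejects") %||%
    tibble(!!!setNames(rep(list(character()), length(diary_schema)), diary_schema),
           reason = character())
}

#' Assign each record to a well-being group
#'
#' Applies the joint grouping rule on the two survey scales (both scored so
#' that higher = worse): `high_swb` requires a subjective well-being score
#' in 1-4 *and* a health score in 1-2; `low_swb` requires well-being 5-7
#' *and* health 3-5. Every other combination — including missing scores —
#' is `excluded`, which keeps the two groups disjoint.
#'
#' @param records Diary tibble with `swb_score` and `health_score` columns.
#' @return `records` with an added `swb_group` column
#'   (`high_swb` / `low_swb` / `excluded`).
#' @examples
#' assign_swb_group(tibble::tibble(swb_score = c(1, 7, 2),
#'                                 health_score = c(1, 5, 4)))
#' @export
assign_swb_group <- function(records) {
  records %>%
    mutate(swb_group = dplyr::case_when(
      is.na(.data$swb_score) | is.na(.data$health_score) ~ "excluded",
      .data$swb_score >= 1 & .data$swb_score <= 4 &
        .data$health_score >= 1 & .data$health_score <= 2 ~ "high_swb",
      .data$swb_score >= 5 & .data$swb_score <= 7 &
        .data$health_score >= 3 & .data$health_score <= 5 ~ "low_swb",
      TRUE ~ "excluded"
    ))
}

#' Apply the study's inclusion and exclusion filters
#'
#' Keeps respondents aged 10-19 inclusive, drops rows with missing
#' mandatory fields (`person_id`, `age`, `day_type`, `activity_code`,
#' `minutes`), and removes exact duplicates on the
#' `(person_id, day_type, activity_code)` triple, keeping the first
#' occurrence. Filters never raise; removals are tallied per rule in a
#' report retrievable with [filter_report()].
#'
#' @param records Diary tibble.
#' @return Filtered tibble with a `filter_report` attribute.
#' @export
apply_inclusion_filters <- function(records) {
  n0 <- nrow(records)
  mandatory_ok <- !is.na(records$person_id) & !is.na(records$age) &
    !is.na(records$day_type) & !is.na(records$activity_code) &
    !is.na(records$minutes)
  r1 <- records[mandatory_ok, ]
  n_missing <- n0 - nrow(r1)

  age_ok <- r1$age >= 10 & r1$age <= 19
  r2 <- r1[age_ok, ]
  n_age <- nrow(r1) - nrow(r2)

  r3 <- r2 %>% distinct(.data$person_id, .data$day_type, .data$activity_code,
                        .keep_all = TRUE)
  n_dup <- nrow(r2) - nrow(r3)

  report <- tibble(
    rule = c("missing_mandatory_field", "age_out_of_range", "duplicate_response"),
    removed = c(n_missing, n_age, n_dup)
  )
  attr(r3, "filter_report") <- report
  attr(r3, "rejects") <- attr(records, "rejects")
  r3
}

#' Retrieve the filter report attached by [apply_inclusion_filters()]
#'
#' @param records Tibble returned by [apply_inclusion_filters()].
#' @return A tibble with columns `rule` and `removed`.
#' @export
filter_report <- function(records) {
  attr(records, "filter_report") %||%
    tibble(rule = character(), removed = integer())
}

#' Build a person-by-activity incidence matrix
#'
#' Constructs the 2-mode structure for one `(group, day type)` stratum:
#' a binary membership matrix (1 if the person recorded the activity at
#' least once on that day type) and a minute-weighted matrix (total minutes
#' summed over records). Activities with zero participants never appear as
#' columns; persons with no records in the stratum never appear as rows.
#'
#' @param records Filtered diary tibble; if it lacks a `swb_group` column,
#'   [assign_swb_group()] is applied first.
#' @param group_label `"high_swb"` or `"low_swb"`.
#' @param day_type `"weekday"` or `"weekend"`.
#' @return An `incidence_matrix` object with elements `binary`, `weights`
#'   (persons x activities matrices), `persons`, `activities`,
#'   `group_label`, `day_type`, and a logical `empty` flag.
#' @export
build_incidence <- function(records, group_label, day_type) {
  group_label <- match.arg(group_label, c("high_swb", "low_swb"))
  day_type <- match.arg(day_type, c("weekday", "weekend"))
  if (!"swb_group" %in% names(records)) {
    records <- assign_swb_group(records)
  }
  sel <- records %>%
    filter(.data$swb_group == group_label, .data$day_type == !!day_type)

  if (nrow(sel) == 0L) {
    warn(sprintf("No records for %s/%s: returning an empty incidence matrix.",
                 group_label, day_type))
    out <- list(
      binary = matrix(0, 0, 0), weights = matrix(0, 0, 0),
      persons = character(), activities = character(),
      group_label = group_label, day_type = day_type, empty = TRUE
    )
    return(structure(out, class = "incidence_matrix"))
  }

  persons <- sort(unique(sel$person_id))
  activities <- sort(unique(sel$activity_code))
  weights <- matrix(0, length(persons), length(activities),
                    dimnames = list(persons, activities))
  agg <- sel %>%
    group_by(.data$person_id, .data$activity_code) %>%
    summarise(minutes = sum(.data$minutes), .groups = "drop")
  weights[cbind(match(agg$person_id, persons),
                match(agg$activity_code, activities))] <- agg$minutes
  binary <- (weights > 0) * 1

  structure(
    list(
      binary = binary, weights = weights,
      persons = persons, activities = activities,
      group_label = group_label, day_type = day_type, empty = FALSE
    ),
    class = "incidence_matrix"
  )
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf(
    "<incidence_matrix> %s / %s: %d persons x %d activities (%d cells filled)\n",
    x$group_label, x$day_type, length(x$persons), length(x$activities),
    sum(x$binary)
  ))
  invisible(x)
}
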