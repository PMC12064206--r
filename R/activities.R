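#' Default leisure-activity universe
#'
#' The 49 leisure-activity labels used by the default synthetic-diary
#' profiles, together with the per-group participation probabilities that
#' drive the generator. The labels follow the common time-use-survey leisure
#' taxonomy (sleep and rest, socialising, media and screen use, games,
#' culture, sports, and related travel). Probabilities are organised in
#' tiers: the high well-being profile spreads participation across many
#' activities (core social/media items plus a broad middle tier), while the
#' low well-being profile concentrates participation on a handful of
#' solitary, screen-centred items and leaves most of the universe rare.
#'
#' @return A tibble with columns `activity_code`, `p_high`, `p_low`.
#' @examples
#' default_activities()
#' @export
default_activities <- function() {
  core_high <- c(
    "Sleeping", "Face-to-face socializing", "Video/audio calls",
    "Community participation", "Watching video", "Mobile games",
    "Doing nothing and resting",
    "Travel related to cultural and leisure activities",
    "Watching live TV", "PC games"
  )
  mid_high <- c(
    "Sleeplessness", "Text messages or e-mails",
    "Socializing via social networking services",
    "Attendance at religious meetings/gatherings",
    "Travel related to socializing and community participation",
    "Cultural and tourism activities",
    "Listening to audio devices (CD, tape, record etc.)",
    "Reading books", "Searching the Internet", "Group games/play",
    "Ball games", "Hobbies", "Personal exercises", "Walking/strolling",
    "Purchasing goods online", "Purchasing goods offline", "Pet care",
    "Drinking alcohol/social drinking", "Other activities related to leisure",
    "Board games", "Watching sports events",
    "Attending performances/concerts", "Fitness training", "Swimming"
  )
  light_high <- c(
    "Personal religious practice", "Attending courses for leisure",
    "Biking and inline skating", "Playing musical instruments", "Singing",
    "Dancing", "Team sports", "Hiking/climbing",
    "Visiting museums/exhibitions"
  )
  rare_high <- c(
    "Drawing/painting", "Crafts", "Photography", "Creative writing",
    "Winter sports", "Gardening"
  )
  activity <- c(core_high, mid_high, light_high, rare_high)
  stopifnot(length(activity) == 49L, !anyDuplicated(activity))

  p_high <- setNames(
    rep(c(0.80, 0.45, 0.30, 0.08),
        times = c(length(core_high), length(mid_high),
                  length(light_high), length(rare_high))),
    activity
  )

  core_low <- c(
    "Sleeping", "Face-to-face socializing", "Watching live TV",
    "Watching video", "Purchasing goods offline"
  )
  mid_low <- c(
    "Community participation", "Searching the Internet",
    "Doing nothing and resting", "Video/audio calls", "Group games/play",
    "Mobile games"
  )
  light_low <- c(
    "Text messages or e-mails", "Socializing via social networking services",
    "Reading books", "PC games",
    "Listening to audio devices (CD, tape, record etc.)", "Hobbies",
    "Personal exercises", "Walking/strolling", "Purchasing goods online",
    "Pet care", "Sleeplessness", "Other activities related to leisure"
  )
  p_low <- setNames(rep(0.03, length(activity)), activity)
  p_low[core_low] <- 0.75
  p_low[mid_low] <- 0.32
  p_low[light_low] <- 0.10

  tibble(
    activity_code = activity,
    p_high = unname(p_high),
    p_low = unname(p_low[activity])
  )
}
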