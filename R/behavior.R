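## per-bird raw exploration rates (per minute) from one assay log
assay_rates <- function(log) {
  ev <- log$events
  c(quarters = length(unique(ev$arg[ev$event == "enter_quarter"])) / log$duration,
    perches  = length(unique(ev$arg[ev$event == "land_perch"])) / log$duration,
    moves    = sum(ev$event == "move") / log$duration,
    hops     = sum(ev$event == "hop") / log$duration,
    flights  = sum(ev$event == "flight") / log$duration)
}

#' Exploration scores for a cohort of assays
#'
#' Five variables are scored per bird: distinct quarters visited (max 4),
#' distinct perches used (max 6), location changes, hops, and flight
#' incidents. Each is normalised for assay duration (count / minutes) and
#' expressed relative to the best rate in the cohort, giving sub-scores in
#' \[0, 1\] (0 when the cohort best is 0); the exploration total is their
#' sum, in \[0, 5\]. A bird that visited 3 perches in 20 minutes scores
#' (3/20) / (6/10) = 0.25 on the perch variable against a cohort best of 6
#' perches in 10 minutes.
#'
#' @param logs list of [assay_log()] objects (the cohort).
#' @return data.frame: one row per bird with the five sub-scores,
#'   `exploration` (their sum) and `neophobia` (see [neophobia_score()]).
#' @export
exploration_score <- function(logs) {
  if (!length(logs)) stop("empty cohort")
  rates <- t(vapply(logs, assay_rates,
                    c(quarters = 0, perches = 0, moves = 0, hops = 0,
                      flights = 0)))
  best <- apply(rates, 2, max)
  scores <- sweep(rates, 2, ifelse(best > 0, best, 1), "/")
  scores[, best == 0] <- 0
  neo <- vapply(logs, function(l) neophobia_score(l)$score, 0)
  data.frame(bird = vapply(logs, `[[`, "", "bird_id"),
             population = vapply(logs, `[[`, "", "population"),
             scores,
             exploration = rowSums(scores),
             neophobia = neo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neophobia score for one assay
#'
#' Mean of two proportions: time on decorated (novel) perches out of total
#' perched time, and time in the center of the arena out of the assay
#' duration. A perch occupation lasts from `land_perch` until the next
#' event (or the end of the assay); center occupation is the summed
#' `enter_center`/`leave_center` intervals (an unmatched enter is closed at
#' the end). Higher scores represent a reduced neophobic response. A bird
#' that never perched contributes 0 for the perch proportion and is
#' flagged.
#'
#' @param log an [assay_log()].
#' @return List `(score, decorated_prop, center_prop, never_perched)`.
#' @export
neophobia_score <- function(log) {
  ev <- log$events
  n <- nrow(ev)
  ends <- if (n) c(ev$time[-1], log$duration) else numeric(0)
  on_perch <- ev$event == "land_perch"
  perch_time <- sum((ends - ev$time)[on_perch])
  dec_time <- sum((ends - ev$time)[on_perch & ev$arg %in% log$decorated])
  never <- perch_time == 0
  dec_prop <- if (never) 0 else dec_time / perch_time
  cs <- ev$time[ev$event == "enter_center"]
  ce <- ev$time[ev$event == "leave_center"]
  center <- 0; open <- NA_real_
  for (i in seq_len(n)) {
    if (ev$event[i] == "enter_center" && is.na(open)) open <- ev$time[i]
    if (ev$event[i] == "leave_center" && !is.na(open)) {
      center <- center + ev$time[i] - open
      open <- NA_real_
    }
  }
  if (!is.na(open)) center <- center + log$duration - open
  list(score = mean(c(dec_prop, center / log$duration)),
       decorated_prop = dec_prop,
       center_prop = center / log$duration,
       never_perched = never)
}
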