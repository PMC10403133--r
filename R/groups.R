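# Group assignment from photograph timing and individual-level filtering.

# count identified members per group
group_table <- function(members, all_groups = NULL) {
  df <- unique(members[, c("group_id", "date")])
  cnt <- table(members$group_id)
  df$n_members <- as.integer(cnt[as.character(df$group_id)])
  if (!is.null(all_groups)) {
    empty <- all_groups[!all_groups$group_id %in% df$group_id, , drop = FALSE]
    if (nrow(empty)) {
      empty$n_members <- 0L
      df <- rbind(df, empty)
    }
  }
  df <- df[order(df$group_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign photographs to encountered groups
#'
#' Within each sampling period (calendar date) photographs are sorted by
#' time and split wherever the gap between consecutive photographs exceeds
#' `gap_minutes`; each run is one encountered group. A photograph exactly
#' `gap_minutes` after the previous one stays in the same group (the rule
#' is strictly greater-than). Group membership is the set of distinct
#' identified individuals among the run's photographs; unidentified images
#' influence the splitting but contribute no members.
#'
#' @param records sighting records with valid timestamps.
#' @param gap_minutes gap threshold in minutes (default 15).
#' @return object of class `group_assignment`: list with `groups`
#'   (data.frame group_id, date, n_members) and `members` (data.frame
#'   group_id, date, individual_id).
#' @export
assign_groups <- function(records, gap_minutes = 15) {
  if (!nrow(records)) {
    return(structure(list(groups = data.frame(group_id = integer(0),
                                              date = as.Date(character(0)),
                                              n_members = integer(0)),
                          members = data.frame(group_id = integer(0),
                                               date = as.Date(character(0)),
                                               individual_id = character(0))),
                     class = "group_assignment"))
  }
  ord <- order(records$timestamp)
  r <- records[ord, , drop = FALSE]
  new_day <- c(TRUE, r$date[-1] != r$date[-nrow(r)])
  gap <- c(0, as.numeric(difftime(r$timestamp[-1], r$timestamp[-nrow(r)],
                                  units = "mins")))
  gid <- cumsum(new_day | gap > gap_minutes)
  members <- unique(data.frame(group_id = gid, date = r$date,
                               individual_id = r$individual_id,
                               stringsAsFactors = FALSE))
  members <- members[!is.na(members$individual_id), , drop = FALSE]
  rownames(members) <- NULL
  all_groups <- unique(data.frame(group_id = gid, date = r$date))
  structure(list(groups = group_table(members, all_groups), members = members),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Groups: %d groups over %d sampling days; %d identified individuals\n",
              nrow(x$groups), length(unique(x$groups$date)),
              length(unique(x$members$individual_id))))
  invisible(x)
}

#' Restrict a group assignment to regularly sighted individuals
#'
#' Keeps individuals seen in at least `min_sightings` sampling periods
#' (calendar days) within the year range; the conventional "seen more than
#' five times" rule is `min_sightings = 6`. Groups are re-formed from the
#' retained members and empty groups dropped.
#'
#' @param ga a `group_assignment`.
#' @param min_sightings minimum number of sampling-day occurrences (default 6).
#' @param years optional integer vector of season-years to keep.
#' @return filtered `group_assignment`.
#' @export
restrict_individuals <- function(ga, min_sightings = 6L, years = NULL) {
  m <- ga$members
  if (!is.null(years) && nrow(m)) {
    sy <- suppressWarnings(assign_season_year(m$date))
    m <- m[!is.na(sy) & sy %in% years, , drop = FALSE]
  }
  if (nrow(m)) {
    days_seen <- tapply(as.character(m$date), m$individual_id,
                        function(d) length(unique(d)))
    keep_ids <- names(days_seen)[days_seen >= min_sightings]
    m <- m[m$individual_id %in% keep_ids, , drop = FALSE]
  }
  if (!nrow(m)) warning("no individuals meet the sighting threshold")
  rownames(m) <- NULL
  structure(list(groups = group_table(m), members = m),
            class = "group_assignment")
}
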