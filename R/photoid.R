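# Urian-style image quality grading, distinctiveness filtering and
# effort/catalogue bookkeeping.

#' Grade images from their five quality-component scores
#'
#' Each photographed fin carries five observer-assigned component scores:
#' focus (2 excellent / 4 moderate / 9 poor), contrast (1 ideal / 3
#' excessive or minimal), angle (1 perpendicular / 2 slight / 8 oblique),
#' partial (1 full fin / 8 partial) and frame (1 fin fills >5% of frame /
#' 5 fills <1%). The total score bands the image as *excellent* (6--9),
#' *average* (10--12) or *poor* (>12); the three bands partition every
#' reachable total.
#'
#' @param focus,contrast,angle,partial,frame integer component scores
#'   (vectorized; recycled to a common length).
#' @return data.frame with columns `total_score` and `band`.
#' @export
grade_image <- function(focus, contrast, angle, partial, frame) {
  comps <- list(focus = focus, contrast = contrast, angle = angle,
                partial = partial, frame = frame)
  n <- max(lengths(comps))
  for (nm in names(comps)) {
    v <- as.integer(comps[[nm]])
    bad <- !(v %in% QUALITY_LEVELS[[nm]])
    if (any(bad)) {
      stop(sprintf("invalid `%s` score %s (permitted: %s)", nm,
                   paste(unique(v[bad]), collapse = ","),
                   paste(QUALITY_LEVELS[[nm]], collapse = ",")))
    }
    comps[[nm]] <- rep_len(v, n)
  }
  total <- Reduce(`+`, comps)
  data.frame(total_score = total, band = quality_band(total),
             stringsAsFactors = FALSE)
}

#' Band a total quality score
#' @param total integer total score(s).
#' @return character vector: "excellent", "average" or "poor".
#' @export
quality_band <- function(total) {
  ifelse(total <= 9, "excellent", ifelse(total <= 12, "average", "poor"))
}

#' Append quality grades to sighting records
#'
#' @param records validated sighting records.
#' @return records with `total_score` and `band` columns appended.
#' @export
grade_records <- function(records) {
  g <- grade_image(records$focus, records$contrast, records$angle,
                   records$partial, records$frame)
  records$total_score <- g$total_score
  records$band <- g$band
  records
}

# Modal distinctiveness label per individual; ties break toward the more
# distinctive class (D1 over D2 over D3), "unknown" never wins over a real
# label.
consensus_distinctiveness <- function(records) {
  ids <- records$individual_id
  keep <- !is.na(ids)
  tab <- table(ids[keep], factor(records$distinctiveness[keep],
                                 levels = DIST_LEVELS))
  labelled <- tab[, c("D1", "D2", "D3"), drop = FALSE]
  pick <- apply(labelled, 1L, function(cnt) {
    if (sum(cnt) == 0) return("unknown")
    c("D1", "D2", "D3")[which.max(cnt)]  # which.max: first max = most distinct
  })
  stats::setNames(as.character(pick), rownames(tab))
}

#' Filter graded records for an analysis stage
#'
#' The *identification* stage keeps only excellent- and average-quality
#' images (the set submitted for individual matching). The
#' *capture_recapture* stage starts from that set and additionally keeps
#' only identified adults whose consensus fin distinctiveness is D1 or D2:
#' weakly marked (D3) animals violate the mark-recognition assumption and
#' calves/juveniles are routed to the reproductive analysis instead.
#'
#' @param records graded sighting records (see [grade_records()]).
#' @param stage `"identification"` or `"capture_recapture"`.
#' @return the filtered records (possibly zero rows).
#' @export
filter_for_analysis <- function(records,
                                stage = c("identification", "capture_recapture")) {
  stage <- match.arg(stage)
  if (!"band" %in% names(records)) records <- grade_records(records)
  out <- records[records$band %in% c("excellent", "average"), , drop = FALSE]
  if (stage == "capture_recapture") {
    out <- out[!is.na(out$individual_id) & out$age_class == "adult", , drop = FALSE]
    cons <- consensus_distinctiveness(out)
    keep_ids <- names(cons)[cons %in% c("D1", "D2")]
    out <- out[out$individual_id %in% keep_ids, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-season effort and image counts
#'
#' Effort in a photo-ID survey is the number of distinct calendar days on
#' which at least one image was obtained, counted per season-year together
#' with the image count. Unidentified images count toward effort: a day in
#' the field is a day in the field whether or not the fins were matchable.
#'
#' @param records sighting records (any stage).
#' @return data.frame: `season_year`, `effort_days`, `images`.
#' @export
effort_summary <- function(records) {
  if (!nrow(records)) {
    return(data.frame(season_year = integer(0), effort_days = integer(0),
                      images = integer(0)))
  }
  sy <- suppressWarnings(assign_season_year(records$date))
  keep <- !is.na(sy)
  sy <- sy[keep]
  d <- records$date[keep]
  years <- sort(unique(sy))
  data.frame(
    season_year = years,
    effort_days = vapply(years, function(y) length(unique(d[sy == y])), integer(1)),
    images = vapply(years, function(y) sum(sy == y), integer(1))
  )
}
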