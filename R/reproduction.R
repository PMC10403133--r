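# Calf bookkeeping, birth-year backdating, calving rate, inter-birth
# interval, and effort-trend regressions.

#' Backdate calf observations to birth years
#'
#' A calf classed *newborn* was born in its observation season-year; an
#' *older* calf (at least one year old) is backdated by one year. Duplicate
#' observations of the same mother-birth-year collapse to a single birth.
#' Records with a missing size class are flagged and excluded from rate
#' computations.
#'
#' @param calves data.frame with columns `season_year`, `mother_id`
#'   (optional values may be NA), `size_class` ("newborn"/"older") and
#'   optionally `calf_id`.
#' @param study_years optional year range; births outside it are flagged
#'   (column `in_study`), not dropped.
#' @return data.frame of births: `mother_id`, `birth_year`, plus flags.
#' @export
backdate_births <- function(calves, study_years = NULL) {
  if (!nrow(calves)) {
    return(data.frame(mother_id = character(0), birth_year = integer(0),
                      in_study = logical(0)))
  }
  missing_size <- is.na(calves$size_class) |
    !(calves$size_class %in% c("newborn", "older"))
  if (any(missing_size)) {
    warning(sum(missing_size), " calf record(s) with missing/invalid size class excluded")
  }
  cc <- calves[!missing_size, , drop = FALSE]
  birth_year <- cc$season_year - (cc$size_class == "older")
  key_id <- if ("calf_id" %in% names(cc)) {
    ifelse(is.na(cc$mother_id), paste0("calf:", cc$calf_id), cc$mother_id)
  } else {
    ifelse(is.na(cc$mother_id), paste0("row:", seq_len(nrow(cc))), cc$mother_id)
  }
  out <- data.frame(mother_id = cc$mother_id, key = key_id,
                    birth_year = as.integer(birth_year),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("key", "birth_year")]), , drop = FALSE]
  out$key <- NULL
  out$in_study <- if (is.null(study_years)) TRUE else
    out$birth_year %in% study_years
  rownames(out) <- NULL
  out
}

#' Per-year calving rate
#'
#' New calves born per identified adult in each year. Years with zero
#' identified adults are masked (NA).
#'
#' @param births data.frame of births (see [backdate_births()]) or a named
#'   vector of per-year birth counts.
#' @param adults named vector (names = years) of identified-adult counts,
#'   or a data.frame with columns `season_year`/`year` and `adults`.
#' @return data.frame: `year`, `births`, `adults`, `cr`.
#' @export
calving_rate <- function(births, adults) {
  if (is.data.frame(adults)) {
    yr_col <- intersect(c("season_year", "year"), names(adults))[1]
    adults <- stats::setNames(adults$adults, adults[[yr_col]])
  }
  years <- sort(as.integer(names(adults)))
  b_cnt <- if (is.data.frame(births)) {
    tab <- table(factor(births$birth_year[births$in_study %||% TRUE],
                        levels = years))
    as.integer(tab)
  } else {
    as.integer(births[as.character(years)])
  }
  b_cnt[is.na(b_cnt)] <- 0L
  a_cnt <- as.numeric(adults[as.character(years)])
  data.frame(year = years, births = b_cnt, adults = a_cnt,
             cr = ifelse(a_cnt > 0, b_cnt / a_cnt, NA_real_))
}

#' Mean inter-birth interval
#'
#' For each mother with at least two distinct birth years, consecutive
#' birth-year differences are averaged within mother; the mean across
#' mothers is reported with its standard error. Mothers with a single
#' birth, and births with no recorded mother, are excluded.
#'
#' @param births data.frame from [backdate_births()].
#' @return list: `mean`, `se`, `n_mothers`, `per_mother` data.frame.
#' @export
inter_birth_interval <- function(births) {
  b <- births[!is.na(births$mother_id), , drop = FALSE]
  per <- lapply(split(b$birth_year, b$mother_id), function(y) {
    y <- sort(unique(y))
    if (length(y) < 2L) return(NULL)
    mean(diff(y))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) {
    message("no mother with two or more births: IBI undefined")
    return(list(mean = NA_real_, se = NA_real_, n_mothers = 0L,
                per_mother = data.frame(mother_id = character(0),
                                        mean_interval = numeric(0))))
  }
  v <- unlist(per)
  list(mean = mean(v),
       se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n_mothers = length(v),
       per_mother = data.frame(mother_id = names(per), mean_interval = v,
                               row.names = NULL, stringsAsFactors = FALSE))
}

#' Poisson regression of annual counts on survey effort
#'
#' Log-link Poisson GLM of a per-year count (identified adults, new
#' calves) on effort days, reporting the effort coefficient with its Wald
#' z and p-value.
#'
#' @param counts integer vector of annual counts.
#' @param effort_days numeric vector of annual effort (same length).
#' @return list: `coefficient`, `se`, `z`, `p_value`, `model` (the glm).
#' @export
effort_trend <- function(counts, effort_days) {
  if (length(counts) != length(effort_days)) stop("length mismatch")
  if (length(counts) < 3L) stop("at least 3 years are required")
  if (all(counts == 0)) stop("all counts are zero: degenerate fit")
  fit <- stats::glm(counts ~ effort_days, family = stats::poisson())
  s <- summary(fit)$coefficients
  list(coefficient = s["effort_days", "Estimate"],
       se = s["effort_days", "Std. Error"],
       z = s["effort_days", "z value"],
       p_value = s["effort_days", "Pr(>|z|)"],
       model = fit)
}

#' Effort-weighted mean with standard error
#'
#' Weighted mean sum(w x) / sum(w); the SE uses
#' sqrt(sum(w^2 (x - xbar_w)^2)) / sum(w).
#'
#' @param x values (e.g. calves seen per year).
#' @param w nonnegative weights (e.g. effort days), not all zero.
#' @return list: `mean`, `se`.
#' @export
effort_weighted_mean <- function(x, w) {
  if (length(x) != length(w)) stop("length mismatch")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) == 0) stop("all weights are zero")
  m <- sum(w * x) / sum(w)
  list(mean = m, se = sqrt(sum(w^2 * (x - m)^2)) / sum(w))
}
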