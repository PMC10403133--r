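#!/usr/bin/env Rscript

# Stage 5: reproductive parameters and effort regressions.
#
# Backdates older calves to their birth season, computes the per-year
# calving rate (births per identified adult), the mean inter-birth
# interval across mothers, the effort-weighted mean number of calves per
# year, and Poisson regressions of annual counts on survey effort.

suppressMessages(library(photopop))

records <- grade_records(read_sightings("results/sightings.csv"))
calves <- utils::read.csv("results/calf_observations.csv",
                          stringsAsFactors = FALSE)

births <- backdate_births(calves, study_years = 2012:2021)
message(sprintf("%d calf observations -> %d distinct births from %d mothers",
                nrow(calves), nrow(births),
                length(unique(births$mother_id))))

ident <- filter_for_analysis(records, "identification")
ident <- ident[!is.na(ident$individual_id) & ident$age_class == "adult", ]
sy <- assign_season_year(ident$date)
adults <- vapply(2012:2021,
                 function(y) length(unique(ident$individual_id[sy == y])),
                 integer(1))
names(adults) <- 2012:2021

cr_tab <- calving_rate(births, adults)
print(cr_tab)
message(sprintf("calving rate range: %.2f-%.2f",
                min(cr_tab$cr, na.rm = TRUE), max(cr_tab$cr, na.rm = TRUE)))

ibi <- inter_birth_interval(births)
message(sprintf("mean IBI %.1f +/- %.1f years across %d mothers",
                ibi$mean, ibi$se, ibi$n_mothers))

effort <- effort_summary(records)
eff <- effort$effort_days[match(2012:2021, effort$season_year)]
eff[is.na(eff)] <- 0

tr_adults <- effort_trend(adults, eff)
message(sprintf("identified adults vs effort: z = %.2f, P = %.3g",
                tr_adults$z, tr_adults$p_value))
tr_calves <- effort_trend(cr_tab$births, eff)
message(sprintf("new calves vs effort:       z = %.2f, P = %.3g",
                tr_calves$z, tr_calves$p_value))

ewm <- effort_weighted_mean(cr_tab$births, eff)
message(sprintf("effort-weighted mean calves/year: %.1f +/- %.1f",
                ewm$mean, ewm$se))

write_report(list(calving = cr_tab,
                  per_mother_ibi = ibi$per_mother,
                  ibi_mean = ibi$mean, ibi_se = ibi$se,
                  calves_effort_z = tr_calves$z,
                  adults_effort_z = tr_adults$z,
                  effort_weighted_calves = ewm$mean,
                  effort_weighted_calves_se = ewm$se),
             "results/stage5")
message("wrote results/stage5")
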