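# Cohort screening: MoCA education adjustment and eligibility rules for a
# research-based MCI sample.

#' Education adjustment of a MoCA score
#'
#' Standard MoCA scoring adds 1 point for participants with at most 12
#' years of education, capped at the 30-point maximum.
#'
#' @param raw_score MoCA total in 0-30.
#' @param education_years years of education.
#' @return adjusted score(s).
#' @examples
#' moca_education_adjust(24, 10)  # 25
#' moca_education_adjust(24, 16)  # 24
#' @export
moca_education_adjust <- function(raw_score, education_years) {
  if (any(raw_score < 0 | raw_score > 30, na.rm = TRUE)) {
    .stopf("MoCA scores must lie in [0, 30]")
  }
  ifelse(!is.na(education_years) & education_years <= 12,
         pmin(raw_score + 1, 30), raw_score)
}

#' Apply MCI eligibility rules to a participant table
#'
#' Keeps participants aged at least 55 with an (education-adjusted) MoCA
#' below 26/30 (research-based MCI) and an MMSE above 20/30 (i.e. >= 21,
#' excluding probable dementia). Records with a missing screening field
#' are excluded with reason `"incomplete"`; every exclusion is logged with
#' the first failed rule.
#'
#' @param records data frame with columns `age`, `moca`, `mmse` (and an
#'   `id` column used in the log when present).
#' @param min_age,moca_below,mmse_min rule thresholds.
#' @return list with `included` (data frame) and `exclusions` (data frame
#'   of `id`, `reason`); included + excluded partition the input.
#' @export
apply_eligibility <- function(records, min_age = 55, moca_below = 26,
                              mmse_min = 21) {
  need <- c("age", "moca", "mmse")
  if (!all(need %in% names(records))) {
    .stopf("records need columns: %s", paste(need, collapse = ", "))
  }
  ids <- if ("id" %in% names(records)) as.character(records$id)
         else as.character(seq_len(nrow(records)))
  reason <- rep(NA_character_, nrow(records))
  inc <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (anyNA(r[need])) {
      inc[i] <- FALSE; reason[i] <- "incomplete"
    } else if (r$age < min_age) {
      inc[i] <- FALSE; reason[i] <- sprintf("age %.0f < %d", r$age, min_age)
    } else if (r$moca >= moca_below) {
      inc[i] <- FALSE; reason[i] <- sprintf("MoCA %.0f >= %d", r$moca, moca_below)
    } else if (r$mmse < mmse_min) {
      inc[i] <- FALSE; reason[i] <- sprintf("MMSE %.0f < %d", r$mmse, mmse_min)
    }
  }
  list(included = records[inc, , drop = FALSE],
       exclusions = data.frame(id = ids[!inc], reason = reason[!inc],
                               stringsAsFactors = FALSE))
}
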