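# Record-removal rules and complete/incomplete classification.

cleaning_rules <- function() invalid_record_classes()

parse_age <- function(age) {
  suppressWarnings(as.numeric(age))
}

#' Apply the record-removal rules and classify completeness
#'
#' Removes every record matching at least one of the five removal rules,
#' checked in a fixed order with the first match recorded, so per-rule counts
#' are well defined even when a record violates several rules:
#' \enumerate{
#'   \item invalid age response (non-parseable, negative, or above 120);
#'   \item underage (parsed age below 18);
#'   \item missing initial socio-demographics (age, gender or country
#'     unanswered);
#'   \item household income reported on the prefinal scale;
#'   \item missing follow-up socio-demographics (education or income
#'     unanswered).
#' }
#' Surviving records are classified complete or incomplete by
#' [classify_completeness()]. A malformed field is a removal reason, never an
#' error. Gender "diverse" and diagnosis "not_assessed" are retained here;
#' they are excluded only inside specific downstream analyses.
#'
#' @param responses A tibble of raw survey records (the `responses` element
#'   of a [simulate_cohort()] result, or an externally loaded table with the
#'   same columns).
#'
#' @return A list with
#'   \describe{
#'     \item{participants}{valid records, with `age` parsed to numeric.}
#'     \item{report}{a `cleaning_report`: totals, per-rule removal counts,
#'       complete/incomplete counts, and the per-record disposition (first
#'       triggered rule, or the completeness class).}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 100), seed = 1)
#' cleaned <- clean_responses(cohort$responses)
#' cleaned$report
#' @export
clean_responses <- function(responses) {
  n <- nrow(responses)
  disposition <- rep(NA_character_, n)
  if (n > 0) {
    age_num <- parse_age(responses$age)
    age_given <- !is.na(responses$age)
    rule_hits <- list(
      invalid_age = age_given & (is.na(age_num) | age_num < 0 | age_num > 120),
      underage = age_given & !is.na(age_num) & age_num < 18,
      missing_initial_sociodemo = is.na(responses$age) |
        is.na(responses$gender) | is.na(responses$country),
      prefinal_income = !is.na(responses$income_scale) &
        responses$income_scale == "prefinal",
      missing_followup_sociodemo = is.na(responses$education_years) |
        is.na(responses$income)
    )
    for (rule in cleaning_rules()) {
      hit <- rule_hits[[rule]] & is.na(disposition)
      disposition[hit] <- rule
    }
  }

  valid <- is.na(disposition)
  participants <- responses[valid, ]
  if (nrow(participants) > 0) {
    participants$age <- parse_age(participants$age)
  }
  completeness <- classify_completeness(participants)
  disposition[valid] <- completeness

  removed_by_rule <- vapply(cleaning_rules(),
                            function(r) sum(disposition == r, na.rm = TRUE),
                            integer(1))
  report <- structure(
    list(
      n_registered = n,
      n_removed = sum(removed_by_rule),
      removed_by_rule = removed_by_rule,
      n_valid = sum(valid),
      n_incomplete = sum(completeness == "incomplete"),
      n_complete = sum(completeness == "complete"),
      dispositions = tibble::tibble(id = responses$id,
                                    disposition = disposition)
    ),
    class = "cleaning_report"
  )
  list(participants = participants, report = report)
}

#' Classify each valid record complete or incomplete
#'
#' A record is complete iff all stressor-exposure endorsements are answered,
#' every endorsed stressor has a severity rating, and all twelve GHQ-12 items
#' are answered — the fields needed to compute the resilience outcome.
#' Optional free-text answers never affect the classification.
#'
#' @param participants Tibble of records that survived cleaning.
#' @return Character vector, `"complete"` or `"incomplete"` per record.
#' @export
classify_completeness <- function(participants) {
  n <- nrow(participants)
  if (n == 0) {
    return(character(0))
  }
  items <- stressor_items()
  stress_cols <- c(paste0("gs_", items$general), paste0("cs_", items$specific))
  ghq_cols <- sprintf("ghq_%02d", 1:12)

  endorse <- as.matrix(participants[, stress_cols])
  sev <- as.matrix(participants[, paste0("sev_", stress_cols)])
  ghq <- as.matrix(participants[, ghq_cols])

  endorse_ok <- rowSums(is.na(endorse)) == 0
  sev_missing <- !is.na(endorse) & endorse == 1L & is.na(sev)
  sev_ok <- rowSums(sev_missing) == 0
  ghq_ok <- rowSums(is.na(ghq)) == 0

  ifelse(endorse_ok & sev_ok & ghq_ok, "complete", "incomplete")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat("  registered:", x$n_registered, "\n")
  cat("  removed:   ", x$n_removed, "\n")
  for (rule in names(x$removed_by_rule)) {
    if (x$removed_by_rule[[rule]] > 0) {
      cat(sprintf("    %-28s %d\n", rule, x$removed_by_rule[[rule]]))
    }
  }
  pct <- if (x$n_valid > 0) {
    sprintf(" (%.1f%%)", 100 * x$n_incomplete / x$n_valid)
  } else {
    ""
  }
  cat("  valid:     ", x$n_valid, "\n")
  cat("  incomplete:", x$n_incomplete, pct, "\n", sep = "")
  cat("  complete:  ", x$n_complete, "\n")
  invisible(x)
}
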