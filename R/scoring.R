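# Symptom totals and severity-weighted stressor-exposure indices.

#' Score a GHQ-12 response
#'
#' Plain Likert 0-3 scoring: the symptom total `P` is the sum of the twelve
#' items, giving the instrument's 0-36 range.
#'
#' @param items A numeric vector of 12 item responses in `{0,1,2,3}`, or a
#'   matrix/data frame with 12 columns (one row per respondent).
#' @return Integer total(s) `P` in 0-36.
#' @examples
#' score_ghq12(rep(3, 12)) # instrument maximum
#' @export
score_ghq12 <- function(items) {
  m <- if (is.null(dim(items))) {
    matrix(as.numeric(unlist(items)), nrow = 1L)
  } else {
    as.matrix(items)
  }
  if (ncol(m) != 12L) {
    stop("GHQ-12 requires exactly 12 items", call. = FALSE)
  }
  bad <- which(is.na(m) | !(m %in% 0:3), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid GHQ-12 response at item %d (must be 0, 1, 2 or 3)",
                 bad[1, "col"]), call. = FALSE)
  }
  totals <- as.integer(rowSums(m))
  if (is.null(dim(items))) totals[1] else totals
}

#' Severity-weighted stressor-exposure sum
#'
#' The exposure index is the sum count of endorsed stressors weighted by
#' their rated severity: each endorsed item contributes its severity (1-5),
#' unendorsed items contribute 0.
#'
#' @param endorsed Integer/logical vector of endorsement flags.
#' @param severities Severity ratings 1-5; may be `NA` for unendorsed items.
#' @param strict If `TRUE` (default), an endorsed item with a missing
#'   severity is an error; otherwise the midpoint severity 3 is imputed with
#'   a warning.
#' @return Nonnegative exposure sum.
#' @examples
#' exposure_sum(c(1, 1, 0), c(2, 5, NA)) # 7
#' @export
exposure_sum <- function(endorsed, severities, strict = TRUE) {
  if (length(endorsed) != length(severities)) {
    stop("`endorsed` and `severities` must have equal length", call. = FALSE)
  }
  endorsed <- as.integer(endorsed)
  on <- !is.na(endorsed) & endorsed == 1L
  missing_sev <- on & is.na(severities)
  if (any(missing_sev)) {
    if (strict) {
      stop(sprintf("endorsed item %d has no severity rating",
                   which(missing_sev)[1]), call. = FALSE)
    }
    warning(sprintf("imputed midpoint severity 3 for %d endorsed item(s)",
                    sum(missing_sev)), call. = FALSE)
    severities[missing_sev] <- 3
  }
  sev_on <- severities[on]
  if (any(!(sev_on %in% 1:5))) {
    stop("severities must be in 1..5", call. = FALSE)
  }
  sum(sev_on)
}

#' Combine general and specific exposure into the common index
#'
#' z-scores each exposure sum over the analysis sample (denominator `n - 1`)
#' and averages the two z-scores into the combined index
#' `e_c = (z_g + z_s) / 2`.
#'
#' @param e_g,e_s Numeric vectors of general and crisis-specific
#'   severity-weighted exposure sums over the same participants.
#' @return A tibble with columns `e_g`, `e_s`, `z_g`, `z_s`, `e_c`.
#' @export
combine_exposure <- function(e_g, e_s) {
  if (length(e_g) != length(e_s) || length(e_g) < 2) {
    stop("`e_g` and `e_s` must be equal-length vectors with n >= 2",
         call. = FALSE)
  }
  if (sd(e_g) == 0 || sd(e_s) == 0) {
    stop("z-score undefined: an exposure vector has zero variance",
         call. = FALSE)
  }
  z_g <- (e_g - mean(e_g)) / sd(e_g)
  z_s <- (e_s - mean(e_s)) / sd(e_s)
  tibble::tibble(e_g = e_g, e_s = e_s, z_g = z_g, z_s = z_s,
                 e_c = (z_g + z_s) / 2)
}

#' Score symptoms and exposure for a cleaned participant table
#'
#' Appends the symptom total `p` and the exposure columns `e_g`, `e_s`,
#' `z_g`, `z_s`, `e_c` to the participant table. Scores are computed for
#' complete records only (z-normalization is defined over the complete
#' analysis sample); incomplete records receive `NA`.
#'
#' @param participants Cleaned participant tibble (see [clean_responses()]).
#' @param strict Passed to [exposure_sum()].
#' @return The participant tibble with scoring columns appended.
#' @export
score_participants <- function(participants, strict = TRUE) {
  items <- stressor_items()
  gen_cols <- paste0("gs_", items$general)
  spec_cols <- paste0("cs_", items$specific)
  ghq_cols <- sprintf("ghq_%02d", 1:12)

  complete <- classify_completeness(participants) == "complete"
  n <- nrow(participants)
  p <- e_g <- e_s <- z_g <- z_s <- e_c <- rep(NA_real_, n)

  if (any(complete)) {
    p[complete] <- score_ghq12(participants[complete, ghq_cols])
    e_g[complete] <- row_exposure(participants[complete, ], gen_cols, strict)
    e_s[complete] <- row_exposure(participants[complete, ], spec_cols, strict)
    ex <- combine_exposure(e_g[complete], e_s[complete])
    z_g[complete] <- ex$z_g
    z_s[complete] <- ex$z_s
    e_c[complete] <- ex$e_c
  }
  participants$p <- p
  participants$e_g <- e_g
  participants$e_s <- e_s
  participants$z_g <- z_g
  participants$z_s <- z_s
  participants$e_c <- e_c
  participants
}

row_exposure <- function(rows, cols, strict) {
  endorse <- as.matrix(rows[, cols])
  sev <- as.matrix(rows[, paste0("sev_", cols)])
  vapply(seq_len(nrow(rows)), function(i) {
    exposure_sum(endorse[i, ], sev[i, ], strict = strict)
  }, numeric(1))
}

#' Descriptive stressor table
#'
#' Per stressor item: endorsement percentage and mean severity among
#' endorsers, sorted by frequency within domain. Items endorsed by nobody
#' report a missing mean severity.
#'
#' @param participants Participant tibble (complete records are used).
#' @return A tibble with columns `domain`, `item`, `n`, `pct_endorsed`,
#'   `mean_severity`.
#' @export
describe_stressors <- function(participants) {
  complete <- classify_completeness(participants) == "complete"
  rows <- participants[complete, ]
  items <- stressor_items()
  all_cols <- c(paste0("gs_", items$general), paste0("cs_", items$specific))
  out <- lapply(all_cols, function(col) {
    endorse <- rows[[col]]
    sev <- rows[[paste0("sev_", col)]]
    n_end <- sum(endorse == 1L, na.rm = TRUE)
    tibble::tibble(
      domain = if (startsWith(col, "gs_")) "general" else "specific",
      item = sub("^(gs|cs)_", "", col),
      n = n_end,
      pct_endorsed = 100 * n_end / max(1L, nrow(rows)),
      mean_severity = if (n_end > 0) {
        mean(sev[endorse == 1L], na.rm = TRUE)
      } else {
        NA_real_
      }
    )
  })
  tab <- do.call(rbind, out)
  tab[order(tab$domain, -tab$pct_endorsed), ]
}
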