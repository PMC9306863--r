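#' Select the blood eosinophil count a grading run should use
#'
#' Filters a patient's dated BEC history to the observations eligible
#' under a window and reduces them to a single value. Eligibility:
#' `obs_date <= enrolment_date` always (post-enrolment data never leak
#' into grading), and for lookback windows additionally
#' `obs_date >= enrolment_date - years * 365.25` days, a closed interval.
#' Mode `"latest"` returns the count at the most recent eligible date
#' (ties on the date resolved to the higher count); `"lookback"` and
#' `"ever"` return the maximum eligible count.
#'
#' @param history Tibble of BEC observations for one patient
#'   (`patient_id`, `obs_date`, `count`); may have zero rows.
#' @param enrolment_date The patient's enrolment date (`Date`).
#' @param window A [window_spec()].
#' @return A one-row tibble: `patient_id`, `value` (cells/uL, `NA` when no
#'   observation is eligible), `source_date`, `n_observations_in_window`.
#' @examples
#' d <- as.Date("2020-01-01")
#' h <- tibble::tibble(
#'   patient_id = "P1",
#'   obs_date = c(d - round(6 * 365.25), d - 365),
#'   count = c(400L, 100L)
#' )
#' select_bec(h, d, window_spec("lookback", 5))$value # 100: 400 is too old
#' select_bec(h, d, window_spec("ever"))$value        # 400
#' @export
select_bec <- function(history, enrolment_date, window) {
  stopifnot(inherits(window, "window_spec"))
  if (!inherits(enrolment_date, "Date") || length(enrolment_date) != 1L ||
      is.na(enrolment_date)) {
    rlang::abort("`enrolment_date` must be a single Date.",
                 class = "eosgradient_validation_error")
  }
  history <- validate_bec(history)
  ids <- unique(history$patient_id)
  if (length(ids) > 1L) {
    rlang::abort("`history` mixes observations from more than one patient.",
                 class = "eosgradient_validation_error")
  }

  eligible <- history[history$obs_date <= enrolment_date, , drop = FALSE]
  if (window$mode == "lookback") {
    earliest <- enrolment_date - window$years * 365.25
    eligible <- eligible[eligible$obs_date >= earliest, , drop = FALSE]
  }

  n <- nrow(eligible)
  if (n == 0L) {
    return(tibble::tibble(
      patient_id = if (length(ids) == 1L) ids else NA_character_,
      value = NA_real_, source_date = as.Date(NA),
      n_observations_in_window = 0L
    ))
  }
  if (window$mode == "latest") {
    latest_day <- max(eligible$obs_date)
    on_day <- eligible[eligible$obs_date == latest_day, , drop = FALSE]
    value <- max(on_day$count)
    source_date <- latest_day
  } else {
    value <- max(eligible$count)
    source_date <- max(eligible$obs_date[eligible$count == value])
  }
  tibble::tibble(
    patient_id = ids, value = as.numeric(value),
    source_date = source_date, n_observations_in_window = n
  )
}

# Vectorised windowed selection across a whole cohort. Same semantics as
# select_bec() per patient; patients with no eligible observation get
# value = NA. Returns one row per patient in `patients` order.
select_bec_cohort <- function(bec, patients, window) {
  stopifnot(inherits(window, "window_spec"))
  df <- dplyr::inner_join(
    bec,
    dplyr::select(patients, "patient_id", "enrolment_date"),
    by = "patient_id"
  )
  df <- df[df$obs_date <= df$enrolment_date, , drop = FALSE]
  if (window$mode == "lookback") {
    df <- df[df$obs_date >= df$enrolment_date - window$years * 365.25, ,
             drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(tibble::tibble(
      patient_id = patients$patient_id, value = NA_real_,
      source_date = as.Date(NA),
      n_observations_in_window = 0L
    ))
  }
  if (window$mode == "latest") {
    sel <- df |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        value = max(.data$count[.data$obs_date == max(.data$obs_date)]),
        source_date = max(.data$obs_date),
        n_observations_in_window = dplyr::n(),
        .groups = "drop"
      )
  } else {
    sel <- df |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        value = max(.data$count),
        source_date = max(.data$obs_date[.data$count == max(.data$count)]),
        n_observations_in_window = dplyr::n(),
        .groups = "drop"
      )
  }
  out <- dplyr::left_join(
    dplyr::select(patients, "patient_id"), sel, by = "patient_id"
  )
  out$value <- as.numeric(out$value)
  out$n_observations_in_window[is.na(out$n_observations_in_window)] <- 0L
  out
}
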