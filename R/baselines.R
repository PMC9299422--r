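#' SVE-burden baseline score
#'
#' The comparator the two-stage model is benchmarked against: the fraction of
#' a patient's 7-s segments that contain at least one supraventricular
#' ectopic beat, used directly as the pAF probability for ranking. Burden is
#' computed over setting-1 segments (SVE retained), since setting-2
#' preprocessing removes the signal by construction.
#'
#' @param segments Segment tibble for one patient with a `contains_sve`
#'   column (setting-1 preprocessing).
#' @return Tibble with `patient_id`, `burden`, `n_sve_segments`,
#'   `n_total_segments`; `NULL` (with a warning) when the patient has no
#'   segments, in which case the patient is excluded from the baseline.
#' @export
sve_burden_score <- function(segments) {
  if (nrow(segments) == 0L) {
    warn("patient has zero segments; excluded from the SVE-burden baseline")
    return(NULL)
  }
  pid <- unique(segments$patient_id)
  if (length(pid) != 1L) abort("sve_burden_score expects one patient's segments")
  n_sve <- sum(segments$contains_sve)
  tibble::tibble(
    patient_id = pid,
    burden = n_sve / nrow(segments),
    n_sve_segments = as.integer(n_sve),
    n_total_segments = nrow(segments)
  )
}

#' SVE burden for every patient of a cohort
#'
#' @param segments Pooled setting-1 segment tibble.
#' @return One burden row per patient (see [sve_burden_score()]).
#' @export
sve_burden_cohort <- function(segments) {
  dplyr::bind_rows(lapply(
    split(segments, segments$patient_id),
    sve_burden_score
  ))
}
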