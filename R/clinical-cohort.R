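# The packaged clinical interim-analysis cohort: 25 lesion-level rows over
# 20 newly diagnosed stage II/III TNBC patients, with baseline SUVmean /
# SULpeak / SUVmax and their percent change between on-treatment (post
# cycle 1) and baseline. Continuation rows without a stage entry are
# additional lesions of the preceding patient.

#' Load the clinical lesion-level SUV cohort
#'
#' Reads the packaged lesion table and validates its structure: 25 lesion
#' rows over 20 patients, 10 patients with pathological complete response
#' (pCR), 4 lesion rows with missing percent-change values, and strictly
#' negative percent changes elsewhere (all patients reduced in SUV).
#'
#' @return data.frame with columns `patient_id`, `lesion`, `stage`, `grade`,
#'   `pcr` (`"Yes"`/`"No"`), `bl_suv_mean`, `bl_sul_peak`, `bl_suv_max`,
#'   `d_suv_mean`, `d_sul_peak`, `d_suv_max`.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_cohort.csv", package = "petrad",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(grade = "character"))
  d_cols <- c("d_suv_mean", "d_sul_peak", "d_suv_max")
  ok <- nrow(df) == 25 &&
    length(unique(df$patient_id)) == 20 &&
    sum(!duplicated(df$patient_id) & df$pcr == "Yes") == 10 &&
    sum(!stats::complete.cases(df[, d_cols])) == 4 &&
    all(as.matrix(df[, d_cols]) < 0, na.rm = TRUE) &&
    all(df$pcr %in% c("Yes", "No"))
  if (!ok) stop("packaged cohort fixture failed its structural checksum")
  df
}

#' Group statistics of percent SUV change
#'
#' Mean and sample (n-1) SD of one percent-change metric over the lesion
#' rows of one response group, excluding missing rows; lesion rows are the
#' observation unit.
#'
#' @param rows Cohort data.frame from [load_table2()].
#' @param metric One of `"d_suv_mean"`, `"d_sul_peak"`, `"d_suv_max"`.
#' @param group `"pCR"` or `"non_pCR"`.
#' @return List: `mean`, `sd` (`NA` with `degenerate = TRUE` when only one
#'   observation), `n`.
#' @export
group_delta_stats <- function(rows,
                              metric = c("d_suv_mean", "d_sul_peak",
                                         "d_suv_max"),
                              group = c("pCR", "non_pCR")) {
  metric <- match.arg(metric)
  group <- match.arg(group)
  want <- if (group == "pCR") "Yes" else "No"
  v <- rows[[metric]][rows$pcr == want]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no observations for this metric/group")
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       degenerate = length(v) == 1,
       n = length(v))
}

#' All six group percent-change statistics
#'
#' Convenience wrapper: mean and SD for each metric x response group.
#'
#' @param rows Cohort data.frame from [load_table2()].
#' @return data.frame with `metric`, `group`, `mean`, `sd`, `n`.
#' @export
cohort_delta_summary <- function(rows = load_table2()) {
  grid <- expand.grid(metric = c("d_suv_mean", "d_sul_peak", "d_suv_max"),
                      group = c("pCR", "non_pCR"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- group_delta_stats(rows, grid$metric[i], grid$group[i])
    data.frame(metric = grid$metric[i], group = grid$group[i],
               mean = s$mean, sd = s$sd, n = s$n)
  }))
  out
}
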