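## Phenotype arithmetic ---------------------------------------------------
##
## Plate-dilution assay (PDA) scoring, minimum-inhibitory-concentration
## (MIC) calling and normalisation, and replicate time-course summaries.

#' Plate-dilution assay scores
#'
#' Per variant and drug, the replicate mean of the last 10-fold dilution
#' step still showing growth, normalised to the wildtype as
#' `variant - wildtype`. Wildtype self-scores are exactly 0.
#'
#' @param data Tibble with columns `variant`, `drug`, `replicate`,
#'   `last_growth_step` (integer dilution index, >= 0).
#' @param wildtype Wildtype variant id.
#' @return Tibble with `variant`, `drug`, `score` (signed dilution steps),
#'   `n_replicates`.
#' @export
pda_score <- function(data, wildtype = "wt") {
  data <- as_tibble(data)
  if (any(data$last_growth_step < 0))
    abort("dilution indices must be >= 0", class = "rnd_phenotype_error")
  means <- dplyr::summarise(
    dplyr::group_by(data, .data$variant, .data$drug),
    mean_step = mean(.data$last_growth_step),
    n_replicates = dplyr::n(), .groups = "drop")
  wt <- means[means$variant == wildtype, c("drug", "mean_step")]
  missing_wt <- setdiff(unique(means$drug), wt$drug)
  if (length(missing_wt))
    abort(paste0("no wildtype measurements for drug(s): ",
                 paste(missing_wt, collapse = ", ")),
          class = "rnd_phenotype_error")
  out <- dplyr::left_join(means, dplyr::rename(wt, wt_step = "mean_step"),
                          by = "drug")
  out$score <- out$mean_step - out$wt_step
  out$score[out$variant == wildtype] <- 0   # exact, no float residue
  dplyr::arrange(out[, c("variant", "drug", "score", "n_replicates")],
                 .data$variant, .data$drug)
}

#' Call a MIC from a concentration/OD series
#'
#' Background-corrected OD values above the growth threshold (default 0.18)
#' count as growth; the MIC is the lowest concentration with no growth at
#' that concentration nor at any higher one (the conservative reading for
#' non-monotone series). Growth at the top concentration gives an
#' above-range call (MIC reported as greater than the maximum); no growth
#' anywhere including a zero-concentration control gives a below-range
#' call.
#'
#' @param series Tibble with `concentration` (strictly increasing) and
#'   `od` columns.
#' @param growth_threshold OD cut-off; values above it are growth.
#' @return A one-row tibble: `mic`, `censored` (`"none"`, `"above"`,
#'   `"below"`).
#' @export
mic_call <- function(series, growth_threshold = 0.18) {
  series <- as_tibble(series)
  conc <- series$concentration; od <- series$od
  if (any(diff(conc) <= 0))
    abort("concentrations must be strictly increasing", class = "rnd_phenotype_error")
  if (any(!is.finite(od)))
    abort("OD values must be finite", class = "rnd_phenotype_error")
  growth <- od > growth_threshold
  ## no growth at c and at every higher concentration
  clear <- rev(cumprod(rev(!growth))) == 1
  if (!any(clear))
    return(tibble(mic = max(conc), censored = "above"))
  mic <- min(conc[clear])
  censored <- if (mic == min(conc) && min(conc) == 0) "below" else "none"
  tibble(mic = mic, censored = censored)
}

#' Normalise MICs to the wildtype
#'
#' Replicate-mean MIC per variant and drug, expressed as the fold ratio
#' `MIC_variant / MIC_wildtype`. Above-range (censored) MICs propagate as
#' inequalities: the ratio is flagged `">="` rather than treated as a
#' number. A censored wildtype leaves the ratio undefined.
#'
#' @param mics Tibble with columns `variant`, `drug`, `replicate`, `mic`
#'   and optionally `censored` (`"none"`/`"above"`/`"below"`).
#' @param wildtype Wildtype variant id.
#' @return Tibble with `variant`, `drug`, `ratio`, `censor` (`""`, `">="`
#'   or `"undefined"`), `n_replicates`.
#' @export
mic_normalize <- function(mics, wildtype = "wt") {
  mics <- as_tibble(mics)
  if (!"censored" %in% names(mics)) mics$censored <- "none"
  agg <- dplyr::summarise(
    dplyr::group_by(mics, .data$variant, .data$drug),
    mean_mic = mean(.data$mic),
    any_above = any(.data$censored == "above"),
    n_replicates = dplyr::n(), .groups = "drop")
  wt <- agg[agg$variant == wildtype, , drop = FALSE]
  missing_wt <- setdiff(unique(agg$drug), wt$drug)
  if (length(missing_wt))
    abort(paste0("no wildtype MIC for drug(s): ",
                 paste(missing_wt, collapse = ", ")),
          class = "rnd_phenotype_error")
  if (any(wt$mean_mic <= 0))
    abort("wildtype MIC must be > 0", class = "rnd_phenotype_error")
  wtv <- setNames(wt$mean_mic, wt$drug)
  wt_above <- setNames(wt$any_above, wt$drug)
  out <- agg
  out$ratio <- out$mean_mic / unname(wtv[out$drug])
  out$ratio[out$variant == wildtype & !out$any_above] <- 1  # exact
  out$censor <- unname(ifelse(wt_above[out$drug], "undefined",
                              ifelse(out$any_above, ">=", "")))
  out$ratio[out$censor == "undefined"] <- NA_real_
  dplyr::arrange(out[, c("variant", "drug", "ratio", "censor", "n_replicates")],
                 .data$variant, .data$drug)
}

#' Summarise replicate time courses
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) across
#' replicates sharing one time grid (e.g. fluorescence accumulation
#' curves). A single replicate yields sd 0 with a warning; mismatched time
#' grids error.
#'
#' @param curves Tibble with columns `time`, `replicate`, `value`.
#' @return Tibble with `time`, `mean`, `sd`, `n_replicates`.
#' @export
summarize_timecourse <- function(curves) {
  curves <- as_tibble(curves)
  grids <- dplyr::group_split(dplyr::group_by(curves, .data$replicate))
  times <- lapply(grids, function(g) sort(g$time))
  if (length(times) > 1 &&
      !all(vapply(times[-1], identical, logical(1), times[[1]])))
    abort("replicates do not share the same time grid",
          class = "rnd_phenotype_error")
  single <- length(grids) == 1
  if (single) warn("single replicate: standard deviation reported as 0")
  out <- dplyr::summarise(
    dplyr::group_by(curves, .data$time),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) sd(.data$value) else 0,
    n_replicates = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$time)
}
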