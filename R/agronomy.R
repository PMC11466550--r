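#' Grain yield in tons per hectare from plot ear weight
#'
#' Standardizes plot ear weight to grain yield at a reference moisture
#' content:
#'
#' \deqn{yield = PE \cdot \frac{100 - H}{100 - H_r} \cdot
#'   \frac{S \cdot 100}{NPA \cdot 10}}
#'
#' where `PE` is ear weight per plot (kg), `H` the grain moisture at harvest
#' (%), `Hr` the reference moisture (%), `S` the shelling coefficient
#' (grain fraction of ear weight) and `NPA` the net harvested plot area
#' (m2). The `S*100/(NPA*10)` factor converts kg per plot to t per hectare:
#' 1 kg of grain-equivalent on 1 m2 at reference moisture with S = 1 is
#' 10 t/ha.
#'
#' @param pe_kg Ear weight per plot, kg (vectorized, >= 0).
#' @param moisture_pct Grain moisture at harvest, percent, in [0, 100).
#' @param hr_pct Reference moisture, percent, default 15.
#' @param shelling Shelling coefficient in (0, 1], default 0.8.
#' @param npa_m2 Net harvested plot area, m2 (> 0).
#' @return Grain yield in t/ha, same length as `pe_kg`.
#' @examples
#' grain_yield_t_ha(1, moisture_pct = 15, npa_m2 = 8)  # exactly 1 t/ha
#' @export
grain_yield_t_ha <- function(pe_kg, moisture_pct, hr_pct = 15,
                             shelling = 0.8, npa_m2) {
  if (any(!is.na(pe_kg) & pe_kg < 0)) {
    abort_mm("ear weight must be >= 0", "domain_error")
  }
  if (any(!is.na(moisture_pct) &
          (moisture_pct < 0 | moisture_pct >= 100))) {
    abort_mm("grain moisture must be in [0, 100)", "domain_error")
  }
  if (hr_pct < 0 || hr_pct >= 100) {
    abort_mm("reference moisture must be in [0, 100)", "domain_error")
  }
  if (shelling <= 0 || shelling > 1) {
    abort_mm("shelling coefficient must be in (0, 1]", "domain_error")
  }
  if (npa_m2 <= 0) abort_mm("net plot area must be > 0", "domain_error")
  pe_kg * (100 - moisture_pct) / (100 - hr_pct) *
    (shelling * 100) / (npa_m2 * 10)
}

#' Fill in grain yield for every plot of a dataset
#'
#' Applies [grain_yield_t_ha()] to each observation's `ear_weight_kg` and
#' `grain_moisture_pct` using the dataset's plot configuration. Plots
#' missing either input are skipped (listed in the `skip_report`
#' attribute), never treated as zero. Existing `grain_yield_t_ha` values
#' are overwritten with a warning.
#'
#' @param dataset A [trial_dataset()] whose observations carry
#'   `ear_weight_kg` and `grain_moisture_pct`.
#' @return The dataset with `grain_yield_t_ha` filled; attribute
#'   `skip_report` is a data frame (environment, genotype, replicate,
#'   reason) of plots that could not be converted.
#' @export
derive_yields <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  obs <- dataset$observations
  for (col in c("ear_weight_kg", "grain_moisture_pct")) {
    if (!col %in% names(obs)) {
      abort_mm(sprintf("dataset has no `%s` column", col), "format_error")
    }
  }
  if ("grain_yield_t_ha" %in% names(obs) &&
      any(!is.na(obs$grain_yield_t_ha))) {
    warning("existing grain_yield_t_ha values are overwritten",
            call. = FALSE)
  }
  usable <- !is.na(obs$ear_weight_kg) & !is.na(obs$grain_moisture_pct)
  cfg <- dataset$plot_config
  yield <- rep(NA_real_, nrow(obs))
  yield[usable] <- grain_yield_t_ha(
    obs$ear_weight_kg[usable], obs$grain_moisture_pct[usable],
    hr_pct = cfg$hr_pct, shelling = cfg$shelling, npa_m2 = cfg$npa_m2)
  obs$grain_yield_t_ha <- yield
  skipped <- obs[!usable, ID_COLUMNS, drop = FALSE]
  if (nrow(skipped) > 0) {
    skipped$reason <- ifelse(
      is.na(dataset$observations$ear_weight_kg[!usable]),
      "missing ear_weight_kg", "missing grain_moisture_pct")
  } else {
    skipped$reason <- character(0)
  }
  rownames(skipped) <- NULL
  out <- dataset
  out$observations <- obs
  attr(out, "skip_report") <- skipped
  out
}
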