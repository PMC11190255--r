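# Media design from carbon ratios and C/N targets, and the consumption /
# growth / lipid accounting of fermentation experiments.

#' Design an SCFA medium from a total concentration and an A:P:B ratio
#'
#' In `"carbon"` mode (default) the A:P:B ratio is interpreted on the carbon
#' basis: per-acid masses `m_i` satisfy `sum(m_i) = total_scfa` with the
#' carbon masses `c_i * m_i` proportional to the ratio, where `c_i` is the
#' carbon mass fraction of each acid (acetic 2C/60.052 g/mol, propionic
#' 3C/74.079, butyric 4C/88.106). In `"mass"` mode the masses themselves are
#' proportional to the ratio.
#'
#' @param total_scfa Total SCFA concentration, g/L (> 0).
#' @param carbon_ratio Numeric length-3 A:P:B ratio, non-negative, not all 0.
#' @param ratio_mode `"carbon"` (default) or `"mass"`.
#' @param cn_ratio Optional target carbon-to-nitrogen mass ratio; if given,
#'   the implied ammonium sulphate concentration is stored (see
#'   [ammoniumSulphateForCN()]).
#' @param ph Recorded initial pH (default 6.0).
#' @return A [MediumSpec-class].
#' @examples
#' designMedium(15, c(3, 1, 1), "mass")    # 9 / 3 / 3 g/L
#' designMedium(25, c(3, 1, 1))            # ~16.46 / 4.51 / 4.03 g/L
#' @export
designMedium <- function(total_scfa, carbon_ratio,
                         ratio_mode = c("carbon", "mass"),
                         cn_ratio = NA_real_, ph = 6.0) {
  ratio_mode <- match.arg(ratio_mode)
  if (total_scfa <= 0) stop("total_scfa must be > 0")
  if (length(carbon_ratio) != 3 || any(carbon_ratio < 0) || sum(carbon_ratio) == 0)
    stop("carbon_ratio must be 3 non-negative values, not all zero")
  m <- if (ratio_mode == "carbon") {
    # carbon_i = ratio_i * lambda  =>  m_i = ratio_i * lambda / c_i
    inv <- carbon_ratio / .CARBON_FRACTION
    total_scfa * inv / sum(inv)
  } else {
    total_scfa * carbon_ratio / sum(carbon_ratio)
  }
  names(m) <- names(.CARBON_FRACTION)
  ms <- new("MediumSpec", total_scfa = total_scfa,
            carbon_ratio = as.numeric(carbon_ratio), acid_gL = m,
            ratio_mode = ratio_mode, cn_ratio = NA_real_,
            ammonium_sulphate_gL = NA_real_, ph = ph)
  if (!is.na(cn_ratio)) {
    ms@cn_ratio <- cn_ratio
    ms@ammonium_sulphate_gL <- ammoniumSulphateForCN(ms, cn_ratio)
  }
  ms
}

#' Ammonium sulphate needed for a target C/N ratio
#'
#' Returns the ammonium sulphate concentration (g/L) that sets the medium's
#' carbon-to-nitrogen mass ratio to `target_cn`, counting SCFA-derived carbon
#' only: `(carbon / target_cn) / 0.212`, with 0.212 the nitrogen mass
#' fraction of ammonium sulphate (2 * 14.007 / 132.14).
#'
#' @param medium A [MediumSpec-class].
#' @param target_cn Target C/N mass ratio (> 0), e.g. 150 or 200.
#' @return Ammonium sulphate, g/L.
#' @export
ammoniumSulphateForCN <- function(medium, target_cn) {
  if (target_cn <= 0) stop("target_cn must be > 0")
  C <- carbonContent(medium)
  if (C <= 0) stop("medium has no SCFA carbon")
  (C / target_cn) / .N_FRACTION_AMS
}

#' Per-acid consumption percentage
#'
#' `100 * (initial - final) / initial`, clamped to [0, 100]. A final
#' concentration above the initial one (measurement noise) clamps to 0 with a
#' warning.
#'
#' @param initial Initial concentration, g/L (> 0).
#' @param final Final concentration, g/L (>= 0).
#' @return Percentage consumed.
#' @export
consumptionPercent <- function(initial, final) {
  if (any(initial <= 0)) stop("initial must be > 0")
  if (any(final < 0)) stop("final must be >= 0")
  raw <- 100 * (initial - final) / initial
  if (any(raw < 0))
    warning("final concentration exceeds initial; consumption clamped to 0")
  pmin(pmax(raw, 0), 100)
}

#' Parse censored table percentages
#'
#' Converts reported consumption values that may be censored as `"<10"` into
#' numbers: censored entries become 0 (`rule = "zero"`, default) or the
#' interval midpoint 5 (`rule = "midpoint"`).
#'
#' @param x Numeric or character vector (e.g. `c("100", "<10", "23")`).
#' @param rule `"zero"` or `"midpoint"`.
#' @return Numeric vector.
#' @export
parseCensored <- function(x, rule = c("zero", "midpoint")) {
  rule <- match.arg(rule)
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  cens <- grepl("^<", x)
  out <- suppressWarnings(as.numeric(sub("^<\\s*", "", x)))
  out[cens] <- if (rule == "zero") 0 else out[cens] / 2
  if (anyNA(out)) stop("unparseable consumption values: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' Carbon-weighted total SCFA consumption
#'
#' The "Total" consumption reported for a fermentation: the weighted mean of
#' the per-acid consumption percentages with weights proportional to the
#' medium's A:P:B carbon ratio (e.g. 3:1:1 gives weights 3/5, 1/5, 1/5).
#' Censored inputs (`"<10"`) are handled by [parseCensored()]. By default the
#' result is rounded half-up to the nearest integer for table-style
#' reporting; mass weights can be supplied via `weights` instead of the
#' ratio.
#'
#' @param per_acid_pct Length-3 vector of per-acid consumption percentages
#'   (acetic, propionic, butyric), numeric or character with `"<10"` censors.
#' @param carbon_ratio Length-3 A:P:B carbon ratio used as weights.
#' @param weights Optional explicit weights overriding `carbon_ratio` (e.g.
#'   per-acid masses for a mass-weighted total).
#' @param censored_rule Passed to [parseCensored()].
#' @param digits Decimal digits of the half-up rounding (default 0); use
#'   `NULL` to return full precision.
#' @return Total consumption, %.
#' @examples
#' totalConsumption(c(70, 100, 100), c(3, 1, 1))       # 82
#' totalConsumption(c("100", "100", "23"), c(3, 1, 1)) # 85
#' @export
totalConsumption <- function(per_acid_pct, carbon_ratio = c(3, 1, 1),
                             weights = NULL, censored_rule = "zero",
                             digits = 0) {
  pct <- parseCensored(per_acid_pct, censored_rule)
  if (length(pct) != 3) stop("per_acid_pct must have 3 values")
  if (any(pct < 0 | pct > 100)) stop("percentages must be in [0, 100]")
  w <- weights %||% carbon_ratio
  if (length(w) != 3 || any(w < 0) || sum(w) == 0)
    stop("weights must be 3 non-negative values, not all zero")
  total <- sum(w * pct) / sum(w)
  if (is.null(digits)) total else roundHalfUp(total, digits)
}

#' Lipid yield Y_L/S
#'
#' Grams of lipid produced per gram of SCFA consumed:
#' `(lipid_content / 100) * biomass / scfa_consumed`.
#'
#' @param lipid_content Lipid content, % w/w of cell dry weight.
#' @param biomass Biomass, g CDW/L.
#' @param scfa_consumed SCFA consumed, g/L.
#' @return Yield, g lipid / g SCFA; `NA` when nothing was consumed.
#' @export
lipidYield <- function(lipid_content, biomass, scfa_consumed) {
  if (any(lipid_content < 0 | biomass < 0, na.rm = TRUE))
    stop("lipid_content and biomass must be >= 0")
  out <- (lipid_content / 100) * biomass / scfa_consumed
  out[is.na(scfa_consumed) | scfa_consumed <= 0] <- NA_real_
  out
}

#' Biomass implied by a lipid yield (consistency utility)
#'
#' Inverse of [lipidYield()]: the biomass (g CDW/L) consistent with a
#' reported lipid content, yield and amount of substrate consumed. Useful to
#' sanity-check reported yield/consumption/lipid triplets when biomass itself
#' is not reported.
#'
#' @param lipid_content Lipid content, % w/w.
#' @param yield Y_L/S, g lipid / g SCFA.
#' @param scfa_consumed SCFA consumed, g/L.
#' @return Biomass, g CDW/L.
#' @export
biomassForYield <- function(lipid_content, yield, scfa_consumed) {
  if (any(lipid_content <= 0)) stop("lipid_content must be > 0")
  yield * scfa_consumed / (lipid_content / 100)
}

#' SCFA consumption rate
#'
#' @param scfa_consumed SCFA consumed, g/L (>= 0).
#' @param duration_h Duration, hours (> 0).
#' @return Rate, g/(L.h).
#' @export
consumptionRate <- function(scfa_consumed, duration_h) {
  if (any(duration_h <= 0)) stop("duration_h must be > 0")
  if (any(scfa_consumed < 0)) stop("scfa_consumed must be >= 0")
  scfa_consumed / duration_h
}

#' Summarize a fermentation time course
#'
#' End-of-cultivation accounting: per-acid consumption from the first and
#' last samples, carbon-weighted total consumption, maximal OD600 over the
#' series, lipid yield Y_L/S and mean consumption rate. The end time is the
#' last sample — deciding when to stop (e.g. at 60-70% carbon consumed) is
#' the experimentalist's call, not the summarizer's.
#'
#' @param tc Data frame with columns `time_h`, `acetic_gL`, `propionic_gL`,
#'   `butyric_gL`, `od600` (>= 2 rows).
#' @param medium The [MediumSpec-class] the culture was grown in.
#' @param lipid_content Endpoint lipid content, % w/w of CDW.
#' @param biomass Endpoint biomass, g CDW/L.
#' @param init_tol Relative tolerance for the check that the first sample
#'   matches the medium's nominal composition (warning only).
#' @return One-row data frame: `acetic_pct`, `propionic_pct`, `butyric_pct`,
#'   `total_pct`, `max_od600`, `lipid_content`, `biomass`, `yield_ls`,
#'   `consumption_rate`, `consumed_gL`, `duration_h`.
#' @export
summarizeFermentation <- function(tc, medium, lipid_content = NA_real_,
                                  biomass = NA_real_, init_tol = 0.05) {
  needed <- c("time_h", "acetic_gL", "propionic_gL", "butyric_gL", "od600")
  miss <- setdiff(needed, names(tc))
  if (length(miss)) stop("time course lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(tc) < 2) stop("need at least 2 time points")
  tc <- tc[order(tc$time_h), ]
  acids <- c("acetic_gL", "propionic_gL", "butyric_gL")
  initial <- as.numeric(tc[1, acids])
  final <- as.numeric(tc[nrow(tc), acids])
  nominal <- acidConcentrations(medium)
  if (any(abs(initial - nominal) > init_tol * pmax(nominal, 1e-9)))
    warning("initial concentrations deviate from the medium specification ",
            "by more than ", 100 * init_tol, "%")
  pct <- vapply(1:3, function(i)
    if (initial[i] > 0) consumptionPercent(initial[i], final[i]) else NA_real_,
    numeric(1))
  present <- !is.na(pct)
  ratio_w <- medium@carbon_ratio
  total <- sum(ratio_w[present] * pct[present]) / sum(ratio_w[present])
  consumed <- sum(initial - pmin(final, initial))
  duration <- tc$time_h[nrow(tc)] - tc$time_h[1]
  data.frame(
    acetic_pct = pct[1], propionic_pct = pct[2], butyric_pct = pct[3],
    total_pct = roundHalfUp(total, 0),
    max_od600 = max(tc$od600),
    lipid_content = lipid_content,
    biomass = biomass,
    yield_ls = lipidYield(lipid_content, biomass, consumed),
    consumption_rate = consumptionRate(consumed, duration),
    consumed_gL = consumed,
    duration_h = duration
  )
}
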