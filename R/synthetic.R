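# Synthetic screening data with known ground truth.
#
# The generator emulates the structure of a colony-size screen: strains
# arrayed on plates at 96/384/1536 density, scanned every 15 min for 4 days,
# with a glucose control medium and SCFA-rich media on which only a subset
# of strains is viable. Growth follows an offset logistic so the planted
# inflection time (true t_max) and carrying capacity (true fitness) are
# available in closed form for recovery tests.

#' Offset logistic colony-growth model
#'
#' `size(t) = s0 + (K - s0) / (1 + exp(-r (t - t_mid)))`. The maximal slope
#' occurs at `t = t_mid` (the inflection), which serves as the ground-truth
#' time at maximal growth.
#'
#' @param t Time(s), hours.
#' @param K Carrying capacity, arbitrary units; `K > s0`.
#' @param s0 Initial size, arbitrary units, `>= 0`.
#' @param r Rate, 1/h, `> 0`.
#' @param t_mid Inflection time, hours.
#' @return Sizes at `t`.
#' @export
logisticSize <- function(t, K, s0, r, t_mid) {
  s0 + (K - s0) / (1 + exp(-r * (t - t_mid)))
}

#' Screen design
#'
#' Bundles the experimental-design parameters of a synthetic screen. Defaults
#' mirror the study conditions of the time-course screen: sampling every
#' 0.25 h for 96 h, at least three biological replicates, a glucose control
#' plus three SCFA compositions.
#'
#' @param media Character vector of medium ids. The first entry is treated as
#'   the glucose control by downstream defaults.
#' @param density Plate density: 96, 384 or 1536 wells.
#' @param replicates Biological replicates per strain (>= 1; study used >= 3).
#' @param interval_h Sampling interval, hours.
#' @param duration_h Total scan duration, hours.
#' @param noise_cv Replicate-to-replicate coefficient of variation: each
#'   colony's whole curve is scaled by one `1 + N(0, noise_cv)` factor.
#' @param noise_floor_sd Per-scan additive measurement noise SD, a.u.
#' @param seed Master seed; per-plate streams are derived from it.
#' @return A validated list of class `screen_design`.
#' @export
screenDesign <- function(media = c("glucose", "APB_2_1_2", "APB_3_1_1", "APB_1_1_3"),
                         density = 384L, replicates = 3L,
                         interval_h = 0.25, duration_h = 96,
                         noise_cv = 0.05, noise_floor_sd = 1,
                         seed = 1L) {
  stopifnot(length(media) >= 1, !anyDuplicated(media))
  if (!density %in% c(96L, 384L, 1536L)) stop("density must be 96, 384 or 1536")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (interval_h <= 0) stop("interval_h must be > 0")
  if (duration_h <= interval_h) stop("duration_h must exceed interval_h")
  if (noise_cv < 0 || noise_floor_sd < 0) stop("noise parameters must be >= 0")
  structure(list(media = media, density = as.integer(density),
                 replicates = as.integer(replicates),
                 interval_h = interval_h, duration_h = duration_h,
                 noise_cv = noise_cv, noise_floor_sd = noise_floor_sd,
                 seed = as.integer(seed)),
            class = "screen_design")
}

.plateDims <- function(density) {
  switch(as.character(density),
         "96" = c(8L, 12L), "384" = c(16L, 24L), "1536" = c(32L, 48L))
}

# Row labels A..Z then AA..AF (1536-density plates have 32 rows).
.rowLabels <- c(LETTERS, paste0("A", LETTERS))

#' Generate ground-truth strain parameters
#'
#' Draws per-strain, per-medium logistic growth parameters, lipid contents and
#' fermentation kinetics. Strains split into fast- and slow-growing groups
#' (earlier vs later inflection, higher vs lower rate) and into high- vs
#' low-lipid accumulators, emulating the bimodal phenotype distributions seen
#' in screens of diverse yeast collections. All strains are viable on the
#' glucose control; on each SCFA medium a strain is viable with probability
#' `viable_fraction`. The reference strain is always viable everywhere.
#'
#' @param strain_ids Character vector of strain identifiers.
#' @param media Medium ids; the first is the always-viable control.
#' @param reference_strain Id of the reference strain (added if absent).
#' @param viable_fraction Probability a strain grows on an SCFA medium.
#' @param fast_fraction Fraction of strains in the fast-growing group.
#' @param high_lipid_fraction Fraction of strains in the high-lipid group.
#' @param seed Integer seed.
#' @return List with `growth` (strain x medium logistic parameters and
#'   viability), `lipid` (true lipid content, fraction of CDW) and
#'   `fermentation` (per-acid uptake rates g/(L.h), preference order encoded
#'   by rate magnitudes, biomass yield g CDW per g SCFA) data frames, plus
#'   `reference_strain`.
#' @export
makeTruths <- function(strain_ids, media = c("glucose", "APB_2_1_2", "APB_3_1_1", "APB_1_1_3"),
                       reference_strain = "REF1",
                       viable_fraction = 0.4, fast_fraction = 0.5,
                       high_lipid_fraction = 0.4, seed = 1L) {
  if (!reference_strain %in% strain_ids)
    strain_ids <- c(reference_strain, strain_ids)
  set.seed(seed)
  ns <- length(strain_ids)
  fast <- stats::runif(ns) < fast_fraction
  fast[strain_ids == reference_strain] <- TRUE
  high_lipid <- stats::runif(ns) < high_lipid_fraction
  high_lipid[strain_ids == reference_strain] <- TRUE

  growth <- do.call(rbind, lapply(seq_along(media), function(j) {
    m <- media[j]
    control <- j == 1L
    viable <- if (control) rep(TRUE, ns) else stats::runif(ns) < viable_fraction
    viable[strain_ids == reference_strain] <- TRUE
    s0 <- stats::runif(ns, 80, 120)
    K <- ifelse(control,
                stats::rnorm(ns, 3000, 300),
                ifelse(fast, stats::rnorm(ns, 2000, 250), stats::rnorm(ns, 900, 150)))
    K <- pmax(K, s0 + 200)
    r <- ifelse(fast, stats::rnorm(ns, 0.25, 0.04), stats::rnorm(ns, 0.10, 0.02))
    r <- pmax(r, 0.03)
    t_mid <- ifelse(control, stats::rnorm(ns, 30, 5),
                    ifelse(fast, stats::rnorm(ns, 42, 7), stats::rnorm(ns, 72, 8)))
    t_mid <- pmin(pmax(t_mid, 10), 90)
    data.frame(strain_id = strain_ids, medium_id = m, viable = viable,
               K = K, s0 = s0, r = r, t_mid = t_mid,
               stringsAsFactors = FALSE)
  }))
  rownames(growth) <- NULL

  lipid <- data.frame(
    strain_id = strain_ids,
    lipid_content = pmin(pmax(ifelse(high_lipid,
                                     stats::rnorm(ns, 0.25, 0.04),
                                     stats::rnorm(ns, 0.10, 0.03)), 0.01), 0.6),
    stringsAsFactors = FALSE
  )

  fermentation <- data.frame(
    strain_id = strain_ids,
    u_acetic = pmax(stats::rnorm(ns, 0.15, 0.03), 0.02),
    u_propionic = pmax(stats::rnorm(ns, 0.06, 0.015), 0.005),
    u_butyric = pmax(stats::rnorm(ns, 0.03, 0.01), 0.002),
    biomass_yield = pmax(stats::rnorm(ns, 0.35, 0.05), 0.1),
    stringsAsFactors = FALSE
  )

  list(growth = growth, lipid = lipid, fermentation = fermentation,
       reference_strain = reference_strain)
}

# Assign (strain, replicate) pairs to wells, one medium per set of plates,
# reserving the first `replicates` wells of every plate for the reference
# strain so it is present on each plate.
.layoutForMedium <- function(medium, strain_ids, reference_strain, design) {
  dims <- .plateDims(design$density)
  density <- design$density
  reps <- design$replicates
  others <- setdiff(strain_ids, reference_strain)
  pairs <- expand.grid(replicate = seq_len(reps), strain_id = others,
                       stringsAsFactors = FALSE)[, c("strain_id", "replicate")]
  per_plate <- density - reps
  n_plates <- max(1L, ceiling(nrow(pairs) / per_plate))
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    idx <- seq.int((p - 1L) * per_plate + 1L, min(p * per_plate, nrow(pairs)))
    block <- rbind(
      data.frame(strain_id = reference_strain, replicate = seq_len(reps),
                 stringsAsFactors = FALSE),
      pairs[idx, , drop = FALSE]
    )
    n <- nrow(block)
    well <- seq_len(n)
    out[[p]] <- data.frame(
      plate_id = sprintf("%s_p%02d", medium, p),
      row = .rowLabels[((well - 1L) %/% dims[2]) + 1L],
      col = ((well - 1L) %% dims[2]) + 1L,
      strain_id = block$strain_id,
      replicate = block$replicate,
      medium_id = medium,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate a colony-size screen
#'
#' Generates plate layouts and colony-size time courses for every strain in
#' `truths` under `design`. Viable strain-medium combinations follow the
#' offset logistic; non-viable ones stay flat at `s0`. Noise has two
#' components: a multiplicative replicate-to-replicate scale factor (one draw
#' per colony, CV `design$noise_cv` — pinning/inoculum variability, the
#' dominant variance in colony screens) and additive per-scan measurement
#' noise (`design$noise_floor_sd`), truncated at zero. Identical design and
#' truths (including seed) give identical output.
#'
#' @param design A [screenDesign()].
#' @param truths Output of [makeTruths()] (or a list with the same `growth`
#'   data frame and `reference_strain`).
#' @return List with `screen` (a [ColonyScreen-class]) and `truth` (the input
#'   truths, for round-trip checks).
#' @export
simulateScreen <- function(design, truths) {
  stopifnot(inherits(design, "screen_design"))
  growth <- truths$growth
  strain_ids <- unique(growth$strain_id)
  key <- paste(growth$strain_id, growth$medium_id)
  need <- expand.grid(strain_id = strain_ids, medium_id = design$media,
                      stringsAsFactors = FALSE)
  missing <- need[!paste(need$strain_id, need$medium_id) %in% key, , drop = FALSE]
  if (nrow(missing))
    stop("missing growth parameters for: ",
         paste(sprintf("%s on %s", missing$strain_id, missing$medium_id),
               collapse = "; "))

  layout <- do.call(rbind, lapply(design$media, .layoutForMedium,
                                  strain_ids = strain_ids,
                                  reference_strain = truths$reference_strain,
                                  design = design))
  rownames(layout) <- NULL
  times <- seq(0, design$duration_h, by = design$interval_h)
  nt <- length(times)

  gmap <- growth
  rownames(gmap) <- paste(gmap$strain_id, gmap$medium_id)

  plates <- unique(layout$plate_id)
  sizes <- matrix(NA_real_, nrow = nt, ncol = nrow(layout))
  for (p in seq_along(plates)) {
    wells <- which(layout$plate_id == plates[p])
    set.seed(childSeed(design$seed, p))
    for (wi in wells) {
      g <- gmap[paste(layout$strain_id[wi], layout$medium_id[wi]), ]
      mu <- if (g$viable) logisticSize(times, g$K, g$s0, g$r, g$t_mid)
            else rep(g$s0, nt)
      obs <- mu
      if (design$noise_cv > 0)
        obs <- obs * (1 + stats::rnorm(1, 0, design$noise_cv))
      if (design$noise_floor_sd > 0)
        obs <- obs + stats::rnorm(nt, 0, design$noise_floor_sd)
      sizes[, wi] <- pmax(obs, 0)
    }
  }
  colnames(sizes) <- sprintf("%s_%s%02d", layout$plate_id, layout$row, layout$col)
  list(screen = ColonyScreen(times, sizes, layout), truth = truths)
}

#' Simulate a Nile-red lipid plate assay
#'
#' Produces background fluorescence, stained fluorescence and OD595 readings
#' for each strain and replicate. The stained signal is
#' `background + gain * lipid_content * od595 * (1 + noise)`, so with zero
#' noise the derived RFU is exactly proportional to the true lipid content.
#'
#' @param lipid_truth Data frame with `strain_id` and `lipid_content`
#'   (fraction of CDW), e.g. `makeTruths(...)$lipid`.
#' @param replicates Replicate wells per strain.
#' @param gain Fluorescence gain (a.u. per unit lipid fraction per OD).
#' @param background Background fluorescence, a.u.
#' @param od_mean,od_half_range OD595 values are drawn uniformly in
#'   `od_mean +/- od_half_range` (cultures diluted to OD 0.6 +/- 0.2).
#' @param noise_cv Multiplicative CV on the lipid signal.
#' @param seed Integer seed.
#' @return Data frame: `strain_id`, `replicate`, `f_background`, `f_stained`,
#'   `od595`.
#' @export
simulateLipidAssay <- function(lipid_truth, replicates = 3L, gain = 1e4,
                               background = 50, od_mean = 0.6,
                               od_half_range = 0.2, noise_cv = 0.05,
                               seed = 1L) {
  stopifnot(all(c("strain_id", "lipid_content") %in% names(lipid_truth)))
  if (any(lipid_truth$lipid_content < 0 | lipid_truth$lipid_content >= 1))
    stop("lipid_content must be in [0, 1)")
  set.seed(seed)
  n <- nrow(lipid_truth) * replicates
  out <- data.frame(
    strain_id = rep(lipid_truth$strain_id, each = replicates),
    replicate = rep(seq_len(replicates), times = nrow(lipid_truth)),
    stringsAsFactors = FALSE
  )
  lipid <- rep(lipid_truth$lipid_content, each = replicates)
  out$od595 <- stats::runif(n, od_mean - od_half_range, od_mean + od_half_range)
  out$f_background <- rep(background, n)
  noise <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else 0
  out$f_stained <- pmax(out$f_background +
                          gain * lipid * out$od595 * (1 + noise), 0)
  out
}

#' Simulate an SCFA fermentation time course
#'
#' Piecewise-linear sequential uptake with acid preference: while a
#' higher-preference acid remains, lower-preference acids are consumed at a
#' fraction (`secondary_fraction`) of their full rate; once it is depleted
#' they switch to full rate. With the default rates (acetic > propionic >
#' butyric) acetic acid is consumed fastest, matching the consumption
#' preference and toxicity ordering observed for SCFA-utilizing yeasts.
#' Biomass (OD600) rises in proportion to cumulative substrate consumed times
#' the biomass yield (OD conversion: 1 OD600 = 0.45 g CDW/L).
#'
#' @param ferm_truth One-row data frame with `u_acetic`, `u_propionic`,
#'   `u_butyric` (g/(L.h)) and `biomass_yield` (g CDW per g SCFA).
#' @param medium A [MediumSpec-class] giving initial acid concentrations.
#' @param duration_h Duration, hours (> 0).
#' @param dt_h Sampling interval, hours.
#' @param od0 Initial OD600.
#' @param secondary_fraction Fraction of full uptake rate applied to an acid
#'   while a more-preferred acid is still present.
#' @param preference Consumption preference order over
#'   `c("acetic","propionic","butyric")`.
#' @param noise_cv Multiplicative observation noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame: `time_h`, `acetic_gL`, `propionic_gL`, `butyric_gL`,
#'   `od600`.
#' @export
simulateFermentation <- function(ferm_truth, medium, duration_h = 120,
                                 dt_h = 1, od0 = 1,
                                 secondary_fraction = 0.2,
                                 preference = c("acetic", "propionic", "butyric"),
                                 noise_cv = 0, seed = 1L) {
  if (duration_h <= 0) stop("duration_h must be > 0")
  stopifnot(is(medium, "MediumSpec"))
  preference <- match.arg(preference, several.ok = TRUE)
  if (length(preference) != 3) stop("preference must order all three acids")
  rates <- c(acetic = ferm_truth$u_acetic,
             propionic = ferm_truth$u_propionic,
             butyric = ferm_truth$u_butyric)
  if (any(rates < 0)) stop("uptake rates must be >= 0")
  yield <- ferm_truth$biomass_yield

  times <- seq(0, duration_h, by = dt_h)
  conc <- acidConcentrations(medium)
  names(conc) <- c("acetic", "propionic", "butyric")
  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("acetic", "propionic", "butyric")))
  od <- numeric(length(times))
  consumed <- 0
  out[1, ] <- conc
  od[1] <- od0
  for (i in seq_along(times)[-1]) {
    eff <- rates
    for (k in seq_along(preference)[-1]) {
      higher <- preference[seq_len(k - 1)]
      if (any(conc[higher] > 1e-12))
        eff[preference[k]] <- eff[preference[k]] * secondary_fraction
    }
    step <- pmin(conc, eff * dt_h)
    conc <- conc - step
    consumed <- consumed + sum(step)
    out[i, ] <- conc
    od[i] <- od0 + yield * consumed / 0.45
  }
  res <- data.frame(time_h = times,
                    acetic_gL = out[, "acetic"],
                    propionic_gL = out[, "propionic"],
                    butyric_gL = out[, "butyric"],
                    od600 = od)
  if (noise_cv > 0) {
    set.seed(seed)
    for (cl in c("acetic_gL", "propionic_gL", "butyric_gL", "od600"))
      res[[cl]] <- pmax(res[[cl]] * (1 + stats::rnorm(length(times), 0, noise_cv)), 0)
  }
  res
}

#' Export a screen as delimited tables
#'
#' Writes the stable, documented tabular form of a screen: a layout table
#' (`plate_id, row, col, strain_id, replicate, medium_id`) and a long
#' time-course table (`plate_id, row, col, time_h, size`).
#'
#' @param screen A [ColonyScreen-class].
#' @return List with `layout` and `timecourse` data frames.
#' @export
screenTables <- function(screen) {
  lay <- screenLayout(screen)
  t <- screenTimes(screen)
  sz <- screenSizes(screen)
  tc <- data.frame(
    plate_id = rep(lay$plate_id, each = length(t)),
    row = rep(lay$row, each = length(t)),
    col = rep(lay$col, each = length(t)),
    time_h = rep(t, times = nrow(lay)),
    size = as.vector(sz),
    stringsAsFactors = FALSE
  )
  list(layout = lay, timecourse = tc)
}

#' Rebuild a ColonyScreen from delimited tables
#'
#' Inverse of [screenTables()]: accepts a layout table and a long time-course
#' table (as data frames or file paths to tab-delimited text) and returns a
#' [ColonyScreen-class].
#'
#' @param layout Layout data frame or TSV path.
#' @param timecourse Time-course data frame or TSV path.
#' @return A [ColonyScreen-class].
#' @export
readColonyScreen <- function(layout, timecourse) {
  if (is.character(layout))
    layout <- utils::read.delim(layout, stringsAsFactors = FALSE)
  if (is.character(timecourse))
    timecourse <- utils::read.delim(timecourse, stringsAsFactors = FALSE)
  wells <- paste(layout$plate_id, layout$row, layout$col)
  tc_well <- paste(timecourse$plate_id, timecourse$row, timecourse$col)
  times <- sort(unique(timecourse$time_h))
  sizes <- matrix(NA_real_, length(times), nrow(layout))
  ord <- order(match(tc_well, wells), timecourse$time_h)
  tc <- timecourse[ord, ]
  if (nrow(tc) != length(times) * nrow(layout))
    stop("timecourse is not complete over wells x times")
  sizes[] <- tc$size
  ColonyScreen(times, sizes, layout)
}
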