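#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ColonyScreen: colony-size time courses from a plate screen
#'
#' A container for high-throughput colony-size screening data. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"size"` assay
#' holding the colony-size signal (arbitrary pixel-intensity units) as a
#' timepoints-by-wells matrix. `rowData` carries `time_h` (hours, strictly
#' increasing); `colData` carries the plate layout: `plate_id`, `row`, `col`,
#' `strain_id`, `replicate`, `medium_id`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [ColonyScreen()] for construction, [phenotypeScreen()] for
#'   growth-parameter extraction, [simulateScreen()] to generate one.
#' @export
setClass("ColonyScreen", contains = "SummarizedExperiment")

.LAYOUT_COLS <- c("plate_id", "row", "col", "strain_id", "replicate", "medium_id")

setValidity("ColonyScreen", function(object) {
  msg <- character()
  if (!"size" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'size' is required")
  rd <- rowData(object)
  if (!"time_h" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain 'time_h'")
  } else {
    t <- rd$time_h
    if (length(t) > 1 && any(diff(t) <= 0))
      msg <- c(msg, "time_h must be strictly increasing")
  }
  miss <- setdiff(.LAYOUT_COLS, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks layout columns: ",
                         paste(miss, collapse = ", ")))
  if ("size" %in% SummarizedExperiment::assayNames(object)) {
    sz <- assay(object, "size")
    if (any(sz < 0, na.rm = TRUE)) msg <- c(msg, "sizes must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ColonyScreen
#'
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing.
#' @param sizes Numeric matrix, `length(times)` rows by one column per well;
#'   colony sizes in arbitrary units, non-negative.
#' @param layout `data.frame` with one row per well and columns `plate_id`,
#'   `row`, `col`, `strain_id`, `replicate`, `medium_id`.
#' @return A [ColonyScreen-class] object.
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' sz <- cbind(w1 = 100 + 10 * t, w2 = rep(100, length(t)))
#' lay <- data.frame(plate_id = "P1", row = "A", col = 1:2,
#'                   strain_id = c("S1", "S2"), replicate = 1L,
#'                   medium_id = "glucose")
#' ColonyScreen(t, sz, lay)
#' @export
ColonyScreen <- function(times, sizes, layout) {
  sizes <- as.matrix(sizes)
  if (nrow(sizes) != length(times))
    stop("nrow(sizes) must equal length(times)")
  if (nrow(layout) != ncol(sizes))
    stop("layout must have one row per column of sizes")
  se <- SummarizedExperiment(
    assays = list(size = sizes),
    rowData = DataFrame(time_h = as.numeric(times)),
    colData = DataFrame(layout)
  )
  new("ColonyScreen", se)
}

#' @describeIn ColonyScreen Sampling times in hours.
#' @param x,object A `ColonyScreen`.
#' @export
screenTimes <- function(x) rowData(x)$time_h

#' @describeIn ColonyScreen Timepoints-by-wells size matrix.
#' @export
screenSizes <- function(x) assay(x, "size")

#' @describeIn ColonyScreen Plate layout as a base `data.frame`.
#' @export
screenLayout <- function(x) as.data.frame(colData(x))

setMethod("show", "ColonyScreen", function(object) {
  lay <- colData(object)
  cat("ColonyScreen:", ncol(object), "wells x", nrow(object), "timepoints\n")
  cat("  plates:", length(unique(lay$plate_id)),
      " strains:", length(unique(lay$strain_id)),
      " media:", paste(unique(lay$medium_id), collapse = ", "), "\n")
  t <- screenTimes(object)
  cat(sprintf("  time: %.2f..%.2f h, interval %.2f h\n",
              min(t), max(t), if (length(t) > 1) t[2] - t[1] else NA))
})

#' MediumSpec: an SCFA-rich medium composition
#'
#' Describes a screening/fermentation medium whose sole carbon source is a
#' mixture of acetic, propionic and butyric acid. Masses are derived from a
#' target total SCFA concentration and an A:P:B ratio interpreted either on
#' the carbon basis (default, matching how compositions such as 3:1:1 are
#' defined) or directly on the mass basis.
#'
#' @slot total_scfa Total SCFA concentration, g/L.
#' @slot carbon_ratio Numeric length-3, the A:P:B ratio as specified.
#' @slot acid_gL Named numeric length-3: acetic, propionic, butyric mass
#'   concentrations in g/L.
#' @slot ratio_mode `"carbon"` or `"mass"`.
#' @slot cn_ratio Carbon-to-nitrogen mass ratio (NA if not set).
#' @slot ammonium_sulphate_gL Ammonium sulphate g/L implied by `cn_ratio`
#'   (NA if not set).
#' @slot ph Recorded initial pH (not computed).
#' @seealso [designMedium()], [ammoniumSulphateForCN()]
#' @export
setClass("MediumSpec",
  representation(
    total_scfa = "numeric",
    carbon_ratio = "numeric",
    acid_gL = "numeric",
    ratio_mode = "character",
    cn_ratio = "numeric",
    ammonium_sulphate_gL = "numeric",
    ph = "numeric"
  )
)

# Carbon mass fraction of each acid (2, 3, 4 carbons; molar masses g/mol).
.CARBON_FRACTION <- c(
  acetic    = 2 * 12.011 / 60.052,
  propionic = 3 * 12.011 / 74.079,
  butyric   = 4 * 12.011 / 88.106
)

# N mass fraction of ammonium sulphate (NH4)2SO4.
.N_FRACTION_AMS <- 2 * 14.007 / 132.14

setValidity("MediumSpec", function(object) {
  msg <- character()
  m <- object@acid_gL
  if (length(m) != 3 || any(m < 0)) msg <- c(msg, "acid_gL must be 3 non-negative values")
  if (abs(sum(m) - object@total_scfa) > 1e-9)
    msg <- c(msg, "acid masses must sum to total_scfa within 1e-9")
  r <- object@carbon_ratio
  if (length(r) != 3 || any(r < 0) || sum(r) == 0)
    msg <- c(msg, "carbon_ratio must be 3 non-negative values, not all zero")
  if (length(msg)) msg else TRUE
})

#' @describeIn MediumSpec Per-acid mass concentrations (g/L), named vector.
#' @param x,object A `MediumSpec`.
#' @export
acidConcentrations <- function(x) x@acid_gL

#' @describeIn MediumSpec Total SCFA concentration (g/L).
#' @export
totalSCFA <- function(x) x@total_scfa

#' @describeIn MediumSpec Total SCFA-derived carbon (g C/L).
#' @export
carbonContent <- function(x) sum(x@acid_gL * .CARBON_FRACTION)

#' @describeIn MediumSpec The A:P:B ratio recomputed from the masses, on the
#'   basis given by `mode`, normalized so the smallest nonzero entry is 1.
#' @param mode `"carbon"` or `"mass"`.
#' @export
recoverRatio <- function(x, mode = c("carbon", "mass")) {
  mode <- match.arg(mode)
  v <- if (mode == "carbon") x@acid_gL * .CARBON_FRACTION else x@acid_gL
  nz <- v[v > 0]
  if (!length(nz)) return(v)
  v / min(nz)
}

setMethod("show", "MediumSpec", function(object) {
  m <- object@acid_gL
  cat(sprintf("MediumSpec: %.4g g/L SCFA, A:P:B = %s (%s basis)\n",
              object@total_scfa,
              paste(format(object@carbon_ratio), collapse = ":"),
              object@ratio_mode))
  cat(sprintf("  acetic %.3f, propionic %.3f, butyric %.3f g/L; C = %.3f g/L\n",
              m[1], m[2], m[3], carbonContent(object)))
  if (!is.na(object@cn_ratio))
    cat(sprintf("  C/N = %g; ammonium sulphate = %.4f g/L\n",
                object@cn_ratio, object@ammonium_sulphate_gL))
})
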