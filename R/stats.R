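# Reference-strain normalization, Nile-red RFU, scaling and the screening
# statistics battery (normality/variance gate, Mann-Whitney U with BH
# correction, ANOVA / Kruskal-Wallis for lipid content).

#' Relative fitness (% of glucose control)
#'
#' Fitness on an SCFA medium as a percentage of the same strain's fitness on
#' the glucose control: `100 * fitness_scfa / fitness_glucose`. A missing or
#' non-positive glucose fitness yields `NA`, not an error.
#'
#' @param fitness_scfa,fitness_glucose Numeric vectors (recycled).
#' @return Percentages.
#' @examples
#' relativeFitness(403, 1500)  # 26.86667
#' @export
relativeFitness <- function(fitness_scfa, fitness_glucose) {
  out <- 100 * fitness_scfa / fitness_glucose
  out[is.na(fitness_glucose) | fitness_glucose <= 0] <- NA_real_
  out
}

#' Fold change relative to a reference value
#'
#' Division by the reference and subtraction of 1: `value / reference - 1`.
#' Zero, negative or missing references yield `NA`.
#'
#' @param value,reference Numeric vectors (recycled).
#' @return Fold changes (0 means equal to the reference).
#' @export
foldChange <- function(value, reference) {
  out <- value / reference - 1
  out[is.na(reference) | reference <= 0] <- NA_real_
  out
}

#' Relative fluorescence units from a Nile-red assay
#'
#' Background-subtracted stained fluorescence normalized to biomass:
#' `max(0, f_stained - f_background) / od595`. Negative background-corrected
#' signal is clamped to zero.
#'
#' @param f_stained,f_background Fluorescence, a.u.
#' @param od595 Absorbance at 595 nm; must be > 0.
#' @return RFU, a.u.
#' @examples
#' computeRFU(600, 100, 0.5)  # 1000
#' @export
computeRFU <- function(f_stained, f_background, od595) {
  if (any(od595 <= 0, na.rm = TRUE)) stop("od595 must be > 0")
  pmax(f_stained - f_background, 0) / od595
}

#' Maximum-absolute-value scaling
#'
#' Divides each column by its maximum absolute value so outputs lie in
#' [-1, 1]; `NA`s are ignored when finding the maximum and propagated.
#' All-zero columns are left as zeros with a warning. Idempotent.
#'
#' @param x Numeric matrix or data frame (strains x variables).
#' @return Matrix of the same shape.
#' @export
maxAbsScale <- function(x) {
  x <- as.matrix(x)
  if (!length(x)) stop("empty matrix")
  m <- apply(abs(x), 2, max, na.rm = TRUE)
  zero <- !is.finite(m) | m == 0
  if (any(zero)) {
    warning("all-zero (or all-NA) columns left unscaled: ",
            paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
    m[zero] <- 1
  }
  sweep(x, 2, m, "/")
}

#' Normality and variance-homogeneity gate
#'
#' Runs Shapiro-Wilk on each group and Levene's test (as implemented in
#' \pkg{car}, median-centered) across groups, at significance level `alpha`.
#' If any test rejects, the nonparametric analysis path is flagged. Groups
#' too small (or constant) for Shapiro-Wilk are skipped with the reason
#' recorded rather than failing.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return List: `shapiro` (data frame group/p/skip reason), `levene_p`,
#'   `nonparametric` (logical), `alpha`.
#' @export
normalityVarianceGate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  sh <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]][!is.na(groups[[i]])]
    if (length(g) < 3)
      return(data.frame(group = nm[i], p = NA_real_,
                        skipped = "fewer than 3 observations"))
    if (length(unique(g)) == 1)
      return(data.frame(group = nm[i], p = NA_real_,
                        skipped = "constant values"))
    data.frame(group = nm[i], p = stats::shapiro.test(g)$p.value,
               skipped = NA_character_)
  }))
  levene_p <- NA_real_
  if (length(groups) >= 2) {
    y <- unlist(groups, use.names = FALSE)
    f <- factor(rep(nm, lengths(groups)))
    ok <- !is.na(y)
    if (all(tapply(y[ok], f[ok], function(v) length(v) >= 2)) &&
        stats::var(y[ok]) > 0) {
      lv <- car::leveneTest(y[ok] ~ f[ok])
      levene_p <- lv[["Pr(>F)"]][1]
    }
  }
  nonpar <- any(sh$p < alpha, na.rm = TRUE) ||
    (!is.na(levene_p) && levene_p < alpha)
  list(shapiro = sh, levene_p = levene_p, nonparametric = nonpar,
       alpha = alpha)
}

#' Mann-Whitney U test (two-sided)
#'
#' Compares two groups with the Mann-Whitney U (Wilcoxon rank-sum) test,
#' reporting the U statistic for `group_a`. The p value is exact (full
#' permutation distribution) when `n1 * n2 <= exact_limit` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @param exact_limit Exact-enumeration switch on `n1 * n2` (default 400).
#' @return List: `u` (U for `group_a`), `p` (two-sided), `n1`, `n2`,
#'   `exact` (logical).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(group_a, group_b, exact_limit = 400) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (n1 * n2 <= exact_limit) && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = use_exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = min(wt$p.value, 1),
       n1 = n1, n2 = n2, exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), with input validation: all p values must lie in
#' [0, 1]. `NA`s are propagated. Output order matches input order.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' ANOVA and Kruskal-Wallis tests for lipid content
#'
#' One-way parametric ANOVA (F test) and the nonparametric Kruskal-Wallis
#' test over the same groups, as used for comparing microbial lipid content
#' (% w/w) across strains or conditions. Degenerate all-equal data take the
#' F = 0 path rather than erroring.
#'
#' @param groups Named list of numeric vectors, >= 2 groups with >= 2
#'   observations each.
#' @return List: `anova_f`, `anova_p`, `kruskal_h`, `kruskal_p`.
#' @export
lipidContentTests <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(nm, lengths(groups)))
  ssb <- sum(tapply(y, f, function(v) length(v) * (mean(v) - mean(y))^2))
  if (ssb < .Machine$double.eps * sum(y^2 + 1)) {
    anova_f <- 0
    anova_p <- 1
  } else {
    a <- stats::anova(stats::aov(y ~ f))
    anova_f <- a[["F value"]][1]
    anova_p <- a[["Pr(>F)"]][1]
  }
  kw <- stats::kruskal.test(y, f)
  list(anova_f = anova_f, anova_p = anova_p,
       kruskal_h = unname(kw$statistic), kruskal_p = kw$p.value)
}

#' Compare candidate strains with the reference strain
#'
#' Builds the comparison table of the screening analysis: for each candidate
#' strain, variable and medium, the fold change of the median value relative
#' to the reference strain, the Mann-Whitney U statistic over replicate
#' values, the two-sided p value and the Benjamini-Hochberg adjusted p value.
#' The BH family is one family per (variable, medium) across all candidate
#' strains; the family definition is recorded in the output.
#'
#' @param replicate_values Data frame with columns `strain_id`, `medium_id`,
#'   `variable`, `value` — one row per replicate measurement.
#' @param reference_strain Reference strain id (must be present).
#' @param higher_is_better Ignored for the test (two-sided); kept for table
#'   annotation.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame: `strain_id`, `variable`, `medium_id`, `fold_change`,
#'   `u_stat`, `p_value`, `p_adj_bh`, `n_strain`, `n_reference`,
#'   `significant`; attribute `bh_family = "variable x medium"`.
#' @export
compareToReference <- function(replicate_values, reference_strain,
                               higher_is_better = TRUE, alpha = 0.05) {
  needed <- c("strain_id", "medium_id", "variable", "value")
  miss <- setdiff(needed, names(replicate_values))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!reference_strain %in% replicate_values$strain_id)
    stop("reference strain '", reference_strain, "' not in data")
  fam <- split(replicate_values,
               list(replicate_values$variable, replicate_values$medium_id),
               drop = TRUE)
  rows <- lapply(fam, function(d) {
    ref <- d$value[d$strain_id == reference_strain]
    ref <- ref[!is.na(ref)]
    cand <- setdiff(unique(d$strain_id), reference_strain)
    res <- lapply(cand, function(s) {
      v <- d$value[d$strain_id == s]
      v <- v[!is.na(v)]
      if (!length(v) || !length(ref)) {
        return(data.frame(strain_id = s, variable = d$variable[1],
                          medium_id = d$medium_id[1], fold_change = NA_real_,
                          u_stat = NA_real_, p_value = NA_real_,
                          n_strain = length(v), n_reference = length(ref)))
      }
      mw <- mannWhitneyU(v, ref)
      data.frame(strain_id = s, variable = d$variable[1],
                 medium_id = d$medium_id[1],
                 fold_change = foldChange(stats::median(v), stats::median(ref)),
                 u_stat = mw$u, p_value = mw$p,
                 n_strain = mw$n1, n_reference = mw$n2)
    })
    out <- do.call(rbind, res)
    out$p_adj_bh <- bhAdjust(out$p_value)
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$significant <- !is.na(tab$p_adj_bh) & tab$p_adj_bh < alpha
  attr(tab, "bh_family") <- "variable x medium"
  tab
}
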