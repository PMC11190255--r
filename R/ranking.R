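# Weighted-rank aggregation for strain selection.
#
# Strains are ranked per variable (fitness and t_max on each SCFA medium,
# plus lipid content), the ranks are multiplied by importance weights
# (k = 1.2 for each growth variable, k = 1.6 for lipid content), summed, and
# re-ranked. Rank n is best throughout, matching the convention that the
# highest weighted rank denotes the best overall performance.

#' Importance weights for the ranking
#'
#' @param k_growth Multiplier applied to each fitness and t_max rank
#'   (default 1.2).
#' @param k_lipid Multiplier applied to the lipid-content rank (default 1.6).
#' @return List of class `weight_config`.
#' @export
weightConfig <- function(k_growth = 1.2, k_lipid = 1.6) {
  stopifnot(k_growth > 0, k_lipid > 0)
  structure(list(k_growth = k_growth, k_lipid = k_lipid),
            class = "weight_config")
}

# Rank one variable: best value gets rank n, worst gets 1, average ranks on
# ties. `higher_is_better` chooses the sort direction. Missing values are
# substituted with the worst observed value so they take the worst rank(s).
.rankVariable <- function(x, higher_is_better) {
  missing <- is.na(x)
  if (all(missing)) stop("variable has no observed values")
  v <- x
  worst <- if (higher_is_better) min(v, na.rm = TRUE) - 1 else max(v, na.rm = TRUE) + 1
  v[missing] <- worst
  r <- if (higher_is_better) rank(v, ties.method = "average")
       else rank(-v, ties.method = "average")
  list(rank = r, missing = missing)
}

#' Weighted ranking of candidate strains
#'
#' Implements the multi-criteria selection: per-variable ranks (descending
#' sort for fitness and lipid content — larger is better; ascending for
#' t_max — smaller is better), each fitness/t_max rank multiplied by
#' `k_growth` and the lipid rank by `k_lipid`, scores summed, and the summed
#' scores ranked again so the largest score receives the top (= n) final
#' rank. Ties within a variable receive the average rank; ties in the final
#' score are broken deterministically by strain id (earlier id wins).
#'
#' A strain missing a variable (e.g. it did not grow on a medium) receives
#' the worst rank for that variable and is flagged.
#'
#' With several growth columns the literal weights make lipid's share of the
#' total weight less than its nominal 60%; `mode = "grouped"` instead applies
#' the stated importance percentages directly: the growth variables jointly
#' carry 40% of the weight (split evenly) and lipid content carries 60%.
#' Which arithmetic produced any given published ranking cannot generally be
#' inferred, so both modes are provided and `"literal"` is the default.
#'
#' @param pheno Data frame or matrix of phenotype values, strains in rows
#'   (row names = strain ids, or a `strain_id` column).
#' @param fitness_cols,tmax_cols,lipid_col Column names of the fitness,
#'   t_max and lipid variables. At least one fitness and one t_max column
#'   and exactly one lipid column are required.
#' @param weights A [weightConfig()].
#' @param mode `"literal"` (default) or `"grouped"`.
#' @return Data frame (a rank table): `strain_id`, per-variable rank columns
#'   (`rank_<col>`), `score`, `final_rank` (n = best), `n_missing`,
#'   `selected` (filled by [selectTop()], `NA` here), ordered by descending
#'   final rank.
#' @examples
#' ph <- data.frame(strain_id = c("S1", "S2", "S3"),
#'                  fitness = c(10, 20, 30), t_max = c(5, 10, 15),
#'                  lipid = c(100, 50, 10))
#' weightedRank(ph, "fitness", "t_max", "lipid")
#' @export
weightedRank <- function(pheno, fitness_cols, tmax_cols, lipid_col,
                         weights = weightConfig(),
                         mode = c("literal", "grouped")) {
  mode <- match.arg(mode)
  pheno <- as.data.frame(pheno)
  if ("strain_id" %in% names(pheno)) {
    ids <- as.character(pheno$strain_id)
  } else if (!is.null(rownames(pheno))) {
    ids <- rownames(pheno)
  } else stop("pheno needs a strain_id column or row names")
  if (anyDuplicated(ids)) stop("duplicate strain ids")
  n <- length(ids)
  if (n < 2) {
    if (n < 1) stop("need at least one strain")
  }
  stopifnot(length(lipid_col) == 1, length(fitness_cols) >= 1,
            length(tmax_cols) >= 1)
  cols <- c(fitness_cols, tmax_cols, lipid_col)
  miss <- setdiff(cols, names(pheno))
  if (length(miss)) stop("pheno lacks columns: ", paste(miss, collapse = ", "))

  growth_cols <- c(fitness_cols, tmax_cols)
  dir_up <- c(rep(TRUE, length(fitness_cols)), rep(FALSE, length(tmax_cols)),
              TRUE)
  ranks <- matrix(NA_real_, n, length(cols),
                  dimnames = list(ids, paste0("rank_", cols)))
  n_missing <- integer(n)
  for (j in seq_along(cols)) {
    rv <- .rankVariable(pheno[[cols[j]]], dir_up[j])
    ranks[, j] <- rv$rank
    n_missing <- n_missing + rv$missing
  }

  g <- length(growth_cols)
  w <- if (mode == "literal") {
    c(rep(weights$k_growth, g), weights$k_lipid)
  } else {
    c(rep(0.4 / g, g), 0.6)            # stated group importances, 40:60
  }
  score <- as.vector(ranks %*% w)

  # Scores are sums of (average) ranks times decimal weights; compare at 1e-9
  # resolution so arithmetically equal scores tie regardless of summation
  # order, then break ties by strain id.
  ord <- order(-round(score, 9), ids)  # best first
  final_rank <- integer(n)
  final_rank[ord] <- n:1L

  out <- data.frame(strain_id = ids, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  out$score <- score
  out$final_rank <- final_rank
  out$n_missing <- n_missing
  out$selected <- NA
  rownames(out) <- NULL
  out[order(-out$final_rank), ]
}

#' Select the top candidate strains
#'
#' Returns the `n_select` strains with the largest final ranks, best first,
#' and marks them in the rank table's `selected` column.
#'
#' @param rank_table Output of [weightedRank()].
#' @param n_select Number of strains to select (default 11).
#' @return The rank table, reordered best-first, with `selected` set; the
#'   selected ids are in `attr(, "selected")`.
#' @export
selectTop <- function(rank_table, n_select = 11) {
  n <- nrow(rank_table)
  if (n_select > n) stop("n_select (", n_select, ") exceeds strains (", n, ")")
  if (n_select < 1) stop("n_select must be >= 1")
  tab <- rank_table[order(-rank_table$final_rank), ]
  tab$selected <- seq_len(n) <= n_select
  attr(tab, "selected") <- tab$strain_id[seq_len(n_select)]
  tab
}
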