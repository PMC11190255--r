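# Independent oracles: deliberately naive implementations used only to
# verify the package's code paths. They share no code with R/.

# Offset logistic, written out directly.
oracle_logistic <- function(t, K, s0, r, t_mid) {
  s0 + (K - s0) / (1 + exp(-r * (t - t_mid)))
}

# Brute-force sliding-window slopes: one lm() per window.
oracle_window_slopes <- function(t, y, w) {
  n <- length(t)
  vapply(seq_len(n - w + 1), function(i) {
    idx <- i:(i + w - 1)
    unname(stats::coef(stats::lm(y[idx] ~ t[idx]))[2])
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments (valid when there are no ties).
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mid <- n1 * n2 / 2
  p <- mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
  list(u = u_obs, p = p)
}

# Hand-applied Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Literal weighted-ranking procedure: explicit sorting, average ranks on
# ties, worst rank for missing, weighted sum, final re-ranking with ties
# broken by strain id.
oracle_weighted_rank <- function(pheno, fitness_cols, tmax_cols, lipid_col,
                                 k_growth = 1.2, k_lipid = 1.6) {
  ids <- pheno$strain_id
  n <- length(ids)
  rank_one <- function(x, higher_better) {
    worst <- if (higher_better) min(x, na.rm = TRUE) - 1
             else max(x, na.rm = TRUE) + 1
    x[is.na(x)] <- worst
    sapply(seq_len(n), function(i) {
      if (higher_better) {
        worse <- sum(x < x[i]); tied <- sum(x == x[i])
      } else {
        worse <- sum(x > x[i]); tied <- sum(x == x[i])
      }
      worse + (tied + 1) / 2
    })
  }
  score <- rep(0, n)
  for (cl in fitness_cols) score <- score + k_growth * rank_one(pheno[[cl]], TRUE)
  for (cl in tmax_cols) score <- score + k_growth * rank_one(pheno[[cl]], FALSE)
  score <- score + k_lipid * rank_one(pheno[[lipid_col]], TRUE)
  ord <- order(-round(score, 9), ids)  # scores tie at 1e-9 resolution
  final <- integer(n)
  final[ord] <- n:1
  data.frame(strain_id = ids, score = score, final_rank = final)
}

# Carbon-mode medium design as an explicit 3-unknown linear solve:
#   m1 + m2 + m3 = total;  c1 m1 / r1 = c2 m2 / r2 = c3 m3 / r3.
oracle_carbon_medium <- function(total, ratio) {
  cf <- c(2 * 12.011 / 60.052, 3 * 12.011 / 74.079, 4 * 12.011 / 88.106)
  A <- rbind(c(1, 1, 1),
             c(cf[1] / ratio[1], -cf[2] / ratio[2], 0),
             c(cf[1] / ratio[1], 0, -cf[3] / ratio[3]))
  solve(A, c(total, 0, 0))
}

# Small planted-truth helper shared by recovery and pipeline tests.
make_small_truths <- function(n_strains, seed = 1,
                              media = c("glucose", "APB_2_1_2", "APB_3_1_1",
                                        "APB_1_1_3")) {
  makeTruths(sprintf("S%02d", seq_len(n_strains)), media = media, seed = seed)
}

# Force one strain to dominate every ranking variable: top carrying capacity,
# earliest inflection, fastest rate, highest lipid, viable everywhere.
plant_dominant <- function(truths, strain) {
  g <- truths$growth
  sel <- g$strain_id == strain
  g$viable[sel] <- TRUE
  g$K[sel] <- max(g$K) * 1.3
  g$r[sel] <- max(g$r)
  g$t_mid[sel] <- max(min(g$t_mid) * 0.8, 10)
  truths$growth <- g
  truths$lipid$lipid_content[truths$lipid$strain_id == strain] <-
    min(max(truths$lipid$lipid_content) * 1.5, 0.6)
  truths
}
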