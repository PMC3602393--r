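# Independent statistical oracles shared by the unit and acceptance tests.

# textbook SS decomposition for a balanced Group x (repeated) Frequency design
mixed_anova_oracle <- function(records) {
  Y <- as.matrix(records[, c("p20", "p30", "p40")])
  g <- factor(records$group)
  k <- ncol(Y); n_tot <- nrow(Y); glev <- levels(g)
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, g, mean)
  cond_means <- colMeans(Y)
  cell_means <- rbind(colMeans(Y[g == glev[1], , drop = FALSE]),
                      colMeans(Y[g == glev[2], , drop = FALSE]))
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(table(g) * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_freq <- n_tot * sum((cond_means - grand)^2)
  ss_cells <- sum(rep(table(g), k) * (t(cell_means) - grand)^2)
  ss_gf <- ss_cells - ss_group - ss_freq
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_freq - ss_gf
  df_group <- length(glev) - 1
  df_subj <- n_tot - length(glev)
  df_freq <- k - 1
  df_err <- df_subj * df_freq
  list(F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
       F_freq = (ss_freq / df_freq) / (ss_err / df_err),
       F_gf = (ss_gf / (df_group * df_freq)) / (ss_err / df_err))
}

toy_records <- function(delta40 = -1, n = 5, sd = 0.3, seed = 8) {
  set.seed(seed)
  mk <- function(group, shift) {
    data.frame(subject = 1:n, group = group, seed = 0,
               p20 = 10 + rnorm(n, sd = sd),
               p30 = 12 + rnorm(n, sd = sd),
               p40 = 15 + shift + rnorm(n, sd = sd),
               ok = TRUE, error = "")
  }
  rbind(mk("control", 0), mk("schizophrenic", delta40))
}
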