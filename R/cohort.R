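# Simulated-subject cohorts and the statistical analyses of their
# on-drive band powers.
#
# A "subject" is a fresh network realization: identical projection
# probabilities, different seed, run through all three drive frequencies.
# The group comparison is a mixed-design ANOVA (Group between subjects,
# Frequency repeated) with Greenhouse-Geisser correction; specificity of
# a 40 Hz group difference is probed with hierarchical regressions; drug
# sweep scores are decomposed with a factorial (up to three-way) ANOVA.

#' Generate a cohort of simulated subjects
#'
#' @param n number of subjects.
#' @param group label recorded on every record (`"control"` or
#'   `"schizophrenic"`).
#' @param lesion `NULL` for control subjects or an [lesion_spec()].
#' @param master_seed master seed; subject `i` uses seeds derived from
#'   `(master_seed, i)`.
#' @param params,pop,rules,morphology forwarded to [build_network()].
#' @param drives drive frequencies, Hz.
#' @param drive_args extra arguments for [drive_spec()].
#' @return data.frame: `subject`, `group`, `seed`, `p20`, `p30`, `p40`,
#'   `ok`, `error`. Failed subjects are flagged, not dropped.
#' @export
generate_cohort <- function(n = 20, group = "control", lesion = NULL,
                            master_seed = 1L, params = default_params(),
                            pop = population_spec(), rules = NULL,
                            morphology = NULL, drives = c(20, 30, 40),
                            drive_args = list()) {
  abort_if(n < 1, "cohort size must be >= 1")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- seed_hash(master_seed, i)
    rows[[i]] <- tryCatch({
      net <- build_network(pop, rules, params, morphology, seed = sseed)
      if (!is.null(lesion)) {
        net <- apply_lesion(net, lesion, seed = seed_hash(master_seed, i, 2))
      }
      pw <- on_drive_powers(
        run_drive_trials(net, drives, master_seed, i, drive_args))
      data.frame(subject = i, group = group, seed = sseed,
                 p20 = pw[["20"]], p30 = pw[["30"]], p40 = pw[["40"]],
                 ok = TRUE, error = "")
    }, error = function(e) {
      data.frame(subject = i, group = group, seed = sseed,
                 p20 = NA_real_, p30 = NA_real_, p40 = NA_real_,
                 ok = FALSE, error = conditionMessage(e))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-design ANOVA of cohort band powers
#'
#' Group (between subjects) x Frequency (20/30/40 Hz, repeated measures),
#' with the Greenhouse-Geisser sphericity correction applied to the
#' within-subject effects.
#'
#' @param records rows from [generate_cohort()] for both groups (columns
#'   `subject`, `group`, `p20`, `p30`, `p40`; subjects must be unique
#'   within group).
#' @return data.frame: one row per effect with `F`, `df1`, `df2`, `p`,
#'   `epsilon` and the corrected `p_gg`.
#' @export
mixed_anova <- function(records) {
  if ("ok" %in% names(records)) records <- records[records$ok, , drop = FALSE]
  need <- c("subject", "group", "p20", "p30", "p40")
  abort_if(!all(need %in% names(records)),
           "records need columns: %s", paste(need, collapse = ", "))
  abort_if(anyNA(records[, c("p20", "p30", "p40")]),
           "missing band powers: unbalanced cells are not supported")
  groups <- unique(records$group)
  abort_if(length(groups) < 2, "need at least two groups")
  abort_if(any(table(records$group) < 2), "need >= 2 subjects per group")

  long <- data.frame(
    sid = factor(rep(paste(records$group, records$subject), 3)),
    group = factor(rep(records$group, 3)),
    freq = factor(rep(c(20, 30, 40), each = nrow(records))),
    power = c(records$p20, records$p30, records$p40))
  fit <- aov(power ~ group * freq + Error(sid / freq), data = long)
  sm <- summary(fit)

  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  g <- pick("Error: sid", "group")
  f <- pick("Error: sid:freq", "freq")
  gf <- pick("Error: sid:freq", "group:freq")

  eps <- gg_epsilon(as.matrix(records[, c("p20", "p30", "p40")]),
                    records$group)
  corr_p <- function(e) pf(e[["F"]], eps * e[["df1"]], eps * e[["df2"]],
                           lower.tail = FALSE)
  out <- data.frame(
    effect = c("group", "frequency", "group:frequency"),
    F = c(g[["F"]], f[["F"]], gf[["F"]]),
    df1 = c(g[["df1"]], f[["df1"]], gf[["df1"]]),
    df2 = c(g[["df2"]], f[["df2"]], gf[["df2"]]),
    p = c(g[["p"]], f[["p"]], gf[["p"]]),
    epsilon = c(NA, eps, eps),
    p_gg = c(NA, corr_p(f), corr_p(gf)))
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the repeated measures. epsilon = (sum lambda)^2 / ((k-1) sum lambda^2)
# over the eigenvalues of the double-centred covariance matrix; bounded in
# (1/(k-1), 1].
gg_epsilon <- function(Y, group) {
  k <- ncol(Y)
  gs <- split(seq_len(nrow(Y)), group)
  S <- matrix(0, k, k)
  dfree <- 0
  for (idx in gs) {
    if (length(idx) > 1) {
      S <- S + stats::cov(Y[idx, , drop = FALSE]) * (length(idx) - 1)
      dfree <- dfree + length(idx) - 1
    }
  }
  S <- S / dfree
  M <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(abs(lam))]
  if (length(lam) == 0) return(1)
  min(1, sum(lam)^2 / ((k - 1) * sum(lam^2)))
}

#' Hierarchical (nested) regression
#'
#' Fits `outcome ~ step1` then `outcome ~ step1 + step2` and reports the
#' increment: delta R^2, the delta-F change test and its p value. Used to
#' ask whether Group still predicts 40 Hz power once 20 and 30 Hz power
#' are controlled for (and vice versa).
#'
#' @param data data.frame of predictors and outcome.
#' @param outcome column name of the outcome.
#' @param step1 character vector of first-step predictors.
#' @param step2 character vector of predictors added in the second step.
#' @return one-row data.frame: `r2_step1`, `r2_step2`, `delta_r2`,
#'   `delta_F`, `df1`, `df2`, `p`.
#' @export
hierarchical_regression <- function(data, outcome, step1, step2) {
  abort_if(!outcome %in% names(data), "unknown outcome '%s'", outcome)
  abort_if(!all(c(step1, step2) %in% names(data)),
           "unknown predictor column(s)")
  f1 <- stats::reformulate(step1, outcome)
  f2 <- stats::reformulate(c(step1, step2), outcome)
  m1 <- lm(f1, data = data)
  m2 <- lm(f2, data = data)
  abort_if(any(is.na(stats::coef(m2))),
           "singular design: step-2 predictors are collinear with step 1")
  r2 <- function(m) summary(m)$r.squared
  cmp <- anova(m1, m2)
  data.frame(r2_step1 = r2(m1), r2_step2 = r2(m2),
             delta_r2 = r2(m2) - r2(m1),
             delta_F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
             p = cmp$`Pr(>F)`[2])
}

#' Factorial ANOVA of virtual-medication scores
#'
#' Decomposes wellness scores over the five graded drug mechanisms with
#' main effects and interactions up to `max_order` (default 3: 5 main +
#' 10 two-way + 10 three-way terms). The mechanisms are graded numeric
#' doses, so each term carries a single degree of freedom. Zero-score
#' (failed) trials are excluded by default, which unbalances the design;
#' Type-II sums of squares are therefore used.
#'
#' @param scored data.frame with the five factor columns and a `score`
#'   column (e.g. an `hg_sweep_result` collapsed to one row per point).
#' @param factors factor column names.
#' @param max_order highest interaction order.
#' @param drop_zero exclude `score == 0` trials (the failed trials).
#' @return data.frame: `term`, `order`, `sum_sq`, `df`, `F`, `p`,
#'   `significant` (p < 0.001).
#' @export
factorial_anova <- function(scored,
                            factors = c("ampa_gmax", "alpha2", "nmda",
                                        "ampa_tau2", "cr_weight"),
                            max_order = 3, drop_zero = TRUE) {
  abort_if(!all(factors %in% names(scored)), "missing factor column(s)")
  abort_if(!"score" %in% names(scored), "missing score column")
  df <- unique(scored[, c(factors, "score"), drop = FALSE])
  if (drop_zero) df <- df[df$score > 0, , drop = FALSE]
  abort_if(nrow(df) == 0 || all(df$score == 0),
           "no non-zero scores to analyse")
  fml <- stats::as.formula(paste("score ~ (",
                                 paste(factors, collapse = " + "),
                                 ") ^", max_order))
  fit <- lm(fml, data = df)
  tab <- car::Anova(fit, type = 2)
  terms <- rownames(tab)
  keep <- terms != "Residuals"
  out <- data.frame(term = terms[keep],
                    order = lengths(strsplit(terms[keep], ":", fixed = TRUE)),
                    sum_sq = tab[keep, "Sum Sq"],
                    df = tab[keep, "Df"],
                    F = tab[keep, "F value"],
                    p = tab[keep, "Pr(>F)"])
  out$significant <- !is.na(out$p) & out$p < 0.001
  out <- out[order(out$order, match(out$term, terms)), ]
  rownames(out) <- NULL
  out
}
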