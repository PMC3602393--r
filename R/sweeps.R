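# Grid enumeration and sweep execution.
#
# The lesion sweep walks the full 10 x 13 x 7 = 910 grid (NMDA reduction x
# spine reduction x GABA ordered pair); the virtual-medication trial walks
# the 5 x 5 x 5 x 3 x 4 = 1500 drug grid. Every grid point is seeded from
# the master seed and its own coordinates, so any subset reproduces the
# full run point-for-point.

#' Enumerate the lesion grid
#'
#' @param nmda,spine,gaba_pair axis level vectors; defaults are the full
#'   grids from the parameter file (10, 13 and 7 levels).
#' @param params parameter list.
#' @return data.frame, one row per grid point, in deterministic
#'   lexicographic order (first axis varying fastest).
#' @export
lesion_grid <- function(nmda = NULL, spine = NULL, gaba_pair = NULL,
                        params = default_params()) {
  g <- params$lesion_grid
  nmda <- nmda %||% as.numeric(g$nmda)
  spine <- spine %||% as.numeric(g$spine)
  gaba_pair <- gaba_pair %||% (seq_along(g$gaba_pairs$tone) - 1L)
  abort_if(length(nmda) == 0 || length(spine) == 0 || length(gaba_pair) == 0,
           "empty grid axis")
  expand.grid(nmda = nmda, spine = spine, gaba_pair = gaba_pair,
              KEEP.OUT.ATTRS = FALSE)
}

#' Enumerate the GABA-deficit decomposition grid
#'
#' The full 7 x 7 factorial of tone reduction and postsynaptic weight
#' increase (49 independent pairs), as opposed to the 7 ordered pairs used
#' on the main lesion grid.
#'
#' @param tone,weight level vectors (fractions).
#' @param params parameter list.
#' @return data.frame with columns `tone`, `weight`.
#' @export
gaba_decomposition_grid <- function(tone = NULL, weight = NULL,
                                    params = default_params()) {
  g <- params$lesion_grid$gaba_pairs
  tone <- tone %||% as.numeric(g$tone)
  weight <- weight %||% as.numeric(g$weight)
  expand.grid(tone = tone, weight = weight, KEEP.OUT.ATTRS = FALSE)
}

#' Enumerate the virtual-medication grid
#'
#' Cartesian product of the five drug mechanisms (Table-1 axes by
#' default: 5 x 5 x 5 x 3 x 4 = 1500 combinations, including the all-control
#' point).
#'
#' @param ampa_gmax,alpha2,nmda,ampa_tau2,cr_weight axis level vectors.
#' @param params parameter list.
#' @return data.frame, one row per virtual medication.
#' @export
drug_grid <- function(ampa_gmax = NULL, alpha2 = NULL, nmda = NULL,
                      ampa_tau2 = NULL, cr_weight = NULL,
                      params = default_params()) {
  g <- params$drug_grid
  expand.grid(ampa_gmax = ampa_gmax %||% as.numeric(g$ampa_gmax),
              alpha2 = alpha2 %||% as.numeric(g$alpha2),
              nmda = nmda %||% as.numeric(g$nmda),
              ampa_tau2 = ampa_tau2 %||% as.numeric(g$ampa_tau2),
              cr_weight = cr_weight %||% as.numeric(g$cr_weight),
              KEEP.OUT.ATTRS = FALSE)
}

#' Enumerate the ampakine dose scan
#'
#' AMPA `g_max` increase levels crossed with AMPA `tau2` lengthening
#' levels (6 x 5 = 30 iterations by default).
#'
#' @param gmax_increase,tau2_increase percent level vectors.
#' @param params parameter list.
#' @return data.frame with columns `gmax_increase`, `tau2_increase`.
#' @export
ampakine_grid <- function(gmax_increase = NULL, tau2_increase = NULL,
                          params = default_params()) {
  g <- params$control_drugs$ampakine
  expand.grid(gmax_increase = gmax_increase %||% as.numeric(g$gmax_increase),
              tau2_increase = tau2_increase %||% as.numeric(g$tau2_increase),
              KEEP.OUT.ATTRS = FALSE)
}

# on-drive band powers: run one trial per drive and read the power at the
# drive's own frequency (plus the full triplet per drive)
run_drive_trials <- function(net, drives, master_seed, point_key,
                             drive_args = list()) {
  res <- list()
  for (f in drives) {
    dr <- do.call(drive_spec,
                  c(list(frequency = f, params = net$params), drive_args))
    trial <- run_ssep_trial(net, dr,
                            seed = seed_hash(master_seed, point_key, f))
    spec <- power_spectrum(trial$trace)
    res[[as.character(f)]] <- band_powers(spec)
  }
  res
}

on_drive_powers <- function(trial_powers) {
  setNames(vapply(names(trial_powers),
                  function(f) trial_powers[[f]][[f]], numeric(1)),
           names(trial_powers))
}

#' Baseline (control) on-drive band powers
#'
#' Runs the unlesioned network at each drive frequency (optionally
#' averaged over replicate seeds) and returns the power at the drive's own
#' frequency — the reference triplet for [illness_metric()] and
#' [wellness_metric()].
#'
#' @param net the control `hg_network`.
#' @param drives drive frequencies, Hz.
#' @param master_seed seed.
#' @param n_reps replicate trials to average.
#' @param drive_args extra arguments for [drive_spec()].
#' @return named numeric vector of on-drive powers.
#' @export
compute_baseline <- function(net, drives = c(20, 30, 40), master_seed = 1L,
                             n_reps = 1L, drive_args = list()) {
  acc <- NULL
  for (r in seq_len(n_reps)) {
    p <- on_drive_powers(
      run_drive_trials(net, drives, seed_hash(master_seed, 1000 + r), 0,
                       drive_args))
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / n_reps
}

#' Execute a sweep over a lesion or drug grid
#'
#' For each grid point the declarative transform is applied to a copy of
#' the base network, one trial per drive frequency is run (each with its
#' own coordinate-derived seed), band powers extracted and the point
#' scored against the baseline. Per-point failures are recorded and the
#' sweep continues.
#'
#' @param net the base `hg_network` (control network for a lesion sweep;
#'   the schizophrenic model for a drug sweep).
#' @param grid a [lesion_grid()], [gaba_decomposition_grid()] or
#'   [drug_grid()] table (possibly subsampled).
#' @param baseline reference on-drive powers from [compute_baseline()].
#' @param metric `"illness"` (lesion sweeps) or `"wellness"` (drug
#'   trials).
#' @param drives drive frequencies, Hz.
#' @param master_seed master seed; per-point seeds derive from it and the
#'   grid coordinates.
#' @param cfg an [metric_config()].
#' @param drive_args extra arguments for [drive_spec()] (e.g. a shorter
#'   `duration_ms` for desk-scale runs).
#' @param gaba_pairs ordered-pair table for lesion grids.
#' @param checkpoint optional CSV path: completed points are appended and
#'   skipped on resume.
#' @return data.frame of class `hg_sweep_result`: one row per grid point
#'   per drive with the band-power triplet, the point's score and seed.
#' @export
run_sweep <- function(net, grid, baseline, metric = c("illness", "wellness"),
                      drives = c(20, 30, 40), master_seed = 1L,
                      cfg = NULL, drive_args = list(), gaba_pairs = NULL,
                      checkpoint = NULL) {
  metric <- match.arg(metric)
  if (is.null(cfg)) cfg <- metric_config(params = net$params)
  score_fun <- if (metric == "illness") illness_metric else wellness_metric
  kind <- grid_kind(grid)
  done <- integer(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- read.csv(checkpoint)
    done <- unique(prev$point)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (i %in% done) next
    coords <- as.numeric(grid[i, ])
    point_seed <- seed_hash(master_seed, coords)
    rec <- tryCatch({
      net_i <- apply_grid_point(net, grid[i, ], kind, point_seed,
                                gaba_pairs = gaba_pairs)
      pw <- run_drive_trials(net_i, drives, master_seed, coords, drive_args)
      test <- on_drive_powers(pw)
      score <- score_fun(baseline, test, cfg)
      do.call(rbind, lapply(names(pw), function(f) {
        cbind(data.frame(point = i), grid[i, , drop = FALSE],
              data.frame(drive = as.numeric(f),
                         p20 = pw[[f]][["20"]], p30 = pw[[f]][["30"]],
                         p40 = pw[[f]][["40"]], score = score,
                         seed = point_seed, ok = TRUE, error = ""))
      }))
    }, error = function(e) {
      cbind(data.frame(point = i), grid[i, , drop = FALSE],
            data.frame(drive = NA_real_, p20 = NA_real_, p30 = NA_real_,
                       p40 = NA_real_, score = NA_real_, seed = point_seed,
                       ok = FALSE, error = conditionMessage(e)))
    })
    rows[[i]] <- rec
    if (!is.null(checkpoint)) {
      write.table(rec, checkpoint, sep = ",", append = file.exists(checkpoint),
                  col.names = !file.exists(checkpoint), row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(checkpoint) && length(done)) out <- rbind(prev, out)
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "baseline") <- baseline
  attr(out, "axes") <- names(grid)
  class(out) <- c("hg_sweep_result", class(out))
  out
}

grid_kind <- function(grid) {
  if (all(c("nmda", "spine", "gaba_pair") %in% names(grid))) return("lesion")
  if (all(c("tone", "weight") %in% names(grid))) return("gaba")
  if (all(c("ampa_gmax", "alpha2", "nmda", "ampa_tau2", "cr_weight")
          %in% names(grid))) return("drug")
  stop("unrecognised grid columns: ", paste(names(grid), collapse = ", "))
}

apply_grid_point <- function(net, row, kind, seed, gaba_pairs = NULL) {
  switch(kind,
    lesion = apply_lesion(
      net, lesion_spec(row$nmda, row$spine, row$gaba_pair,
                       gaba_pairs = gaba_pairs, params = net$params), seed),
    gaba = {
      # independent (tone, weight) pair: reuse the lesion machinery with a
      # one-row pair table
      pairs <- data.frame(tone = c(0, row$tone), weight = c(0, row$weight))
      apply_lesion(net, lesion_spec(0, 0, 1L, gaba_pairs = pairs,
                                    params = net$params), seed)
    },
    drug = apply_drug(
      net, drug_spec(row$ampa_gmax, row$alpha2, row$nmda, row$ampa_tau2,
                     row$cr_weight, params = net$params)))
}

#' Dose scan of a negative-control agent
#'
#' Applies a named control drug (phenytoin: Na conductance reduction;
#' nifedipine: Ca conductance reduction; ampakine: AMPA `g_max` and `tau2`
#' increases) at each dose to the supplied model and records the raw
#' band-power triplet per dose per drive. No score is attached: the point
#' of the scan is that no dose selectively restores the 40 Hz response.
#'
#' @param net the test model (typically the primary-point schizophrenic
#'   network).
#' @param name `"phenytoin"`, `"nifedipine"` or `"ampakine"`.
#' @param doses dose vector (fractions) for phenytoin / nifedipine; for the
#'   ampakine the [ampakine_grid()] is used instead.
#' @param drives drive frequencies, Hz.
#' @param master_seed master seed.
#' @param drive_args extra arguments for [drive_spec()].
#' @param params parameter list.
#' @return data.frame, one row per dose per drive.
#' @export
scan_control_drug <- function(net, name = c("phenytoin", "nifedipine",
                                            "ampakine"),
                              doses = NULL, drives = c(20, 30, 40),
                              master_seed = 1L, drive_args = list(),
                              params = NULL) {
  name <- match.arg(name)
  if (is.null(params)) params <- net$params
  rows <- list()
  if (name == "ampakine") {
    gridd <- ampakine_grid(params = params)
    for (i in seq_len(nrow(gridd))) {
      dr <- control_drug_spec("ampakine",
                              gmax_increase = gridd$gmax_increase[i],
                              tau2_increase = gridd$tau2_increase[i])
      pw <- run_drive_trials(apply_drug(net, dr), drives, master_seed,
                             as.numeric(gridd[i, ]), drive_args)
      rows[[i]] <- do.call(rbind, lapply(names(pw), function(f) {
        cbind(gridd[i, , drop = FALSE],
              data.frame(drive = as.numeric(f), p20 = pw[[f]][["20"]],
                         p30 = pw[[f]][["30"]], p40 = pw[[f]][["40"]]))
      }))
    }
  } else {
    doses <- doses %||% as.numeric(params$control_drugs[[name]]$doses)
    for (i in seq_along(doses)) {
      dr <- control_drug_spec(name, dose = doses[i])
      pw <- run_drive_trials(apply_drug(net, dr), drives, master_seed,
                             doses[i] * 1000, drive_args)
      rows[[i]] <- do.call(rbind, lapply(names(pw), function(f) {
        data.frame(dose = doses[i], drive = as.numeric(f),
                   p20 = pw[[f]][["20"]], p30 = pw[[f]][["30"]],
                   p40 = pw[[f]][["40"]])
      }))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect clusters of high-scoring grid points
#'
#' Connected components, among points with `score > threshold`, of the
#' grid graph whose edges join points one level step apart along exactly
#' one axis. Clusters are returned sorted by their peak score.
#'
#' @param results an `hg_sweep_result` (or any data.frame with axis
#'   columns and a `score` column; multiple drive rows per point are
#'   collapsed).
#' @param threshold score threshold (default 0.65).
#' @param axes axis column names; defaults to the sweep's grid axes.
#' @return list of clusters; each has `points` (data.frame of member grid
#'   points with scores), `peak` (the best row) and `peak_score`.
#' @export
find_clusters <- function(results, threshold = 0.65, axes = NULL) {
  if (is.null(axes)) axes <- attr(results, "axes")
  if (is.null(axes)) {
    axes <- setdiff(names(results),
                    c("point", "drive", "p20", "p30", "p40", "score",
                      "seed", "ok", "error"))
  }
  df <- unique(results[, c(axes, "score"), drop = FALSE])
  df <- df[is.finite(df$score), , drop = FALSE]
  sel <- which(df$score > threshold)
  if (length(sel) == 0) return(list())
  pts <- df[sel, , drop = FALSE]
  lev <- vapply(axes, function(a) match(pts[[a]], sort(unique(df[[a]]))),
                numeric(nrow(pts)))
  lev <- matrix(lev, nrow = nrow(pts))
  n <- nrow(pts)
  edges <- NULL
  if (n > 1) {
    pr <- utils::combn(n, 2)
    d <- abs(lev[pr[1, ], , drop = FALSE] - lev[pr[2, ], , drop = FALSE])
    adj <- rowSums(d) == 1 & apply(d, 1, max) == 1
    edges <- pr[, adj, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)$membership
  clusters <- lapply(seq_len(max(comp)), function(k) {
    member <- pts[comp == k, , drop = FALSE]
    peak <- member[which.max(member$score), , drop = FALSE]
    list(points = member, peak = peak, peak_score = peak$score)
  })
  clusters[order(vapply(clusters, `[[`, numeric(1), "peak_score"),
                 decreasing = TRUE)]
}
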