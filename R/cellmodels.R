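# Multicompartment cell models.
#
# A cell is a tree of cylindrical compartments (soma root) with role-based
# channel densities distributed along the somato-dendritic axis. Two stock
# morphologies per type: "full" (64-compartment pyramidal cell,
# 46-compartment interneuron, matching the cited compartmental models) and
# "reduced" (8 / 5 compartments, the desk-scale default).

.hg_roles <- c("soma", "apical_dendrite", "basal_dendrite",
               "initial_segment", "axon")

#' Build a compartmental cell model
#'
#' @param cell_type one of `"pyramidal"`, `"basket"`, `"chandelier"`,
#'   `"calretinin"`. The three interneuron types share the interneuron
#'   morphology and channel distribution; they differ in their axonal
#'   projection patterns, which live in the network connectivity rules.
#' @param morphology `"reduced"`, `"full"`, a compartment count, or a
#'   data.frame with columns `role`, `length_um`, `diam_um`, `parent`
#'   (root has `parent = NA`).
#' @param params parameter list, see [default_params()].
#' @return an object of class `hg_cell`.
#' @examples
#' cell <- build_cell("pyramidal", "reduced")
#' nrow(cell$comps)
#' @export
build_cell <- function(cell_type = c("pyramidal", "basket", "chandelier",
                                     "calretinin"),
                       morphology = NULL, params = default_params()) {
  cell_type <- match.arg(cell_type)
  kind <- if (cell_type == "pyramidal") "pyramidal" else "interneuron"
  mp <- params$morphology
  if (is.null(morphology)) morphology <- mp$default

  if (is.data.frame(morphology)) {
    comps <- morphology
    variant <- "custom"
  } else {
    if (is.character(morphology)) {
      abort_if(!morphology %in% c("reduced", "full"),
               "unknown morphology '%s'", morphology)
      n <- mp[[kind]][[morphology]]
      variant <- morphology
    } else {
      n <- as.integer(morphology)
      variant <- if (n <= 10) "reduced" else "full"
    }
    abort_if(n < 1, "compartment count must be >= 1")
    comps <- make_morphology(kind, n, mp$dims_um[[variant]])
  }
  validate_morphology(comps)

  dens <- params$channel_densities[[kind]]
  for (role in unique(comps$role)) {
    abort_if(is.null(dens[[role]]),
             "no channel densities configured for role '%s'", role)
    unknown <- setdiff(names(dens[[role]]), .hg_channels)
    abort_if(length(unknown) > 0, "unknown channel name: %s",
             paste(unknown, collapse = ", "))
  }

  structure(list(cell_type = cell_type, kind = kind, variant = variant,
                 comps = comps, densities = dens,
                 membrane = params$membrane),
            class = "hg_cell")
}

# Deterministic stock morphology: soma root, initial segment (pyramidal),
# then basal and apical chains. The middle apical compartment is the
# click-train drive target.
make_morphology <- function(kind, n, dims) {
  soma <- dims$soma; iseg <- dims$initial_segment; dend <- dims$dendrite
  role <- character(n); len <- numeric(n); dia <- numeric(n)
  parent <- rep(NA_integer_, n)
  role[1] <- "soma"; len[1] <- soma[1]; dia[1] <- soma[2]
  if (n == 1) {
    return(data.frame(comp = 1L, role = role, length_um = len,
                      diam_um = dia, parent = parent))
  }
  i <- 2L
  if (kind == "pyramidal") {
    role[i] <- "initial_segment"; len[i] <- iseg[1]; dia[i] <- iseg[2]
    parent[i] <- 1L
    i <- i + 1L
  }
  n_dend <- n - i + 1L
  if (n_dend > 0) {
    n_basal <- if (kind == "pyramidal") max(0L, floor(n_dend / 3)) else n_dend
    n_apical <- n_dend - n_basal
    prev <- 1L
    for (k in seq_len(n_basal)) {
      role[i] <- "basal_dendrite"; len[i] <- dend[1]; dia[i] <- dend[2]
      parent[i] <- prev; prev <- i
      i <- i + 1L
    }
    prev <- 1L
    for (k in seq_len(n_apical)) {
      role[i] <- "apical_dendrite"; len[i] <- dend[1]; dia[i] <- dend[2]
      parent[i] <- prev; prev <- i
      i <- i + 1L
    }
  }
  data.frame(comp = seq_len(n), role = role, length_um = len,
             diam_um = dia, parent = parent)
}

validate_morphology <- function(comps) {
  need <- c("role", "length_um", "diam_um", "parent")
  abort_if(!all(need %in% names(comps)),
           "morphology table needs columns: %s", paste(need, collapse = ", "))
  abort_if(!all(comps$role %in% .hg_roles),
           "unknown compartment role(s): %s",
           paste(setdiff(comps$role, .hg_roles), collapse = ", "))
  abort_if(any(comps$length_um <= 0) || any(comps$diam_um <= 0),
           "compartment lengths and diameters must be positive")
  n <- nrow(comps)
  roots <- which(is.na(comps$parent))
  abort_if(length(roots) != 1L, "morphology is not a tree: %d roots",
           length(roots))
  # walk to root from every compartment; cycles never reach it
  for (i in seq_len(n)) {
    seen <- 0L; j <- i
    while (!is.na(comps$parent[j])) {
      j <- comps$parent[j]
      abort_if(j < 1 || j > n, "morphology parent index out of range")
      seen <- seen + 1L
      abort_if(seen > n, "morphology is not a tree: cycle detected")
    }
  }
  invisible(TRUE)
}

# the drive / spine reference compartment: middle of the apical chain
mid_apical_comp <- function(comps) {
  ap <- which(comps$role == "apical_dendrite")
  if (length(ap) == 0) ap <- which(comps$role == "basal_dendrite")
  if (length(ap) == 0) return(1L)
  ap[ceiling(length(ap) / 2)]
}

#' @export
print.hg_cell <- function(x, ...) {
  cat(sprintf("<hg_cell> %s (%s): %d compartments (%s)\n",
              x$cell_type, x$kind, nrow(x$comps),
              paste(sprintf("%s x%d", names(table(x$comps$role)),
                            as.integer(table(x$comps$role))), collapse = ", ")))
  invisible(x)
}

#' Initialise the integration state of a cell
#'
#' Gates start at their voltage-clamp steady state for `v`; the cell is
#' then relaxed input-free (default 1 s) so the returned state sits at the
#' resting fixed point of the full channel set (which lies a few mV below
#' the leak reversal because of the resting potassium conductances).
#'
#' @param cell an `hg_cell`.
#' @param v starting potential (mV); default the leak reversal.
#' @param relax_ms input-free relaxation time before the state is
#'   returned; 0 skips the relaxation.
#' @return an `hg_cell_state` list (`v`, `gates`, `chi`, `t_now`, ...).
#' @export
init_cell_state <- function(cell, v = NULL, relax_ms = 1000) {
  if (is.null(v)) v <- cell$membrane$e_leak_mV
  cc <- compile_cell(cell)
  out <- .sim_core(cc, core_opts(dt = 1e-4, n_steps = 1L, v_init = v))
  if (relax_ms > 0) {
    out <- .sim_core(cc, core_opts(dt = 0.05,
                                   n_steps = as.integer(relax_ms / 0.05),
                                   init_state = out$state))
  }
  st <- out$state
  st$t_now <- 0
  st$t_last_spike <- rep(-1e9, length(st$t_last_spike))
  class(st) <- "hg_cell_state"
  st
}

#' Advance a cell one (or more) integration steps
#'
#' Exponential-Euler update of voltages, gates and the calcium pool. Spike
#' times (upward somatic crossings of the configured threshold, with a
#' refractory lockout) are detected as they occur.
#'
#' @param cell an `hg_cell`.
#' @param state an `hg_cell_state` from [init_cell_state()] or a previous
#'   call.
#' @param dt time step, ms.
#' @param i_inj injected current per compartment, nA: either `NULL`, a
#'   single value (applied at the soma) or a vector over compartments.
#' @param n_steps number of steps to advance.
#' @return list with the updated `state`, the somatic voltage trace `v_soma`
#'   and any `spike_times` (ms).
#' @export
step_cell <- function(cell, state, dt, i_inj = NULL, n_steps = 1L) {
  abort_if(dt <= 0, "dt must be positive")
  cc <- compile_cell(cell)
  ncomp <- nrow(cell$comps)
  if (!is.null(i_inj)) {
    if (length(i_inj) == 1L) {
      cc$inj_comp <- 0L; cc$inj_amp <- i_inj * 1e-3
    } else {
      abort_if(length(i_inj) != ncomp,
               "i_inj must have one entry per compartment")
      nz <- which(i_inj != 0)
      cc$inj_comp <- as.integer(nz - 1L); cc$inj_amp <- i_inj[nz] * 1e-3
    }
    cc$inj_on <- rep(0L, length(cc$inj_comp))
    cc$inj_off <- rep(as.integer(n_steps), length(cc$inj_comp))
  }
  opts <- core_opts(dt = dt, n_steps = as.integer(n_steps),
                    init_state = unclass(state),
                    record_comps = 0L, t_start = state$t_now,
                    spike_threshold = cell$membrane$spike_threshold_mV %||% 0,
                    refractory_ms = cell$membrane$refractory_ms %||% 2)
  out <- .sim_core(cc, opts)
  st <- out$state
  st$t_now <- state$t_now + n_steps * dt
  class(st) <- "hg_cell_state"
  list(state = st, v_soma = out$vtrace[, 1], spike_times = out$spike_time)
}

#' Simulate an isolated cell under current injection
#'
#' @param cell an `hg_cell`.
#' @param duration_ms simulated time, ms.
#' @param dt integration step, ms.
#' @param i_inj `NULL` or a data.frame with columns `comp`, `amp_nA`,
#'   `on_ms`, `off_ms` describing constant current steps.
#' @param record compartments whose voltage to record (default soma).
#' @param v_init initial voltage, mV.
#' @return list: `t` (ms), `v` (matrix, one column per recorded
#'   compartment), `spike_times` (ms), final `state`.
#' @export
simulate_cell <- function(cell, duration_ms, dt = 0.025, i_inj = NULL,
                          record = 1L, v_init = NULL) {
  abort_if(dt <= 0, "dt must be positive")
  n_steps <- as.integer(round(duration_ms / dt))
  cc <- compile_cell(cell)
  if (!is.null(i_inj)) {
    cc$inj_comp <- as.integer(i_inj$comp - 1L)
    cc$inj_amp <- i_inj$amp_nA * 1e-3
    cc$inj_on <- as.integer(round(i_inj$on_ms / dt))
    cc$inj_off <- as.integer(round(i_inj$off_ms / dt))
  }
  if (is.null(v_init)) v_init <- cell$membrane$e_leak_mV
  opts <- core_opts(dt = dt, n_steps = n_steps, v_init = v_init,
                    record_comps = as.integer(record - 1L))
  out <- .sim_core(cc, opts)
  list(t = seq_len(n_steps) * dt, v = out$vtrace,
       spike_times = out$spike_time, state = out$state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
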