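# Translation of R-level cell / network tables into the flat arrays the
# compiled integrator consumes. Units: compartment dimensions in um are
# converted to cm; conductances to absolute mS (density x area); currents uA.

# per-compartment electrical quantities for one comps table + density set
comp_electrics <- function(comps, densities, membrane) {
  n <- nrow(comps)
  l_cm <- comps$length_um * 1e-4
  d_cm <- comps$diam_um * 1e-4
  area <- pi * d_cm * l_cm                      # cylinder side area, cm^2
  cm <- membrane$cm_uF_cm2 * area               # uF
  g_leak <- membrane$g_leak_mS_cm2 * area       # mS
  # axial conductance to parent: series of the two half-cylinder resistances
  g_ax <- numeric(n)
  r_cm <- d_cm / 2
  for (i in seq_len(n)) {
    p <- comps$parent[i]
    if (!is.na(p)) {
      R <- (membrane$ra_ohm_cm / pi) *
        ((l_cm[i] / 2) / r_cm[i]^2 + (l_cm[p] / 2) / r_cm[p]^2) # Ohm
      g_ax[i] <- 1e3 / R                                        # mS
    }
  }
  gchan <- matrix(0, n, length(.hg_channels),
                  dimnames = list(NULL, .hg_channels))
  for (i in seq_len(n)) {
    dset <- densities[[comps$role[i]]]
    for (ch in names(dset)) gchan[i, ch] <- dset[[ch]] * area[i]
  }
  list(area = area, cm = cm, g_leak = g_leak, g_ax = g_ax, gchan = gchan,
       ca_phi = membrane$ca_phi_per_area / area,
       ca_tau = rep(membrane$ca_tau_ms, n))
}

# single isolated cell -> core input list (no synapses)
compile_cell <- function(cell) {
  el <- comp_electrics(cell$comps, cell$densities, cell$membrane)
  mb <- cell$membrane
  list(
    parent = as.integer(ifelse(is.na(cell$comps$parent), -1L,
                               cell$comps$parent - 1L)),
    g_ax = el$g_ax, cm = el$cm, g_leak = el$g_leak,
    e_leak = rep(mb$e_leak_mV, nrow(cell$comps)),
    gchan = el$gchan, ca_phi = el$ca_phi, ca_tau = el$ca_tau,
    soma = 0L,
    e_na = mb$e_na_mV, e_ca = mb$e_ca_mV, e_k = mb$e_k_mV,
    st_comp = integer(0), st_e = numeric(0), st_tau1 = numeric(0),
    st_tau2 = numeric(0), st_nmda = integer(0), st_eeg = integer(0),
    out_ptr = c(0L, 0L), out_state = integer(0), out_delay = integer(0),
    out_amt = numeric(0),
    ev_state = integer(0), ev_step = integer(0), ev_amt = numeric(0),
    inj_comp = integer(0), inj_amp = numeric(0), inj_on = integer(0),
    inj_off = integer(0))
}

core_opts <- function(dt, n_steps, v_init = -60, init_state = list(),
                      spike_threshold = 0, refractory_ms = 2, mg_mM = 1,
                      record_comps = integer(0), record_every = 1L,
                      eeg = FALSE, t_start = 0) {
  list(dt = dt, n_steps = as.integer(n_steps), v_init = v_init,
       init_state = init_state, spike_threshold = spike_threshold,
       refractory_ms = refractory_ms, mg_mM = mg_mM,
       record_comps = as.integer(record_comps),
       record_every = as.integer(record_every), eeg = eeg,
       t_start = t_start)
}

# peak-normalisation factor of the dual exponential, so that g_max is the
# literal peak conductance
dual_exp_norm <- function(tau1, tau2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  1 / (exp(-tp / tau2) - exp(-tp / tau1))
}

# full network -> core input list; synapses are aggregated per
# (postsynaptic compartment, kinetic class) and presynaptic fan-out is laid
# out in CSR order over cells.
compile_network <- function(net, dt) {
  mb <- net$membrane
  comps <- net$comps
  el <- net$electrics # precomputed at build time

  syn <- net$synapses
  if (nrow(syn) > 0) {
    key <- paste(syn$post_comp, syn$kind, syn$tau1, syn$tau2, syn$e_rev,
                 sep = "/")
    sid <- match(key, unique(key))
    first <- !duplicated(sid)
    st_comp <- as.integer(syn$post_comp[first] - 1L)
    st_e <- syn$e_rev[first]
    st_tau1 <- syn$tau1[first]
    st_tau2 <- syn$tau2[first]
    st_nmda <- as.integer(syn$kind[first] == "NMDA")
    st_eeg <- as.integer(net$eeg_comp[syn$post_comp[first]])
    amt <- syn$weight * syn$g_max_nS * 1e-6 *
      dual_exp_norm(syn$tau1, syn$tau2)                       # mS per event
    ord <- order(syn$pre_cell, method = "radix")
    out_state <- as.integer(sid[ord] - 1L)
    out_amt <- amt[ord]
    out_delay <- as.integer(round(syn$delay_ms[ord] / dt))
    counts <- tabulate(syn$pre_cell, nbins = nrow(net$cells))
    out_ptr <- as.integer(c(0L, cumsum(counts)))
  } else {
    st_comp <- integer(0); st_e <- st_tau1 <- st_tau2 <- numeric(0)
    st_nmda <- st_eeg <- integer(0)
    out_state <- out_delay <- integer(0); out_amt <- numeric(0)
    out_ptr <- rep(0L, nrow(net$cells) + 1L)
  }

  list(
    parent = as.integer(ifelse(is.na(comps$parent_global), -1L,
                               comps$parent_global - 1L)),
    g_ax = el$g_ax, cm = el$cm, g_leak = el$g_leak,
    e_leak = rep(mb$e_leak_mV, nrow(comps)),
    gchan = as.matrix(comps[, paste0("g_", .hg_channels)]) * el$area,
    ca_phi = el$ca_phi, ca_tau = el$ca_tau,
    soma = as.integer(net$cells$soma_comp - 1L),
    e_na = mb$e_na_mV, e_ca = mb$e_ca_mV, e_k = mb$e_k_mV,
    st_comp = st_comp, st_e = st_e, st_tau1 = st_tau1, st_tau2 = st_tau2,
    st_nmda = st_nmda, st_eeg = st_eeg,
    out_ptr = out_ptr, out_state = out_state, out_delay = out_delay,
    out_amt = out_amt,
    ev_state = integer(0), ev_step = integer(0), ev_amt = numeric(0),
    inj_comp = integer(0), inj_amp = numeric(0), inj_on = integer(0),
    inj_off = integer(0))
}

# single compiled entry point
.sim_core <- function(net, opts) {
  .Call("hg_sim_core", net, opts, PACKAGE = "hippogamma")
}
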