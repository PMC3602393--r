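# Compartmental cell models: morphology construction, channel validation,
# integration accuracy and qualitative firing behaviour.

test_that("stock morphologies have the configured compartment counts", {
  expect_equal(nrow(build_cell("pyramidal", "full")$comps), 64)
  expect_equal(nrow(build_cell("basket", "full")$comps), 46)
  expect_equal(nrow(build_cell("pyramidal", "reduced")$comps), 8)
  expect_equal(nrow(build_cell("chandelier", "reduced")$comps), 5)
  one <- build_cell("pyramidal", 1)
  expect_equal(nrow(one$comps), 1)
  expect_equal(one$comps$role, "soma")
})

test_that("pyramidal cells carry an initial segment; morphology is a tree", {
  cell <- build_cell("pyramidal", "reduced")
  expect_true("initial_segment" %in% cell$comps$role)
  expect_equal(sum(is.na(cell$comps$parent)), 1)
  # identical calls give identical tables (deterministic construction)
  expect_identical(cell$comps, build_cell("pyramidal", "reduced")$comps)
})

test_that("bad channel names and non-tree morphologies are rejected", {
  p <- default_params()
  p$channel_densities$pyramidal$soma$Kv7 <- 1
  expect_error(build_cell("pyramidal", "reduced", params = p),
               "unknown channel")
  loop <- data.frame(role = c("soma", "apical_dendrite", "apical_dendrite"),
                     length_um = 50, diam_um = 2, parent = c(NA, 3L, 2L))
  expect_error(build_cell("pyramidal", loop), "cycle")
  two_roots <- data.frame(role = c("soma", "apical_dendrite"),
                          length_um = 50, diam_um = 2,
                          parent = c(NA, NA))
  expect_error(build_cell("pyramidal", two_roots), "root")
})

test_that("voltage-gated channels relax to their clamp steady state", {
  # hold the compartment at -30 mV with an overwhelming leak and compare
  # relaxed gates to alpha/(alpha+beta) computed from the rate functions
  v_hold <- -30
  p <- default_params(list(
    membrane = list(e_leak_mV = v_hold, g_leak_mS_cm2 = 1e5)))
  cell <- build_cell("pyramidal", 1, params = p)
  st <- init_cell_state(cell, v = -70, relax_ms = 0) # gates at -70 steady state
  out <- step_cell(cell, st, dt = 0.01, n_steps = 20000) # 200 ms clamped
  g <- out$state$gates[1, ]

  u <- v_hold + 60
  vtrap <- function(x, y) ifelse(abs(x) < 1e-7, y, x / expm1(x / y))
  rates <- list(
    m = c(0.32 * vtrap(13.1 - u, 4), 0.28 * vtrap(u - 40.1, 5)),
    h = c(0.128 * exp((17 - u) / 18), 4 / (1 + exp((40 - u) / 5))),
    s = c(1.6 / (1 + exp(-0.072 * (u - 65))), 0.02 * vtrap(u - 51.1, 5)),
    n = c(0.016 * vtrap(35.1 - u, 5), 0.25 * exp((20 - u) / 40)),
    a = c(0.02 * vtrap(13.1 - u, 10), 0.0175 * vtrap(u - 40.1, 10)),
    b = c(0.0016 * exp((-13 - u) / 18), 0.05 / (1 + exp((10.1 - u) / 5))))
  for (k in seq_along(rates)) {
    ab <- rates[[k]]
    # reached to 1e-3 (absolute) after >> 10/(alpha+beta) ms
    expect_lt(abs(g[[k]] - ab[1] / sum(ab)), 1e-3)
  }
})

test_that("a relaxed cell is a fixed point: free run drifts < 0.5 mV", {
  cell <- build_cell("pyramidal", "reduced")
  st <- init_cell_state(cell)
  out <- step_cell(cell, st, dt = 0.025, n_steps = 4000) # 100 ms
  expect_lt(max(abs(out$v_soma - out$v_soma[1])), 0.5)
  expect_length(out$spike_times, 0)
})

test_that("suprathreshold step firing matches a fine-timestep reference", {
  cell <- build_cell("pyramidal", "reduced")
  inj <- data.frame(comp = 1, amp_nA = 1.5, on_ms = 20, off_ms = 180)
  coarse <- simulate_cell(cell, 200, dt = 0.025, i_inj = inj)
  fine <- simulate_cell(cell, 200, dt = 0.0025, i_inj = inj)
  expect_gt(length(coarse$spike_times), 3) # tonic firing under current
  expect_lte(abs(length(coarse$spike_times) - length(fine$spike_times)), 1)
})

test_that("integrator converges under dt halving on subthreshold input", {
  cell <- build_cell("pyramidal", "reduced")
  inj <- data.frame(comp = 1, amp_nA = 0.04, on_ms = 20, off_ms = 180)
  a <- simulate_cell(cell, 200, dt = 0.025, i_inj = inj, v_init = -70)
  b <- simulate_cell(cell, 200, dt = 0.0125, i_inj = inj, v_init = -70)
  expect_length(a$spike_times, 0)
  vb <- b$v[seq(2, nrow(b$v), by = 2), 1]
  expect_lt(sqrt(mean((a$v[, 1] - vb)^2)), 1)
})

test_that("sodium-free cells cannot spike", {
  p <- default_params()
  for (role in names(p$channel_densities$pyramidal)) {
    p$channel_densities$pyramidal[[role]]$Na <- 0
  }
  cell <- build_cell("pyramidal", "reduced", params = p)
  inj <- data.frame(comp = 1, amp_nA = 2, on_ms = 20, off_ms = 180)
  out <- simulate_cell(cell, 200, dt = 0.025, i_inj = inj)
  expect_length(out$spike_times, 0)
})

test_that("integration failure names the offending compartment", {
  cell <- build_cell("pyramidal", "reduced")
  st <- init_cell_state(cell)
  expect_error(step_cell(cell, st, dt = 0.025, i_inj = NaN, n_steps = 50),
               "compartment")
})

test_that("interneurons fire fast and tonically under current", {
  cell <- build_cell("basket", "reduced")
  inj <- data.frame(comp = 1, amp_nA = 0.5, on_ms = 0, off_ms = 500)
  out <- simulate_cell(cell, 500, dt = 0.025, i_inj = inj)
  expect_gt(length(out$spike_times), 20) # > 40 Hz sustained
})
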