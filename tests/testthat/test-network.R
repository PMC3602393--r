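# Network construction and the declarative lesion / drug transforms.

test_that("default composition and projection constraints hold", {
  net <- control_net()
  tb <- table(net$cells$type)
  expect_equal(unname(tb[c("pyramidal", "basket", "chandelier", "calretinin")]),
               c(160L, 30L, 30L, 20L), ignore_attr = TRUE)
  # calretinin cells synapse on zero pyramidal cells
  cr <- net$cells$cell[net$cells$type == "calretinin"]
  pyr <- net$cells$cell[net$cells$type == "pyramidal"]
  out_cr <- net$synapses[net$synapses$pre_cell %in% cr, ]
  expect_gt(nrow(out_cr), 0)
  expect_equal(sum(out_cr$post_cell %in% pyr), 0)
  # chandelier projections to pyramidal cells land on the initial segment
  ch <- net$cells$cell[net$cells$type == "chandelier"]
  ch_pyr <- net$synapses[net$synapses$pre_cell %in% ch &
                           net$synapses$post_cell %in% pyr, ]
  expect_true(all(ch_pyr$role == "initial_segment"))
  expect_true(all(ch_pyr$subtype == "alpha2_initial_segment"))
})

test_that("network generation is seed-deterministic", {
  a <- build_network(tiny_pop(), seed = 11)
  b <- build_network(tiny_pop(), seed = 11)
  c <- build_network(tiny_pop(), seed = 12)
  expect_identical(a$synapses, b$synapses)
  expect_false(identical(a$synapses, c$synapses))
})

test_that("realized edge counts stay inside the binomial 99.9% band", {
  rules <- default_connectivity()
  r <- rules[rules$source == "pyramidal" & rules$target == "basket", ]
  n_pairs <- 24 * 6
  lo <- qbinom(5e-4, n_pairs, r$p)
  hi <- qbinom(1 - 5e-4, n_pairs, r$p)
  for (s in 1:25) {
    net <- build_network(tiny_pop(), seed = 100 + s)
    syn <- net$synapses
    pyr <- net$cells$cell[net$cells$type == "pyramidal"]
    bas <- net$cells$cell[net$cells$type == "basket"]
    contacts <- unique(syn$contact[syn$pre_cell %in% pyr &
                                     syn$post_cell %in% bas])
    expect_gte(length(contacts), lo)
    expect_lte(length(contacts), hi)
  }
})

test_that("invalid connectivity rules are rejected", {
  rules <- default_connectivity()
  bad <- rules; bad$p[1] <- 1.7
  expect_error(build_network(tiny_pop(), rules = bad), "probability")
  cr_pyr <- rules
  cr_pyr$target[cr_pyr$source == "calretinin"][1] <- "pyramidal"
  expect_error(build_network(tiny_pop(), rules = cr_pyr), "calretinin")
})

test_that("the identity lesion is a no-op and transforms are pure", {
  net <- tiny_net()
  before <- net$synapses
  out <- apply_lesion(net, lesion_spec(0, 0, 0L), seed = 5)
  expect_identical(out$synapses, before)
  lesioned <- apply_lesion(net, lesion_spec(0.30, 0.30, 2L), seed = 5)
  expect_identical(net$synapses, before) # source untouched
  expect_lt(nrow(lesioned$synapses), nrow(before))
})

test_that("NMDA reduction scales every NMDA g_max exactly", {
  net <- tiny_net()
  out <- apply_lesion(net, lesion_spec(0.30, 0, 0L), seed = 1)
  nm <- net$synapses$kind == "NMDA"
  expect_equal(out$synapses$g_max_nS[nm], net$synapses$g_max_nS[nm] * 0.7)
  expect_equal(out$synapses$g_max_nS[!nm], net$synapses$g_max_nS[!nm])
})

test_that("spine pruning removes an exact hypergeometric count of contacts", {
  net <- tiny_net()
  registry <- unique(net$synapses$contact[net$synapses$spine])
  n <- length(registry)
  expect_gt(n, 10)
  out <- apply_lesion(net, lesion_spec(0, 0.60, 0L), seed = 3)
  remaining <- unique(out$synapses$contact[out$synapses$spine])
  expect_equal(length(remaining), n - round(0.60 * n))
  # both AMPA and NMDA components of a pruned contact disappear together
  gone <- setdiff(registry, remaining)
  expect_equal(sum(out$synapses$contact %in% gone), 0)
})

test_that("GABA ordered pairs prune projections and upweight the rest", {
  net <- tiny_net()
  pairs <- default_gaba_pairs()
  i <- 4L # tone -22.5 %, weight +30 %
  out <- apply_lesion(net, lesion_spec(0, 0, i, gaba_pairs = pairs), seed = 9)
  n0 <- sum(net$synapses$kind == "GABA_A")
  n1 <- sum(out$synapses$kind == "GABA_A")
  expect_equal(n1, n0 - round(pairs$tone[i + 1] * n0))
  expect_equal(unique(out$synapses$weight[out$synapses$kind == "GABA_A"]),
               1 + pairs$weight[i + 1])
})

test_that("off-grid lesions are rejected with the axis named", {
  expect_error(lesion_spec(0.37, 0, 0L), "nmda")
  expect_error(lesion_spec(0, 0.33, 0L), "spine")
  expect_error(lesion_spec(0, 0, 9L), "gaba_pair")
})

test_that("virtual medications apply their five mechanisms exactly", {
  net <- tiny_net()
  # control drug is the identity
  ctl <- apply_drug(net, drug_spec())
  expect_identical(ctl$synapses, net$synapses)
  drug <- drug_spec(ampa_gmax_increase = 40, alpha2_increase = 30,
                    nmda_increase = 20, ampa_tau2 = 1,
                    cr_weight_increase = 60)
  out <- apply_drug(net, drug)
  syn0 <- net$synapses; syn1 <- out$synapses
  am <- syn0$kind == "AMPA"; nm <- syn0$kind == "NMDA"
  a2 <- syn0$subtype == "alpha2_initial_segment"
  expect_equal(syn1$g_max_nS[am & !a2], syn0$g_max_nS[am & !a2] * 1.4)
  expect_equal(syn1$g_max_nS[a2], syn0$g_max_nS[a2] * 1.3)
  expect_equal(syn1$g_max_nS[nm], syn0$g_max_nS[nm] * 1.2)
  # the LTP coupling: +4.7 % excitatory weight per 20 % NMDA step
  expect_equal(syn1$weight[am | nm] / syn0$weight[am | nm],
               rep(1.047, sum(am | nm)))
  expect_equal(unique(syn1$tau2[am]), 1)
  cr <- net$cells$cell[net$cells$type == "calretinin"]
  is_cr <- syn0$pre_cell %in% cr
  expect_equal(syn1$weight[is_cr & !(am | nm)] / syn0$weight[is_cr & !(am | nm)],
               rep(1.6, sum(is_cr & !(am | nm))))
  expect_error(drug_spec(nmda_increase = 35), "off grid")
})

test_that("negative-control agents scale channel densities or AMPA kinetics", {
  net <- tiny_net()
  ph <- apply_drug(net, control_drug_spec("phenytoin", dose = 0.4))
  expect_equal(ph$comps$g_Na, net$comps$g_Na * 0.6)
  expect_equal(ph$comps$g_Ca, net$comps$g_Ca)
  nf <- apply_drug(net, control_drug_spec("nifedipine", dose = 0.5))
  expect_equal(nf$comps$g_Ca, net$comps$g_Ca * 0.5)
  ak <- apply_drug(net, control_drug_spec("ampakine", gmax_increase = 50,
                                          tau2_increase = 80))
  am <- net$synapses$kind == "AMPA"
  expect_equal(ak$synapses$g_max_nS[am], net$synapses$g_max_nS[am] * 1.5)
  expect_equal(unique(ak$synapses$tau2[am]), 3 * 1.8)
})

test_that("edge lists round-trip through CSV", {
  net <- tiny_net()
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(nrow(back), nrow(net$synapses))
  expect_equal(back$pre, net$synapses$pre_cell)
  expect_equal(back$g_max, net$synapses$g_max_nS)
  expect_equal(back$kind, net$synapses$kind)
})
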