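# Network construction and declarative parameter transforms.
#
# The default circuit: 160 pyramidal cells plus three interneuron classes
# (30 basket, 30 chandelier, 20 calretinin-positive cells), wired randomly
# from per-pair projection probabilities. Basket cells inhibit pyramidal
# somata, chandelier cells the pyramidal axon initial segment (the alpha2
# GABA_A site), calretinin cells only other interneurons. Excitatory
# contacts carry paired AMPA + NMDA synapses; pyramidal-to-pyramidal
# dendritic contacts form the spine registry eligible for pruning.

.hg_cell_types <- c("pyramidal", "basket", "chandelier", "calretinin")

#' Population sizes for a network
#'
#' @param pyramidal,basket,chandelier,calretinin cell counts (defaults match
#'   the standard composition 160/30/30/20).
#' @return named integer vector of class `hg_population_spec`.
#' @export
population_spec <- function(pyramidal = 160, basket = 30, chandelier = 30,
                            calretinin = 20) {
  counts <- c(pyramidal = pyramidal, basket = basket,
              chandelier = chandelier, calretinin = calretinin)
  abort_if(any(counts < 0), "population counts must be >= 0")
  structure(as.integer(counts), names = names(counts),
            class = "hg_population_spec")
}

#' Default connectivity rules
#'
#' One row per projection: source and target type, connection probability,
#' target compartment role and synapse class. The bundled defaults are
#' documented substitutes (see the parameter file) and can be overridden.
#'
#' @param params parameter list.
#' @return data.frame of rules.
#' @export
default_connectivity <- function(params = default_params()) {
  rules <- do.call(rbind, lapply(params$connectivity, as.data.frame))
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  need <- c("source", "target", "p", "role", "kind", "spine")
  abort_if(!all(need %in% names(rules)),
           "connectivity rules need columns: %s", paste(need, collapse = ", "))
  bad <- !(rules$source %in% .hg_cell_types) | !(rules$target %in% .hg_cell_types)
  abort_if(any(bad), "connectivity rule references unknown cell type")
  abort_if(any(rules$p < 0 | rules$p > 1),
           "connection probability outside [0, 1]")
  abort_if(any(rules$source == "calretinin" & rules$target == "pyramidal"),
           "calretinin cells must not target pyramidal cells")
  invisible(rules)
}

#' Build the four-population hippocampal network
#'
#' Realizes every connectivity rule by independent Bernoulli draws over
#' ordered cell pairs; regeneration with the same seed and rules yields an
#' identical synapse list.
#'
#' @param pop an [population_spec()] (or named counts).
#' @param rules connectivity rule table, see [default_connectivity()].
#' @param params parameter list.
#' @param morphology `"reduced"` (default, desk scale) or `"full"`.
#' @param seed integer RNG seed.
#' @return object of class `hg_network`.
#' @export
build_network <- function(pop = population_spec(),
                          rules = NULL,
                          params = default_params(),
                          morphology = NULL, seed = 1L) {
  if (is.null(rules)) rules <- default_connectivity(params)
  validate_rules(rules)
  counts <- as.integer(pop)
  names(counts) <- names(pop)
  abort_if(!all(.hg_cell_types %in% names(counts)),
           "population spec must name all four cell types")

  templates <- list(
    pyramidal = build_cell("pyramidal", morphology, params),
    interneuron = build_cell("basket", morphology, params))

  # --- assemble cell and compartment tables ---
  cells <- data.frame(cell = integer(0), type = character(0))
  for (ty in .hg_cell_types) {
    if (counts[[ty]] > 0) {
      cells <- rbind(cells, data.frame(
        cell = seq_len(counts[[ty]]), type = ty))
    }
  }
  cells$cell <- seq_len(nrow(cells))

  comp_list <- vector("list", nrow(cells))
  offset <- 0L
  comp0 <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tpl <- if (cells$type[i] == "pyramidal") templates$pyramidal else templates$interneuron
    cm <- tpl$comps
    n <- nrow(cm)
    dens <- t(vapply(cm$role, function(r) {
      v <- setNames(numeric(length(.hg_channels)), .hg_channels)
      d <- tpl$densities[[r]]
      v[names(d)] <- unlist(d)
      v
    }, numeric(length(.hg_channels))))
    colnames(dens) <- paste0("g_", .hg_channels)
    comp_list[[i]] <- cbind(
      data.frame(cell = i, local = cm$comp, role = cm$role,
                 length_um = cm$length_um, diam_um = cm$diam_um,
                 parent_global = ifelse(is.na(cm$parent), NA_integer_,
                                        cm$parent + offset)),
      as.data.frame(dens))
    comp0[i] <- offset + 1L
    offset <- offset + n
  }
  comps <- do.call(rbind, comp_list)
  rownames(comps) <- NULL
  comps$comp <- seq_len(nrow(comps))
  cells$comp0 <- comp0
  cells$n_comp <- vapply(comp_list, nrow, integer(1))
  cells$soma_comp <- comp0  # soma is always the local root (local id 1)

  pyr_tpl <- templates$pyramidal$comps
  int_tpl <- templates$interneuron$comps
  mid_ap <- c(pyramidal = mid_apical_comp(pyr_tpl),
              interneuron = mid_apical_comp(int_tpl))
  cells$drive_comp <- ifelse(
    cells$type == "pyramidal",
    cells$comp0 + mid_ap[["pyramidal"]] - 1L, NA_integer_)

  # role-local candidate compartments per template, with dendritic fallback
  cand_for <- function(tpl, role) {
    k <- which(tpl$comps$role == role)
    if (length(k) == 0) k <- which(tpl$comps$role %in%
                                     c("apical_dendrite", "basal_dendrite"))
    if (length(k) == 0) k <- 1L
    k
  }

  sp <- params$synapses
  kin <- function(kind) sp[[kind]]

  # --- realize synapses rule by rule ---
  syn_rows <- list()
  contact_next <- 1L
  with_seed(seed, {
    for (r in seq_len(nrow(rules))) {
      rule <- rules[r, ]
      pre <- cells$cell[cells$type == rule$source]
      post <- cells$cell[cells$type == rule$target]
      if (length(pre) == 0 || length(post) == 0) next
      pairs <- expand.grid(pre = pre, post = post)
      pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
      hit <- runif(nrow(pairs)) < rule$p
      pairs <- pairs[hit, , drop = FALSE]
      ne <- nrow(pairs)
      if (ne == 0) next
      tpl <- if (rule$target == "pyramidal") templates$pyramidal else templates$interneuron
      cand <- cand_for(tpl, rule$role)
      loc <- cand[sample.int(length(cand), ne, replace = TRUE)]
      gcomp <- cells$comp0[pairs$post] + loc - 1L
      grole <- comps$role[gcomp]
      contact <- seq.int(contact_next, length.out = ne)
      contact_next <- contact_next + ne
      mk <- function(kind_name) {
        k <- kin(kind_name)
        data.frame(contact = contact, pre_cell = pairs$pre,
                   post_cell = pairs$post, post_comp = gcomp,
                   role = grole, kind = kind_name,
                   subtype = ifelse(kind_name == "GABA_A" &
                                      grole == "initial_segment",
                                    "alpha2_initial_segment", "other"),
                   g_max_nS = k$g_max_nS, weight = 1,
                   tau1 = k$tau1_ms, tau2 = k$tau2_ms, e_rev = k$e_rev_mV,
                   delay_ms = k$delay_ms, spine = FALSE)
      }
      if (rule$kind == "excitatory") {
        a <- mk("AMPA"); n <- mk("NMDA")
        if (isTRUE(rule$spine) && rule$target == "pyramidal") {
          dendritic <- grole %in% c("apical_dendrite", "basal_dendrite")
          a$spine <- dendritic; n$spine <- dendritic
        }
        syn_rows[[length(syn_rows) + 1L]] <- rbind(a, n)
      } else {
        syn_rows[[length(syn_rows) + 1L]] <- mk("GABA_A")
      }
    }
  })
  synapses <- if (length(syn_rows)) do.call(rbind, syn_rows) else
    data.frame()
  rownames(synapses) <- NULL
  if (nrow(synapses)) synapses$syn <- seq_len(nrow(synapses))

  mb <- params$membrane
  mb$spike_threshold_mV <- params$integration$spike_threshold_mV
  mb$refractory_ms <- params$integration$refractory_ms
  el <- comp_electrics(
    data.frame(role = comps$role, length_um = comps$length_um,
               diam_um = comps$diam_um,
               parent = match(comps$parent_global, comps$comp)),
    templates$pyramidal$densities, mb)

  pyr_cells <- cells$cell[cells$type == "pyramidal"]
  eeg_comp <- comps$role == "apical_dendrite" & comps$cell %in% pyr_cells

  structure(list(
    cells = cells, comps = comps, synapses = synapses,
    electrics = el[c("area", "cm", "g_leak", "g_ax", "ca_phi", "ca_tau")],
    eeg_comp = eeg_comp, membrane = mb, params = params,
    rules = rules, seed = as.integer(seed),
    provenance = list(seed = as.integer(seed),
                      morphology = templates$pyramidal$variant)),
    class = "hg_network")
}

#' @export
print.hg_network <- function(x, ...) {
  tb <- table(x$cells$type)[.hg_cell_types]
  cat(sprintf(
    "<hg_network> %d cells (%s), %d compartments, %d synapses (seed %d)\n",
    nrow(x$cells),
    paste(sprintf("%s %d", names(tb), as.integer(tb)), collapse = ", "),
    nrow(x$comps), nrow(x$synapses), x$seed))
  if (length(x$provenance$lesion))
    cat("  lesion:", format_spec(x$provenance$lesion), "\n")
  if (length(x$provenance$drug))
    cat("  drug:", format_spec(x$provenance$drug), "\n")
  invisible(x)
}

format_spec <- function(s) paste(names(s), unlist(s), sep = "=", collapse = " ")

# ---------------------------------------------------------------------------
# Lesions

#' Default GABA-system ordered pairs
#'
#' Seven (tone reduction, postsynaptic weight increase) pairs: the uniform
#' diagonal from (0, 0) to (-45 %, +60 %) in tone steps of 7.5 % and weight
#' steps of 10 %. The list is configurable because the published secondary
#' lesion point, (-37.5, +30), is not on any uniform diagonal.
#'
#' @param params parameter list.
#' @return data.frame with columns `tone`, `weight` (fractions).
#' @export
default_gaba_pairs <- function(params = default_params()) {
  g <- params$lesion_grid$gaba_pairs
  data.frame(tone = as.numeric(g$tone), weight = as.numeric(g$weight))
}

#' Declare a lesion (schizophrenogenic parameter change)
#'
#' @param nmda_reduction fractional NMDA `g_max` reduction, on the grid
#'   0-0.45 step 0.05.
#' @param spine_reduction fractional dendritic spine removal, grid 0-0.60
#'   step 0.05.
#' @param gaba_pair index 0-6 into `gaba_pairs` (0 = no GABA lesion).
#' @param gaba_pairs the ordered-pair table, see [default_gaba_pairs()].
#' @param params parameter list (grid definitions).
#' @return object of class `hg_lesion_spec`.
#' @export
lesion_spec <- function(nmda_reduction = 0, spine_reduction = 0,
                        gaba_pair = 0L, gaba_pairs = NULL,
                        params = default_params()) {
  if (is.null(gaba_pairs)) gaba_pairs <- default_gaba_pairs(params)
  g <- params$lesion_grid
  abort_if(!on_grid(nmda_reduction, g$nmda),
           "nmda_reduction %.3f is not on the lesion grid", nmda_reduction)
  abort_if(!on_grid(spine_reduction, g$spine),
           "spine_reduction %.3f is not on the lesion grid", spine_reduction)
  abort_if(gaba_pair < 0 || gaba_pair >= nrow(gaba_pairs),
           "gaba_pair index %d outside 0..%d", gaba_pair,
           nrow(gaba_pairs) - 1L)
  structure(list(nmda_reduction = nmda_reduction,
                 spine_reduction = spine_reduction,
                 gaba_pair = as.integer(gaba_pair),
                 gaba_tone = gaba_pairs$tone[gaba_pair + 1L],
                 gaba_weight = gaba_pairs$weight[gaba_pair + 1L]),
            class = "hg_lesion_spec")
}

#' Apply a lesion to a network
#'
#' A pure transform: the input network is never modified. NMDA `g_max` is
#' scaled by `1 - nmda_reduction` on every NMDA synapse; an exact-count
#' (hypergeometric) random subset of the spine registry is deleted (both
#' AMPA and NMDA components of each pruned contact); the GABA ordered pair
#' removes an exact-count fraction of interneuron projections and scales
#' the surviving GABA_A weights up.
#'
#' @param net an `hg_network`.
#' @param lesion an [lesion_spec()].
#' @param seed RNG seed for the random removals.
#' @return a new `hg_network`.
#' @export
apply_lesion <- function(net, lesion, seed = 1L) {
  stopifnot(inherits(net, "hg_network"), inherits(lesion, "hg_lesion_spec"))
  syn <- net$synapses
  with_seed(seed, {
    if (lesion$nmda_reduction > 0) {
      is_nmda <- syn$kind == "NMDA"
      syn$g_max_nS[is_nmda] <- syn$g_max_nS[is_nmda] * (1 - lesion$nmda_reduction)
    }
    if (lesion$spine_reduction > 0) {
      registry <- unique(syn$contact[syn$spine])
      k <- round(lesion$spine_reduction * length(registry))
      if (k > 0) {
        drop <- sample(registry, k)
        syn <- syn[!(syn$contact %in% drop), , drop = FALSE]
      }
    }
    if (lesion$gaba_tone > 0 || lesion$gaba_weight > 0) {
      gaba_idx <- which(syn$kind == "GABA_A")
      k <- round(lesion$gaba_tone * length(gaba_idx))
      if (k > 0) {
        drop <- sample(gaba_idx, k)
        syn <- syn[-drop, , drop = FALSE]
      }
      keep <- syn$kind == "GABA_A"
      syn$weight[keep] <- syn$weight[keep] * (1 + lesion$gaba_weight)
    }
  })
  rownames(syn) <- NULL
  out <- net
  out$synapses <- syn
  out$provenance$lesion <- lesion[c("nmda_reduction", "spine_reduction",
                                    "gaba_pair")]
  out
}

# ---------------------------------------------------------------------------
# Drugs

#' Declare a virtual medication
#'
#' Five graded mechanisms (the trial grid): AMPA `g_max` increase, alpha2
#' GABA_A `g_max` increase at the pyramidal initial segment, NMDA `g_max`
#' increase (with its LTP side effect: +4.7 % excitatory synaptic weight per
#' 20 % NMDA step), the AMPA decay constant `tau2`, and the calretinin
#' projection weight increase.
#'
#' @param ampa_gmax_increase percent, grid `c(0, 20, 40, 60, 80)`.
#' @param alpha2_increase percent, grid `c(0, 15, 30, 45, 60)`.
#' @param nmda_increase percent, grid `c(0, 20, 40, 60, 80)`.
#' @param ampa_tau2 ms, grid `c(1, 3, 5)` (3 is control).
#' @param cr_weight_increase percent, grid `c(0, 20, 40, 60)`.
#' @param params parameter list (grid definitions).
#' @return object of class `hg_drug_spec`.
#' @export
drug_spec <- function(ampa_gmax_increase = 0, alpha2_increase = 0,
                      nmda_increase = 0, ampa_tau2 = 3,
                      cr_weight_increase = 0, params = default_params()) {
  g <- params$drug_grid
  abort_if(!on_grid(ampa_gmax_increase, g$ampa_gmax),
           "ampa_gmax_increase %g off grid", ampa_gmax_increase)
  abort_if(!on_grid(alpha2_increase, g$alpha2),
           "alpha2_increase %g off grid", alpha2_increase)
  abort_if(!on_grid(nmda_increase, g$nmda),
           "nmda_increase %g off grid", nmda_increase)
  abort_if(!on_grid(ampa_tau2, g$ampa_tau2), "ampa_tau2 %g off grid",
           ampa_tau2)
  abort_if(!on_grid(cr_weight_increase, g$cr_weight),
           "cr_weight_increase %g off grid", cr_weight_increase)
  structure(list(ampa_gmax_increase = ampa_gmax_increase,
                 alpha2_increase = alpha2_increase,
                 nmda_increase = nmda_increase, ampa_tau2 = ampa_tau2,
                 cr_weight_increase = cr_weight_increase,
                 ltp = params$drug_grid$ltp_weight_per_20pct_nmda),
            class = "hg_drug_spec")
}

#' Declare a negative-control agent
#'
#' Phenytoin scales sodium channel densities down on every cell, nifedipine
#' calcium channel densities; an ampakine scales AMPA `g_max` up and
#' lengthens the AMPA decay constant.
#'
#' @param name `"phenytoin"`, `"nifedipine"` or `"ampakine"`.
#' @param dose fractional conductance reduction (phenytoin / nifedipine).
#' @param gmax_increase,tau2_increase percent (ampakine).
#' @return object of class `hg_control_drug`.
#' @export
control_drug_spec <- function(name = c("phenytoin", "nifedipine", "ampakine"),
                              dose = 0, gmax_increase = 0,
                              tau2_increase = 0) {
  name <- match.arg(name)
  abort_if(dose < 0 || dose > 1, "dose must be a fraction in [0, 1]")
  structure(list(name = name, dose = dose, gmax_increase = gmax_increase,
                 tau2_increase = tau2_increase),
            class = "hg_control_drug")
}

#' Apply a drug to a network
#'
#' Pure transform, like [apply_lesion()]. The all-zero spec with
#' `ampa_tau2 = 3` is the control medication and is a no-op.
#'
#' @param net an `hg_network`.
#' @param drug an [drug_spec()] or [control_drug_spec()].
#' @return a new `hg_network`.
#' @export
apply_drug <- function(net, drug) {
  stopifnot(inherits(net, "hg_network"))
  out <- net
  syn <- net$synapses
  if (inherits(drug, "hg_control_drug")) {
    if (drug$name == "phenytoin") {
      out$comps$g_Na <- out$comps$g_Na * (1 - drug$dose)
    } else if (drug$name == "nifedipine") {
      out$comps$g_Ca <- out$comps$g_Ca * (1 - drug$dose)
    } else { # ampakine
      is_ampa <- syn$kind == "AMPA"
      syn$g_max_nS[is_ampa] <- syn$g_max_nS[is_ampa] *
        (1 + drug$gmax_increase / 100)
      syn$tau2[is_ampa] <- syn$tau2[is_ampa] * (1 + drug$tau2_increase / 100)
    }
    out$synapses <- syn
    out$provenance$drug <- drug[c("name", "dose", "gmax_increase",
                                  "tau2_increase")]
    return(out)
  }
  stopifnot(inherits(drug, "hg_drug_spec"))
  is_ampa <- syn$kind == "AMPA"
  is_nmda <- syn$kind == "NMDA"
  syn$g_max_nS[is_ampa] <- syn$g_max_nS[is_ampa] *
    (1 + drug$ampa_gmax_increase / 100)
  a2 <- syn$subtype == "alpha2_initial_segment"
  syn$g_max_nS[a2] <- syn$g_max_nS[a2] * (1 + drug$alpha2_increase / 100)
  syn$g_max_nS[is_nmda] <- syn$g_max_nS[is_nmda] *
    (1 + drug$nmda_increase / 100)
  # LTP coupling of the NMDA mechanism: excitatory weights rise by `ltp`
  # (default 4.7 %) for each 20 % NMDA conductance step
  ltp_fac <- 1 + drug$ltp * drug$nmda_increase / 20
  syn$weight[is_ampa | is_nmda] <- syn$weight[is_ampa | is_nmda] * ltp_fac
  syn$tau2[is_ampa] <- drug$ampa_tau2
  cr_cells <- net$cells$cell[net$cells$type == "calretinin"]
  is_cr <- syn$pre_cell %in% cr_cells
  syn$weight[is_cr] <- syn$weight[is_cr] * (1 + drug$cr_weight_increase / 100)
  out$synapses <- syn
  out$provenance$drug <- drug[c("ampa_gmax_increase", "alpha2_increase",
                                "nmda_increase", "ampa_tau2",
                                "cr_weight_increase")]
  out
}

# ---------------------------------------------------------------------------
# Serialization

#' Write / read a network's synapse list as a tabular edge list
#'
#' @param net an `hg_network`.
#' @param path CSV path.
#' @return `write_edge_list` the path invisibly; `read_edge_list` a
#'   data.frame.
#' @export
write_edge_list <- function(net, path) {
  syn <- net$synapses
  out <- data.frame(pre = syn$pre_cell, post = syn$post_cell,
                    compartment = syn$post_comp, kind = syn$kind,
                    subtype = syn$subtype,
                    g_max = syn$g_max_nS, weight = syn$weight,
                    tau1 = syn$tau1, tau2 = syn$tau2, delay = syn$delay_ms)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) read.csv(path, stringsAsFactors = FALSE)
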