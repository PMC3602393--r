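# Shared fixtures. Networks and baselines are built once per test run and
# cached; all sizes are desk scale (small populations, short trials).

.fx <- new.env(parent = emptyenv())

# small four-population network used by unit tests
tiny_pop <- function() population_spec(24, 6, 6, 4)

tiny_net <- function() {
  if (is.null(.fx$tiny_net)) .fx$tiny_net <- build_network(tiny_pop(), seed = 42)
  .fx$tiny_net
}

# full-composition control network (reduced morphology)
control_net <- function() {
  if (is.null(.fx$control_net)) .fx$control_net <- build_network(seed = 1)
  .fx$control_net
}

short_drive <- function(frequency = 40) {
  drive_spec(frequency, duration_ms = 700, transient_ms = 200)
}

short_args <- function() list(duration_ms = 700, transient_ms = 200)

tiny_baseline <- function() {
  if (is.null(.fx$tiny_baseline)) {
    .fx$tiny_baseline <- compute_baseline(tiny_net(), master_seed = 7,
                                          drive_args = short_args())
  }
  .fx$tiny_baseline
}

# brute-force union-find clustering oracle over a grid score table
oracle_clusters <- function(df, axes, threshold) {
  sel <- which(df$score > threshold)
  if (length(sel) == 0) return(list())
  lev <- vapply(axes, function(a) match(df[[a]], sort(unique(df[[a]]))),
                numeric(nrow(df)))
  lev <- matrix(lev[sel, ], nrow = length(sel))
  parent <- seq_along(sel)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(sel)) for (j in seq_len(i - 1L)) {
    d <- abs(lev[i, ] - lev[j, ])
    if (sum(d) == 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(sel), find, numeric(1))
  unname(split(sel, roots))
}
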