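# Parameter handling: one bundled YAML file holds every default, with a
# source tag ([published] / [traub-default] / [assumed]) next to each value.

.hg_env <- new.env(parent = emptyenv())

#' Default model parameters
#'
#' Reads the bundled parameter file (`inst/params/defaults.yaml`), which
#' documents every biophysical, synaptic, connectivity and experimental
#' default together with its provenance tag. Overrides are merged
#' recursively, so `default_params(list(drive = list(g_max_nS = 4)))`
#' changes one value and keeps the rest.
#'
#' @param overrides named list merged over the defaults (recursively).
#' @return nested named list of parameters.
#' @export
default_params <- function(overrides = NULL) {
  if (is.null(.hg_env$defaults)) {
    path <- system.file("params", "defaults.yaml", package = "hippogamma")
    abort_if(!nzchar(path), "bundled parameter file not found")
    .hg_env$defaults <- yaml::read_yaml(path)
  }
  p <- .hg_env$defaults
  if (!is.null(overrides)) {
    abort_if(!is.list(overrides), "params overrides must be a named list")
    p <- merge_params(p, overrides)
  }
  p
}

# recursive list merge (overrides win; new names allowed)
merge_params <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# channel order used throughout the compiled core
.hg_channels <- c("Na", "Ca", "KDR", "KA", "KAHP", "KC")
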