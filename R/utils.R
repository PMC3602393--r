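# Internal helpers: deterministic seeding and RNG hygiene.

#' Derive a reproducible sub-seed from a master seed and coordinates
#'
#' Grid points, cohort subjects and drive trials each get their own RNG seed
#' derived from the experiment's master seed plus their coordinates, so any
#' subset of a sweep can be re-run in isolation and reproduce the full run.
#'
#' @param master_seed integer master seed.
#' @param ... numeric coordinates (grid levels, subject index, drive
#'   frequency, ...). Values are scaled by 1000 and floored, so fractional
#'   levels such as 0.075 hash distinctly.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
seed_hash <- function(master_seed, ...) {
  xs <- c(master_seed, unlist(list(...), use.names = FALSE))
  h <- 17
  m <- 2147483629 # prime below 2^31
  for (v in xs) {
    if (!is.finite(v)) stop("seed_hash: non-finite coordinate")
    h <- (h * 31 + (floor(abs(v) * 1000) %% m) + 7) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# near-membership of a value on an explicit grid of levels
on_grid <- function(x, levels, tol = 1e-9) {
  any(abs(levels - x) < tol)
}
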