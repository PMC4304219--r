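#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package internals never perturb user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

camodi_stop <- function(...) stop(sprintf(...), call. = FALSE)

camodi_warn <- function(...) warning(sprintf(...), call. = FALSE)

fmt_num <- function(x) sprintf("%.10g", x)
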