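## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All package randomness goes through
## this so pipelines are reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

stop_mce <- function(..., class = "mcetools_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition"),
                      call = sys.call(-1)))
}

config_error <- function(...) stop_mce(..., class = "mcetools_config_error")
parse_error  <- function(...) stop_mce(..., class = "mcetools_parse_error")

## Canonical architecture string: comma+space joined domain names.
arch_string <- function(domains) {
  if (length(domains) == 0L) "" else paste(domains, collapse = ", ")
}
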