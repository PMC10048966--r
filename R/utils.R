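#' Derive a child RNG seed from a root seed and a stream name
#'
#' One root seed fans out to named per-stage streams so pipeline stages are
#' independently reproducible. The mixer is a fixed LCG-style hash; results
#' stay below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param root integer root seed.
#' @param name character stream name (e.g. `"latents"`, `"cv"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (ch in utf8ToInt(name)) {
    h <- (h * 48271 + ch) %% m
  }
  as.integer(max(1, h %% (m - 1)))
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with a consistent condition class so callers can test errors
abort_sf12 <- function(msg, class = "sf12risk_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

fmt_pct <- function(x, digits = 2) formatC(100 * x, format = "f", digits = digits)
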