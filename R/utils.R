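# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# micrometres <-> metres; velocity m/s expressed in um/s
.um_to_m <- function(x) x * 1e-6
.v_um_per_s <- function(v_m_per_s) v_m_per_s * 1e6

.assertScalar <- function(x, nm, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(nm, " must be a single finite number", call. = FALSE)
  if (strict && x <= min) stop(nm, " must be > ", min, call. = FALSE)
  if (!strict && x < min) stop(nm, " must be >= ", min, call. = FALSE)
  invisible(x)
}
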