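#' @keywords internal
"_PACKAGE"

# Canonical task-event order (session clock, ms). NoGo trials stop at GoNogo.
EVENT_ORDER <- c("LCDon", "ObjCue", "GoNogo", "HPR", "DO", "HO", "HOFF", "HPN")
MOVEMENT_EVENTS <- c("HPR", "DO", "HO", "HOFF", "HPN")
CONDITIONS <- c("execution", "observation", "nogo")
GRASPS <- c("PG", "WHG")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Linear-congruential mixing keeps every derived seed a positive 32-bit
#' integer, so a single pipeline master seed can fan out to per-stage and
#' per-replicate streams without collisions in practice.
#'
#' @param seed master seed (integer)
#' @param i stream index (integer >= 0)
#' @return a positive integer < 2^31
#' @export
derive_seed <- function(seed, i = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  m <- 2147483629
  s <- (abs(seed) %% m)
  as.integer(((s * 48271) %% m + (i * 7919) %% m) %% m + 1)
}

rectify <- function(x) pmax(x, 0)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded analyses do not perturb surrounding
#' randomness.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# polynomial with given (complex) roots, leading coefficient 1
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}
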