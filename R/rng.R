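#' Seeded random stream
#'
#' All stochastic operations in cwmsim draw from an explicit stream object
#' rather than the global RNG, so a single run seed reproduces every trace
#' bit-for-bit and adding a draw in one module does not perturb another.
#' Child streams ([rng_child()]) derive independent, deterministically
#' seeded streams for the named sources of randomness (timing, velocity,
#' noise, hrv, amplitude).
#'
#' @param seed integer seed (mandatory; no silent entropy).
#' @return an object of class `cwm_rng`.
#' @examples
#' r <- cwm_rng(1)
#' rng_runif(r, 3)
#' @export
cwm_rng <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("cwm_rng(): an explicit integer seed is required", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  old <- .save_global_rng()
  on.exit(.restore_global_rng(old), add = TRUE)
  set.seed(e$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  e$state <- get(".Random.seed", envir = globalenv())
  class(e) <- "cwm_rng"
  e
}

.save_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_global_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream's saved state into the session RNG, evaluates `expr`,
#' and captures the advanced state back into the stream. The caller's
#' global RNG state is untouched.
#'
#' @param rng a `cwm_rng` stream.
#' @param expr expression performing the draws.
#' @keywords internal
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "cwm_rng"))
  old <- .save_global_rng()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_global_rng(old)
  }, add = TRUE)
  expr
}

#' @rdname cwm_rng
#' @param name character label of the child stream.
#' @export
rng_child <- function(rng, name) {
  stopifnot(inherits(rng, "cwm_rng"), is.character(name), length(name) == 1L)
  # fold the stream name into a sub-seed; kept below 2^31 - 1
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 65521L
  sub <- (as.double(rng$seed) * 65537 + as.double(h) * 2654435.0) %% 2147483647
  cwm_rng(as.integer(sub))
}

#' @rdname cwm_rng
#' @param n number of draws.
#' @param min,max uniform bounds.
#' @export
rng_runif <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))

#' @rdname cwm_rng
#' @param mean,sd normal parameters.
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1)
  with_rng(rng, stats::rnorm(n, mean, sd))
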