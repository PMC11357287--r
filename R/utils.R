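# Utilities shared across modules.

#' Isolated seeded random stream
#'
#' Returns a list of draw functions (`rnorm`, `runif`, `sample_int`,
#' `derive`) backed by a private RNG state that is a pure function of
#' `seed` and never touches the caller's global random state. Every
#' stochastic operation in the package routes through one of these
#' streams, so a single integer reproduces a whole run bit-for-bit under
#' serial execution.
#'
#' @param seed a single finite numeric seed.
#' @return A list of closures sharing one private RNG state.
#' @export
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  grab <- function() {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else {
      NULL
    }
  }
  restore <- function(s) {
    if (is.null(s)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", s, envir = .GlobalEnv)
    }
  }
  outer_state <- grab()
  set.seed(as.integer(seed %% .Machine$integer.max))
  state <- grab()
  restore(outer_state)

  with_state <- function(expr) {
    prev <- grab()
    restore(state)
    on.exit({
      state <<- grab()
      restore(prev)
    })
    expr
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    sample_int = function(n, size = n, replace = FALSE, prob = NULL) {
      with_state(sample.int(n, size, replace = replace, prob = prob))
    },
    derive = function(label) {
      # stable sub-seed for a named stage
      h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
      as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
    }
  )
}

#' Stable per-stage seed derivation
#'
#' Maps a global seed and a stage label to a reproducible sub-seed
#' (always below 2^31), so that one integer fans out deterministically to
#' every stochastic stage of a pipeline run.
#'
#' @param seed global integer seed.
#' @param stage character label of the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  local_rng(seed)$derive(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
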