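# internal helpers: validation, seed hygiene, small numerics

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a fixed RNG stream without disturbing the caller's
# .Random.seed. All stochastic operations in the package route through this,
# so identical seeds give bit-identical output regardless of session state.
with_seed <- function(seed, expr) {
  .assert(.is_num1(seed), "seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# quadrature sum that tolerates NA (treated as unknown -> NA)
.quad <- function(...) sqrt(sum(c(...)^2))

# gyromagnetic ratio of 19F, rad s^-1 T^-1
GAMMA_19F <- 2.5181e8
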