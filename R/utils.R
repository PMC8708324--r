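#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed and a counter
#'
#' All stochastic stages draw their seeds through this splitter so that module
#' outputs are reproducible independently of call order. The mixing is a small
#' multiplicative hash kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m)
  for (k in c(counter + 1, 2654435769)) {
    s <- (s * 48271 + (as.numeric(k) %% m)) %% m
  }
  as.integer(max(1, s))
}

#' Evaluate an expression under a locally-set RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded computations never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Row-major flatten of a rows x cols matrix into a vector, and its inverse.
# Row-major means the first `cols` entries are the first image row.
flatten_rowmajor <- function(m) as.vector(t(m))

unflatten_rowmajor <- function(v, shape) {
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(structure(class = c("plantlatent_param_error", "error", "condition"),
                                           list(message = paste0(...), call = sys.call(-1))))

stop_data <- function(...) stop(structure(class = c("plantlatent_data_error", "error", "condition"),
                                          list(message = paste0(...), call = sys.call(-1))))
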