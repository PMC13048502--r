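# Internal helpers: seeded evaluation, classed errors, small matrix utilities.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "continue the current stream" (no reseeding).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based sub-seed derivation: independent, reorderable streams from one
# master seed.  Kept below 2^31 - 1 (R integers are 32 bit).
spawn_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  as.integer(((s * 48271) %% m + 16807 * (as.double(i) %% m)) %% m)
}

glv_error <- function(msg, class) {
  stop(structure(
    class = c(class, "glv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

offdiag <- function(M) M[row(M) != col(M)]

check_square_matrix <- function(A, what = "A") {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A)) {
    glv_error(sprintf("`%s` must be a square numeric matrix", what),
              "glv_input_error")
  }
  if (any(!is.finite(A))) {
    glv_error(sprintf("`%s` contains non-finite entries", what),
              "glv_input_error")
  }
  invisible(A)
}
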