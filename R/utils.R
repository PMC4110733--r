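# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# stream is untouched. seed = NULL means "use the current stream".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# soft-thresholding operator: sign(x) * max(|x| - t, 0)
soft_threshold <- function(x, t) {
  sign(x) * pmax(abs(x) - t, 0)
}

stop_ <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_symmetric <- function(S, name = "S", tol = 1e-10) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop_(sprintf("`%s` must be a square numeric matrix", name))
  }
  if (max(abs(S - t(S))) > tol) {
    stop_(sprintf("`%s` must be symmetric (tolerance %g)", name, tol))
  }
  invisible(S)
}
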