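#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so that generators can use
#' stage-local deterministic streams without disturbing the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
}

stopifnot_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("'%s' must be a fraction in %s", name,
                        if (open) "(0,1)" else "[0,1]"), call. = FALSE)
}

#' Reverse complement of a DNA string (character vector of strings)
#' @keywords internal
revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(DNA_COMP[b])), collapse = ""), "")
}
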