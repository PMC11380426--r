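`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring RNG state afterwards
#'
#' All stochastic steps in the package route their randomness through this
#' helper so that a single user-supplied seed makes a whole analysis
#' reproducible without touching the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deduplicate symbols 10x-style: second occurrence of "GZMB" becomes "GZMB-1"
dedup_symbols <- function(x) {
  occ <- stats::ave(seq_along(x), x, FUN = seq_along)
  dup <- occ > 1L
  if (any(dup)) {
    x[dup] <- paste0(x[dup], "-", occ[dup] - 1L)
    warnf("%d duplicate gene symbol(s) deduplicated by suffixing: %s",
          sum(dup), paste(utils::head(unique(x[dup]), 5L), collapse = ", "))
  }
  x
}
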