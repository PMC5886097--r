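#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package operations do
#' not disturb the caller's random number stream.  `seed = NULL` uses the
#' current stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration error with the offending field in the condition
#' @noRd
stop_config <- function(field, msg) {
  cond <- structure(
    class = c("twinage_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = NULL, field = field))
  stop(cond)
}

#' Validation error for file inputs
#' @noRd
stop_validation <- function(msg, ...) {
  cond <- structure(
    class = c("twinage_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL))
  stop(cond)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' Order samples so that family members are adjacent, and describe the
#' family-block structure for the C++ engine.
#'
#' Returns `ord` (row order into the original table), and 0-based `first`,
#' `size`, `zyg` per family unit (zyg: 0 = MZ pair, 1 = DZ pair,
#' 2 = singleton).
#' @noRd
twin_blocks <- function(samples) {
  ord <- order(samples$family_id, samples$individual_id)
  fam <- samples$family_id[ord]
  zygo <- as.character(samples$zygosity[ord])
  starts <- which(!duplicated(fam))
  sizes <- diff(c(starts, length(fam) + 1L))
  if (any(sizes > 2L))
    stop_validation("family `%s` has more than 2 samples",
                    fam[starts[which(sizes > 2L)[1L]]])
  zcode <- ifelse(sizes == 1L, 2L, ifelse(zygo[starts] == "MZ", 0L, 1L))
  list(ord = ord, first = as.integer(starts - 1L), size = as.integer(sizes),
       zyg = as.integer(zcode))
}
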