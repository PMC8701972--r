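#' The canonical buffer radii (metres)
#'
#' The 22 buffer radii, from 100 m to 10 km, at which buffer-type predictors
#' are conventionally summarised around each monitoring site.
#'
#' @return Integer vector of length 22, sorted ascending.
#' @export
#' @examples
#' lur_buffer_radii()
lur_buffer_radii <- function() {
  c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 1000L, 1200L, 1500L,
    1800L, 2000L, 2500L, 3000L, 3500L, 4000L, 5000L, 6000L, 7000L, 8000L,
    10000L)
}

# Derive a deterministic 32-bit sub-seed from a base seed and a text tag, so
# each generator draws from its own stream and regeneration of one layer
# never perturbs another.
op_seed <- function(seed, tag) {
  h <- sum(as.numeric(utf8ToInt(tag)) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Evaluate `code` under a temporary, deterministic RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
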