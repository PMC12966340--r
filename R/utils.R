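#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic code in the package funnels through this so that a single
# integer seed makes a whole run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed by a fixed offset, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pc_log <- function(...) {
  message("[prevcommon] ", sprintf(...))
}

canonical_classes <- function() c("rare", "fairly_common", "very_common")

assert_classes <- function(labels, arg = "labels") {
  bad <- setdiff(unique(labels), canonical_classes())
  if (length(bad) > 0) {
    stop(sprintf("%s contains values outside the commonness alphabet: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}
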