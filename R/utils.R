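# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Seeds for compounds, learner families, search trials, folds and
#' permutations are all derived from one master seed so that any subset of the
#' workflow can be rerun in isolation with identical results. The derivation
#' is a small deterministic string hash folded into the 32-bit signed integer
#' range; it depends only on the labels, never on scheduling order.
#'
#' @param seed master seed (integer).
#' @param ... labels (coerced to character) identifying the consumer.
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                  collapse = "\r")
  h <- 17
  for (c in utf8ToInt(labels)) {
    h <- (h * 31 + c) %% 2147483629
  }
  as.integer(h %% 2147483645L + 1L)
}

# run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG stream afterwards so derived randomness never perturbs user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

stop_pdr <- function(..., class = "pathwayDR_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_pdr(...)
  invisible(TRUE)
}

# numeric formatting for manifests: full precision, locale-independent
num_chr <- function(x) formatC(x, digits = 15, format = "g")
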