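# Shared internal helpers.

#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   left_join inner_join bind_rows bind_cols n across rename distinct pull
#'   slice_min count anti_join semi_join row_number first if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pchisq pnorm pt qchisq rbinom rnbinom rbeta rnorm runif
#'   lm optimize prcomp quantile median sd setNames rmultinom ks.test plogis
#'   qlogis complete.cases rpois dist hclust cutree
#' @importFrom utils adist head tail
NULL

# x * log(x) with the 0 * log(0) == 0 convention
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] * log(x[pos])
  out[is.na(x)] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child stream: every generator draws from seed + fixed offset
with_stream <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "asqtl_error")
  invisible(TRUE)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = c("asqtl_config_error", "asqtl_error"))
}
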