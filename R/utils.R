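#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n row_number across all_of distinct pull
#'   rename count slice if_else
#' @importFrom stats rnorm runif setNames sd var lm loess predict coef vcov
#'   pt qnorm p.adjust rstudent model.matrix optim aggregate median quantile
#'   rbinom complete.cases
#' @importFrom utils head tail
NULL

# Deterministic RNG substream handling. Each stream owns a saved .Random.seed;
# draws restore the stream, sample, and save it back, so interleaved streams
# stay reproducible regardless of draw order elsewhere.
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

stream_draw <- function(stream, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

clamp01 <- function(x) pmin(1, pmax(0, x))

is_unknown_parent <- function(p) {
  is.na(p) | p == "" | p == "0"
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "breedgain_schema_error")
  }
  invisible(df)
}

trial_id <- function(df) {
  paste(df$year, df$season, df$location, sep = "/")
}
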