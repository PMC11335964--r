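#' @importFrom stats rnorm runif quantile qf pf sd var fft t.test pnorm dnorm
#' @importFrom utils read.csv write.csv head
NULL

## Deterministic seed sub-streams: each pipeline stage draws from a seed
## derived from (global seed, stage name), so stages are independently
## reproducible.  Plain polynomial hash mod 2^31 - 1, exact in doubles.

#' Derive a stage-specific seed from a global seed
#'
#' Hashes a global integer seed together with a stage name into a new
#' integer seed, so that every stochastic stage of the pipeline has its own
#' reproducible random stream.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. `"train"`).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "simulate")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2L) + 1L)
}

## Rolling string hash used for provenance records (no cryptographic intent).
.cheapHash <- function(x) {
  stopifnot(is.character(x))
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(paste(x, collapse = "\n"))) h <- (h * 131 + code) %% m
  sprintf("%08x", as.integer(h))
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## JSON writer shared by all report exports; fixed settings keep repeated
## exports byte-identical.
.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
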