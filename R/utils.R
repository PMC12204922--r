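# Internal utilities: seeded evaluation without touching the caller's RNG
# state, stage-seed fan-out, and JSON-lines logging.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Stable fan-out of one global seed into independent stage seeds by hashing
#' the stage name, so reruns of a pipeline reproduce every stage and no two
#' stages share a random stream.
#'
#' @param seed global integer seed.
#' @param stage character stage name (e.g. `"generate"`, `"train"`).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 17
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  s <- ((as.numeric(seed) %% 94906265) * 22695477 + h) %% (m - 1)
  as.integer(s) + 1L
}

log_jsonl <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
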