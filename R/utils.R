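#' Derive a stage-specific sub-seed from a global seed
#'
#' Hashes a character tag into the seed so that independent pipeline stages
#' consume independent, reproducible random streams: re-ordering or skipping
#' one stage never perturbs another stage's draws.
#'
#' @param seed Integer global seed.
#' @param tag Character scalar naming the consumer (e.g. a stage name).
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  code <- utf8ToInt(tag)
  h <- sum(code * seq_along(code))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: fail with a readable message when required columns are absent
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
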