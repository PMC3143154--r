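#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published percentage tables are
#' conventionally rounded half-up, so summaries use this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages of the pipeline draw their own seeds deterministically from a single
#' global seed plus the stage name, so a stage re-run in isolation matches its
#' in-pipeline execution.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# internal: check a scalar probability-like argument
.checkProportion <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !lo_ok || !hi_ok)
    stop(sprintf("'%s' must be a single number in %s0,1%s", name,
                 if (open_lower) "(" else "[", if (open_upper) ")" else "]"),
         call. = FALSE)
  invisible(x)
}
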