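#' @importFrom rlang abort warn %||% .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 imap
NULL

# Deterministic per-probe random streams: derive a child seed from the run
# seed and a probe identifier, so serial and parallel execution agree.
# Plain polynomial string hash; only determinism matters, kept < 2^31.
derive_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% 2147480009
  }
  as.integer((h + as.numeric(seed)) %% 2147480009)
}

# Percent of a total as the paper prints it: round-half-even (base round()).
format_percent <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round(100 * count / total, digits)
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a fraction in %s%g, %g%s, got %s",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", format(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min &&
    x == as.integer(x)
  if (!ok) abort(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}
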