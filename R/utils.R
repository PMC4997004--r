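#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr %>%
NULL

# Half-up rounding to `digits` decimals (R's round() is half-to-even, which
# does not reproduce conventional percentage tables).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 32-bit sub-seed from a master seed and a string tag, so
# per-user streams are independent and order-insensitive.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the prior
# RNG state afterwards (keeps package functions from clobbering user RNG).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

format_iso <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

stopifnot_sorted <- function(ts, what = "timestamps") {
  if (length(ts) > 1 && any(diff(as.numeric(ts)) < 0)) {
    abort(sprintf("%s must be non-decreasing", what), class = "moodphone_validation_error")
  }
}
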