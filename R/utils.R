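#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic 31-bit sub-seed from a top-level seed plus context strings
# (FNV-1a over the utf-8 bytes of the joined key). Used so every stochastic
# stage draws from its own reproducible stream: adding plates or chips never
# perturbs the stream of an existing chip.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "\x1f")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    # xor on the low byte only (b < 256); h is kept as a double in [0, 2^32)
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Median and raw median absolute deviation (no consistency constant unless asked)
raw_mad <- function(x, scale = FALSE) {
  m <- stats::median(x)
  stats::median(abs(x - m)) * if (scale) 1.4826 else 1
}
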