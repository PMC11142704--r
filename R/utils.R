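#' @keywords internal
#' @useDynLib psinter, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Condition helpers: every user-facing error carries a subclass so callers
# (and the test suite) can distinguish schema errors from data errors from
# numeric failures.
ps_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "psinter_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ps_warn <- function(message, class) {
  warning(structure(
    class = c(class, "psinter_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# FNV-1a 32-bit string hash, done in double arithmetic (R has no native
# unsigned 32-bit integers). Used to derive per-token RNG seeds; only needs
# to be deterministic and well-mixed, not cryptographic.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two doubles holding values in [0, 2^32)
bitwXor64 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  hi * 2147483648 + (lo %% 2147483648) + (lo < 0) * 2147483648
}

# Derive a valid 32-bit signed seed from arbitrary doubles (kept < 2^31).
derive_seed <- function(...) {
  parts <- vapply(list(...), function(p) fnv1a32(paste0(p, collapse = "\r")),
                  numeric(1))
  h <- 2166136261
  for (p in parts) {
    h <- bitwXor64(h, p %% 4294967296)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Run code with a local RNG state so library internals never perturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ps_abort(sprintf("`%s` must be a single finite number", name),
             "psinter_value_error")
  if (positive && x <= 0)
    ps_abort(sprintf("`%s` must be > 0", name), "psinter_value_error")
  invisible(x)
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
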