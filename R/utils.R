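#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed from a master seed and a counter index.
# Keeps everything inside 32-bit integer range; doubles are exact well past
# the magnitudes used here (< 2^47).
.substream_seed <- function(master, index) {
  master <- as.double(master) %% 2147483647
  s <- (master * 48271 + as.double(index) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# Status logging goes to stderr via message(); machine outputs never do.
.log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# Full-precision number formatting so text round-trips are bit-exact.
.format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
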