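#' @keywords internal
"_PACKAGE"

# Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Rolling hash of an R object (for provenance stamps)
#'
#' Polynomial rolling hash over the serialized bytes (exact in double
#' arithmetic, modulus 2^40), returned as 10 hex digits. Used only to detect
#' accidental edits of stored session components; not cryptographic.
#' @noRd
fnv1a_hash <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2))
  # drop the serialization header (first 14 bytes vary with R version strings)
  if (length(bytes) > 14L) bytes <- bytes[-seq_len(14L)]
  h <- 17
  m <- 2^40   # keeps h * 257 + b exact in double arithmetic
  for (b in bytes) h <- (h * 257 + b + 1) %% m
  sprintf("%05x%05x", h %/% 2^20, h %% 2^20)
}

# centered moving average; ends are NA (callers decide how to treat them)
moving_average <- function(x, width) {
  stopifnot(width >= 1L)
  if (width == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# truncated-normal draw with a hard floor (resampling, seed-stream driven)
rtnorm_floor <- function(n, mean, sd, floor) {
  if (sd <= 0) return(rep(max(mean, floor), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < floor)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
    guard <- guard + 1L
  }
  out[out < floor] <- floor
  out
}

median_iqr <- function(x) {
  c(median = stats::median(x), iqr = unname(diff(stats::quantile(x, c(0.25, 0.75)))))
}
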