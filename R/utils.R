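#' @keywords internal
"_PACKAGE"

## Condition helpers -------------------------------------------------------

adm_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "adm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

adm_warn <- function(class, message) {
  warning(structure(
    class = c(class, "adm_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Quiet wrapper around Open Babel calls: OB writes warnings to the console
## (e.g. missing coordinates when emitting SDF); they are noise here.
ob_quiet <- function(expr) {
  tmp <- tempfile()
  con <- file(tmp, open = "wt")
  sink(con, type = "message")
  on.exit({
    sink(type = "message")
    close(con)
    unlink(tmp)
  })
  suppressWarnings(suppressMessages(expr))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

## Deterministic 32-bit FNV-1a hash over a vector of small non-negative
## integers.  Arithmetic is done in double precision; all intermediates stay
## below 2^53 because we reduce modulo 2^32 after every multiplication.
fnv1a32 <- function(ints) {
  h <- 2166136261
  p <- 16777619
  two32 <- 4294967296
  for (v in ints) {
    ## fold values wider than a byte, byte by byte (little-endian)
    b <- c(v %% 256, (v %/% 256) %% 256)
    for (byte in b) {
      h <- bitwXor64(h, byte)
      ## (h * p) mod 2^32 without exceeding 2^53:
      ## split h into high and low 16-bit halves
      lo <- h %% 65536
      hi <- h %/% 65536
      h <- ((hi * p) %% 65536) * 65536 + lo * p
      h <- h %% two32
    }
  }
  h
}

## XOR for doubles holding 32-bit unsigned values (bitwXor needs ints < 2^31)
bitwXor64 <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}
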