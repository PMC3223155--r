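# Round a double vector to the nearest IEEE-754 binary32 value (still
# stored as double). The reference-database matrix lives at this
# precision so that the on-disk container (little-endian float32, the
# precision single-precision GEMM kernels consume) round-trips
# bit-exactly.
quantize_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_missing_cost <- function(missing_cost) {
  if (length(missing_cost) != 1L || is.na(missing_cost) || missing_cost < 0) {
    stop("`missing_cost` must be a single non-negative number", call. = FALSE)
  }
  as.numeric(missing_cost)
}

check_strand_policy <- function(strand_policy) {
  match.arg(strand_policy, c("both", "forward"))
}
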