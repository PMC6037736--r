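# Internal helpers shared across modules.

# All randomness funnels through one user-visible seed; independent
# sub-streams are derived deterministically from (seed, label) so that
# simulation stages can be re-run in isolation without correlating.
substreamSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Local box mean with replicated borders; w must be odd.
localBoxMean <- function(x, w) {
  brush <- matrix(1 / (w * w), w, w)
  as.matrix(EBImage::filter2(x, brush, boundary = "replicate"))
}

# Centered moving 3x3 (or w x w) box *sum* of a matrix, zero-padded borders.
localBoxSum <- function(x, w = 3L) {
  brush <- matrix(1, w, w)
  pad <- as.matrix(EBImage::filter2(x, brush, boundary = 0))
  pad
}

# Column-stacked circular shift of a vector by an integer number of bins.
circShift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# Fractional circular shift by `delta` bins via linear interpolation
# between the two neighbouring integer shifts.
circShiftFrac <- function(x, delta) {
  k0 <- floor(delta)
  frac <- delta - k0
  a <- circShift(x, as.integer(k0))
  if (frac == 0) return(a)
  b <- circShift(x, as.integer(k0) + 1L)
  (1 - frac) * a + frac * b
}
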