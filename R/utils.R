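## internal helpers shared across modules

clamp01 <- function(x) pmin(1, pmax(0, x))

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

stop_arg <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg(name, " must be a single finite number")
  }
  if (x < lo || x > hi) {
    stop_arg(name, " must be in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

## 32-bit FNV-1a over a character scalar; used for schema / config
## fingerprints (stable across sessions, no external dependency).
fnv1a_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte only (b < 256), keeping h a double in [0, 2^32)
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b %% 256)
    ## 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    h <- (h %% 65536) * 16777619 + (h %/% 65536 %% 65536) * 403 * 65536
    h <- h %% 4294967296
  }
  ## format as hex from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## smoothed day-of-year climatology (365-vector); day 366 folds onto 365
doy_climatology <- function(x, dates, window = 31) {
  if (window %% 2 == 0) window <- window + 1
  doy <- as.integer(format(dates, "%j"))
  doy[doy == 366L] <- 365L
  clim <- tapply(x, factor(doy, levels = 1:365), mean)
  if (anyNA(clim)) {
    idx <- which(!is.na(clim))
    clim <- stats::approx(x = c(idx - 365, idx, idx + 365),
                          y = rep(clim[idx], 3), xout = 1:365)$y
  }
  half <- (window - 1) / 2
  ext <- c(clim[(365 - half + 1):365], clim, clim[1:half])
  sm <- as.numeric(stats::filter(ext, rep(1 / window, window), sides = 2))
  unname(sm[(half + 1):(half + 365)])
}

fold_doy <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  doy[doy == 366L] <- 365L
  doy
}

## derive a stream-specific 31-bit seed from a master seed
derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  s <- as.integer(strtoi(substr(fnv1a_hash(paste0(seed, ":", stream)), 1, 7),
                         base = 16L))
  s %% .Machine$integer.max
}
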