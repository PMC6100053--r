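# Multilevel 1-D discrete wavelet transform with Daubechies filters and
# symmetric (half-point) boundary extension. Implemented here because the
# de-noising step needs exact control over per-level detail thresholds and
# perfect reconstruction; the filter banks are the published Daubechies
# coefficients.

# db5 decomposition/reconstruction filter bank (10 taps, 5 vanishing moments)
DB5_DEC_LO <- c(
  0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
  0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
  0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
  0.16010239797419293)
DB5_DEC_HI <- c(
  -0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
  0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
  -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
  0.0033357252854737712)
DB5_REC_LO <- rev(DB5_DEC_LO)
DB5_REC_HI <- c(
  0.0033357252854737712, 0.012580751999081999, -0.006241490212798274,
  -0.07757149384004572, -0.032244869584638375, 0.24229488706638203,
  0.13842814590132074, -0.7243085284377729, 0.6038292697971896,
  -0.16010239797419293)

wavelet_filters <- function(wavelet) {
  if (!identical(tolower(wavelet), "db5")) {
    stop("only the 'db5' wavelet is provided", call. = FALSE)
  }
  list(dec_lo = DB5_DEC_LO, dec_hi = DB5_DEC_HI,
       rec_lo = DB5_REC_LO, rec_hi = DB5_REC_HI, len = 10L)
}

#' Maximum admissible decomposition depth
#'
#' Depth at which the coarsest coefficients are still longer than the
#' filter: `floor(log2(n / (filter_len - 1)))`.
#'
#' @param n signal length.
#' @param wavelet wavelet name (only `"db5"`).
#' @return integer depth (possibly 0).
#' @export
dwt_max_level <- function(n, wavelet = "db5") {
  L <- wavelet_filters(wavelet)$len
  if (n < L - 1) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# half-point symmetric extension by k samples each side: ...x3 x2 x1 | x1 x2...
sym_ext <- function(x, k) {
  n <- length(x)
  if (k > n) stop("extension longer than signal", call. = FALSE)
  c(x[k:1], x, x[n:(n - k + 1)])
}

# full linear convolution
conv_full <- function(x, h) {
  # convolve(x, rev(h), type = "open") is the ordinary convolution x * h
  stats::convolve(x, rev(h), type = "open")
}

# one analysis step: returns approximation and detail of length
# floor((n + L - 1) / 2)
dwt_step <- function(x, filt) {
  L <- filt$len
  n <- length(x)
  ext <- sym_ext(x, L - 1L)
  valid <- function(h) {
    full <- conv_full(ext, h)
    v <- full[L:(length(ext))]
    v[seq.int(2L, length(v), by = 2L)]
  }
  list(cA = valid(filt$dec_lo), cD = valid(filt$dec_hi))
}

# one synthesis step, cropped to out_len
idwt_step <- function(cA, cD, filt, out_len) {
  L <- filt$len
  up <- function(cc) {
    u <- numeric(2L * length(cc) - 1L)
    u[seq.int(1L, length(u), by = 2L)] <- cc
    u
  }
  branch <- function(cc, h) {
    full <- conv_full(up(cc), h)
    full[(L - 1L):(length(full) - (L - 2L))]
  }
  y <- branch(cA, filt$rec_lo) + branch(cD, filt$rec_hi)
  y[seq_len(out_len)]
}

#' Multilevel discrete wavelet decomposition
#'
#' Cascades [dwt_step] analysis `levels` times on the approximation branch.
#'
#' @param x numeric signal.
#' @param levels decomposition depth, `1 <= levels <= dwt_max_level(n)`.
#' @param wavelet wavelet name.
#' @return list with `cA` (coarsest approximation), `details` (list of
#'   detail vectors, level 1 = finest, last = coarsest), `lengths`
#'   (intermediate approximation lengths, for reconstruction), `wavelet`,
#'   `levels`.
#' @export
wavedec <- function(x, levels, wavelet = "db5") {
  filt <- wavelet_filters(wavelet)
  n <- length(x)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  # every analysis step needs a signal at least as long as the extension
  len <- n
  feasible <- 0L
  while (len >= filt$len - 1L && feasible < levels) {
    feasible <- feasible + 1L
    len <- (len + filt$len - 1L) %/% 2L
  }
  if (levels > feasible) {
    stop(sprintf(
      "signal of length %d admits at most %d db5 levels (requested %d)",
      n, feasible, levels), call. = FALSE)
  }
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lengths[j] <- length(cur)
    st <- dwt_step(cur, filt)
    details[[j]] <- st$cD
    cur <- st$cA
  }
  list(cA = cur, details = details, lengths = lengths,
       wavelet = wavelet, levels = levels)
}

#' Multilevel wavelet reconstruction
#'
#' Inverse of [wavedec()]; with unmodified coefficients the round trip is
#' exact to machine precision.
#'
#' @param dec a decomposition from [wavedec()].
#' @return numeric signal of the original length.
#' @export
waverec <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  cur <- dec$cA
  for (j in rev(seq_len(dec$levels))) {
    cur <- idwt_step(cur, dec$details[[j]], filt, dec$lengths[j])
  }
  cur
}
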