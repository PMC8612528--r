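# Internal prominence-filtered extremum detection.
#
# Quantized traces (0.5 mm head width) and sampled angular-velocity pulses
# have plateaus, so candidate extrema are plateau-centered direction changes;
# a hysteresis walk then confirms only oscillations with amplitude at least
# `prominence` (the zigzag rule: an extreme is confirmed once the series has
# moved away from it by the prominence).

# candidate turning points: data.frame(idx, val, type) with type +1 = max,
# -1 = min; plateau extrema contribute their central sample
.candidate_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(idx = integer(0), val = numeric(0), type = integer(0)))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(data.frame(idx = integer(0), val = numeric(0), type = integer(0)))
  s <- sign(d[nz])
  ch <- which(s[-length(s)] != s[-1])
  if (!length(ch)) return(data.frame(idx = integer(0), val = numeric(0), type = integer(0)))
  idx <- floor((nz[ch] + 1 + nz[ch + 1]) / 2)
  data.frame(idx = idx, val = x[idx], type = ifelse(s[ch] > 0, 1L, -1L))
}

# confirmed extrema after hysteresis filtering at the given prominence
.prominent_extrema <- function(x, prominence) {
  cand <- .candidate_extrema(x)
  n <- length(x)
  # include endpoints so excursions against the boundary can confirm extrema
  cand <- rbind(data.frame(idx = 1L, val = x[1], type = 0L),
                cand,
                data.frame(idx = n, val = x[n], type = 0L))
  m <- nrow(cand)
  out_idx <- integer(m); out_type <- integer(m); n_out <- 0L
  dir <- 0L
  cur_min <- cand$val[1]; cur_max <- cand$val[1]
  imin <- cand$idx[1]; imax <- cand$idx[1]
  for (k in seq_len(m)) {
    v <- cand$val[k]; i <- cand$idx[k]
    if (dir == 0L) {
      if (v > cur_max) { cur_max <- v; imax <- i }
      if (v < cur_min) { cur_min <- v; imin <- i }
      if (cur_max - cur_min >= prominence)
        dir <- if (imax > imin) 1L else -1L
    } else if (dir > 0L) {  # rising: tracking a maximum
      if (v > cur_max) { cur_max <- v; imax <- i }
      else if (cur_max - v >= prominence) {
        n_out <- n_out + 1L
        out_idx[n_out] <- imax; out_type[n_out] <- 1L
        dir <- -1L; cur_min <- v; imin <- i
      }
    } else {                # falling: tracking a minimum
      if (v < cur_min) { cur_min <- v; imin <- i }
      else if (v - cur_min >= prominence) {
        n_out <- n_out + 1L
        out_idx[n_out] <- imin; out_type[n_out] <- -1L
        dir <- 1L; cur_max <- v; imax <- i
      }
    }
  }
  data.frame(idx = out_idx[seq_len(n_out)], type = out_type[seq_len(n_out)])
}

.find_prominent_minima <- function(x, prominence) {
  e <- .prominent_extrema(x, prominence)
  e$idx[e$type < 0]
}

.count_prominent_peaks <- function(x, prominence) {
  e <- .prominent_extrema(x, prominence)
  max(sum(e$type > 0), 1L)
}
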