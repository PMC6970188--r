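#' Per-bin log2 ratio of two linear tracks
#'
#' Computes `log2((ip + pseudocount) / (control + pseudocount))` per bin.
#' The standard first step for ChIP enrichment maps: IP signal over an input
#' (or occupancy) control. Masked bins in either input propagate to the
#' output; bins where the ratio is undefined (both terms zero with zero
#' pseudocount) are masked.
#'
#' @param ip,control linear-unit [signal_track()]s on the same grid.
#' @param pseudocount non-negative pseudocount added to both tracks
#'   (default 1).
#' @return A `SignalTrack` in `log2_ratio` units.
#' @export
log2_ratio <- function(ip, control, pseudocount = 1) {
  check_linear_pair(ip, control, pseudocount)
  vals <- lapply(ip$genome$chrom, function(chrom) {
    a <- ip$values[[chrom]] + pseudocount
    b <- control$values[[chrom]] + pseudocount
    r <- log2(a / b)
    r[!is.na(r) & !is.finite(r)] <- NA_real_
    r
  })
  names(vals) <- ip$genome$chrom
  signal_track(ip$genome, ip$bin_width, vals, units = "log2_ratio")
}

check_linear_pair <- function(a, b, pseudocount) {
  stopifnot(inherits(a, "SignalTrack"), inherits(b, "SignalTrack"))
  if (!same_grid(a, b)) stop_("tracks are not on the same genome/bin grid")
  if (a$units != "linear" || b$units != "linear")
    stop_("log-ratio normalization needs linear-unit tracks")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop_("pseudocount must be a single non-negative number")
  if (any(track_values(a) < 0) || any(track_values(b) < 0))
    stop_("negative values in a linear track")
  invisible(TRUE)
}

#' Occupancy-normalized double log2 ratio
#'
#' The H3K56ac normalization used for histone-mark maps: the IP/input ratio
#' is further normalized to H3 occupancy,
#' `log2((ip+pc)/(input+pc)) - log2((occupancy+pc)/(input+pc))`.
#' A bin masked in any of the three tracks is masked in the output.
#'
#' @param ip,input,occupancy linear-unit [signal_track()]s on one grid.
#' @param pseudocount non-negative pseudocount (default 1).
#' @return A `SignalTrack` in `log2_ratio` units.
#' @export
double_ratio <- function(ip, input, occupancy, pseudocount = 1) {
  check_linear_pair(ip, input, pseudocount)
  check_linear_pair(occupancy, input, pseudocount)
  vals <- lapply(ip$genome$chrom, function(chrom) {
    a <- ip$values[[chrom]] + pseudocount
    i <- input$values[[chrom]] + pseudocount
    o <- occupancy$values[[chrom]] + pseudocount
    r <- log2(a / i) - log2(o / i)
    r[!is.na(r) & !is.finite(r)] <- NA_real_
    r
  })
  names(vals) <- ip$genome$chrom
  signal_track(ip$genome, ip$bin_width, vals, units = "log2_ratio")
}

#' Centered moving-average smoothing
#'
#' Moving mean over an odd window of bins, ignoring masked bins; at
#' chromosome edges the window is truncated. Masked positions stay masked.
#'
#' @param track a [signal_track()].
#' @param window_bins odd window width in bins (default 5).
#' @return A smoothed `SignalTrack` with the same units.
#' @export
smooth_track <- function(track, window_bins = 5) {
  stopifnot(inherits(track, "SignalTrack"))
  if (!is_count(window_bins) || window_bins %% 2 == 0)
    stop_("window_bins must be a positive odd integer")
  h <- (window_bins - 1) / 2
  vals <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0L) return(v)
    ok <- !is.na(v)
    s <- ifelse(ok, v, 0)
    cs <- cumsum(c(0, s))
    cn <- cumsum(c(0, as.numeric(ok)))
    i <- seq_len(n)
    lo <- pmax(1, i - h)
    hi <- pmin(n, i + h)
    cnt <- cn[hi + 1] - cn[lo]
    out <- (cs[hi + 1] - cs[lo]) / cnt
    out[cnt == 0] <- NA_real_
    out[!ok] <- NA_real_
    out
  })
  signal_track(track$genome, track$bin_width, vals, units = track$units)
}

#' Genome-wide z-scoring of a track
#'
#' Standardizes unmasked bins with the genome-wide mean and population
#' standard deviation (divisor n).
#'
#' @param track a [signal_track()].
#' @return A z-scored `SignalTrack`; masked bins stay masked.
#' @export
zscore_track <- function(track) {
  st <- track_baseline(track)
  vals <- lapply(track$values, function(v) (v - st$mean) / st$sd)
  signal_track(track$genome, track$bin_width, vals, units = track$units)
}

#' Genome-wide mean and population sd of a track
#'
#' @param track a [signal_track()].
#' @return List with `mean` and `sd` over unmasked bins.
#' @export
track_baseline <- function(track) {
  stopifnot(inherits(track, "SignalTrack"))
  x <- track_values(track)
  if (length(x) < 2L) stop_("need at least 2 unmasked bins")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop_("zero variance track cannot be z-scored")
  list(mean = m, sd = s)
}
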