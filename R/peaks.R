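#' Threshold peak calling on a signal track
#'
#' A transparent threshold caller: bins whose z-scored value is at least
#' `z_threshold` are candidates; candidate runs separated by at most
#' `merge_gap_bins` non-candidate bins are merged (gap bins become part of
#' the peak); merged runs shorter than `min_width_bins` are discarded. Each
#' peak is annotated with its summit (midpoint of the maximum-signal bin,
#' leftmost on ties) and the mean raw signal over its bins.
#'
#' The z-scoring baseline (genome-wide mean and population sd) is computed
#' from `track` unless `baseline` is supplied; passing a fixed baseline makes
#' calls on restricted or subsetted tracks comparable with the original run.
#'
#' @param track a [signal_track()].
#' @param z_threshold threshold in z units (default 2).
#' @param min_width_bins minimum peak width in bins (default 3).
#' @param merge_gap_bins maximum bridged gap in bins (default 2).
#' @param baseline optional list with `mean` and `sd` (see
#'   [track_baseline()]).
#' @return A [peak_set()].
#' @export
call_peaks <- function(track, z_threshold = 2, min_width_bins = 3,
                       merge_gap_bins = 2, baseline = NULL) {
  stopifnot(inherits(track, "SignalTrack"))
  if (!is_count(min_width_bins)) stop_("min_width_bins must be >= 1")
  if (!is_count(merge_gap_bins, min = 0)) stop_("merge_gap_bins must be >= 0")
  if (is.null(baseline)) {
    x <- track_values(track)
    if (length(x) >= 2L && sqrt(mean((x - mean(x))^2)) == 0) {
      # a flat track has no peaks by definition; short-circuit before
      # z-scoring, which requires nonzero variance
      return(peak_set(track$genome, data.frame(), label = "peaks"))
    }
  }
  st <- baseline %||% track_baseline(track)
  cutoff <- st$mean + z_threshold * st$sd
  bw <- track$bin_width
  out <- list()
  for (chrom in track$genome$chrom) {
    v <- track$values[[chrom]]
    pos <- which(!is.na(v) & v >= cutoff)
    if (length(pos) == 0L) next
    grp <- cumsum(c(1L, diff(pos) > merge_gap_bins + 1))
    for (g in split(pos, grp)) {
      b0 <- min(g); b1 <- max(g)
      if (b1 - b0 + 1 < min_width_bins) next
      seg <- v[b0:b1]
      imax <- b0 + which.max(ifelse(is.na(seg), -Inf, seg)) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = (b0 - 1) * bw,
        end = min(b1 * bw, chrom_length(track$genome, chrom)),
        summit = (imax - 1) * bw + bw %/% 2,
        mean_signal = mean(seg, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(peak_set(track$genome, data.frame(), label = "peaks"))
  df <- do.call(rbind, out)
  df$strand <- "."
  df$name <- sprintf("peak_%04d", seq_len(nrow(df)))
  df$score <- df$mean_signal
  peak_set(track$genome, df, label = "peaks")
}

#' Peak summit points
#'
#' One 1-bp point per peak at its summit, in peak order.
#'
#' @param peaks a [peak_set()].
#' @return A [feature_set()] of 1-bp intervals.
#' @export
peak_midpoints <- function(peaks) {
  stopifnot(inherits(peaks, "PeakSet"))
  df <- peaks$intervals
  if (nrow(df) == 0L)
    return(feature_set(peaks$genome, data.frame(),
                       label = paste0(peaks$label, "_summits")))
  feature_set(peaks$genome,
              data.frame(chrom = df$chrom, start = df$summit,
                         end = df$summit + 1, strand = ".",
                         name = df$name, score = df$mean_signal,
                         stringsAsFactors = FALSE),
              label = paste0(peaks$label, "_summits"))
}

#' Write a PeakSet as BED6 plus summit and mean signal columns
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- peaks$intervals
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\tsummit\tmean_signal"
  lines <- if (nrow(df) == 0L) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d\t%s",
            df$chrom, as.integer(df$start), as.integer(df$end),
            ifelse(df$name == "", ".", df$name), num_chr(df$score), df$strand,
            as.integer(df$summit), num_chr(df$mean_signal))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a PeakSet written by [write_peaks()]
#'
#' @param path file path.
#' @param genome a [genome_model()].
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^\\s*$", lines)]
  if (length(lines) == 0L) return(peak_set(genome, data.frame()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 8L)) stop_("read_peaks: need 8 columns")
  g <- function(k) vapply(parts, `[`, "", k)
  peak_set(genome, data.frame(
    chrom = g(1), start = as.numeric(g(2)), end = as.numeric(g(3)),
    name = ifelse(g(4) == ".", "", g(4)), score = as.numeric(g(5)),
    strand = g(6), summit = as.numeric(g(7)), mean_signal = as.numeric(g(8)),
    stringsAsFactors = FALSE))
}
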