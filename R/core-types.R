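#' Genome model: the coordinate universe
#'
#' A `GenomeModel` is an ordered list of chromosome names and lengths. Every
#' feature set and signal track carries a reference to one; all coordinates in
#' the package are 0-based, half-open (BED convention).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return An object of class `GenomeModel`.
#' @examples
#' gm <- genome_model(c("chrI", "chrII"), c(1e5, 8e4))
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop_("genome_model: need at least one chromosome")
  if (anyDuplicated(chrom)) stop_("genome_model: chromosome names must be unique")
  if (length(chrom) != length(length)) stop_("genome_model: chrom/length mismatch")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length)))
    stop_("genome_model: lengths must be positive integers")
  structure(list(chrom = chrom, length = length), class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %.3g Mb total\n",
              length(x$chrom), sum(x$length) / 1e6))
  for (i in seq_along(x$chrom))
    cat(sprintf("  %-8s %10.0f bp\n", x$chrom[i], x$length[i]))
  invisible(x)
}

#' @rdname genome_model
#' @param genome a `GenomeModel`.
#' @export
chrom_names <- function(genome) genome$chrom

#' @rdname genome_model
#' @param name chromosome name.
#' @export
chrom_length <- function(genome, name) {
  i <- match(name, genome$chrom)
  if (anyNA(i)) stop_("unknown chromosome: %s", paste(name[is.na(i)], collapse = ", "))
  genome$length[i]
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$length, b$length)
}

#' Feature set: a named collection of genomic intervals
#'
#' Intervals are stored in a data frame with columns `chrom`, `start`, `end`
#' (0-based half-open), `strand` (one of `+`, `-`, `.`), `name` and `score`.
#' Intervals are validated against the genome and stored in canonical order
#' (genome chromosome order, then start, then end).
#'
#' @param genome a [genome_model()].
#' @param intervals data frame with at least `chrom`, `start`, `end`; optional
#'   `strand`, `name`, `score`.
#' @param label short label describing the set.
#' @return An object of class `FeatureSet`.
#' @export
feature_set <- function(genome, intervals, label = "features") {
  stopifnot(inherits(genome, "GenomeModel"))
  df <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     strand = character(), name = character(), score = numeric(),
                     stringsAsFactors = FALSE)
    return(structure(list(label = label, genome = genome, intervals = df),
                     class = "FeatureSet"))
  }
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stop_("feature_set: need columns chrom/start/end")
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$strand <- if ("strand" %in% names(df)) as.character(df$strand) else "."
  df$name <- if ("name" %in% names(df)) as.character(df$name) else ""
  df$score <- if ("score" %in% names(df)) as.numeric(df$score) else 0
  df <- df[c("chrom", "start", "end", "strand", "name", "score",
             setdiff(names(df), c("chrom", "start", "end", "strand", "name", "score")))]
  bad <- !(df$chrom %in% genome$chrom)
  if (any(bad))
    stop_("feature_set: interval on unknown chromosome '%s'", df$chrom[which(bad)[1]])
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop_("feature_set: start/end must be integers")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop_("feature_set: require 0 <= start < end")
  over <- df$end > chrom_length(genome, df$chrom)
  if (any(over))
    stop_("feature_set: interval beyond chromosome end (%s:%d-%d)",
          df$chrom[which(over)[1]], df$start[which(over)[1]], df$end[which(over)[1]])
  if (!all(df$strand %in% c("+", "-", ".")))
    stop_("feature_set: strand must be one of +, -, .")
  ord <- order(match(df$chrom, genome$chrom), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(label = label, genome = genome, intervals = df),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet '%s': %d interval(s)\n", x$label, nrow(x$intervals)))
  if (nrow(x$intervals) > 0) print(utils::head(x$intervals, 6))
  invisible(x)
}

#' Number of intervals in a FeatureSet
#' @param fs a `FeatureSet`.
#' @export
n_features <- function(fs) nrow(fs$intervals)

#' Interval midpoints
#'
#' Midpoint is `floor((start + end) / 2)`.
#'
#' @param fs a `FeatureSet`.
#' @param as_features if `TRUE` return a `FeatureSet` of 1-bp points,
#'   otherwise a data frame of `chrom` and `mid`.
#' @export
feature_midpoints <- function(fs, as_features = FALSE) {
  df <- fs$intervals
  mid <- floor((df$start + df$end) / 2)
  if (!as_features) return(data.frame(chrom = df$chrom, mid = mid,
                                      stringsAsFactors = FALSE))
  feature_set(fs$genome,
              data.frame(chrom = df$chrom, start = mid, end = mid + 1,
                         strand = df$strand, name = df$name, score = df$score,
                         stringsAsFactors = FALSE),
              label = paste0(fs$label, "_midpoints"))
}

#' Convert a FeatureSet to GRanges
#'
#' Internal bridge to the GenomicRanges overlap machinery; coordinates are
#' shifted to 1-based closed on the way in.
#'
#' @param fs a `FeatureSet`.
#' @return A `GRanges` with seqlengths from the genome.
#' @export
as_granges <- function(fs) {
  df <- fs$intervals
  sl <- stats::setNames(fs$genome$length, fs$genome$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = fs$genome$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand),
    seqlengths = sl)
  if (nrow(df) > 0) {
    S4Vectors::mcols(gr)$name <- df$name
    S4Vectors::mcols(gr)$score <- df$score
  }
  gr
}

#' Signal track: fixed-width binned per-chromosome signal
#'
#' Bin `i` (1-based) of a chromosome covers `[(i-1)*bin_width, i*bin_width)`;
#' the last bin is truncated at the chromosome end. Masked (unmappable) bins
#' are represented by `NA` and are excluded from every statistic in the
#' package.
#'
#' @param genome a [genome_model()].
#' @param bin_width bin width in bp.
#' @param values named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(length / bin_width)`; `NULL` for an all-zero track.
#' @param units `"linear"` or `"log2_ratio"`.
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(genome, bin_width, values = NULL,
                         units = c("linear", "log2_ratio")) {
  stopifnot(inherits(genome, "GenomeModel"))
  units <- match.arg(units)
  if (!is_count(bin_width)) stop_("signal_track: bin_width must be a positive integer")
  nb <- ceiling(genome$length / bin_width)
  if (is.null(values)) {
    values <- lapply(nb, function(n) numeric(n))
    names(values) <- genome$chrom
  }
  if (!identical(sort(names(values)), sort(genome$chrom)))
    stop_("signal_track: values must cover exactly the genome's chromosomes")
  values <- values[genome$chrom]
  for (i in seq_along(values)) {
    v <- as.numeric(values[[i]])
    if (length(v) != nb[i])
      stop_("signal_track: %s needs %d bins, got %d", genome$chrom[i], nb[i], length(v))
    if (any(!is.na(v) & !is.finite(v)))
      stop_("signal_track: non-finite unmasked value on %s", genome$chrom[i])
    values[[i]] <- v
  }
  structure(list(genome = genome, bin_width = as.numeric(bin_width),
                 values = values, units = units),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  n <- sum(vapply(x$values, length, 1L))
  cat(sprintf("SignalTrack: %d bins of %d bp (%s units), %d masked\n",
              n, as.integer(x$bin_width), x$units,
              sum(vapply(x$values, function(v) sum(is.na(v)), 1L))))
  invisible(x)
}

#' All unmasked values of a track as one vector
#' @param track a `SignalTrack`.
#' @param na_rm drop masked bins.
#' @export
track_values <- function(track, na_rm = TRUE) {
  v <- unlist(track$values, use.names = FALSE)
  if (na_rm) v <- v[!is.na(v)]
  v
}

same_grid <- function(a, b) {
  same_genome(a$genome, b$genome) && a$bin_width == b$bin_width
}

#' Indices of bins overlapping a bp interval
#'
#' @param track a `SignalTrack`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bp interval.
#' @return Integer vector of bin indices (possibly empty after clipping).
#' @keywords internal
bin_span <- function(track, chrom, start, end) {
  bw <- track$bin_width
  n <- length(track$values[[chrom]])
  lo <- max(1L, floor(start / bw) + 1L)
  hi <- min(n, ceiling(end / bw))
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

#' Peak set: intervals from peak calling
#'
#' A `PeakSet` is a `FeatureSet` whose interval table carries two extra
#' columns: `summit` (bp position of the maximum-signal bin midpoint,
#' leftmost on ties) and `mean_signal` (mean track signal over the peak's
#' bins). Peaks on a chromosome are non-overlapping and sorted.
#'
#' @param genome a [genome_model()].
#' @param intervals data frame with the `FeatureSet` columns plus `summit`
#'   and `mean_signal`.
#' @param label set label.
#' @return An object of class `PeakSet` (inherits `FeatureSet`).
#' @export
peak_set <- function(genome, intervals, label = "peaks") {
  df <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && !all(c("summit", "mean_signal") %in% names(df)))
    stop_("peak_set: need summit and mean_signal columns")
  fs <- feature_set(genome, df, label = label)
  df <- fs$intervals
  if (nrow(df) > 0) {
    if (any(df$summit < df$start | df$summit >= df$end))
      stop_("peak_set: summit must lie within [start, end)")
    sp <- split(df, df$chrom)
    for (d in sp) {
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop_("peak_set: peaks overlap on %s", d$chrom[1])
    }
  }
  class(fs) <- c("PeakSet", "FeatureSet")
  fs
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peak(s)\n", x$label, nrow(x$intervals)))
  if (nrow(x$intervals) > 0) print(utils::head(x$intervals, 6))
  invisible(x)
}
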