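#' Relative distance between two interval sets
#'
#' For each query midpoint `q` with flanking reference midpoints
#' `b_left <= q <= b_right` on the same chromosome, the relative distance is
#' `d = min(q - b_left, b_right - q) / (b_right - b_left)`, which lies in
#' `[0, 0.5]` and is uniform under independence. Queries on chromosomes with
#' fewer than two reference points, or outside the span of the reference
#' points, are skipped (not clamped) and counted.
#'
#' @param query,reference [feature_set()]s on one genome; midpoints are used
#'   for both.
#' @return An object of class `ReldistResult`: list with `d` (per-query
#'   distances), `hist` (counts in bins of width 0.05), `mean`, `median`,
#'   `n_used`, `n_skipped`.
#' @export
relative_distance <- function(query, reference) {
  stopifnot(inherits(query, "FeatureSet"), inherits(reference, "FeatureSet"))
  if (!same_genome(query$genome, reference$genome))
    stop_("query and reference are on different genomes")
  if (n_features(reference) == 0L) stop_("empty reference set")
  qm <- feature_midpoints(query)
  rm_ <- feature_midpoints(reference)
  usable <- names(which(table(rm_$chrom) >= 2))
  if (length(usable) == 0L)
    stop_("reference has < 2 points on every chromosome")
  d <- numeric(0)
  n_skipped <- 0L
  for (chrom in unique(qm$chrom)) {
    q <- qm$mid[qm$chrom == chrom]
    r <- sort(rm_$mid[rm_$chrom == chrom])
    if (length(r) < 2L) { n_skipped <- n_skipped + length(q); next }
    idx <- findInterval(q, r)
    exact <- q %in% r
    inside <- exact | (idx >= 1L & idx < length(r))
    n_skipped <- n_skipped + sum(!inside)
    q <- q[inside]; idx <- idx[inside]; exact <- exact[inside]
    if (length(q) == 0L) next
    di <- numeric(length(q))
    reg <- !exact
    if (any(reg)) {
      left <- r[idx[reg]]
      right <- r[idx[reg] + 1L]
      di[reg] <- pmin(q[reg] - left, right - q[reg]) / (right - left)
    }
    d <- c(d, di)
  }
  breaks <- seq(0, 0.5, by = 0.05)
  h <- if (length(d)) hist(d, breaks = breaks, plot = FALSE, right = FALSE,
                           include.lowest = TRUE)$counts else integer(10)
  # hist(right = FALSE) puts d == 0.5 in the last bin via include.lowest
  structure(list(d = d, hist = h, breaks = breaks,
                 mean = if (length(d)) mean(d) else NA_real_,
                 median = if (length(d)) stats::median(d) else NA_real_,
                 n_used = length(d), n_skipped = n_skipped),
            class = "ReldistResult")
}

#' @export
print.ReldistResult <- function(x, ...) {
  cat(sprintf("ReldistResult: n_used=%d n_skipped=%d mean=%.4f median=%.4f\n",
              x$n_used, x$n_skipped, x$mean, x$median))
  invisible(x)
}

# allowed placement segments of one chromosome: [0, len) minus forbidden
allowed_segments <- function(genome, chrom, forbidden = NULL) {
  len <- chrom_length(genome, chrom)
  if (is.null(forbidden)) return(data.frame(start = 0, end = len))
  fb <- forbidden$intervals
  fb <- fb[fb$chrom == chrom, , drop = FALSE]
  if (nrow(fb) == 0L) return(data.frame(start = 0, end = len))
  ir <- IRanges::reduce(IRanges::IRanges(fb$start + 1, fb$end))
  gaps <- IRanges::gaps(ir, start = 1, end = len)
  data.frame(start = IRanges::start(gaps) - 1, end = IRanges::end(gaps))
}

# uniform non-overlapping placement of interval lengths into one [0, free+len]
# segment space via the stars-and-bars bijection; returns sorted starts
place_lengths <- function(lengths, seg_start, seg_end, gap = 0) {
  k <- length(lengths)
  if (k == 0L) return(numeric(0))
  lengths <- lengths[sample.int(k)]  # random order across slots
  free <- (seg_end - seg_start) - sum(lengths) - gap * (k - 1)
  if (free < 0) return(NULL)
  p <- sort(sample.int(free + 1, k, replace = TRUE) - 1)
  starts <- seg_start + p + cumsum(c(0, lengths[-k] + gap))
  list(start = starts, length = lengths)
}

#' Randomly shuffle intervals over a genome
#'
#' Re-places the intervals at uniform random positions, preserving the count
#' and the multiset of interval lengths (per chromosome when
#' `mode = "within_chromosome"`). Placements avoid `forbidden` regions and
#' the output intervals do not overlap each other. Placement is by the exact
#' combinatorial construction (uniform over non-overlapping configurations),
#' with interval-to-segment assignment retried up to 1000 rounds before an
#' insufficient-space error.
#'
#' @param features a [feature_set()].
#' @param genome a [genome_model()] (defaults to the feature set's genome).
#' @param mode `"within_chromosome"` (default) or `"genome_wide"`.
#' @param seed integer seed.
#' @param forbidden optional [feature_set()] of excluded regions.
#' @return A shuffled [feature_set()].
#' @export
shuffle_intervals <- function(features, genome = features$genome,
                              mode = c("within_chromosome", "genome_wide"),
                              seed, forbidden = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "FeatureSet"))
  df <- features$intervals
  if (nrow(df) == 0L) return(feature_set(genome, data.frame(),
                                         label = paste0(features$label, "_shuffled")))
  widths <- df$end - df$start
  with_seed(seed, {
    if (mode == "within_chromosome") {
      chrom_of <- df$chrom
    } else {
      cap <- vapply(genome$chrom, function(ch) {
        s <- allowed_segments(genome, ch, forbidden); sum(s$end - s$start)
      }, 1)
      chrom_of <- sample(genome$chrom, nrow(df), replace = TRUE, prob = cap)
    }
    out <- NULL
    for (chrom in unique(chrom_of)) {
      w <- widths[chrom_of == chrom]
      segs <- allowed_segments(genome, chrom, forbidden)
      placed <- NULL
      for (round in seq_len(1000)) {
        segi <- apply_segment_assignment(w, segs)
        if (is.null(segi)) next
        ok <- TRUE
        starts <- numeric(0); lens <- numeric(0)
        for (s in seq_len(nrow(segs))) {
          wi <- w[segi == s]
          if (length(wi) == 0L) next
          pl <- place_lengths(wi, segs$start[s], segs$end[s])
          if (is.null(pl)) { ok <- FALSE; break }
          starts <- c(starts, pl$start); lens <- c(lens, pl$length)
        }
        if (ok) { placed <- data.frame(start = starts, length = lens); break }
      }
      if (is.null(placed))
        stop_("shuffle_intervals: insufficient placeable space on %s after 1000 rounds",
              chrom)
      out <- rbind(out, data.frame(chrom = chrom, start = placed$start,
                                   end = placed$start + placed$length,
                                   stringsAsFactors = FALSE))
    }
    feature_set(genome, out, label = paste0(features$label, "_shuffled"))
  })
}

# assign widths to segments with probability proportional to segment length
# among segments that can hold the interval; NULL if per-segment capacity
# is violated (caller retries)
apply_segment_assignment <- function(w, segs) {
  seglen <- segs$end - segs$start
  segi <- integer(length(w))
  for (i in seq_along(w)) {
    fits <- which(seglen >= w[i])
    if (length(fits) == 0L) return(NULL)
    segi[i] <- if (length(fits) == 1L) fits else
      sample(fits, 1, prob = seglen[fits])
  }
  for (s in seq_along(seglen))
    if (sum(w[segi == s]) > seglen[s]) return(NULL)
  segi
}

#' Empirical null for a colocalization statistic via query shuffling
#'
#' Recomputes the chosen statistic on `n_perm` seeded shuffles of the query
#' set and reports both one-sided empirical p-values with the add-one
#' convention, `p = (1 + #{null <= obs}) / (n_perm + 1)` for the left tail
#' (clustering, for relative-distance statistics) and analogously for the
#' right tail. p-values are never exactly zero.
#'
#' @param query,reference [feature_set()]s.
#' @param statistic `"mean_reldist"`, `"median_reldist"` or
#'   `"overlap_count"`.
#' @param n_perm number of shuffles (>= 1).
#' @param seed integer seed; shuffle `i` uses `seed + i`.
#' @param mode,forbidden passed to [shuffle_intervals()].
#' @return List with `observed`, `null` (length `n_perm`), `p_left`,
#'   `p_right`, `statistic`, `n_perm`.
#' @export
empirical_null <- function(query, reference,
                           statistic = c("mean_reldist", "median_reldist",
                                         "overlap_count"),
                           n_perm = 99, seed = 1,
                           mode = "within_chromosome", forbidden = NULL) {
  statistic <- match.arg(statistic)
  if (!is_count(n_perm)) stop_("n_perm must be >= 1")
  stat_fun <- switch(statistic,
    mean_reldist = function(q) relative_distance(q, reference)$mean,
    median_reldist = function(q) relative_distance(q, reference)$median,
    overlap_count = function(q)
      sum(IRanges::overlapsAny(as_granges(q), as_granges(reference))))
  observed <- stat_fun(query)
  null <- vapply(seq_len(n_perm), function(i) {
    stat_fun(shuffle_intervals(query, seed = seed + i, mode = mode,
                               forbidden = forbidden))
  }, 1)
  list(observed = observed, null = null,
       p_left = (1 + sum(null <= observed)) / (n_perm + 1),
       p_right = (1 + sum(null >= observed)) / (n_perm + 1),
       statistic = statistic, n_perm = n_perm)
}

#' Mean signal around site midpoints
#'
#' For each site, the mean of unmasked track bins overlapping
#' `[midpoint - flank_bp, midpoint + flank_bp)`; with `flank_bp = 0` this is
#' the value of the single bin containing the midpoint. Sites with no
#' unmasked bins are dropped; their count is attached as the `n_dropped`
#' attribute.
#'
#' @param track a [signal_track()].
#' @param sites a [feature_set()].
#' @param flank_bp flank in bp (>= 0).
#' @return Named numeric vector of per-site means.
#' @export
site_signal <- function(track, sites, flank_bp = 0) {
  stopifnot(inherits(track, "SignalTrack"), inherits(sites, "FeatureSet"))
  if (flank_bp < 0) stop_("flank_bp must be >= 0")
  mp <- feature_midpoints(sites)
  nm <- sites$intervals$name
  if (all(nm == "")) nm <- sprintf("site_%04d", seq_len(nrow(mp)))
  out <- vapply(seq_len(nrow(mp)), function(i) {
    lo <- max(0, mp$mid[i] - flank_bp)
    hi <- min(chrom_length(track$genome, mp$chrom[i]),
              mp$mid[i] + max(flank_bp, 1))
    bins <- bin_span(track, mp$chrom[i], lo, hi)
    v <- track$values[[mp$chrom[i]]][bins]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 1)
  names(out) <- nm
  dropped <- sum(is.na(out))
  out <- out[!is.na(out)]
  attr(out, "n_dropped") <- dropped
  out
}

#' Classify control peaks against a mutant peak set
#'
#' Venn-style differential classification of a control peak inventory
#' against a mutant map. A control peak is `eliminated` when no mutant peak
#' overlaps it by at least 1 bp. For retained peaks the signal fold change
#' `site_signal(mut_track) / site_signal(ctrl_track)` is evaluated over the
#' control peak midpoint +/- `flank_bp`; peaks with fold change at least
#' `fc_up` are `increased`, the rest `unaffected`. Retained peaks with zero
#' (or fully masked) control signal are excluded from the fold-change split
#' and counted as `unaffected`; their number is reported.
#'
#' @param ctrl_peaks,mut_peaks [peak_set()]s on one genome.
#' @param ctrl_track,mut_track the corresponding [signal_track()]s.
#' @param fc_up fold-change threshold (> 1) for the `increased` label.
#' @param flank_bp flank around the control peak midpoint for signal
#'   extraction.
#' @return An object of class `OverlapClassification`: list with `table`
#'   (one row per control peak: label and fold change), `counts`, `total`,
#'   `eliminated_pct`, `n_fc_excluded`.
#' @export
overlap_classify <- function(ctrl_peaks, mut_peaks, ctrl_track, mut_track,
                             fc_up = 1.5, flank_bp = 2000) {
  stopifnot(inherits(ctrl_peaks, "PeakSet"), inherits(mut_peaks, "PeakSet"))
  if (!same_genome(ctrl_peaks$genome, mut_peaks$genome))
    stop_("peak sets on different genomes")
  if (fc_up <= 1) stop_("fc_up must be > 1")
  df <- ctrl_peaks$intervals
  n <- nrow(df)
  if (n == 0L) {
    res <- list(table = data.frame(), counts = c(eliminated = 0L,
                unaffected = 0L, increased = 0L), total = 0L,
                eliminated_pct = NA_real_, n_fc_excluded = 0L,
                fc_up = fc_up, flank_bp = flank_bp)
    class(res) <- "OverlapClassification"
    return(res)
  }
  retained <- if (n_features(mut_peaks) == 0L) rep(FALSE, n) else
    IRanges::overlapsAny(as_granges(ctrl_peaks), as_granges(mut_peaks))
  fc <- rep(NA_real_, n)
  label <- rep("eliminated", n)
  excluded <- 0L
  if (any(retained)) {
    sub <- feature_set(ctrl_peaks$genome, df[retained, , drop = FALSE])
    s_ctrl <- site_signal_all(ctrl_track, sub, flank_bp)
    s_mut <- site_signal_all(mut_track, sub, flank_bp)
    ok <- !is.na(s_ctrl) & s_ctrl > 0 & !is.na(s_mut)
    f <- rep(NA_real_, sum(retained))
    f[ok] <- s_mut[ok] / s_ctrl[ok]
    fc[retained] <- f
    lab <- rep("unaffected", sum(retained))
    lab[ok & f >= fc_up] <- "increased"
    excluded <- sum(!ok)
    if (excluded > 0)
      message(sprintf("overlap_classify: %d retained peak(s) excluded from fold change", excluded))
    label[retained] <- lab
  }
  counts <- c(eliminated = sum(label == "eliminated"),
              unaffected = sum(label == "unaffected"),
              increased = sum(label == "increased"))
  stopifnot(sum(counts) == n)
  res <- list(
    table = data.frame(name = df$name, chrom = df$chrom, start = df$start,
                       end = df$end, label = label, fold_change = fc,
                       stringsAsFactors = FALSE),
    counts = counts, total = n,
    eliminated_pct = 100 * counts[["eliminated"]] / n,
    n_fc_excluded = excluded, fc_up = fc_up, flank_bp = flank_bp)
  class(res) <- "OverlapClassification"
  res
}

# site_signal variant that keeps NA entries aligned with the input sites
site_signal_all <- function(track, sites, flank_bp) {
  mp <- feature_midpoints(sites)
  vapply(seq_len(nrow(mp)), function(i) {
    lo <- max(0, mp$mid[i] - flank_bp)
    hi <- min(chrom_length(track$genome, mp$chrom[i]),
              mp$mid[i] + max(flank_bp, 1))
    bins <- bin_span(track, mp$chrom[i], lo, hi)
    v <- track$values[[mp$chrom[i]]][bins]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 1)
}

#' @export
print.OverlapClassification <- function(x, ...) {
  cat(sprintf("OverlapClassification: %d control peaks\n", x$total))
  cat(sprintf("  eliminated %d (%.1f%%), unaffected %d, increased %d (fc_up=%.2g)\n",
              x$counts[["eliminated"]], x$eliminated_pct,
              x$counts[["unaffected"]], x$counts[["increased"]], x$fc_up))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Computes the U statistic of `x` from midranks. The p-value is exact (full
#' enumeration of the permutation null, via the exact U distribution) when
#' `n1 + n2 <= 12` and there are no ties, and otherwise uses the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return An object of class `RankSumResult`: list with `U`, `z`, `p`,
#'   `n1`, `n2`, `method`, `alternative`.
#' @export
ranksum_test <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop_("ranksum_test: empty input")
  if (anyNA(x) || anyNA(y)) stop_("ranksum_test: NA in input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  z <- if (sigma > 0) (U - mu) / sigma else 0
  if (N <= 12 && !ties) {
    method <- "exact"
    p_less <- stats::pwilcox(U, n1, n2)
    p_greater <- 1 - stats::pwilcox(U - 1, n1, n2)
  } else {
    method <- "normal"
    if (sigma == 0) {
      p_less <- p_greater <- 1
    } else {
      p_less <- stats::pnorm((U - mu + 0.5) / sigma)
      p_greater <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    }
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_less, p_greater)),
              greater = p_greater,
              less = p_less)
  structure(list(U = U, z = z, p = p, n1 = n1, n2 = n2,
                 method = method, alternative = alternative),
            class = "RankSumResult")
}

#' @export
print.RankSumResult <- function(x, ...) {
  cat(sprintf("RankSumResult (%s, %s): U=%.1f z=%.3f p=%.4g (n1=%d, n2=%d)\n",
              x$method, x$alternative, x$U, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

#' Jaccard statistic of two interval sets
#'
#' Base-pair Jaccard index `|intersection| / |union|` over the merged
#' intervals of each set.
#'
#' @param a,b [feature_set()]s on one genome.
#' @return A single number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "FeatureSet"), inherits(b, "FeatureSet"))
  if (!same_genome(a$genome, b$genome)) stop_("sets on different genomes")
  if (n_features(a) == 0L && n_features(b) == 0L)
    stop_("jaccard_index: both sets empty")
  ga <- GenomicRanges::reduce(as_granges(a), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(as_granges(b), ignore.strand = TRUE)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb, ignore.strand = TRUE)))
  inter / uni
}
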