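# weighted mean of track signal over k equal segments of [a, b) on one
# chromosome; weights are bin/segment overlap in bp; NA where a segment has
# no unmasked coverage or falls off the chromosome
seg_means <- function(track, chrom, a, b, k) {
  bw <- track$bin_width
  v <- track$values[[chrom]]
  clen <- chrom_length(track$genome, chrom)
  edges <- a + (b - a) * (0:k) / k
  out <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    lo <- max(0, edges[j]); hi <- min(clen, edges[j + 1])
    if (hi <= lo) next
    bins <- bin_span(track, chrom, lo, hi)
    if (length(bins) == 0L) next
    bs <- (bins - 1) * bw
    be <- pmin(bins * bw, clen)
    w <- pmin(be, hi) - pmax(bs, lo)
    x <- v[bins]
    ok <- !is.na(x) & w > 0
    if (!any(ok)) next
    out[j] <- sum(x[ok] * w[ok]) / sum(w[ok])
  }
  out
}

summarize_profile <- function(mat, summary) {
  fun <- if (summary == "median") function(col) stats::median(col, na.rm = TRUE)
         else function(col) mean(col, na.rm = TRUE)
  s <- apply(mat, 2, fun)
  n <- apply(mat, 2, function(col) sum(!is.na(col)))
  s[n == 0] <- NA_real_
  list(summary = s, n = n)
}

#' Metagene profile over scaled gene bodies
#'
#' Each gene body is rescaled to `body_bins` segments (weighted mean within
#' each segment); fixed-width flanks of `flank_bp` are split into
#' `flank_bins` segments on each side. Minus-strand genes are reversed so
#' the profile axis always reads 5' to 3'. The per-segment summary (median
#' by default, as is usual for metagene plots of skewed ChIP signal) is
#' taken across genes. Genes shorter than `body_bins` track bins are skipped
#' and counted.
#'
#' @param track a [signal_track()].
#' @param genes a stranded [feature_set()].
#' @param body_bins number of scaled body segments (default 50).
#' @param flank_bp flank width in bp on each side (default 500).
#' @param flank_bins number of flank segments per side (default 10).
#' @param summary `"median"` or `"mean"`.
#' @return An object of class `MetaProfile`: list with `summary` (length
#'   `2*flank_bins + body_bins`), `n` per segment, `axis` (segment labels),
#'   `section` (upstream/body/downstream), `n_genes_used`, `n_skipped`,
#'   `summary_type`.
#' @export
metagene <- function(track, genes, body_bins = 50, flank_bp = 500,
                     flank_bins = 10, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(inherits(track, "SignalTrack"), inherits(genes, "FeatureSet"))
  if (!is_count(body_bins)) stop_("body_bins must be >= 1")
  df <- genes$intervals
  min_len <- body_bins * track$bin_width
  keep <- (df$end - df$start) >= min_len
  n_skipped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ncol_total <- 2 * flank_bins + body_bins
  if (nrow(df) == 0L)
    return(structure(list(summary = rep(NA_real_, ncol_total),
                          n = integer(ncol_total), axis = seq_len(ncol_total),
                          section = profile_sections(flank_bins, body_bins),
                          n_genes_used = 0L, n_skipped = n_skipped,
                          summary_type = summary), class = "MetaProfile"))
  mat <- matrix(NA_real_, nrow(df), ncol_total)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]; s <- df$start[i]; e <- df$end[i]
    up <- if (flank_bins > 0) seg_means(track, ch, s - flank_bp, s, flank_bins) else numeric(0)
    body <- seg_means(track, ch, s, e, body_bins)
    down <- if (flank_bins > 0) seg_means(track, ch, e, e + flank_bp, flank_bins) else numeric(0)
    row <- c(up, body, down)
    if (df$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  sm <- summarize_profile(mat, summary)
  structure(list(summary = sm$summary, n = sm$n, axis = seq_len(ncol_total),
                 section = profile_sections(flank_bins, body_bins),
                 n_genes_used = nrow(df), n_skipped = n_skipped,
                 summary_type = summary), class = "MetaProfile")
}

profile_sections <- function(flank_bins, body_bins) {
  c(rep("upstream", flank_bins), rep("body", body_bins),
    rep("downstream", flank_bins))
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile (%s): %d segments, %s\n", x$summary_type,
              length(x$summary),
              if (!is.null(x$n_genes_used))
                sprintf("%d genes used, %d skipped", x$n_genes_used, x$n_skipped)
              else sprintf("%d anchors", x$n_anchors)))
  invisible(x)
}

#' Anchor-point profile
#'
#' Signal in `[midpoint - window_bp, midpoint + window_bp)` around each
#' anchor, divided into `n_bins` equal segments, summarized across anchors.
#' Strand is ignored. Windows running off a chromosome end contribute `NA`
#' for the truncated segments, and the per-segment `n` is adjusted.
#'
#' @param track a [signal_track()].
#' @param anchors a [feature_set()]; midpoints are used.
#' @param window_bp half-window in bp (default 2000).
#' @param n_bins number of segments (default 80).
#' @param summary `"median"` or `"mean"`.
#' @return A `MetaProfile` with an `offset` component giving segment-center
#'   offsets from the anchor in bp.
#' @export
anchor_profile <- function(track, anchors, window_bp = 2000, n_bins = 80,
                           summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(inherits(track, "SignalTrack"), inherits(anchors, "FeatureSet"))
  if (window_bp <= 0) stop_("window_bp must be > 0")
  mp <- feature_midpoints(anchors)
  if (nrow(mp) == 0L)
    return(structure(list(summary = rep(NA_real_, n_bins), n = integer(n_bins),
                          offset = anchor_offsets(window_bp, n_bins),
                          n_anchors = 0L, summary_type = summary),
                     class = "MetaProfile"))
  mat <- matrix(NA_real_, nrow(mp), n_bins)
  for (i in seq_len(nrow(mp)))
    mat[i, ] <- seg_means(track, mp$chrom[i], mp$mid[i] - window_bp,
                          mp$mid[i] + window_bp, n_bins)
  sm <- summarize_profile(mat, summary)
  structure(list(summary = sm$summary, n = sm$n,
                 offset = anchor_offsets(window_bp, n_bins),
                 n_anchors = nrow(mp), summary_type = summary),
            class = "MetaProfile")
}

anchor_offsets <- function(window_bp, n_bins) {
  -window_bp + (2 * window_bp) * (seq_len(n_bins) - 0.5) / n_bins
}

#' Random 1-bp sites over a genome
#'
#' `n` positions sampled uniformly over the genome outside `forbidden`
#' regions; chromosomes are chosen with probability proportional to their
#' allowed length. Deterministic for a given seed.
#'
#' @param genome a [genome_model()].
#' @param n number of sites.
#' @param seed integer seed.
#' @param forbidden optional [feature_set()] of excluded regions.
#' @return A [feature_set()] of 1-bp points.
#' @export
random_sites <- function(genome, n, seed, forbidden = NULL) {
  if (!is_count(n)) stop_("n must be >= 1")
  segs <- do.call(rbind, lapply(genome$chrom, function(ch) {
    s <- allowed_segments(genome, ch, forbidden)
    if (nrow(s) == 0L) return(NULL)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), s)
  }))
  segs <- segs[!is.null(segs) & (segs$end - segs$start) >= 1, , drop = FALSE]
  if (is.null(segs) || nrow(segs) == 0L)
    stop_("random_sites: no allowed space left")
  with_seed(seed, {
    w <- segs$end - segs$start
    i <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
    pos <- floor(segs$start[i] + stats::runif(n) * w[i])
    feature_set(genome,
                data.frame(chrom = segs$chrom[i], start = pos, end = pos + 1,
                           stringsAsFactors = FALSE),
                label = "random_sites")
  })
}

#' Locus-level enrichment against a negative-control region
#'
#' ChIP-qPCR-style quantification on tracks: the ratio of the mean signal
#' over a target region to the mean over a negative-control region (for
#' example a DSB hotspot versus the recombinationally cold rDNA).
#'
#' @param track a linear [signal_track()].
#' @param target,negative [feature_set()]s (or single-interval sets).
#' @return An object of class `FoldChangeEstimate` with `target_mean`,
#'   `control_mean`, `ratio` and `orientation = "target/negative"`.
#' @export
locus_enrichment <- function(track, target, negative) {
  tm <- region_mean(track, target)
  nm <- region_mean(track, negative)
  if (is.na(nm) || nm <= 0)
    stop_("locus_enrichment: negative region mean is zero, masked or negative")
  structure(list(target_mean = tm, control_mean = nm, ratio = tm / nm,
                 orientation = "target/negative"),
            class = "FoldChangeEstimate")
}

region_mean <- function(track, region) {
  stopifnot(inherits(region, "FeatureSet"))
  if (n_features(region) == 0L) stop_("empty region")
  df <- region$intervals
  tot <- 0; wtot <- 0
  for (i in seq_len(nrow(df))) {
    bins <- bin_span(track, df$chrom[i], df$start[i], df$end[i])
    v <- track$values[[df$chrom[i]]][bins]
    v <- v[!is.na(v)]
    tot <- tot + sum(v); wtot <- wtot + length(v)
  }
  if (wtot == 0) return(NA_real_)
  tot / wtot
}

#' Fold change of one region between two tracks
#'
#' Ratio of mean control signal to mean mutant signal over a region
#' (orientation ctrl/mut, so a threefold signal loss in the mutant reports
#' ~3).
#'
#' @param ctrl_track,mut_track [signal_track()]s on one grid.
#' @param region a [feature_set()].
#' @return A `FoldChangeEstimate` with `orientation = "ctrl/mut"`.
#' @export
fold_change_between <- function(ctrl_track, mut_track, region) {
  if (!same_grid(ctrl_track, mut_track)) stop_("tracks on different grids")
  cm <- region_mean(ctrl_track, region)
  mm <- region_mean(mut_track, region)
  if (is.na(mm) || mm == 0) stop_("fold_change_between: zero mutant mean")
  structure(list(target_mean = cm, control_mean = mm, ratio = cm / mm,
                 orientation = "ctrl/mut"),
            class = "FoldChangeEstimate")
}

#' @export
print.FoldChangeEstimate <- function(x, ...) {
  cat(sprintf("FoldChangeEstimate (%s): %.4g (means %.4g / %.4g)\n",
              x$orientation, x$ratio, x$target_mean, x$control_mean))
  invisible(x)
}

#' Pearson correlation of two tracks
#'
#' Pearson r over jointly unmasked bins.
#'
#' @param a,b [signal_track()]s on one grid.
#' @return A single correlation coefficient.
#' @export
track_pearson <- function(a, b) {
  if (!same_grid(a, b)) stop_("tracks on different grids")
  x <- unlist(a$values, use.names = FALSE)
  y <- unlist(b$values, use.names = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop_("need >= 3 jointly unmasked bins")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop_("zero variance in a track")
  stats::cor(x[ok], y[ok])
}

#' Expression of peak-associated genes versus random genes
#'
#' Group 1 holds genes overlapped (>= 1 bp) by the supplied peaks; group 2
#' is `n_random` genes sampled uniformly without replacement from all genes.
#' The comparison is a Wilcoxon-Mann-Whitney rank-sum test; the one-sided
#' (group 1 greater) and two-sided p-values are both reported.
#'
#' @param expr data frame with columns `gene` and `expr`.
#' @param genes a [feature_set()] whose `name` column matches `expr$gene`.
#' @param peaks a [peak_set()] (or any `FeatureSet`) of e.g. H3K56ac peaks.
#' @param n_random size of the random gene sample (default: size of
#'   group 1).
#' @param seed integer seed for the random sample.
#' @return List with `test_greater`, `test_two_sided` ([ranksum_test()]
#'   results), `n_group1`, `n_random`, `median_group1`, `median_random`.
#' @export
expression_association <- function(expr, genes, peaks, n_random = NULL,
                                   seed = 1) {
  stopifnot(is.data.frame(expr), all(c("gene", "expr") %in% names(expr)))
  gdf <- genes$intervals
  miss <- setdiff(gdf$name, expr$gene)
  if (length(miss) > 0)
    stop_("expression table missing %d gene id(s), e.g. %s", length(miss), miss[1])
  ov <- IRanges::overlapsAny(as_granges(genes), as_granges(peaks))
  g1 <- gdf$name[ov]
  if (length(g1) == 0L) stop_("no genes overlap the peak set")
  n_random <- n_random %||% length(g1)
  if (n_random > nrow(gdf)) stop_("n_random exceeds the number of genes")
  g2 <- with_seed(seed, sample(gdf$name, n_random))
  lev <- stats::setNames(expr$expr, expr$gene)
  x <- as.numeric(lev[g1]); y <- as.numeric(lev[g2])
  list(test_greater = ranksum_test(x, y, "greater"),
       test_two_sided = ranksum_test(x, y, "two_sided"),
       n_group1 = length(g1), n_random = n_random,
       median_group1 = stats::median(x), median_random = stats::median(y))
}
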