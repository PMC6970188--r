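# shared toy objects and independent oracles used across the test files

toy_genome <- function(lengths = c(chrI = 1e5, chrII = 8e4)) {
  genome_model(names(lengths), unname(lengths))
}

toy_track <- function(values, bin_width = 50, genome = NULL,
                      units = "linear") {
  if (is.null(genome))
    genome <- genome_model("chrI", length(values) * bin_width)
  signal_track(genome, bin_width, list(chrI = values), units = units)
}

# a small generator configuration that keeps tests fast; scaled-down but
# structurally identical to the default fixture
small_config <- function(seed = 3, ...) {
  sim_config(seed = seed, chrom_lengths = c(4e5, 3e5), n_genes = 120,
             n_hotspots = 60, n_suppressed = 30, n_boosted = 10,
             cold_length = 4e4, n_axis = 15, n_origins = 10, n_ncRNA = 5,
             n_snRNA = 5, n_snoRNA = 5, n_tRNA = 8, n_LTR = 5, ...)
}

# the default study-scale fixture, generated once per test session
default_fixture <- local({
  cache <- new.env()
  function(noise = TRUE) {
    key <- if (noise) "noisy" else "clean"
    if (is.null(cache[[key]])) {
      cfg <- if (noise) sim_config(seed = 42) else
        sim_config(seed = 42, noise_sigma = 0)
      cache[[key]] <- simulate_fixture(cfg)
    }
    cache[[key]]
  }
})

# independent closed-form oracle for the generator's expected signal,
# written bin-by-bin from the model definition (bounded-support Gaussian
# resection flanks truncated at offset + 5 sd, bin membership by midpoint)
oracle_lambda <- function(truth, track, chrom) {
  cfg <- truth$config
  bw <- cfg$bin_width
  n <- ceiling(chrom_length(truth$genome, chrom) / bw)
  bg <- cfg$background
  gdf <- truth$genes$intervals
  gdf <- gdf[gdf$chrom == chrom, , drop = FALSE]
  k56f <- stats::setNames(truth$gene_table$k56_factor, truth$gene_table$gene)
  pdf <- truth$promoters$intervals
  pdf <- pdf[pdf$chrom == chrom, , drop = FALSE]
  hs <- truth$hotspots[truth$hotspots$chrom == chrom, , drop = FALSE]
  cold <- truth$cold_region$intervals
  cold <- cold[cold$chrom == chrom, , drop = FALSE]
  vapply(seq_len(n), function(i) {
    x <- (i - 0.5) * bw
    in_gene <- which(gdf$start <= x & x < gdf$end)
    in_prom <- any(pdf$start <= x & x < pdf$end)
    in_core <- nrow(hs) > 0 &&
      any(hs$mid - cfg$core_half_width <= x & x < hs$mid + cfg$core_half_width)
    in_cold <- nrow(cold) > 0 && any(cold$start <= x & x < cold$end)
    switch(track,
      input = bg,
      H3 = bg * (if (in_prom || in_core) cfg$ndr_factor else 1),
      H3K56ac = {
        if (in_cold) bg else {
          v <- if (length(in_gene) > 0) bg * k56f[[gdf$name[in_gene[1]]]] else bg
          if (in_core) v * cfg$k56_depletion else v
        }
      },
      RPA_ctrl = bg + bump_sum(x, hs, hs$intensity, cfg),
      RPA_mut = {
        amp <- ifelse(hs$status == "suppressed", 0,
                      ifelse(hs$status == "boosted",
                             cfg$boost_factor * hs$intensity,
                             cfg$mut_efficiency * hs$intensity))
        bg + bump_sum(x, hs, amp, cfg)
      })
  }, 1)
}

bump_sum <- function(x, hs, amp, cfg) {
  if (nrow(hs) == 0) return(0)
  within <- abs(x - hs$mid) <= cfg$flank_offset + 5 * cfg$flank_sd
  if (!any(within)) return(0)
  m <- hs$mid[within]; a <- amp[within]
  sum(a * (exp(-((x - m - cfg$flank_offset)^2) / (2 * cfg$flank_sd^2)) +
           exp(-((x - m + cfg$flank_offset)^2) / (2 * cfg$flank_sd^2))))
}

# full-enumeration Mann-Whitney oracle: exact null distribution of U for
# group sizes (n1, n2) from all C(N, n1) assignments of the ranks 1..N
enum_null_U <- local({
  cache <- new.env()
  function(n1, n2) {
    key <- paste(n1, n2, sep = "_")
    if (is.null(cache[[key]])) {
      N <- n1 + n2
      sets <- utils::combn(N, n1)
      cache[[key]] <- apply(sets, 2, sum) - n1 * (n1 + 1) / 2
    }
    cache[[key]]
  }
})

enum_ranksum_p <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  null <- enum_null_U(n1, n2)
  p_less <- mean(null <= U)
  p_greater <- mean(null >= U)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}
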