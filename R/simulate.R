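#' Generator configuration for the synthetic meiotic ChIP fixture
#'
#' Returns the configuration that drives [build_genome()],
#' [simulate_tracks()] and [simulate_expression()]. Defaults describe a
#' 4-chromosome, 6 Mb yeast-like genome binned at 50 bp, carrying 1004 DSB
#' hotspots whose RPA (resected ssDNA) signal forms two Gaussian flanks
#' around each hotspot midpoint; in the mutant map 661 hotspots are fully
#' suppressed, 182 of the remainder are boosted twofold, and every other
#' hotspot keeps one third of its control amplitude. H3K56ac is enriched
#' over gene bodies, depleted over hotspot cores and flat across a cold
#' rDNA-like region; H3 occupancy dips at promoter NDRs and hotspot cores.
#' Noise is multiplicative log-normal per bin.
#'
#' @param seed mandatory integer seed; sub-streams are derived as
#'   `seed` (genome), `seed + 1` (track noise), `seed + 2` (expression).
#' @param ... overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42, ...) {
  cfg <- list(
    seed = seed,
    chrom_lengths = c(1.8e6, 1.6e6, 1.4e6, 1.2e6),
    bin_width = 50,
    # genes
    n_genes = 2000,
    gene_len_min = 500,
    gene_len_max = 3000,
    gene_min_gap = 400,
    # hotspots and RPA geometry
    n_hotspots = 1004,
    hotspot_meanlog = log(300),
    hotspot_sdlog = 0.4,
    flank_offset = 800,
    flank_sd = 400,
    min_hotspot_spacing = 5000,
    promoter_snap_prob = 0.8,
    # mutant map
    n_suppressed = 661,
    n_boosted = 182,
    boost_factor = 2.0,
    mut_efficiency = 1 / 3,
    # H3K56ac / H3
    k56_orf_enrichment = 3.0,
    k56_gene_sdlog = 0.5,
    k56_depletion = 0.3,
    core_half_width = 500,
    ndr_width = 300,
    ndr_factor = 0.4,
    # cold (rDNA-like) region
    cold_length = 150000,
    # auxiliary feature classes
    n_axis = 200, n_origins = 150, n_ncRNA = 50, n_snRNA = 20,
    n_snoRNA = 40, n_tRNA = 100, n_LTR = 50,
    # noise and scale
    background = 1.0,
    noise_sigma = 0.25,
    # expression model
    expr_base_meanlog = log(10),
    expr_sdlog = 0.7,
    expr_shift_log2 = 1.0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_("sim_config: unknown parameter(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is_count(cfg$seed, min = 0))
    stop_("sim_config: seed is mandatory and must be a non-negative integer")
  if (cfg$n_suppressed + cfg$n_boosted > cfg$n_hotspots)
    stop_("sim_config: n_suppressed + n_boosted must not exceed n_hotspots")
  pos <- c("boost_factor", "mut_efficiency", "k56_orf_enrichment",
           "k56_depletion", "ndr_factor", "background", "bin_width")
  for (p in pos) if (cfg[[p]] <= 0) stop_("sim_config: %s must be > 0", p)
  if (cfg$noise_sigma < 0) stop_("sim_config: noise_sigma must be >= 0")
  if (any(cfg$chrom_lengths %% cfg$bin_width != 0))
    stop_("sim_config: chromosome lengths must be multiples of bin_width")
  invisible(cfg)
}

# largest-remainder allocation of n items proportional to weights
allocate_counts <- function(n, weights) {
  if (n == 0L) return(rep(0L, length(weights)))
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build the synthetic genome and its ground-truth annotation
#'
#' Places non-overlapping grid-aligned genes with intergenic promoter gaps;
#' plants hotspot midpoints in quasi-regular slots (guaranteeing a minimum
#' inter-hotspot spacing so that resection flanks of neighbours do not
#' fuse), snapping them to nearby promoters with probability
#' `promoter_snap_prob`; reserves one contiguous cold rDNA-like region that
#' carries no hotspots or genes; scatters the auxiliary feature classes
#' (axis sites, meiotic origins, ncRNA, snRNA, snoRNA, tRNA, LTR) outside
#' the cold region; and registers three named loci: `BUD23like` and
#' `ERG1like` (median-strength hotspots left unchanged in the mutant) and
#' `rDNAlike` (inside the cold region).
#'
#' @param config a [sim_config()].
#' @return A list of class `ground_truth` with elements `genome`,
#'   `cold_region`, `genes`, `gene_table` (gene, k56_factor, tier),
#'   `promoters`, `hotspots` (chrom, mid, intensity, status), `aux`
#'   (list of [feature_set()]s), `named_loci`, `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  bw <- cfg$bin_width
  genome <- genome_model(paste0("chr", utils::as.roman(seq_along(cfg$chrom_lengths))),
                         cfg$chrom_lengths)
  last <- genome$chrom[length(genome$chrom)]
  cold <- if (cfg$cold_length > 0) {
    clen <- chrom_length(genome, last)
    if (cfg$cold_length >= clen) stop_("cold region longer than its chromosome")
    s <- floor((clen - cfg$cold_length) / 2 / bw) * bw
    feature_set(genome, data.frame(chrom = last, start = s,
                                   end = s + cfg$cold_length,
                                   name = "rDNAlike_region"),
                label = "cold_region")
  } else feature_set(genome, data.frame(), label = "cold_region")

  with_seed(cfg$seed, {
    genes <- place_genes(genome, cold, cfg)
    gdf <- genes$intervals
    n_g <- nrow(gdf)
    k56 <- cfg$k56_orf_enrichment * exp(stats::rnorm(n_g, 0, cfg$k56_gene_sdlog))
    tier <- rep("low", n_g)
    if (n_g > 0) {
      n_high <- floor(n_g / 4)
      tier[order(-k56, seq_len(n_g))[seq_len(n_high)]] <- "high"
    }
    gene_table <- data.frame(gene = gdf$name, k56_factor = k56, tier = tier,
                             stringsAsFactors = FALSE)
    promoters <- gene_promoters(genes, cfg$ndr_width)
    hotspots <- place_hotspots(genome, cold, promoters, cfg)
    aux <- place_aux(genome, cold, cfg)
    named_loci <- register_loci(genome, cold, hotspots, cfg)
    structure(list(genome = genome, cold_region = cold, genes = genes,
                   gene_table = gene_table, promoters = promoters,
                   hotspots = hotspots, aux = aux, named_loci = named_loci,
                   config = cfg),
              class = "ground_truth")
  })
}

place_genes <- function(genome, cold, cfg) {
  bw <- cfg$bin_width
  if (cfg$n_genes == 0)
    return(feature_set(genome, data.frame(), label = "genes"))
  segs <- do.call(rbind, lapply(genome$chrom, function(ch) {
    s <- allowed_segments(genome, ch, if (n_features(cold)) cold else NULL)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), s)
  }))
  # work on the bin lattice so gene boundaries align to the track grid
  segs$start_b <- ceiling(segs$start / bw)
  segs$end_b <- floor(segs$end / bw)
  gap_b <- ceiling(cfg$gene_min_gap / bw)
  len_b <- sample(seq(ceiling(cfg$gene_len_min / bw), floor(cfg$gene_len_max / bw)),
                  cfg$n_genes, replace = TRUE)
  seglen_b <- segs$end_b - segs$start_b
  segi <- NULL
  for (round in seq_len(1000)) {
    cand <- apply_segment_assignment(len_b + gap_b, data.frame(start = 0, end = seglen_b))
    if (!is.null(cand)) { segi <- cand; break }
  }
  if (is.null(segi))
    stop_("build_genome: cannot place %d genes in the available space", cfg$n_genes)
  out <- NULL
  for (s in seq_len(nrow(segs))) {
    li <- len_b[segi == s]
    if (length(li) == 0L) next
    pl <- place_lengths(li, segs$start_b[s], segs$end_b[s], gap = gap_b)
    if (is.null(pl))
      stop_("build_genome: cannot place %d genes in the available space", cfg$n_genes)
    out <- rbind(out, data.frame(chrom = segs$chrom[s],
                                 start = pl$start * bw,
                                 end = (pl$start + pl$length) * bw,
                                 stringsAsFactors = FALSE))
  }
  out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
  out <- out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
  out$name <- sprintf("gene%05d", seq_len(nrow(out)))
  feature_set(genome, out, label = "genes")
}

# strand-aware promoter (NDR) window upstream of each gene start
gene_promoters <- function(genes, ndr_width) {
  df <- genes$intervals
  if (nrow(df) == 0L) return(feature_set(genes$genome, data.frame(), label = "promoters"))
  plus <- df$strand != "-"
  start <- ifelse(plus, pmax(0, df$start - ndr_width), df$end)
  end <- ifelse(plus, df$start, pmin(chrom_length(genes$genome, df$chrom),
                                     df$end + ndr_width))
  keep <- end > start
  feature_set(genes$genome,
              data.frame(chrom = df$chrom[keep], start = start[keep],
                         end = end[keep], strand = df$strand[keep],
                         name = paste0(df$name[keep], "_prom"),
                         stringsAsFactors = FALSE),
              label = "promoters")
}

place_hotspots <- function(genome, cold, promoters, cfg) {
  empty <- data.frame(chrom = character(), mid = numeric(),
                      intensity = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  if (cfg$n_hotspots == 0) return(empty)
  segs <- do.call(rbind, lapply(genome$chrom, function(ch) {
    s <- allowed_segments(genome, ch, if (n_features(cold)) cold else NULL)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), s)
  }))
  margin <- cfg$min_hotspot_spacing / 2
  k <- allocate_counts(cfg$n_hotspots, segs$end - segs$start)
  pm <- feature_midpoints(promoters)
  chrom <- character(0); mid <- numeric(0)
  for (s in seq_len(nrow(segs))) {
    if (k[s] == 0) next
    slot_w <- (segs$end[s] - segs$start[s]) / k[s]
    if (slot_w < 2 * margin + 1)
      stop_("build_genome: %d hotspots do not fit on %s at %d bp spacing",
            cfg$n_hotspots, segs$chrom[s], as.integer(cfg$min_hotspot_spacing))
    for (j in seq_len(k[s])) {
      lo <- segs$start[s] + (j - 1) * slot_w + margin
      hi <- segs$start[s] + j * slot_w - margin
      cand <- pm$mid[pm$chrom == segs$chrom[s] & pm$mid >= lo & pm$mid <= hi]
      m <- if (length(cand) > 0 && stats::runif(1) < cfg$promoter_snap_prob) {
        if (length(cand) == 1L) cand else sample(cand, 1)
      } else floor(stats::runif(1, lo, hi))
      chrom <- c(chrom, segs$chrom[s]); mid <- c(mid, m)
    }
  }
  ord <- order(match(chrom, genome$chrom), mid)
  chrom <- chrom[ord]; mid <- mid[ord]
  n <- length(mid)
  intensity <- stats::rlnorm(n, cfg$hotspot_meanlog, cfg$hotspot_sdlog)
  status <- rep("unchanged", n)
  sup <- sample.int(n, cfg$n_suppressed)
  status[sup] <- "suppressed"
  rest <- setdiff(seq_len(n), sup)
  if (cfg$n_boosted > 0)
    status[rest[sample.int(length(rest), cfg$n_boosted)]] <- "boosted"
  data.frame(chrom = chrom, mid = mid, intensity = intensity, status = status,
             name = sprintf("hs%04d", seq_len(n)), stringsAsFactors = FALSE)
}

place_aux <- function(genome, cold, cfg) {
  classes <- c(axis = 400, origins = 400, ncRNA = 200, snRNA = 150,
               snoRNA = 100, tRNA = 80, LTR = 300)
  counts <- c(axis = cfg$n_axis, origins = cfg$n_origins, ncRNA = cfg$n_ncRNA,
              snRNA = cfg$n_snRNA, snoRNA = cfg$n_snoRNA, tRNA = cfg$n_tRNA,
              LTR = cfg$n_LTR)
  out <- list()
  for (cl in names(classes)) {
    n <- counts[[cl]]
    if (n == 0) {
      out[[cl]] <- feature_set(genome, data.frame(), label = cl)
      next
    }
    pts <- random_sites_local(genome, n, if (n_features(cold)) cold else NULL)
    w <- classes[[cl]]
    start <- pmax(0, pts$mid - floor(w / 2))
    end <- pmin(chrom_length(genome, pts$chrom), start + w)
    out[[cl]] <- feature_set(genome,
      data.frame(chrom = pts$chrom, start = start, end = end,
                 name = sprintf("%s%04d", cl, seq_len(n)),
                 stringsAsFactors = FALSE), label = cl)
  }
  out
}

# uniform points in allowed space drawn from the current RNG stream
random_sites_local <- function(genome, n, forbidden) {
  segs <- do.call(rbind, lapply(genome$chrom, function(ch) {
    s <- allowed_segments(genome, ch, forbidden)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), s)
  }))
  w <- segs$end - segs$start
  i <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  data.frame(chrom = segs$chrom[i],
             mid = floor(segs$start[i] + stats::runif(n) * w[i]),
             stringsAsFactors = FALSE)
}

register_loci <- function(genome, cold, hotspots, cfg) {
  loci <- list()
  if (n_features(cold) > 0) {
    cd <- cold$intervals
    c_mid <- floor((cd$start[1] + cd$end[1]) / 2)
    loci$rDNAlike <- feature_set(genome,
      data.frame(chrom = cd$chrom[1], start = c_mid - 2000, end = c_mid + 2000,
                 name = "rDNAlike"), label = "rDNAlike")
  }
  if (nrow(hotspots) > 0) {
    pool <- which(hotspots$status == "unchanged")
    if (length(pool) < 2) pool <- seq_len(nrow(hotspots))
    med <- stats::median(hotspots$intensity)
    ord <- pool[order(abs(hotspots$intensity[pool] - med))]
    mk <- function(i, nm) {
      m <- hotspots$mid[i]
      lo <- max(0, m - 2000)
      feature_set(genome, data.frame(
        chrom = hotspots$chrom[i], start = lo,
        end = min(chrom_length(genome, hotspots$chrom[i]), m + 2000),
        name = nm), label = nm)
    }
    loci$BUD23like <- mk(ord[1], "BUD23like")
    if (length(ord) > 1) loci$ERG1like <- mk(ord[2], "ERG1like")
    loci$BUD23like_hotspot <- hotspots$name[ord[1]]
    if (length(ord) > 1) loci$ERG1like_hotspot <- hotspots$name[ord[2]]
  }
  loci
}

#' Simulate the five ChIP signal tracks
#'
#' Computes the per-bin expected value `lambda` of each track from the
#' ground truth and multiplies it by independent log-normal noise,
#' `observed = lambda * exp(eps)`, `eps ~ N(0, noise_sigma^2)`, independent
#' across bins and tracks. Track structure:
#' \describe{
#'   \item{input}{flat background.}
#'   \item{H3}{background occupancy with NDR dips (factor `ndr_factor`) at
#'     promoters and hotspot cores.}
#'   \item{H3K56ac}{per-gene body plateau `background * k56_factor(gene)`,
#'     multiplied by `k56_depletion` within `core_half_width` of a hotspot
#'     midpoint, forced to background inside the cold region.}
#'   \item{RPA_ctrl}{background plus, per hotspot, two Gaussian resection
#'     flanks centred at `mid +/- flank_offset` with sd `flank_sd` and peak
#'     amplitude equal to the hotspot intensity.}
#'   \item{RPA_mut}{as RPA_ctrl with suppressed hotspots contributing
#'     nothing, boosted hotspots `boost_factor` times their amplitude and
#'     all others `mut_efficiency` times it.}
#' }
#'
#' @param truth a [build_genome()] result.
#' @param noise_seed seed for the noise stream (default `config seed + 1`);
#'   rerunning with a different `noise_seed` yields an independent replicate
#'   of the same underlying landscape.
#' @return Named list of five [signal_track()]s.
#' @export
simulate_tracks <- function(truth, noise_seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  noise_seed <- noise_seed %||% (cfg$seed + 1)
  genome <- truth$genome
  bw <- cfg$bin_width
  lam <- track_lambdas(truth)
  with_seed(noise_seed, {
    out <- list()
    for (tr in names(lam)) {
      vals <- list()
      for (ch in genome$chrom) {
        l <- lam[[tr]][[ch]]
        vals[[ch]] <- l * exp(stats::rnorm(length(l), 0, cfg$noise_sigma))
      }
      out[[tr]] <- signal_track(genome, bw, vals, units = "linear")
    }
    out
  })
}

#' Closed-form expected signal (lambda) of every track
#'
#' The noise-free expectation used by [simulate_tracks()]; exposed so that
#' analyses and tests can compare observed tracks with their generating
#' surface.
#'
#' @param truth a [build_genome()] result.
#' @return Named list (track) of named lists (chromosome) of numeric
#'   vectors.
#' @export
track_lambdas <- function(truth) {
  cfg <- truth$config
  genome <- truth$genome
  bw <- cfg$bin_width
  nb <- ceiling(genome$length / bw)
  names(nb) <- genome$chrom
  bg <- cfg$background
  gdf <- truth$genes$intervals
  k56f <- stats::setNames(truth$gene_table$k56_factor, truth$gene_table$gene)
  hs <- truth$hotspots
  lam <- list(input = list(), H3 = list(), H3K56ac = list(),
              RPA_ctrl = list(), RPA_mut = list())
  for (ci in seq_along(genome$chrom)) {
    ch <- genome$chrom[ci]
    n <- nb[[ch]]
    x <- (seq_len(n) - 0.5) * bw
    l_in <- rep(bg, n)
    h3_f <- rep(1, n)
    l_k56 <- rep(bg, n)
    l_rc <- rep(bg, n)
    l_rm <- rep(bg, n)
    gi <- which(gdf$chrom == ch)
    for (g in gi) {
      idx <- which(x >= gdf$start[g] & x < gdf$end[g])
      l_k56[idx] <- bg * k56f[[gdf$name[g]]]
    }
    pdf <- truth$promoters$intervals
    for (p in which(pdf$chrom == ch)) {
      idx <- which(x >= pdf$start[p] & x < pdf$end[p])
      h3_f[idx] <- pmin(h3_f[idx], cfg$ndr_factor)
    }
    hi <- which(hs$chrom == ch)
    for (h in hi) {
      m <- hs$mid[h]
      core <- which(x >= m - cfg$core_half_width & x < m + cfg$core_half_width)
      l_k56[core] <- l_k56[core] * cfg$k56_depletion
      h3_f[core] <- pmin(h3_f[core], cfg$ndr_factor)
      win <- which(abs(x - m) <= cfg$flank_offset + 5 * cfg$flank_sd)
      if (length(win) > 0) {
        bump <- exp(-((x[win] - m - cfg$flank_offset)^2) / (2 * cfg$flank_sd^2)) +
                exp(-((x[win] - m + cfg$flank_offset)^2) / (2 * cfg$flank_sd^2))
        l_rc[win] <- l_rc[win] + hs$intensity[h] * bump
        amp_mut <- switch(hs$status[h],
                          suppressed = 0,
                          boosted = cfg$boost_factor * hs$intensity[h],
                          cfg$mut_efficiency * hs$intensity[h])
        l_rm[win] <- l_rm[win] + amp_mut * bump
      }
    }
    if (n_features(truth$cold_region) > 0) {
      cd <- truth$cold_region$intervals
      for (k in which(cd$chrom == ch)) {
        idx <- which(x >= cd$start[k] & x < cd$end[k])
        l_k56[idx] <- bg
      }
    }
    lam$input[[ch]] <- l_in
    lam$H3[[ch]] <- bg * h3_f
    lam$H3K56ac[[ch]] <- l_k56
    lam$RPA_ctrl[[ch]] <- l_rc
    lam$RPA_mut[[ch]] <- l_rm
  }
  lam
}

#' Simulate the gene-expression table
#'
#' mRNA levels are log-normal around a tier mean: genes in the high-H3K56ac
#' tier (top quartile of the planted per-gene H3K56ac factor) have their
#' location parameter shifted up by `expr_shift_log2` log2 units.
#'
#' @param truth a [build_genome()] result.
#' @param seed seed for the expression draw (default `config seed + 2`).
#' @return Data frame with columns `gene`, `tier`, `expr`.
#' @export
simulate_expression <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  seed <- seed %||% (cfg$seed + 2)
  gt <- truth$gene_table
  with_seed(seed, {
    ml <- cfg$expr_base_meanlog +
      log(2) * cfg$expr_shift_log2 * (gt$tier == "high")
    data.frame(gene = gt$gene, tier = gt$tier,
               expr = stats::rlnorm(nrow(gt), ml, cfg$expr_sdlog),
               stringsAsFactors = FALSE)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d chromosomes, %d genes, %d hotspots (seed %d)\n",
              length(x$genome$chrom), n_features(x$genes), nrow(x$hotspots),
              x$config$seed))
  if (nrow(x$hotspots) > 0) print(table(x$hotspots$status))
  invisible(x)
}

#' Generate the full fixture in memory (and optionally on disk)
#'
#' @param config a [sim_config()].
#' @param dir if non-`NULL`, write the fixture files there via
#'   [write_fixture()].
#' @return List of class `sim_fixture` with `truth`, `tracks`, `expression`
#'   and `config`.
#' @export
simulate_fixture <- function(config = sim_config(), dir = NULL) {
  truth <- build_genome(config)
  tracks <- simulate_tracks(truth)
  expr <- simulate_expression(truth)
  sim <- structure(list(truth = truth, tracks = tracks, expression = expr,
                        config = config), class = "sim_fixture")
  if (!is.null(dir)) write_fixture(dir, sim)
  sim
}

#' @export
print.sim_fixture <- function(x, ...) {
  cat("sim_fixture with tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  print(x$truth)
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `genome.tsv`, `genes.gff3`, `hotspots.bed` (midpoints, score =
#' intensity), `cold_region.bed`, one BED per auxiliary class, the five
#' bedGraph tracks, `expression.tsv`, `truth.json` (ground truth) and
#' `manifest.json` (full configuration). Output is byte-deterministic for a
#' given configuration and seed.
#'
#' @param dir output directory (created if missing).
#' @param sim a [simulate_fixture()] result.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, sim) {
  stopifnot(inherits(sim, "sim_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim$truth
  genome <- truth$genome
  write_genome_tsv(genome, file.path(dir, "genome.tsv"))
  write_gff3_genes(truth$genes, file.path(dir, "genes.gff3"))
  hs <- truth$hotspots
  hs_fs <- feature_set(genome, if (nrow(hs) == 0) data.frame() else
    data.frame(chrom = hs$chrom, start = hs$mid, end = hs$mid + 1,
               name = hs$name, score = hs$intensity, stringsAsFactors = FALSE),
    label = "hotspots")
  write_bed(hs_fs, file.path(dir, "hotspots.bed"))
  write_bed(truth$cold_region, file.path(dir, "cold_region.bed"))
  for (cl in names(truth$aux))
    write_bed(truth$aux[[cl]], file.path(dir, paste0(cl, ".bed")))
  for (tr in names(sim$tracks))
    write_bedgraph(sim$tracks[[tr]], file.path(dir, paste0(tr, ".bedGraph")))
  utils::write.table(sim$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(
    n_hotspots = nrow(hs),
    hotspots = hs,
    gene_table = truth$gene_table,
    cold_region = truth$cold_region$intervals,
    named_loci = lapply(truth$named_loci, function(x)
      if (inherits(x, "FeatureSet")) x$intervals else x))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
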