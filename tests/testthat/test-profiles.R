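test_that("profiles of a constant track are flat at that constant", {
  gm <- genome_model("chrI", 2e4)
  tr <- signal_track(gm, 50, list(chrI = rep(2.5, 400)))
  genes <- feature_set(gm, data.frame(chrom = "chrI", start = c(2000, 9000),
                                      end = c(6000, 14000),
                                      strand = c("+", "-"),
                                      name = c("g1", "g2")))
  mg <- metagene(tr, genes, body_bins = 20, flank_bp = 500, flank_bins = 5)
  expect_true(all(mg$summary == 2.5))
  an <- anchor_profile(tr, genes, window_bp = 1000, n_bins = 20)
  expect_true(all(an$summary == 2.5))
})

test_that("metagene recovers a planted ORF plateau exactly at zero noise", {
  cfg <- sim_config(seed = 8, noise_sigma = 0, chrom_lengths = c(5e5),
                    n_genes = 20, gene_len_min = 5000, gene_len_max = 8000,
                    k56_gene_sdlog = 0, n_hotspots = 0, n_suppressed = 0,
                    n_boosted = 0, cold_length = 0, n_axis = 2, n_origins = 2,
                    n_ncRNA = 2, n_snRNA = 2, n_snoRNA = 2, n_tRNA = 2,
                    n_LTR = 2)
  truth <- build_genome(cfg)
  tracks <- simulate_tracks(truth)
  # precondition of the closed form: clear 500 bp flanks around every gene
  g <- truth$genes$intervals
  expect_gte(min(g$start[-1] - g$end[-nrow(g)]), 500)
  mg <- metagene(tracks$H3K56ac, truth$genes, 50, 500, 10)
  body <- mg$summary[mg$section == "body"]
  flank <- mg$summary[mg$section != "body"]
  expect_equal(unname(body),
               rep(cfg$background * cfg$k56_orf_enrichment, 50))
  expect_equal(unname(flank), rep(cfg$background, 20))
  expect_equal(mg$n_genes_used, 20)
})

test_that("genes shorter than the body grid are skipped and counted", {
  gm <- genome_model("chrI", 2e4)
  tr <- signal_track(gm, 50, list(chrI = rep(1, 400)))
  genes <- feature_set(gm, data.frame(chrom = "chrI", start = c(1000, 5000),
                                      end = c(1400, 9000), strand = "+",
                                      name = c("short", "long")))
  mg <- metagene(tr, genes, body_bins = 10)
  expect_equal(mg$n_genes_used, 1)
  expect_equal(mg$n_skipped, 1)
})

test_that("minus-strand genes are read 5' to 3'", {
  gm <- genome_model("chrI", 1000)
  tr <- signal_track(gm, 50, list(chrI = as.numeric(1:20)))
  gene <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 500,
                                     strand = "-", name = "g"))
  mg <- metagene(tr, gene, body_bins = 10, flank_bp = 0, flank_bins = 0)
  expect_equal(unname(mg$summary), as.numeric(10:1))
})

test_that("mirroring the genome leaves the stranded metagene invariant", {
  gm <- genome_model("chrI", 2e4)
  set.seed(13)
  v <- stats::rlnorm(400)
  tr <- signal_track(gm, 50, list(chrI = v))
  genes <- feature_set(gm, data.frame(chrom = "chrI",
                                      start = c(1000, 8000, 14000),
                                      end = c(4000, 12000, 18000),
                                      strand = c("+", "-", "+"),
                                      name = c("a", "b", "c")))
  trm <- signal_track(gm, 50, list(chrI = rev(v)))
  gdf <- genes$intervals
  mirrored <- feature_set(gm, data.frame(
    chrom = "chrI", start = 2e4 - gdf$end, end = 2e4 - gdf$start,
    strand = ifelse(gdf$strand == "+", "-", "+"), name = gdf$name))
  m1 <- metagene(tr, genes, 20, 500, 5)
  m2 <- metagene(trm, mirrored, 20, 500, 5)
  expect_equal(m1$summary, m2$summary)
})

test_that("anchor profiles recover the planted depletion and flank geometry", {
  cfg <- sim_config(seed = 5, noise_sigma = 0, chrom_lengths = c(6e5, 5e5),
                    n_genes = 120, gene_len_min = 5000, gene_len_max = 8000,
                    n_hotspots = 60, n_suppressed = 0, n_boosted = 0,
                    promoter_snap_prob = 0, cold_length = 5e4,
                    n_axis = 10, n_origins = 10, n_ncRNA = 5, n_snRNA = 5,
                    n_snoRNA = 5, n_tRNA = 5, n_LTR = 5)
  truth <- build_genome(cfg)
  tracks <- simulate_tracks(truth)
  g <- truth$genes$intervals
  hs <- truth$hotspots
  ing <- vapply(seq_len(nrow(hs)), function(i)
    any(g$chrom == hs$chrom[i] & g$start + 1200 <= hs$mid[i] &
          g$end - 1200 >= hs$mid[i]), TRUE)
  expect_gt(sum(ing), 5)
  anch <- feature_set(truth$genome,
                      data.frame(chrom = hs$chrom[ing], start = hs$mid[ing],
                                 end = hs$mid[ing] + 1))
  ap <- anchor_profile(tracks$H3K56ac, anch, 2000, 80)
  centre <- mean(ap$summary[abs(ap$offset) <= 250])
  ring <- mean(ap$summary[abs(ap$offset) >= 600 & abs(ap$offset) <= 1000])
  expect_equal(centre / ring, cfg$k56_depletion, tolerance = 0.05)
  # RPA double bump peaks within one bin of +/- flank_offset
  ap2 <- anchor_profile(tracks$RPA_ctrl, anch, 2000, 80)
  top <- order(-ap2$summary)[1:2]
  expect_equal(sort(abs(ap2$offset[top])), rep(cfg$flank_offset, 2),
               tolerance = 50 / cfg$flank_offset)
  # random anchors away from hotspots give a flat background profile
  forb <- feature_set(truth$genome, data.frame(
    chrom = hs$chrom, start = pmax(0, hs$mid - 5000),
    end = pmin(chrom_length(truth$genome, hs$chrom), hs$mid + 5000)))
  rnd <- random_sites(truth$genome, 200, seed = 3, forbidden = forb)
  ap3 <- anchor_profile(tracks$RPA_ctrl, rnd, 2000, 80)
  expect_lt(max(ap3$summary) / min(ap3$summary), 1.2)
})

test_that("windows truncated at chromosome ends reduce the per-bin n", {
  gm <- genome_model("chrI", 5000)
  tr <- signal_track(gm, 50, list(chrI = rep(1, 100)))
  anch <- feature_set(gm, data.frame(chrom = "chrI", start = c(500, 2500),
                                     end = c(501, 2501)))
  ap <- anchor_profile(tr, anch, window_bp = 1000, n_bins = 20)
  expect_equal(ap$n[1], 1)         # only the interior anchor covers -1000
  expect_equal(ap$n[20], 2)
})

test_that("random sites are uniform, seeded, and respect forbidden space", {
  gm <- genome_model("chrI", 1e6)
  s1 <- random_sites(gm, 5000, seed = 17)
  s2 <- random_sites(gm, 5000, seed = 17)
  expect_identical(s1$intervals, s2$intervals)
  ks <- suppressWarnings(stats::ks.test(s1$intervals$start / 1e6, "punif"))
  expect_gt(ks$p.value, 0.01)
  forb <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 1e6))
  expect_error(random_sites(gm, 10, seed = 1, forbidden = forb), "allowed")
  half <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 5e5))
  s3 <- random_sites(gm, 1000, seed = 2, forbidden = half)
  expect_true(all(s3$intervals$start >= 5e5))
})

test_that("locus enrichment and fold change follow their ratio definitions", {
  gm <- genome_model("chrI", 5000)
  v <- c(rep(8, 40), rep(2, 60))
  tr <- signal_track(gm, 50, list(chrI = v))
  target <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 2000))
  neg <- feature_set(gm, data.frame(chrom = "chrI", start = 2000, end = 5000))
  le <- locus_enrichment(tr, target, neg)
  expect_equal(le$ratio, 4)
  expect_equal(locus_enrichment(tr, target, target)$ratio, 1)
  zero <- signal_track(gm, 50, list(chrI = rep(0, 100)))
  expect_error(locus_enrichment(zero, target, neg), "negative region")

  mut <- signal_track(gm, 50, list(chrI = v / 2))
  fc <- fold_change_between(tr, mut, target)
  expect_equal(fc$ratio, 2)
  expect_equal(fc$orientation, "ctrl/mut")
  expect_equal(fold_change_between(tr, tr, target)$ratio, 1)
  # scale invariance
  tr3 <- signal_track(gm, 50, list(chrI = v * 7))
  mut3 <- signal_track(gm, 50, list(chrI = v * 7 / 2))
  expect_equal(fold_change_between(tr3, mut3, target)$ratio, 2)
  expect_equal(locus_enrichment(tr3, target, neg)$ratio, 4)
})

test_that("fixture quantifications match the planted construction", {
  sim <- default_fixture(noise = FALSE)
  truth <- sim$truth
  le <- locus_enrichment(sim$tracks$RPA_ctrl, truth$named_loci$BUD23like,
                         truth$named_loci$rDNAlike)
  expect_gt(le$ratio, 20)
  li <- locus_enrichment(sim$tracks$input, truth$named_loci$BUD23like,
                         truth$named_loci$rDNAlike)
  expect_equal(li$ratio, 1, tolerance = 1e-6)
})

test_that("track correlation matches the analytic noise attenuation", {
  expect_equal(track_pearson(toy_track(c(1, 2, 3)), toy_track(c(1, 2, 3))), 1)
  expect_equal(track_pearson(toy_track(c(1, 2, 3)),
                             toy_track(c(-1, -2, -3), units = "linear")), -1)
  expect_error(track_pearson(toy_track(c(1, 1, 1)), toy_track(c(1, 2, 3))),
               "variance")
  # two independent-noise replicates of one landscape
  cfg <- small_config(seed = 6)
  truth <- build_genome(cfg)
  a <- simulate_tracks(truth, noise_seed = 100)
  b <- simulate_tracks(truth, noise_seed = 200)
  lam <- unlist(track_lambdas(truth)$RPA_ctrl, use.names = FALSE)
  s2 <- cfg$noise_sigma^2
  m <- exp(s2 / 2)
  r_analytic <- (stats::var(lam) * m^2) /
    (mean(lam^2) * exp(2 * s2) - (mean(lam) * m)^2)
  expect_equal(track_pearson(a$RPA_ctrl, b$RPA_ctrl), r_analytic,
               tolerance = 0.03 / r_analytic)
})

test_that("expression association contrasts peak genes against a random sample", {
  sim <- default_fixture()
  truth <- sim$truth
  k56 <- double_ratio(sim$tracks$H3K56ac, sim$tracks$input, sim$tracks$H3, 1)
  kp <- call_peaks(k56, 1.2, 3, 2)
  ea <- expression_association(sim$expression, truth$genes, kp, seed = 1)
  expect_lt(ea$test_greater$p, 1e-4)
  expect_gt(ea$median_group1, ea$median_random)
  expect_error(expression_association(sim$expression, truth$genes, kp,
                                      n_random = 1e6), "exceeds")
  empty <- peak_set(truth$genome, data.frame())
  expect_error(expression_association(sim$expression, truth$genes, empty),
               "no genes overlap")
})
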