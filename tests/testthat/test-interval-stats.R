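test_that("relative distance follows the flanking-midpoint formula", {
  gm <- toy_genome(c(chrI = 1000))
  ref <- feature_set(gm, data.frame(chrom = "chrI", start = c(100, 200),
                                    end = c(101, 201)))
  q <- feature_set(gm, data.frame(chrom = "chrI", start = 120, end = 121))
  rd <- relative_distance(q, ref)
  expect_equal(rd$d, 0.2)
  # self-comparison: identically zero
  rd0 <- relative_distance(ref, ref)
  expect_true(all(rd0$d == 0))
  # query outside the reference span is skipped, not clamped
  qout <- feature_set(gm, data.frame(chrom = "chrI", start = c(10, 150),
                                     end = c(11, 151)))
  rdo <- relative_distance(qout, ref)
  expect_equal(rdo$n_used, 1)
  expect_equal(rdo$n_skipped, 1)
  expect_equal(rdo$d, 0.5)
  expect_error(relative_distance(q, feature_set(gm, data.frame())), "empty")
  one <- feature_set(gm, data.frame(chrom = "chrI", start = 5, end = 6))
  expect_error(relative_distance(q, one), "< 2 points")
})

test_that("relative distance of an independent query is uniform on [0, 0.5]", {
  gm <- genome_model("chrI", 1e6)
  ref <- random_sites(gm, 500, seed = 21)
  q <- random_sites(gm, 1e4, seed = 22)
  rd <- relative_distance(q, ref)
  expect_true(all(rd$d >= 0 & rd$d <= 0.5))
  expect_equal(sum(rd$hist), rd$n_used)
  expect_equal(rd$mean, 0.25, tolerance = 0.005 / 0.25)
  gof <- stats::chisq.test(rd$hist, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("shuffling preserves counts and length multisets and avoids forbidden space", {
  gm <- toy_genome(c(chrI = 5e4, chrII = 3e4))
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    start <- sample(0:25000, n)
    fs <- feature_set(gm, data.frame(chrom = sample(c("chrI", "chrII"), n, TRUE),
                                     start = start,
                                     end = start + sample(100:800, n, TRUE)))
    forb <- feature_set(gm, data.frame(chrom = "chrI", start = 30000, end = 40000))
    sh <- shuffle_intervals(fs, seed = rep, forbidden = forb)
    expect_equal(n_features(sh), n)
    for (ch in c("chrI", "chrII")) {
      a <- fs$intervals[fs$intervals$chrom == ch, ]
      b <- sh$intervals[sh$intervals$chrom == ch, ]
      expect_equal(sort(b$end - b$start), sort(a$end - a$start))
      if (nrow(b) > 1)
        expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
    bad <- sh$intervals$chrom == "chrI" &
      sh$intervals$end > 30000 & sh$intervals$start < 40000
    expect_false(any(bad))
  }
  fs1 <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 1000))
  expect_equal(shuffle_intervals(fs1, seed = 4)$intervals,
               shuffle_intervals(fs1, seed = 4)$intervals)
  # insufficient space errors out
  big <- feature_set(gm, data.frame(chrom = "chrII", start = 0, end = 29000))
  forb2 <- feature_set(gm, data.frame(chrom = "chrII", start = 10000, end = 25000))
  expect_error(shuffle_intervals(big, seed = 1, forbidden = forb2),
               "insufficient placeable space")
})

test_that("a single shuffled interval lands uniformly on the chromosome", {
  gm <- genome_model("chrI", 1e6)
  fs <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 1000))
  starts <- vapply(1:4000, function(i)
    shuffle_intervals(fs, seed = 10000 + i)$intervals$start, 1)
  ks <- suppressWarnings(stats::ks.test(starts / 999000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical null p-values behave at the extremes and validate input", {
  gm <- genome_model("chrI", 1e5)
  ref <- feature_set(gm, data.frame(chrom = "chrI",
                                    start = seq(0, 9e4, 1e4), end = seq(0, 9e4, 1e4) + 1))
  en <- empirical_null(ref, ref, "mean_reldist", n_perm = 19, seed = 5)
  expect_equal(en$observed, 0)
  expect_equal(en$p_left, 1 / 20)
  expect_error(empirical_null(ref, ref, "mean_reldist", n_perm = 0), "n_perm")
})

test_that("rank-sum exact path equals the full-enumeration oracle on tie-free grids", {
  # worked case: complete separation of 3 vs 3
  rs <- ranksum_test(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 1 / 20)
  expect_equal(rs$method, "exact")
  # every assignment of the values 1..N into groups, N up to 10
  for (N in c(4, 6, 8, 10)) {
    for (n1 in c(2, N %/% 2)) {
      sets <- utils::combn(N, n1)
      for (k in seq_len(ncol(sets))) {
        x <- sets[, k]; y <- setdiff(1:N, x)
        for (alt in c("two_sided", "greater", "less")) {
          expect_equal(ranksum_test(x, y, alt)$p, enum_ranksum_p(x, y, alt),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("rank-sum exact p agrees with stats::wilcox.test", {
  set.seed(31)
  for (rep in 1:20) {
    x <- sample(1:50, sample(2:6, 1))
    y <- sample(setdiff(1:50, x), sample(2:6, 1))
    for (alt in c("two_sided", "greater", "less")) {
      walt <- sub("two_sided", "two.sided", alt)
      expect_equal(ranksum_test(x, y, alt)$p,
                   stats::wilcox.test(x, y, alternative = walt, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("tied and large samples use the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(1, 2, 2, 3)
  rs <- ranksum_test(x, y)
  expect_equal(rs$p, 1)
  expect_equal(rs$method, "normal")
  # large-n normal path against a Monte-Carlo permutation estimate
  set.seed(32)
  x <- round(stats::rnorm(30, 0.3), 1)
  y <- round(stats::rnorm(35), 1)
  rs <- ranksum_test(x, y, "greater")
  r <- rank(c(x, y)); n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  perm <- vapply(1:1e5, function(i) sum(sample(r, n1)), 1)
  p_perm <- mean(perm >= obs)
  expect_lt(abs(rs$p - p_perm), 0.005)
  expect_error(ranksum_test(numeric(0), 1), "empty")
})

test_that("site signal averages unmasked bins in the midpoint flank", {
  tr <- toy_track(c(1, 2, 3, 4, 5, 6))
  gm <- tr$genome
  sites <- feature_set(gm, data.frame(chrom = "chrI", start = 100, end = 101))
  # flank 0: the single containing bin
  expect_equal(as.numeric(site_signal(tr, sites, 0)), 3)
  # flank 100: bins overlapping [0, 200) -> 1..4
  expect_equal(as.numeric(site_signal(tr, sites, 100)), mean(1:4))
  cons <- toy_track(rep(7, 6))
  expect_equal(as.numeric(site_signal(cons, sites, 100)), 7)
  # fully masked site is dropped and counted
  v <- c(NA, NA, NA, 4, 5, 6)
  trm <- toy_track(v)
  s2 <- feature_set(gm, data.frame(chrom = "chrI", start = c(50, 250),
                                   end = c(51, 251)))
  out <- site_signal(trm, s2, 0)
  expect_equal(length(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("overlap classification partitions control peaks and finds planted losses", {
  gm <- genome_model("chrI", 1e5)
  mk_peaks <- function(starts) {
    peak_set(gm, data.frame(chrom = "chrI", start = starts, end = starts + 500,
                            summit = starts + 250, mean_signal = 1,
                            name = sprintf("p%02d", seq_along(starts))))
  }
  starts <- seq(0, 9e4, 1e4)
  ctrl <- mk_peaks(starts)
  v <- rep(1, 2000)
  for (s in starts) v[(s / 50 + 1):(s / 50 + 10)] <- 10
  ctrl_tr <- signal_track(gm, 50, list(chrI = v))
  # zero out 4 planted peaks in the mutant
  vm <- v
  for (s in starts[c(2, 4, 6, 8)]) vm[(s / 50 + 1):(s / 50 + 10)] <- 1
  mut_tr <- signal_track(gm, 50, list(chrI = vm))
  mut <- mk_peaks(starts[-c(2, 4, 6, 8)])
  cl <- overlap_classify(ctrl, mut, ctrl_tr, mut_tr, fc_up = 1.5, flank_bp = 250)
  expect_equal(unname(cl$counts[["eliminated"]]), 4)
  expect_equal(cl$total - unname(cl$counts[["eliminated"]]), 6)
  expect_equal(sum(cl$counts), cl$total)
  # identical inputs: everything unaffected
  cl0 <- overlap_classify(ctrl, ctrl, ctrl_tr, ctrl_tr)
  expect_equal(unname(cl0$counts[["unaffected"]]), 10)
  expect_equal(unname(cl0$counts[["eliminated"]]), 0)
  expect_equal(unname(cl0$counts[["increased"]]), 0)
  expect_true(all(abs(cl0$table$fold_change - 1) < 1e-12))
})

test_that("jaccard index matches hand-computed overlaps", {
  gm <- genome_model("chrI", 1000)
  a <- feature_set(gm, data.frame(chrom = "chrI", start = 0, end = 100))
  b <- feature_set(gm, data.frame(chrom = "chrI", start = 50, end = 150))
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, a), 1)
  d <- feature_set(gm, data.frame(chrom = "chrI", start = 500, end = 600))
  expect_equal(jaccard_index(a, d), 0)
  e <- feature_set(gm, data.frame())
  expect_error(jaccard_index(e, e), "empty")
})
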