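test_that("the six-record toy leaves one survivor with unit tallies", {
  m <- filter_toy_matrix()
  out <- filter_variants(m, filter_profile())
  expect_equal(length(out$pos), 1)
  expect_equal(out$pos, 600L)
  expect_equal(filter_tally(out),
               c(qual = 1L, depth = 1L, maf = 1L, missing = 1L, hard = 1L))
})

test_that("exclusive depth bounds keep DP 2..14 and drop 1 and 15", {
  m <- depth_boundary_matrix()
  prof <- filter_profile(dp_bounds_override = c(1, 15))
  out <- filter_variants(m, prof)
  expect_equal(out$pos, c(200L, 300L))     # min DP 2 and 14 survive
  expect_equal(unname(filter_tally(out)["depth"]), 2L)
})

test_that("INFO hard filters remove failing records and pass NA metrics", {
  m <- filter_toy_matrix()
  m$info$SOR[6] <- 3.5
  out <- filter_variants(m, filter_profile())
  expect_equal(length(out$pos), 0)
  expect_equal(unname(filter_tally(out)["hard"]), 2L)
  ## a record with no computable metric passes the hard filters
  m2 <- filter_toy_matrix()
  m2$info[6, ] <- NA_real_
  expect_equal(filter_variants(m2, filter_profile())$pos, 600L)
  ## empty input is an empty result, not a failure
  empty <- filter_variants(codes_matrix(list(c(0, 1, 2))),
                           filter_profile(maf_min = 0.9))
  expect_equal(length(empty$pos), 0)
  expect_equal(length(filter_variants(empty, filter_profile())$pos), 0)
})

test_that("pairwise r2 matches hand values and honors the distance cap", {
  m <- codes_matrix(list(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2),
                         c(0, 0, 1, 1, 0, 1)), pos = c(1000, 2000, 350000))
  pairs <- pairwise_r2(m, maf_min = 0, max_dist_bp = 300000)
  ## identical vectors -> r2 = 1; both pairs beyond 300 kbp are never formed
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$r2[pairs$pos_a == 1000 & pairs$pos_b == 2000], 1)
  expect_false(any(pairs$distance > 300000))
  m2 <- codes_matrix(list(c(0, 0, 2, 2), c(0, 2, 0, 2)),
                     pos = c(100, 200))
  expect_equal(pairwise_r2(m2, maf_min = 0)$r2, 0)
})

test_that("monomorphic sites and pairs with too few shared calls are skipped", {
  m <- codes_matrix(list(c(1, 1, 1, 1), c(0, 1, 2, 0), c(0, 2, 1, 0)),
                    pos = c(100, 200, 300))
  pairs <- pairwise_r2(m, maf_min = 0)
  expect_false(100 %in% c(pairs$pos_a, pairs$pos_b))
  m$geno[2, 1:2] <- NA
  pairs2 <- pairwise_r2(m, maf_min = 0)
  expect_equal(nrow(pairs2), 0)
  expect_equal(attr(pairs2, "skipped_pairs"), 1L)
})

test_that("Hill-Weir fitting recovers rho from noiseless curve points", {
  d <- rep(seq(10, 50000, length.out = 200), 5)
  r2 <- hill_weir_expectation(d, 1e-4, 20)
  r2 <- r2 + rep(c(-1e-9, 1e-9), length.out = length(r2))  # break exact ties
  fit <- fit_ld_decay(data.frame(distance = d, r2 = r2), 20)
  expect_lt(abs(fit$rho - 1e-4) / 1e-4, 1e-6)
  expect_false(fit$no_decay)
  ## half-decay solves E[r2](d) = E[r2](0)/2
  expect_equal(hill_weir_expectation(fit$half_decay_bp, fit$rho, 20),
               hill_weir_expectation(0, fit$rho, 20) / 2, tolerance = 1e-6)
})

test_that("degenerate and no-decay inputs are flagged", {
  flat <- data.frame(distance = 1:100, r2 = 0.4)
  expect_error(fit_ld_decay(flat, 20), "degenerate")
  d <- seq(10, 2000, length.out = 300)
  r2 <- hill_weir_expectation(d, 1e-9, 20) + rnorm(300, 0, 1e-6)
  expect_warning(fit <- fit_ld_decay(data.frame(distance = d, r2 = r2), 20),
                 "no decay")
  expect_true(fit$no_decay)
  expect_gt(fit$half_decay_bp, max(d))
})

test_that("landscape bins average endpoint r2 and mask sparse bins", {
  pairs <- data.frame(pos_a = c(100, 200, 300), pos_b = c(5100, 5200, 5300),
                      distance = 5000, r2 = c(0.2, 0.4, 0.6))
  land <- aggregate_ld_bins(pairs, region = c(1, 6000), bin_bp = 1000,
                            min_snps = 0)
  expect_equal(land$mean_r2[land$bin_start == 0], 0.4)
  expect_equal(land$mean_r2[land$bin_start == 5000], 0.4)
  expect_equal(land$snp_count[land$bin_start == 0], 3)
  ## empty bin: no SNPs, masked once a threshold applies, mean undefined
  land5 <- aggregate_ld_bins(pairs, c(1, 6000), 1000, min_snps = 5)
  expect_true(land5$masked[land5$bin_start == 0])       # 3 < 5 SNPs
  empty <- land5[land5$bin_start == 2000, ]
  expect_equal(empty$snp_count, 0)
  expect_true(empty$masked)
  expect_true(is.na(empty$mean_r2))
  ## bins tile the region without overlap
  expect_equal(diff(land$bin_start), rep(1000, nrow(land) - 1))
})

test_that("hom/het ratios divide hom-alt by het calls and flag infinities", {
  rows <- c(rep(list(c(2, 1, 0)), 6), rep(list(c(1, 1, 0)), 3))
  m <- codes_matrix(rows)          # S1: 6 hom-alt + 3 het; S2: 9 het; S3: none
  hh <- hom_het_ratio(m, region = c(1000, 9000))
  expect_equal(hh$per_sample$ratio[1], 2)
  expect_equal(hh$per_sample$ratio[2], 0)
  expect_equal(hh$per_sample$ratio[hh$per_sample$sample == "S3"], Inf)
  expect_true(hh$per_sample$infinite[3])
})

test_that("r2 decays with distance under uniform recombination", {
  samples <- data.frame(sample_id = sprintf("S%02d", 1:15),
                        sex_type = "homogametic")
  sim <- simulate_population(pop_sim_config(
    samples = samples, chrom_length_bp = 5e5, sdr_interval = NULL,
    recomb_rate = 4e-4, seed = 31))
  pairs <- pairwise_r2(sim$matrix, max_dist_bp = 50000)
  dec <- cut(pairs$distance, quantile(pairs$distance, 0:10 / 10),
             include.lowest = TRUE)
  means <- tapply(pairs$r2, dec, mean)
  expect_lte(cor(seq_along(means), as.numeric(means), method = "spearman"), 0)
  ## and the fitted curve is monotone non-increasing
  fit <- fit_ld_decay(pairs, 30)
  grid <- hill_weir_expectation(seq(0, 5e4, length.out = 50), fit$rho, 30)
  expect_true(all(diff(grid) <= 0))
})

test_that("high-LD segment recovery returns the dominant elevated run", {
  land <- data.frame(bin_start = seq(0, 9000, by = 1000),
                     mean_r2 = c(0.1, 0.1, 0.8, 0.9, 0.2, 0.85, 0.8, 0.1,
                                 0.1, 0.6),
                     snp_count = 10, masked = FALSE)
  seg <- detect_high_ld_segment(land, 0.5, max_bridge = 1)
  ## the one-bin dip is bridged; the two-bin gap to the trailing bin is not
  expect_equal(seg, c(2001, 7000))
  expect_null(detect_high_ld_segment(land, 0.95))
})
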