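test_that("probe map honors hotspot count, spacing contract and determinism", {
  cfg <- test_config(seed = 3)
  ps <- generate_probe_map(cfg)
  expect_equal(nrow(ps$hotspots), cfg$n_hotspots)
  expect_identical(ps, generate_probe_map(test_config(seed = 3)))

  p <- ps$probes
  # strictly increasing within chromosome
  for (ch in unique(p$chrom))
    expect_true(all(diff(p$pos[p$chrom == ch]) > 0))
  # density contract: median gap inside hotspots vs backbone
  for (i in seq_len(nrow(ps$hotspots))) {
    h <- ps$hotspots[i, ]
    inside <- p$pos[p$chrom == h$chrom & p$pos >= h$start & p$pos < h$end]
    expect_lte(median(diff(inside)), cfg$hotspot_spacing * 1.5)
    # one hotspot of 251,000 bp at 2,600 bp spacing -> 96-97 probes
    expect_true(length(inside) %in% 96:97)
  }
  backbone <- p[p$chrom == "1", ]
  h1 <- ps$hotspots[ps$hotspots$chrom == "1", ]
  in_hs <- vapply(backbone$pos, function(x)
    any(x >= h1$start & x < h1$end), logical(1))
  gaps <- diff(backbone$pos[!in_hs])
  # gaps straddling a hotspot are larger; all backbone gaps clear the floor
  expect_true(all(gaps >= cfg$backbone_spacing * 0.5))
  expect_error(sim_config(hotspot_length = 1000, hotspot_spacing = 2600),
               "hotspot_length")
})

test_that("intensity simulation is exact when noiseless and unbiased with noise", {
  cfg0 <- test_config(noise_sd = 0)
  ps <- generate_probe_map(cfg0)
  flat <- simulate_sample(ps, NULL, cfg0)
  expect_true(all(flat$log2 == 0))

  h <- ps$hotspots[3, ]
  truth <- gi(h$chrom, h$start, h$end)
  truth$state <- "gain"
  tr0 <- simulate_sample(ps, truth, cfg0)
  member <- ps$probes$chrom == h$chrom & ps$probes$pos >= h$start &
    ps$probes$pos < h$end
  expect_true(all(tr0$log2[member] == cfg0$dup_effect))
  expect_true(all(tr0$log2[!member] == 0))

  # with noise, the member mean sits within 3 standard errors of the effect
  cfg <- test_config(noise_sd = 0.15)
  tr <- simulate_sample(ps, truth, cfg, seed = 99)
  se <- cfg$noise_sd / sqrt(sum(member))
  expect_lt(abs(mean(tr$log2[member]) - cfg$dup_effect), 3 * se)
  # determinism
  tr2 <- simulate_sample(ps, truth, cfg, seed = 99)
  expect_identical(tr$log2, tr2$log2)

  # overlapping truth intervals are rejected
  t2 <- rbind(truth, truth)
  expect_error(simulate_sample(ps, t2, cfg), "overlapping truth")
})

test_that("control database: binomial carrier counts, determinism, degenerate freqs", {
  cfg <- test_config(seed = 5)
  ps <- generate_probe_map(cfg)
  hs <- ps$hotspots
  loci <- data.frame(chrom = hs$chrom[1:3], start = hs$start[1:3],
                     end = hs$start[1:3] + 100000,
                     state = c("loss", "gain", "loss"),
                     freq = c(0, 0.05, 1))
  cfg <- test_config(seed = 5, polymorphic_loci = loci, background_rate = 0)
  db <- generate_control_db(cfg, ps)
  expect_identical(db, generate_control_db(cfg, ps))
  expect_equal(db$n_controls, 8328L)
  # freq 0 -> no carriers (row dropped); freq 1 -> every control
  key <- paste(db$events$chrom, db$events$start)
  expect_false(paste(loci$chrom[1], loci$start[1]) %in% key)
  expect_equal(db$events$count[key == paste(loci$chrom[3], loci$start[3])],
               8328L)
  # freq 0.05 within the central 99.9% binomial interval
  c2 <- db$events$count[key == paste(loci$chrom[2], loci$start[2])]
  expect_gte(c2, qbinom(5e-4, 8328, 0.05))
  expect_lte(c2, qbinom(1 - 5e-4, 8328, 0.05))
  expect_error(
    generate_control_db(test_config(polymorphic_loci = transform(loci, freq = 2)),
                        ps),
    "frequencies")
})

test_that("carrier frequencies converge to configured frequencies (LLN)", {
  cfg <- test_config(seed = 8, n_controls = 1e5, background_rate = 0)
  ps <- generate_probe_map(cfg)
  db <- generate_control_db(cfg, ps)
  loci <- hotspotCNV:::default_polymorphic_loci(ps)
  for (i in seq_len(nrow(loci))) {
    cnt <- db$events$count[db$events$start == loci$start[i] &
                             db$events$chrom == loci$chrom[i]]
    expect_lt(abs(cnt / 1e5 - loci$freq[i]), 0.005)
  }
})

test_that("cohort generation: group sizes, CGG range, injection probabilities", {
  cfg <- test_config(seed = 2)
  ps <- generate_probe_map(cfg)
  coh <- generate_cohort(cfg, ps)
  expect_equal(nrow(coh$participants), 56L)
  expect_equal(as.vector(table(coh$participants$group)), c(19L, 20L, 9L, 8L))
  expect_true(all(coh$participants$cgg1 >= 55 & coh$participants$cgg1 <= 200))
  expect_identical(coh, generate_cohort(cfg, ps))

  # degenerate injection: every group-4 participant carries a truth event
  cfg4 <- test_config(seed = 2, injection_prob = c(0, 0, 0, 1))
  coh4 <- generate_cohort(cfg4, ps)
  g4 <- coh4$participants$id[coh4$participants$group == 4]
  expect_true(all(vapply(coh4$truth[g4], nrow, integer(1)) >= 1L))
  others <- coh4$participants$id[coh4$participants$group != 4]
  expect_true(all(vapply(coh4$truth[others], nrow, integer(1)) == 0L))
})

test_that("burden size generator respects the mixture and threshold", {
  sz <- generate_burden_sizes(5000, prob_large = 0.2, threshold = 325000,
                              seed = 4)
  expect_equal(length(sz), 5000L)
  expect_true(all(sz >= 50000 & sz <= 2e6))
  frac <- mean(sz > 325000)
  expect_lt(abs(frac - 0.2), 0.02)
  expect_identical(sz, generate_burden_sizes(5000, 0.2, seed = 4))
})
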