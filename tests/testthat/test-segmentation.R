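# Brute-force Viterbi oracle: enumerate all 3^n state paths and return the
# highest-probability one. Independent of the dynamic-programming decoder.
enumerate_best_path <- function(z, params) {
  n <- length(z)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  logp <- apply(grid, 1, function(path) {
    lp <- params$log_init[path[1]] +
      dnorm(z[1], params$means[path[1]], params$emission_sd, log = TRUE)
    if (n > 1) for (t in 2:n)
      lp <- lp + params$log_trans[path[t - 1], path[t]] +
        dnorm(z[t], params$means[path[t]], params$emission_sd, log = TRUE)
    lp
  })
  list(path = params$states[grid[which.max(logp), ]], logp = max(logp))
}

path_logp <- function(states, z, params) {
  path <- match(states, params$states)
  lp <- params$log_init[path[1]] +
    dnorm(z[1], params$means[path[1]], params$emission_sd, log = TRUE)
  if (length(z) > 1) for (t in 2:length(z))
    lp <- lp + params$log_trans[path[t - 1], path[t]] +
      dnorm(z[t], params$means[path[t]], params$emission_sd, log = TRUE)
  unname(lp)
}

make_probeset <- function(pos, chrom = "1") {
  structure(list(
    probes = data.frame(probe = sprintf("P%03d", seq_along(pos)),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    hotspots = gi(chrom, min(pos), max(pos) + 1),
    segdups = gi("1", 0, 1)[0, ]), class = "probe_set")
}

test_that("z-scores have exact zero mean and unit SD per chromosome", {
  ps <- make_probeset(seq(1000, 50000, by = 1000))
  x <- rnorm(50, sd = 0.2)
  zt <- zscore_normalize(x, ps)
  expect_lt(abs(mean(zt$z)), 1e-9)
  expect_lt(abs(sqrt(mean(zt$z^2)) - 1), 1e-9)

  # constant track degenerates to all-zero z
  expect_true(all(zscore_normalize(rep(0.3, 50), ps)$z == 0))

  # two-point symmetry under the population-SD convention
  ps2 <- make_probeset(c(100, 200))
  expect_equal(zscore_normalize(c(-1, 1), ps2)$z, c(-1, 1))

  ps1 <- make_probeset(100)
  expect_error(zscore_normalize(0.5, ps1), "fewer than 2 probes")
})

test_that("Viterbi matches exhaustive path enumeration on short chromosomes", {
  params <- hmm_params()
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    z <- rnorm(n, sd = 2)
    oracle <- enumerate_best_path(z, params)
    got <- decode_states(z, params)
    expect_identical(got, oracle$path)
    expect_equal(path_logp(got, z, params), oracle$logp)
  }
})

test_that("Viterbi calls: neutral track is silent, a clear block is one call", {
  params <- hmm_params()
  pos <- seq(2600, by = 2600, length.out = 60)
  ps <- make_probeset(pos)
  zt <- structure(list(z = rep(0, 60), sample = "s"), class = "zscore_track")
  expect_equal(nrow(viterbi_segment(zt, ps, params)), 0L)

  z <- rep(0, 60); z[10:29] <- 3.0
  zt$z <- z
  calls <- viterbi_segment(zt, ps, params, sample_id = "s")
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$state, "gain")
  expect_equal(calls$n_probes, 20L)
  expect_equal(calls$mean_z, 3.0)
  # boundaries: midpoints to the neighbouring probes
  expect_equal(calls$start, floor((pos[9] + pos[10]) / 2))
  expect_equal(calls$end, floor((pos[29] + pos[30]) / 2))
})

test_that("negating every z swaps loss and gain calls exactly", {
  params <- hmm_params()
  ps <- make_probeset(seq(2600, by = 2600, length.out = 80))
  set.seed(31)
  z <- rnorm(80); z[5:20] <- z[5:20] + 3; z[50:70] <- z[50:70] - 3
  zt <- structure(list(z = z, sample = "s"), class = "zscore_track")
  a <- viterbi_segment(zt, ps, params)
  zt$z <- -z
  b <- viterbi_segment(zt, ps, params)
  swap <- c(loss = "gain", gain = "loss")
  expect_identical(b$state, unname(swap[a$state]))
  expect_equal(b[, c("start", "end", "n_probes")],
               a[, c("start", "end", "n_probes")])
  expect_equal(b$mean_z, -a$mean_z)
})

test_that("raising |z| inside a called region never removes the call", {
  params <- hmm_params()
  ps <- make_probeset(seq(2600, by = 2600, length.out = 60))
  set.seed(41)
  for (rep in 1:20) {
    z <- rnorm(60, sd = 0.5)
    region <- 20:35
    z[region] <- z[region] + runif(1, 2, 3)
    before <- decode_states(z, params)
    z2 <- z
    z2[region] <- z2[region] + 1 # uniformly higher |z| in the region
    after <- decode_states(z2, params)
    # every probe called gain inside the region stays a gain call
    was_gain <- intersect(region, which(before == "gain"))
    expect_true(all(after[was_gain] == "gain"))
  }
})

test_that("log-space decoding survives 1e5 probes without underflow", {
  params <- hmm_params()
  set.seed(53)
  z <- rnorm(1e5); z[5000:5200] <- z[5000:5200] + 4
  states <- decode_states(z, params)
  expect_equal(length(states), 1e5L)
  expect_true(all(states[5010:5190] == "gain"))
  expect_true(is.finite(path_logp(states, z, params)))
})

test_that("call boundaries use midpoints inside and probe positions at edges", {
  expect_equal(call_boundaries(2, 2, c(0, 1000, 2000)), c(500, 1500))
  pos <- c(50, seq(100, 2000, by = 100), 2100)
  expect_equal(call_boundaries(2, length(pos) - 1L, pos), c(75, 2050))
  # chromosome-edge runs
  expect_equal(call_boundaries(1, 1, c(1000, 2000)), c(1000, 1500))
  expect_equal(call_boundaries(2, 2, c(0, 1000)), c(500, 1001))

  # noiseless simulated event lands within one inter-probe gap of truth
  cfg <- test_config(noise_sd = 0)
  ps <- generate_probe_map(cfg)
  h <- ps$hotspots[4, ]
  truth <- gi(h$chrom, h$start + 26000, h$start + 26000 + 52000)
  truth$state <- "loss"
  tr <- simulate_sample(ps, truth, cfg)
  calls <- viterbi_segment(zscore_normalize(tr, ps), ps, hmm_params(),
                           sample_id = "s")
  calls <- calls[calls$state == "loss", ]
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$start - truth$start), cfg$hotspot_spacing)
  expect_lte(abs(calls$end - truth$end), cfg$hotspot_spacing)
})
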