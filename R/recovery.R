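# Seeded end-to-end recovery experiment: inject one known CNV per replicate,
# run the full calling pipeline, and score recovery against the truth
# interval by reciprocal overlap.

#' End-to-end recovery experiment on simulated samples
#'
#' Each replicate injects a single truth CNV (random state, spanning a
#' configurable number of hotspot probes) into one simulated sample, runs
#' z-score normalization, HMM segmentation, the filter cascade and rarity
#' classification, and scores the replicate as recovered when some retained
#' rare call has at least `min_ro` reciprocal overlap with the truth
#' interval. Truth events are placed in hotspots free of polymorphic control
#' loci, so they are rare by construction — the experiment measures the
#' pipeline's sensitivity to rare events under the configured noise.
#'
#' @param n_replicates Number of seeded replicates.
#' @param config A [sim_config()]; `truth_probes` bounds the injected event's
#'   probe span.
#' @param params,thresholds,rarity Stage parameters (defaults).
#' @param min_ro Reciprocal overlap required to count a recovery.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return A list: `recovered` (logical per replicate), `rate` (fraction),
#'   `detail` (data.frame with truth span and best reciprocal overlap).
#' @export
recovery_experiment <- function(n_replicates = 200L, config = sim_config(),
                                params = hmm_params(),
                                thresholds = filter_thresholds(),
                                rarity = rarity_config(),
                                min_ro = 0.5, seed = 1L) {
  probeset <- generate_probe_map(config)
  db <- generate_control_db(config, probeset, seed = config$seed)
  loci <- config$polymorphic_loci
  if (is.null(loci)) loci <- default_polymorphic_loci(probeset)
  hs <- probeset$hotspots
  poly_hit <- vapply(seq_len(nrow(hs)), function(i)
    any(loci$chrom == hs$chrom[i] &
          pmin(loci$end, hs$end[i]) > pmax(loci$start, hs$start[i])),
    logical(1))
  free_hs <- hs[!poly_hit, , drop = FALSE]
  stopifnot(nrow(free_hs) > 0)

  detail <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    h <- free_hs[sample.int(nrow(free_hs), 1L), , drop = FALSE]
    np <- sample(seq(config$truth_probes[1], config$truth_probes[2]), 1L)
    span <- min(np * config$hotspot_spacing, config$hotspot_length)
    s <- h$start + floor(stats::runif(1) * (config$hotspot_length - span))
    truth <- gi(h$chrom, s, s + span)
    truth$state <- sample(c("loss", "gain"), 1L)

    track <- simulate_sample(probeset, truth, config,
                             sample_id = sprintf("rep%03d", r),
                             seed = seed + 10000L + r)
    zt <- zscore_normalize(track, probeset)
    raw <- viterbi_segment(zt, probeset, params, sample_id = track$sample)
    ref <- apply_filters(raw, probeset$segdups, thresholds)
    kept <- ref[ref$retained, , drop = FALSE]
    best <- 0
    if (nrow(kept)) {
      names(kept)[names(kept) == "sample"] <- "id"
      verd <- control_frequency(kept, db, rarity)
      rare <- verd[verd$rare, , drop = FALSE]
      if (nrow(rare))
        best <- max(reciprocal_overlap(truth[, c("chrom", "start", "end")],
                                       rare[, c("chrom", "start", "end")]))
    }
    detail[[r]] <- data.frame(replicate = r, chrom = truth$chrom,
                              start = truth$start, end = truth$end,
                              state = truth$state, n_probes = np,
                              best_ro = best, stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  recovered <- detail$best_ro >= min_ro
  list(recovered = recovered, rate = mean(recovered), detail = detail)
}
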