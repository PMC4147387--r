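# Synthetic hotspot-array data: probe maps, intensity tracks, control CNV
# databases and a four-group clinical cohort. Everything is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' One object holds every tunable of the synthetic-data generators. The
#' defaults describe the study conditions the pipeline is built for: a
#' hotspot-targeted array (~2.6 Kb probe spacing inside ~251 Kb hotspot
#' regions, ~36 Kb backbone spacing), heterozygous-deletion and single-copy
#' duplication log2 shifts, an 8,328-sample control CNV database, and a
#' 56-participant cohort split 19/20/9/8 across four clinical groups with
#' premutation CGG alleles in 55-200.
#'
#' Two scales are provided. `"desk"` (default) is a 2-chromosome, ~20 Mb,
#' ~2,000-probe genome with 16 hotspots so that full pipeline runs take
#' seconds; `"full"` approximates the 107-hotspot array on a 23-chromosome
#' genome. The statistical structure (spacing, effects, noise) is identical
#' at both scales.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param scale `"desk"` or `"full"`.
#' @param noise_sd Per-probe Gaussian noise SD in log2-ratio units.
#' @param del_effect Mean log2 shift of a heterozygous deletion (1 copy):
#'   `log2(1/2) = -1`.
#' @param dup_effect Mean log2 shift of a single-copy duplication (3 copies):
#'   `log2(3/2) ~ +0.58`.
#' @param n_hotspots Number of hotspot regions (desk 16, full 107).
#' @param hotspot_length Hotspot region length in bp.
#' @param hotspot_spacing Probe spacing inside hotspots, bp.
#' @param backbone_spacing Probe spacing in the genomic backbone, bp.
#' @param segdup_flank Length of the segmental-duplication blocks flanking
#'   each hotspot, bp.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param n_controls Size of the control CNV database.
#' @param polymorphic_loci Data.frame (`chrom`, `start`, `end`, `state`,
#'   `freq`) of common CNV loci segregating in the controls. `NULL` places
#'   the default two loci (one loss, one gain, frequency 0.05) in the first
#'   two hotspots.
#' @param background_rate Expected number of rare background control events
#'   per 1,000 controls.
#' @param group_sizes Cohort group sizes, groups 1-4.
#' @param cgg_range Premutation CGG allele range.
#' @param injection_prob Per-group probability that a participant carries one
#'   injected rare truth CNV.
#' @param truth_probes Range (min, max) of hotspot probes an injected truth
#'   event spans.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       scale = c("desk", "full"),
                       noise_sd = 0.15,
                       del_effect = -1.0,
                       dup_effect = 0.58,
                       n_hotspots = NULL,
                       hotspot_length = 251000,
                       hotspot_spacing = 2600,
                       backbone_spacing = 36000,
                       segdup_flank = 20000,
                       chrom_lengths = NULL,
                       n_controls = 8328L,
                       polymorphic_loci = NULL,
                       background_rate = 10,
                       group_sizes = c(19L, 20L, 9L, 8L),
                       cgg_range = c(55L, 200L),
                       injection_prob = rep(0.2, 4),
                       truth_probes = c(20L, 80L)) {
  scale <- match.arg(scale)
  if (is.null(n_hotspots)) n_hotspots <- if (scale == "desk") 16L else 107L
  if (is.null(chrom_lengths)) {
    chrom_lengths <- if (scale == "desk") {
      c("1" = 10e6, "2" = 10e6)
    } else {
      stats::setNames(rep(130e6, 23), c(as.character(1:22), "X"))
    }
  }
  if (hotspot_length < hotspot_spacing)
    stop("hotspot_length must be >= hotspot_spacing", call. = FALSE)
  if (any(group_sizes <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (!is.null(polymorphic_loci) &&
      (any(polymorphic_loci$freq < 0) || any(polymorphic_loci$freq > 1)))
    stop("polymorphic locus frequencies must be in [0, 1]", call. = FALSE)
  if (length(injection_prob) == 1L) injection_prob <- rep(injection_prob, 4)
  cfg <- list(seed = as.integer(seed), scale = scale, noise_sd = noise_sd,
              del_effect = del_effect, dup_effect = dup_effect,
              n_hotspots = as.integer(n_hotspots),
              hotspot_length = hotspot_length,
              hotspot_spacing = hotspot_spacing,
              backbone_spacing = backbone_spacing,
              segdup_flank = segdup_flank,
              chrom_lengths = chrom_lengths,
              n_controls = as.integer(n_controls),
              polymorphic_loci = polymorphic_loci,
              background_rate = background_rate,
              group_sizes = as.integer(group_sizes),
              cgg_range = as.integer(cgg_range),
              injection_prob = injection_prob,
              truth_probes = as.integer(truth_probes))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the hotspot-array probe map
#'
#' Hotspot regions are placed evenly along each chromosome (round-robin
#' across chromosomes) and flanked by segmental-duplication blocks — the
#' architecture that makes these regions rearrangement hotspots. Probes are
#' laid at `hotspot_spacing` inside hotspots and `backbone_spacing` outside.
#' Deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A list of class `"probe_set"`: `probes` (data.frame `probe`,
#'   `chrom`, `pos`, sorted), `hotspots` (interval data.frame with `label`),
#'   `segdups` (interval data.frame), and the spacing parameters.
#' @export
generate_probe_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- names(config$chrom_lengths)
  n_chrom <- length(chroms)
  hs_chrom <- chroms[((seq_len(config$n_hotspots) - 1L) %% n_chrom) + 1L]
  hotspots <- do.call(rbind, lapply(chroms, function(ch) {
    k <- sum(hs_chrom == ch)
    if (k == 0L) return(NULL)
    len <- config$chrom_lengths[[ch]]
    # even placement, keeping segdup flanks inside the chromosome
    centers <- seq(len / (k + 1), len * k / (k + 1), length.out = k)
    start <- round(centers - config$hotspot_length / 2)
    data.frame(chrom = ch, start = start,
               end = start + config$hotspot_length,
               stringsAsFactors = FALSE)
  }))
  hotspots <- gi_sort(hotspots)
  hotspots$label <- sprintf("hotspot_%02d", seq_len(nrow(hotspots)))
  segdups <- rbind(
    data.frame(chrom = hotspots$chrom,
               start = hotspots$start - config$segdup_flank,
               end = hotspots$start, stringsAsFactors = FALSE),
    data.frame(chrom = hotspots$chrom, start = hotspots$end,
               end = hotspots$end + config$segdup_flank,
               stringsAsFactors = FALSE))
  segdups$start <- pmax(segdups$start, 0)
  segdups <- gi_sort(segdups)

  probes <- do.call(rbind, lapply(chroms, function(ch) {
    len <- config$chrom_lengths[[ch]]
    hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    pos <- seq(config$backbone_spacing / 2, len, by = config$backbone_spacing)
    if (nrow(hs)) {
      in_hs <- unlist(lapply(seq_len(nrow(hs)), function(i)
        seq(hs$start[i], hs$end[i] - 1, by = config$hotspot_spacing)))
      keep <- !vapply(pos, function(p)
        any(p >= hs$start & p < hs$end), logical(1))
      pos <- sort(unique(c(pos[keep], in_hs)))
    }
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  probes <- data.frame(probe = sprintf("P%06d", seq_len(nrow(probes))),
                       probes, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(probes = probes, hotspots = hotspots, segdups = segdups,
                 hotspot_spacing = config$hotspot_spacing,
                 backbone_spacing = config$backbone_spacing,
                 chrom_lengths = config$chrom_lengths),
            class = "probe_set")
}

#' Simulate one sample's intensity track
#'
#' Per-probe log2 ratios are drawn i.i.d. Gaussian around the copy-number
#' effect of the truth state at that probe (0 outside truth events). With
#' `noise_sd = 0` the values equal the state effects exactly.
#'
#' @param probeset A [generate_probe_map()] result.
#' @param truth Interval data.frame with a `state` column (`"loss"`/`"gain"`);
#'   may be empty (`NULL`). Events must not overlap.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier carried into the track.
#' @param seed Seed for this sample's noise (defaults to `config$seed`).
#' @return A list of class `"intensity_track"`: `sample`, `log2` (one value
#'   per probe, in probe order), `truth`.
#' @export
simulate_sample <- function(probeset, truth = NULL, config,
                            sample_id = "S1", seed = config$seed) {
  stopifnot(inherits(probeset, "probe_set"), inherits(config, "sim_config"))
  p <- probeset$probes
  mu <- rep(0, nrow(p))
  if (!is.null(truth) && nrow(truth)) {
    validate_gi(truth)
    stopifnot("state" %in% names(truth),
              all(truth$state %in% c("loss", "gain")))
    for (ch in unique(truth$chrom)) {
      tt <- truth[truth$chrom == ch, , drop = FALSE]
      if (nrow(tt) > 1L) {
        tt <- tt[order(tt$start), , drop = FALSE]
        if (any(tt$start[-1] < tt$end[-nrow(tt)]))
          stop("overlapping truth intervals for sample ", sample_id,
               call. = FALSE)
      }
    }
    for (i in seq_len(nrow(truth))) {
      hit <- p$chrom == truth$chrom[i] &
        p$pos >= truth$start[i] & p$pos < truth$end[i]
      mu[hit] <- if (truth$state[i] == "loss") config$del_effect else config$dup_effect
    }
  }
  set.seed(seed)
  log2r <- mu + if (config$noise_sd > 0) stats::rnorm(nrow(p), 0, config$noise_sd) else 0
  structure(list(sample = sample_id, log2 = log2r,
                 truth = if (is.null(truth)) gi_empty() else truth),
            class = "intensity_track")
}

# Default polymorphic loci: one loss and one gain at the first two hotspots,
# each segregating at 5% in the controls.
default_polymorphic_loci <- function(probeset) {
  hs <- probeset$hotspots
  stopifnot(nrow(hs) >= 2L)
  data.frame(chrom = hs$chrom[1:2],
             start = hs$start[1:2] + 10000,
             end = hs$start[1:2] + 10000 + 150000,
             state = c("loss", "gain"),
             freq = c(0.05, 0.05),
             stringsAsFactors = FALSE)
}

#' Generate the control CNV database
#'
#' Each polymorphic locus contributes `Binomial(n_controls, freq)` carrier
#' events; rare background events (unique intervals drawn uniformly inside
#' random hotspots) are added at `background_rate` per 1,000 controls.
#'
#' @param config A [sim_config()].
#' @param probeset A [generate_probe_map()] result (for locus placement).
#' @param seed Seed (defaults to `config$seed`).
#' @return A list of class `"control_db"`: `events` (data.frame `chrom`,
#'   `start`, `end`, `state`, `count` — carriers per distinct event) and
#'   `n_controls`.
#' @export
generate_control_db <- function(config, probeset, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  loci <- config$polymorphic_loci
  if (is.null(loci)) loci <- default_polymorphic_loci(probeset)
  if (any(loci$freq < 0) || any(loci$freq > 1))
    stop("polymorphic locus frequencies must be in [0, 1]", call. = FALSE)
  set.seed(seed + 1L)
  events <- data.frame(chrom = normalize_chrom(loci$chrom), start = loci$start,
                       end = loci$end, state = loci$state,
                       count = stats::rbinom(nrow(loci), config$n_controls, loci$freq),
                       stringsAsFactors = FALSE)
  n_bg <- stats::rpois(1, config$background_rate * config$n_controls / 1000)
  if (n_bg > 0) {
    hs <- probeset$hotspots
    idx <- sample.int(nrow(hs), n_bg, replace = TRUE)
    len <- round(stats::runif(n_bg, 50000, config$hotspot_length * 0.8))
    start <- hs$start[idx] +
      round(stats::runif(n_bg) * (config$hotspot_length - len))
    events <- rbind(events,
                    data.frame(chrom = hs$chrom[idx], start = start,
                               end = start + len,
                               state = sample(c("loss", "gain"), n_bg, TRUE),
                               count = 1L, stringsAsFactors = FALSE))
  }
  events <- events[events$count > 0, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, n_controls = config$n_controls),
            class = "control_db")
}

#' Generate the four-group cohort with injected truth CNVs
#'
#' Participants are assigned to groups 1-4 at the configured sizes
#' (default 19/20/9/8). Sex follows the study make-up (mostly male with a few
#' female carriers), ages are drawn around a young-clinic profile, and every
#' participant carries a premutation CGG allele uniform in `cgg_range`
#' (females get a second, normal-range allele). Per group, a participant
#' receives one rare truth CNV with probability `injection_prob[group]`; the
#' event spans `truth_probes` hotspot probes and is placed in a hotspot that
#' does not host a polymorphic control locus, so injected events are rare by
#' construction. Synthetic ADOS/FSIQ/SCQ scores and an ADHD flag are attached
#' for exercising the score comparisons.
#'
#' @param config A [sim_config()].
#' @param probeset A [generate_probe_map()] result.
#' @param seed Seed (defaults to `config$seed`).
#' @return A list of class `"cohort"`: `participants` (data.frame) and
#'   `truth` (named list of interval data.frames with `state`, one entry per
#'   participant id).
#' @export
generate_cohort <- function(config, probeset, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(probeset, "probe_set"))
  set.seed(seed + 2L)
  n <- sum(config$group_sizes)
  grp <- rep(1:4, times = config$group_sizes)
  id <- sprintf("S%03d", seq_len(n))
  n_f <- max(1L, round(n * 4 / 56))
  sex <- rep("M", n); sex[sample.int(n, n_f)] <- "F"
  age <- pmax(2, round(stats::rnorm(n, 17.7, 13.2)))
  cgg1 <- sample(seq(config$cgg_range[1], config$cgg_range[2]), n, replace = TRUE)
  cgg2 <- ifelse(sex == "F", sample(20:45, n, replace = TRUE), NA_integer_)
  ados <- pmax(0, round(stats::rnorm(n, 6, 5)))
  fsiq <- pmax(40, round(stats::rnorm(n, 83, 23)))
  scq <- pmax(0, round(stats::rnorm(n, 12, 9)))
  adhd <- stats::runif(n) < 0.5

  loci <- config$polymorphic_loci
  if (is.null(loci)) loci <- default_polymorphic_loci(probeset)
  hs <- probeset$hotspots
  # hotspots free of polymorphic loci: injected events are rare by construction
  poly_hit <- vapply(seq_len(nrow(hs)), function(i) {
    any(loci$chrom == hs$chrom[i] &
          pmin(loci$end, hs$end[i]) > pmax(loci$start, hs$start[i]))
  }, logical(1))
  free_hs <- hs[!poly_hit, , drop = FALSE]
  if (!nrow(free_hs))
    stop("no hotspot free of polymorphic loci to place truth events",
         call. = FALSE)

  truth <- stats::setNames(vector("list", n), id)
  carries <- stats::runif(n) < config$injection_prob[grp]
  for (i in which(carries)) {
    h <- free_hs[sample.int(nrow(free_hs), 1L), , drop = FALSE]
    np <- sample(seq(config$truth_probes[1], config$truth_probes[2]), 1L)
    span <- np * config$hotspot_spacing
    span <- min(span, config$hotspot_length)
    s <- h$start + floor(stats::runif(1) * (config$hotspot_length - span))
    ev <- gi(h$chrom, s, s + span)
    ev$state <- sample(c("loss", "gain"), 1L)
    truth[[i]] <- ev
  }
  for (i in which(!carries)) truth[[i]] <- gi_empty()

  participants <- data.frame(id = id, sex = sex, age = age, group = grp,
                             cgg1 = cgg1, cgg2 = cgg2, ados = ados,
                             fsiq = fsiq, scq = scq, adhd = adhd,
                             stringsAsFactors = FALSE)
  structure(list(participants = participants, truth = truth),
            class = "cohort")
}

#' Simulate event sizes for burden experiments
#'
#' Draws per-event sizes from a two-component mixture: with probability
#' `prob_large` a size above `threshold` (uniform up to `max_large`),
#' otherwise a size between `min_small` and `threshold`. Used to build
#' synthetic case/control arms with a known size-threshold enrichment.
#'
#' @param n Number of events.
#' @param prob_large Probability an event exceeds `threshold`.
#' @param threshold Size threshold in bp (default 325 Kb).
#' @param min_small,max_large Size bounds in bp.
#' @param seed Integer seed.
#' @return Numeric vector of event sizes in bp.
#' @export
generate_burden_sizes <- function(n, prob_large, threshold = 325000,
                                  min_small = 50000, max_large = 2e6,
                                  seed = 1L) {
  set.seed(seed)
  large <- stats::runif(n) < prob_large
  sz <- numeric(n)
  sz[large] <- stats::runif(sum(large), threshold + 1, max_large)
  sz[!large] <- stats::runif(sum(!large), min_small, threshold)
  round(sz)
}
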