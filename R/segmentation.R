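# z-score normalization and 3-state HMM segmentation of probe log2 ratios.

#' HMM parameters for loss/neutral/gain segmentation
#'
#' Three states with Gaussian emissions in z-score units: means
#' `(-mu, 0, +mu)` and shared SD 1. `mu = 2` encodes a 2-SD separation
#' between the neutral and altered copy-number states. Transitions leave the
#' current state with per-probe probability `tau` to each other state; the
#' initial distribution puts `1 - 2 * init_cnv` on neutral.
#'
#' @param mu Emission-mean separation in z units (> 0).
#' @param tau Per-probe switch probability to each other state
#'   (0 < tau < 0.5).
#' @param emission_sd Shared emission SD (z units).
#' @param init_cnv Initial probability of each non-neutral state.
#' @return A list of class `"hmm_params"` with the state set, emission means,
#'   log transition matrix and log initial distribution.
#' @export
hmm_params <- function(mu = 2.0, tau = 1e-4, emission_sd = 1.0,
                       init_cnv = 5e-4) {
  stopifnot(mu > 0, tau > 0, tau < 0.5, emission_sd > 0,
            init_cnv > 0, init_cnv < 0.5)
  states <- c("loss", "neutral", "gain")
  means <- c(loss = -mu, neutral = 0, gain = mu)
  A <- matrix(tau, 3, 3, dimnames = list(states, states))
  diag(A) <- 1 - 2 * tau
  pi0 <- c(loss = init_cnv, neutral = 1 - 2 * init_cnv, gain = init_cnv)
  structure(list(states = states, means = means, emission_sd = emission_sd,
                 mu = mu, tau = tau, log_trans = log(A), log_init = log(pi0)),
            class = "hmm_params")
}

#' Per-chromosome z-score normalization
#'
#' For each chromosome, `z = (x - mean(x)) / sd(x)` with the population
#' (divide-by-n) SD, so mean 0 / SD 1 holds exactly per chromosome. A
#' zero-SD chromosome (constant track) degenerates to all-zero z-scores.
#'
#' @param track An [simulate_sample()] intensity track, or a numeric vector
#'   of log2 ratios in probe order.
#' @param probeset A [generate_probe_map()] result (supplies probe order and
#'   chromosome assignment).
#' @return A list of class `"zscore_track"`: `z` (per-probe z-scores),
#'   `stats` (data.frame `chrom`, `mean`, `sd`, `n`).
#' @export
zscore_normalize <- function(track, probeset) {
  x <- if (inherits(track, "intensity_track")) track$log2 else as.numeric(track)
  p <- probeset$probes
  stopifnot(length(x) == nrow(p))
  z <- numeric(length(x))
  st <- lapply(unique(p$chrom), function(ch) {
    i <- which(p$chrom == ch)
    if (length(i) < 2L)
      stop("chromosome ", ch, " has fewer than 2 probes", call. = FALSE)
    m <- mean(x[i])
    s <- sqrt(mean((x[i] - m)^2)) # population SD
    z[i] <<- if (s == 0) 0 else (x[i] - m) / s
    data.frame(chrom = ch, mean = m, sd = s, n = length(i),
               stringsAsFactors = FALSE)
  })
  structure(list(z = z, stats = do.call(rbind, st),
                 sample = if (inherits(track, "intensity_track")) track$sample else NA_character_),
            class = "zscore_track")
}

#' Viterbi decoding of one chromosome's z-scores
#'
#' Log-space Viterbi over the loss/neutral/gain HMM. Ties in the backtrace
#' resolve toward the neutral state (then loss), making the decoded path
#' deterministic and calling conservative.
#'
#' @param z Numeric vector of z-scores for one chromosome, in probe order.
#' @param params An [hmm_params()].
#' @return Character vector of decoded states, one per probe.
#' @export
decode_states <- function(z, params) {
  stopifnot(inherits(params, "hmm_params"))
  n <- length(z)
  if (n == 0L) return(character(0))
  # state preference for argmax ties: neutral, then loss, then gain
  pref <- c(2L, 1L, 3L)
  emit <- function(t) stats::dnorm(z[t], params$means, params$emission_sd, log = TRUE)
  delta <- params$log_init + emit(1)
  back <- matrix(0L, nrow = 3, ncol = n)
  if (n > 1L) for (t in 2:n) {
    cand <- delta + params$log_trans # cand[i, j] = delta[i] + log A[i -> j]
    best <- pref[max.col(t(cand[pref, , drop = FALSE]), ties.method = "first")]
    back[, t] <- best
    delta <- cand[cbind(best, 1:3)] + emit(t)
  }
  path <- integer(n)
  path[n] <- pref[which.max(delta[pref])]
  if (n > 1L) for (t in n:2) path[t - 1L] <- back[path[t], t]
  params$states[path]
}

#' Convert a state run to genomic boundaries
#'
#' A run of probes `i..j` maps to the interval from the midpoint between
#' probe `i` and its left neighbour to the midpoint between probe `j` and its
#' right neighbour (midpoints floored). A run touching the chromosome edge
#' uses the edge probe's own position (left edge) or position + 1 (right
#' edge, so the half-open interval stays non-empty).
#'
#' @param first,last Indices (into `pos`) of the first and last probes of the
#'   run.
#' @param pos Sorted probe positions of the whole chromosome.
#' @return Numeric `c(start, end)`.
#' @export
call_boundaries <- function(first, last, pos) {
  stopifnot(first >= 1L, last >= first, last <= length(pos))
  start <- if (first > 1L) floor((pos[first - 1L] + pos[first]) / 2) else pos[first]
  end <- if (last < length(pos)) floor((pos[last] + pos[last + 1L]) / 2) else pos[last] + 1
  c(start, end)
}

#' Segment a z-score track into raw CNV calls
#'
#' Runs Viterbi decoding independently per chromosome (no inter-chromosome
#' transitions) and converts each maximal run of non-neutral states into a
#' raw call with genomic boundaries, probe count and mean z.
#'
#' @param ztrack A [zscore_normalize()] result.
#' @param probeset A [generate_probe_map()] result.
#' @param params An [hmm_params()].
#' @param sample_id Sample identifier for the output rows.
#' @return Data.frame of raw calls: `sample`, `chrom`, `start`, `end`,
#'   `state`, `n_probes`, `mean_z` (zero rows when nothing is called).
#' @export
viterbi_segment <- function(ztrack, probeset, params = hmm_params(),
                            sample_id = ztrack$sample) {
  stopifnot(inherits(ztrack, "zscore_track"))
  p <- probeset$probes
  out <- list()
  for (ch in unique(p$chrom)) {
    i <- which(p$chrom == ch)
    zc <- ztrack$z[i]
    states <- decode_states(zc, params)
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != "neutral")
    for (k in keep) {
      b <- call_boundaries(starts[k], ends[k], p$pos[i])
      out[[length(out) + 1L]] <- data.frame(
        sample = sample_id, chrom = ch, start = b[1], end = b[2],
        state = r$values[k], n_probes = r$lengths[k],
        mean_z = mean(zc[starts[k]:ends[k]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      state = character(0), n_probes = integer(0),
                      mean_z = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
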