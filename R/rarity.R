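# Rarity classification against a control CNV database and the
# size-threshold burden test.

#' Rarity configuration
#'
#' A call is matched to a control event when their reciprocal overlap exceeds
#' `reciprocal_threshold` (strictly, per the > 50% criterion) and, when
#' `state_matched`, the copy-number state agrees. A call is rare when its
#' matched-carrier frequency is strictly below `rare_cutoff`. With the
#' default 8,328-control database the rare/common boundary therefore sits
#' between 8 and 9 matched carriers.
#'
#' @param reciprocal_threshold Reciprocal-overlap threshold in (0, 1].
#' @param rare_cutoff Control-frequency cutoff in (0, 1).
#' @param state_matched Compare only state-matched control events
#'   (dup vs dup, del vs del).
#' @param burden_threshold Size threshold in bp for the burden test.
#' @return A list of class `"rarity_config"`.
#' @export
rarity_config <- function(reciprocal_threshold = 0.5, rare_cutoff = 0.001,
                          state_matched = TRUE, burden_threshold = 325000) {
  stopifnot(reciprocal_threshold > 0, reciprocal_threshold <= 1,
            rare_cutoff > 0, rare_cutoff < 1, burden_threshold > 0)
  structure(list(reciprocal_threshold = reciprocal_threshold,
                 rare_cutoff = rare_cutoff,
                 state_matched = isTRUE(state_matched),
                 burden_threshold = burden_threshold),
            class = "rarity_config")
}

#' Control frequency and rarity verdict for calls
#'
#' For each call, counts control carriers whose events have reciprocal
#' overlap above the threshold (state-matched by default), converts the
#' count to a frequency over the database size, and flags the call rare when
#' the frequency is strictly below the cutoff.
#'
#' @param calls Data.frame of calls (needs `chrom`, `start`, `end`, `state`).
#' @param db A [generate_control_db()] result, or any list with `events`
#'   (data.frame `chrom`, `start`, `end`, `state`, `count`) and `n_controls`.
#' @param cfg A [rarity_config()].
#' @return `calls` with columns `matched_controls`, `control_freq`, `rare`
#'   appended.
#' @export
control_frequency <- function(calls, db, cfg = rarity_config()) {
  stopifnot(inherits(cfg, "rarity_config"))
  if (is.null(db$n_controls) || db$n_controls < 1)
    stop("control database is empty (n_controls must be >= 1)", call. = FALSE)
  ev <- db$events
  if (!"count" %in% names(ev)) ev$count <- 1L
  n <- nrow(calls)
  matched <- integer(n)
  for (i in seq_len(n)) {
    cand <- ev
    if (cfg$state_matched && "state" %in% names(ev))
      cand <- cand[cand$state == calls$state[i], , drop = FALSE]
    if (nrow(cand)) {
      ro <- reciprocal_overlap(calls[i, c("chrom", "start", "end")],
                               cand[, c("chrom", "start", "end")])
      matched[i] <- sum(cand$count[ro > cfg$reciprocal_threshold])
    }
  }
  calls$matched_controls <- matched
  calls$control_freq <- matched / db$n_controls
  calls$rare <- calls$control_freq < cfg$rare_cutoff
  calls
}

#' Size-threshold CNV burden test
#'
#' Builds the 2x2 table (events above vs at/below the size threshold) x
#' (cases vs controls) on per-event counts and tests association with
#' Fisher's exact test. A label-permutation p-value (extremeness measured by
#' hypergeometric table probability, the same ordering Fisher's two-sided
#' p uses) is available as a cross-check.
#'
#' @param case_sizes,control_sizes Event sizes in bp (numeric vectors), or
#'   interval data.frames whose widths are used.
#' @param cfg A [rarity_config()] (supplies the size threshold).
#' @param alternative Passed to [stats::fisher.test()].
#' @param permutations Number of label permutations for the permutation
#'   p-value (0 = skip).
#' @param seed Seed for the permutation draw.
#' @return A list of class `"burden_test"`: `table` (2x2), `odds_ratio`,
#'   `p_value` (Fisher), `p_permutation` (or NA), `alternative`, `threshold`,
#'   `degenerate` (TRUE when the table has an empty size class, in which case
#'   p = 1).
#' @export
burden_test <- function(case_sizes, control_sizes, cfg = rarity_config(),
                        alternative = "two.sided", permutations = 0L,
                        seed = 1L) {
  stopifnot(inherits(cfg, "rarity_config"))
  if (is.data.frame(case_sizes)) case_sizes <- gi_width(case_sizes)
  if (is.data.frame(control_sizes)) control_sizes <- gi_width(control_sizes)
  thr <- cfg$burden_threshold
  tab <- matrix(c(sum(case_sizes > thr), sum(case_sizes <= thr),
                  sum(control_sizes > thr), sum(control_sizes <= thr)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("above", "at_or_below")))
  degenerate <- any(colSums(tab) == 0) || any(rowSums(tab) == 0)
  if (degenerate) {
    ft <- list(p.value = 1, estimate = NA_real_)
  } else {
    ft <- stats::fisher.test(tab, alternative = alternative)
  }
  p_perm <- NA_real_
  if (permutations > 0L && !degenerate) {
    set.seed(seed)
    sizes <- c(case_sizes, control_sizes)
    large <- sizes > thr
    n_case <- length(case_sizes)
    m <- sum(large); nn <- sum(!large)
    p_obs <- stats::dhyper(tab["case", "above"], m, nn, n_case)
    a_star <- stats::rhyper(permutations, m, nn, n_case)
    p_perm <- mean(stats::dhyper(a_star, m, nn, n_case) <= p_obs * (1 + 1e-7))
  }
  structure(list(table = tab,
                 odds_ratio = unname(if (is.null(ft$estimate)) NA_real_ else ft$estimate),
                 p_value = ft$p.value, p_permutation = p_perm,
                 alternative = alternative, threshold = thr,
                 degenerate = degenerate),
            class = "burden_test")
}
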