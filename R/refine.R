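# The four-rule filter cascade applied to raw HMM calls.
#
# A call is discarded when |mean z| < 1.5, when it has < 10 probes, when
# > 50% of its bases fall in segmental duplications, or when it is < 50 Kb
# long. Removal is by strict inequality, so boundary calls (exactly 10
# probes, exactly 50 Kb, exactly 50% overlap, |z| exactly 1.5) are RETAINED.
# All four rules are evaluated for every call so the flag vector is complete
# for audit output; nothing is silently dropped.

#' Filter thresholds for call refinement
#'
#' @param min_abs_z Minimum |mean segment z| (calls below are removed).
#' @param min_probes Minimum probe support.
#' @param max_segdup_frac Maximum fraction of the call covered by segmental
#'   duplications.
#' @param min_length Minimum call length in bp.
#' @return A list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_abs_z = 1.5, min_probes = 10L,
                              max_segdup_frac = 0.5, min_length = 50000) {
  stopifnot(min_abs_z > 0, min_probes > 0, min_length > 0,
            max_segdup_frac > 0, max_segdup_frac <= 1)
  structure(list(min_abs_z = min_abs_z, min_probes = as.integer(min_probes),
                 max_segdup_frac = max_segdup_frac, min_length = min_length),
            class = "filter_thresholds")
}

#' Fraction of a call covered by segmental duplications
#'
#' Segdup intervals are merged (union) before measuring, so stacked segdups
#' never push the fraction past 1.
#'
#' @param call Single-row interval data.frame.
#' @param segdups Interval data.frame of segmental duplications (may be
#'   empty).
#' @return Covered fraction in `[0, 1]`.
#' @export
segdup_overlap_fraction <- function(call, segdups) {
  validate_gi(call)
  stopifnot(nrow(call) == 1L)
  if (is.null(segdups) || nrow(segdups) == 0L) return(0)
  validate_gi(segdups)
  sd_ch <- segdups[segdups$chrom == call$chrom, , drop = FALSE]
  if (!nrow(sd_ch)) return(0)
  clipped <- data.frame(chrom = call$chrom,
                        start = pmax(sd_ch$start, call$start),
                        end = pmin(sd_ch$end, call$end),
                        stringsAsFactors = FALSE)
  clipped <- clipped[clipped$start < clipped$end, , drop = FALSE]
  if (!nrow(clipped)) return(0)
  gi_union_length(clipped) / (call$end - call$start)
}

#' Apply the filter cascade to raw calls
#'
#' Every input call is returned with its segdup overlap fraction, one
#' pass/fail flag per rule, and `retained` (the conjunction of the four
#' flags). Boundary cases sit exactly on the thresholds and are retained.
#'
#' @param calls Raw calls from [viterbi_segment()].
#' @param segdups Segmental-duplication intervals.
#' @param thresholds A [filter_thresholds()].
#' @return The calls with columns `segdup_frac`, `pass_z`, `pass_probes`,
#'   `pass_segdup`, `pass_length`, `retained` appended.
#' @export
apply_filters <- function(calls, segdups, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(calls)
  if (n == 0L) {
    calls$segdup_frac <- numeric(0)
    calls$pass_z <- calls$pass_probes <- calls$pass_segdup <-
      calls$pass_length <- calls$retained <- logical(0)
    return(calls)
  }
  calls$segdup_frac <- vapply(seq_len(n), function(i)
    segdup_overlap_fraction(calls[i, c("chrom", "start", "end")], segdups),
    numeric(1))
  calls$pass_z <- abs(calls$mean_z) >= thresholds$min_abs_z
  calls$pass_probes <- calls$n_probes >= thresholds$min_probes
  calls$pass_segdup <- calls$segdup_frac <= thresholds$max_segdup_frac
  calls$pass_length <- (calls$end - calls$start) >= thresholds$min_length
  calls$retained <- calls$pass_z & calls$pass_probes &
    calls$pass_segdup & calls$pass_length
  calls
}
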