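# Cohort-level statistics: carrier rates, 2x2 chi-square, exact McNemar,
# Welch t, and the summary report joining rarity verdicts to the phenotype
# sheet.

# Percent with one decimal, half-up (printed-table convention: 11/56 -> 19.6).
percent_1dp <- function(k, n) {
  floor(100 * k / n * 10 + 0.5) / 10
}

#' Carrier rate within a group selection
#'
#' A carrier is a participant with at least one rare CNV; a participant with
#' several counts once. Percent is reported to one decimal, half-up, the
#' convention of clinical tables.
#'
#' @param cohort Participant data.frame (needs `id` and `group`).
#' @param calls Data.frame of rare calls with a participant `id` column (or a
#'   character vector of carrier ids).
#' @param groups Groups to select (default: all); ignored when `ids` given.
#' @param ids Explicit participant ids to select instead of groups.
#' @return A list of class `"carrier_rate"`: `k`, `n`, `percent`.
#' @export
carrier_rate <- function(cohort, calls, groups = NULL, ids = NULL) {
  carriers <- unique(if (is.character(calls)) calls else calls$id)
  sel <- cohort
  if (!is.null(ids)) sel <- sel[sel$id %in% ids, , drop = FALSE]
  else if (!is.null(groups)) sel <- sel[sel$group %in% groups, , drop = FALSE]
  if (!nrow(sel)) stop("group filter selects no participants", call. = FALSE)
  k <- sum(sel$id %in% carriers)
  structure(list(k = k, n = nrow(sel), percent = percent_1dp(k, nrow(sel))),
            class = "carrier_rate")
}

#' @export
format.carrier_rate <- function(x, ...) {
  sprintf("%d/%d (%.1f%%)", x$k, x$n, x$percent)
}

#' @export
print.carrier_rate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Chi-square test on a 2x2 table (closed form)
#'
#' Without continuity correction the statistic is
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`; with Yates' correction `|ad - bc|` is
#' shrunk by `n/2` (floored at zero). p comes from the chi-square
#' distribution with 1 df.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct Apply Yates' continuity correction.
#' @return A list: `statistic`, `df` (= 1), `p_value`, `method`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table; use Fisher's exact test instead",
         call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = if (correct) "chi-square (Yates)" else "chi-square")
}

#' Exact McNemar test on discordant counts
#'
#' Two-sided exact binomial test on the discordant cells of a paired 2x2
#' table: `p = min(1, 2 P(X >= max(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `p = 1` when there are no discordant pairs.
#'
#' @param b,c Discordant counts.
#' @return The two-sided exact p-value.
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) return(1)
  m <- max(b, c)
  min(1, 2 * stats::pbinom(m - 1, n, 0.5, lower.tail = FALSE))
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] (Welch-Satterthwaite df) returning
#' the triplet the report needs.
#'
#' @param x,y Numeric vectors, each with at least 2 values and nonzero
#'   variance (jointly).
#' @return A list: `t`, `df`, `p_value`, `mean_x`, `mean_y`, `sd_x`, `sd_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 non-missing values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y),
                  sd_x = 0, sd_y = 0))
    stop("both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
       sd_x = stats::sd(x), sd_y = stats::sd(y))
}

#' Build the cohort summary report
#'
#' Joins rare calls to the phenotype sheet and computes the summary a
#' clinical CNV table prints: per-event rows with formatted sizes,
#' event/carrier totals, per-group carrier counts, size statistics (mean
#' floored to Kb), the standard group contrasts (neurological involvement,
#' ASD), and a CGG carrier-vs-non-carrier Welch t when both groups have
#' enough values.
#'
#' @param cohort Participant data.frame (`id`, `group`, optionally `sex`,
#'   `age`, `cgg1`).
#' @param calls Data.frame of rare calls: `id`, `chrom`, `start`, `end`,
#'   `state` (`"loss"`/`"gain"`), optionally `band`.
#' @param neuro_groups Groups counted as neurologically involved (default 3
#'   and 4).
#' @param asd_groups Groups counted as ASD (default 1 and 3).
#' @return A list of class `"cnv_report"`; see the fields set below.
#' @export
build_report <- function(cohort, calls, neuro_groups = c(3, 4),
                         asd_groups = c(1, 3)) {
  if (nrow(calls)) {
    unknown <- setdiff(calls$id, cohort$id)
    if (length(unknown))
      stop("calls reference unknown participants: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  sizes <- if (nrow(calls)) calls$end - calls$start else numeric(0)
  events <- if (nrow(calls)) {
    data.frame(calls,
               size_bp = sizes, size_label = format_size(sizes),
               stringsAsFactors = FALSE)
  } else calls
  carriers <- unique(calls$id)
  k <- length(carriers)
  n <- nrow(cohort)
  per_group <- vapply(sort(unique(cohort$group)), function(g)
    sum(cohort$id[cohort$group == g] %in% carriers), integer(1))
  names(per_group) <- sort(unique(cohort$group))

  contrast <- function(g1, g2) {
    r1 <- carrier_rate(cohort, calls, groups = g1)
    r2 <- carrier_rate(cohort, calls, groups = g2)
    tab <- matrix(c(r1$k, r1$n - r1$k, r2$k, r2$n - r2$k), 2, byrow = TRUE)
    stats_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    list(rate1 = r1, rate2 = r2, table = tab,
         chi_square = if (stats_ok) chi_square_2x2(tab) else NULL,
         chi_square_yates = if (stats_ok) chi_square_2x2(tab, correct = TRUE) else NULL,
         fisher_p = stats::fisher.test(tab)$p.value)
  }
  all_groups <- sort(unique(cohort$group))
  non_neuro <- setdiff(all_groups, neuro_groups)
  non_asd <- setdiff(all_groups, asd_groups)
  contrasts <- list(
    neuro_vs_not = contrast(neuro_groups, non_neuro),
    neuro_asd_vs_neuro_only = contrast(intersect(neuro_groups, asd_groups),
                                       setdiff(neuro_groups, asd_groups)),
    asd_vs_not = contrast(asd_groups, non_asd))
  # full-cohort-denominator percentages for the ASD split
  asd_rate <- carrier_rate(cohort, calls, groups = asd_groups)
  nonasd_rate <- carrier_rate(cohort, calls, groups = non_asd)
  full_denominator <- list(
    asd = list(k = asd_rate$k, n = n, percent = percent_1dp(asd_rate$k, n)),
    non_asd = list(k = nonasd_rate$k, n = n,
                   percent = percent_1dp(nonasd_rate$k, n)))

  cgg_t <- NULL
  if ("cgg1" %in% names(cohort)) {
    in_c <- cohort$cgg1[cohort$id %in% carriers]
    out_c <- cohort$cgg1[!cohort$id %in% carriers]
    if (sum(!is.na(in_c)) >= 2 && sum(!is.na(out_c)) >= 2)
      cgg_t <- welch_t(out_c, in_c)
  }

  structure(list(
    events = events,
    n_events = nrow(calls),
    n_dup = sum(calls$state == "gain"),
    n_del = sum(calls$state == "loss"),
    carriers = carriers,
    n_carriers = k,
    n_participants = n,
    carrier_percent = percent_1dp(k, n),
    per_group_carriers = per_group,
    size_min = if (length(sizes)) min(sizes) else NA_real_,
    size_max = if (length(sizes)) max(sizes) else NA_real_,
    mean_size_kb = if (length(sizes)) floor(sum(sizes) / length(sizes) / 1000) else NA_real_,
    contrasts = contrasts,
    full_denominator = full_denominator,
    cgg_t = cgg_t), class = "cnv_report")
}

#' @export
print.cnv_report <- function(x, ...) {
  cat(sprintf("CNV cohort report: %d events (%d dup / %d del) in %d of %d participants (%.1f%%)\n",
              x$n_events, x$n_dup, x$n_del, x$n_carriers, x$n_participants,
              x$carrier_percent))
  if (x$n_events) {
    cat(sprintf("event sizes: %s to %s, mean %d Kb\n",
                format_size(x$size_min), format_size(x$size_max),
                x$mean_size_kb))
    cat("per-group carriers:",
        paste(sprintf("group %s: %d", names(x$per_group_carriers),
                      x$per_group_carriers), collapse = ", "), "\n")
  }
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    p <- if (!is.null(ct$chi_square)) sprintf("chi-sq p = %.3f", ct$chi_square$p_value)
         else sprintf("Fisher p = %.3f", ct$fisher_p)
    cat(sprintf("%s: %s vs %s (%s)\n", nm, format(ct$rate1), format(ct$rate2), p))
  }
  invisible(x)
}
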