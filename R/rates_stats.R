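#' Mutation rate per cell division and per base pair
#'
#' Implements the MA-design rate estimator
#' mu = N / (s * n * g * G) per bp per division, where `N` is the total
#' number of detected events of one class across the cohort, `s` the number
#' of isolates, `n` the number of subculture passages, `g` the generations
#' per passage (24 by default) and `G` the assayed genome size (23 Mb by
#' default). The per-division rate is N / (s * n * g). Per-bp rates are
#' meaningful for SNVs and InDels; the per-division rate applies to all five
#' classes. Exact Poisson 95% confidence intervals on `N` are propagated to
#' both scales.
#'
#' @param N total event count (>= 0).
#' @param s number of isolates.
#' @param n number of passages.
#' @param generations generations per passage (default 24).
#' @param genome_bp assayed genome size in bp (default 23e6).
#' @param class_label optional class name carried in the result.
#' @return list of class `RateResult`: `N`, `divisions`, `per_division`,
#'   `per_bp`, `ci_per_division`, `ci_per_bp`, `class`.
#' @export
mutation_rate <- function(N, s, n, generations = 24L, genome_bp = 23e6,
                          class_label = NA_character_) {
  stopifnot(N >= 0, s >= 1, n >= 1, generations >= 1, genome_bp > 0)
  divisions <- as.numeric(s) * n * generations
  ci_N <- c(if (N == 0) 0 else stats::qgamma(0.025, N),
            stats::qgamma(0.975, N + 1))
  out <- list(N = N, divisions = divisions,
              per_division = N / divisions,
              per_bp = N / (divisions * genome_bp),
              ci_per_division = ci_N / divisions,
              ci_per_bp = ci_N / (divisions * genome_bp),
              class = class_label)
  class(out) <- "RateResult"
  out
}

#' @export
print.RateResult <- function(x, ...) {
  cat(sprintf("Rate%s: N = %d over %g divisions\n",
              if (is.na(x$class)) "" else paste0(" (", x$class, ")"),
              x$N, x$divisions))
  cat(sprintf("  per division: %.4g  [95%% CI %.4g, %.4g]\n",
              x$per_division, x$ci_per_division[1], x$ci_per_division[2]))
  cat(sprintf("  per bp:       %.4g  [95%% CI %.4g, %.4g]\n",
              x$per_bp, x$ci_per_bp[1], x$ci_per_bp[2]))
  invisible(x)
}

#' Fold change between two rates
#'
#' Ratio of per-division rates (mutant over reference). A zero reference
#' rate yields `Inf` with attribute `undefined_reference = TRUE`.
#'
#' @param rate_mut,rate_wt [mutation_rate()] results for the same class.
#' @return numeric ratio.
#' @export
fold_change <- function(rate_mut, rate_wt) {
  if (rate_wt$per_division == 0) {
    out <- Inf
    attr(out, "undefined_reference") <- TRUE
    return(out)
  }
  rate_mut$per_division / rate_wt$per_division
}

#' Wilcoxon rank-sum comparison of per-isolate event counts
#'
#' Two-sided rank-sum test. When the smaller group has at most `exact_max`
#' observations the null distribution of the rank-sum statistic is
#' enumerated exhaustively over all group assignments (ties handled via
#' midranks), doubling the smaller tail; otherwise the normal approximation
#' with tie correction is used (via [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors of per-isolate counts.
#' @param exact_max largest min(group size) for exhaustive enumeration
#'   (default 8).
#' @return list with `W` (Mann-Whitney statistic of group `a`), `p`, and
#'   `method`.
#' @export
compare_rate_distributions <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(W = W, p = 1, method = "degenerate"))
  if (min(na, nb) <= exact_max &&
      choose(na + nb, min(na, nb)) <= 2e6) {
    idx <- utils::combn(na + nb, min(na, nb))
    sums <- colSums(matrix(rk[idx], nrow = min(na, nb)))
    stat <- if (na <= nb) sum(rk[seq_len(na)]) else sum(rk[na + seq_len(nb)])
    lo <- mean(sums <= stat)
    hi <- mean(sums >= stat)
    p <- min(1, 2 * min(lo, hi))
    list(W = W, p = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    list(W = W, p = wt$p.value, method = "normal approximation")
  }
}

#' Per-group subtype composition of one event class
#'
#' @param events a combined `EventTable` with an added `group` column, or a
#'   plain data.frame with `group`, `class`, `subtype`.
#' @param class_label which class to tabulate (e.g. `"SNV"`).
#' @return matrix of counts, groups in rows, subtypes in columns; attribute
#'   `proportions` holds row-normalized fractions.
#' @export
composition_table <- function(events, class_label) {
  stopifnot("group" %in% names(events))
  d <- events[events$class == class_label, , drop = FALSE]
  tab <- table(d$group, d$subtype)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  attr(m, "proportions") <- prop.table(m + 0, margin = 1)
  m
}

#' Fisher's exact test on a 2 x k composition table
#'
#' Exact test when the table total is at most `exhaustive_max`; otherwise a
#' Monte-Carlo p-value with a fixed seed and `B` replicates.
#'
#' @param tab integer matrix with 2 rows (groups) and k >= 2 columns
#'   (subtypes).
#' @param exhaustive_max largest table total for the exact computation
#'   (default 200).
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed Monte-Carlo seed (default 1).
#' @return list with `p`, `method`, and `B` (NA for exact).
#' @export
composition_test <- function(tab, exhaustive_max = 200L, B = 1e5L,
                             seed = 1L) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("composition_test expects a 2 x k table with k >= 2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty table margin")
  if (sum(tab) <= exhaustive_max) {
    p <- stats::fisher.test(tab)$p.value
    list(p = min(1, p), method = "exact", B = NA_integer_)
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
    list(p = p, method = "monte-carlo", B = B)
  }
}

# Poisson two-sided tail probability of observing x given mean lambda
poisson_tail_p <- function(x, lambda) {
  if (lambda <= 0) return(as.numeric(x == 0))
  lo <- stats::ppois(x, lambda)
  hi <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Detect hypermutator isolates in a cohort
#'
#' Flags isolates whose point-mutation load (SNV + InDel count) exceeds the
#' cohort median by more than `k` median absolute deviations, whose C>T/G>A
#' transition fraction exceeds the cohort median fraction, and whose
#' large-scale event count (LOH + CR + aneuploidy) stays within `k` MADs of
#' the cohort median -- the signature of a replication-fidelity (MMR-type)
#' hypermutator, as opposed to generalized chromosome instability. When a
#' MAD degenerates to zero the corresponding criterion falls back to a
#' two-sided Poisson tail test at alpha = 1e-3 around the cohort median.
#'
#' @param events a combined `EventTable` across isolates.
#' @param isolates isolate identifiers making up the cohort (defaults to the
#'   identifiers present in `events`; list explicitly if isolates may have
#'   zero events).
#' @param k MAD multiplier (default 5).
#' @return list with `flagged` (hypermutator ids), `main` (the remaining
#'   cohort) and the per-isolate `stats` data.frame.
#' @export
detect_hypermutators <- function(events, isolates = NULL, k = 5) {
  if (is.null(isolates)) isolates <- sort(unique(events$isolate))
  if (length(isolates) < 5L) stop("need at least 5 isolates")
  per <- lapply(isolates, function(id) {
    e <- events[events$isolate == id, , drop = FALSE]
    snv <- e[e$class == "SNV", , drop = FALSE]
    data.frame(isolate = id,
               small = sum(e$class %in% c("SNV", "InDel")),
               large = sum(e$class %in% c("LOH", "CR", "aneuploidy")),
               ct_frac = if (nrow(snv)) mean(snv$subtype == "C>T") else 0,
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  med_s <- stats::median(st$small); mad_s <- stats::mad(st$small)
  med_l <- stats::median(st$large); mad_l <- stats::mad(st$large)
  med_ct <- stats::median(st$ct_frac)
  elevated <- if (mad_s > 0) st$small > med_s + k * mad_s else
    vapply(st$small, function(x)
      x > med_s && poisson_tail_p(x, med_s) < 1e-3, TRUE)
  comparable <- if (mad_l > 0)
    abs(st$large - med_l) <= k * mad_l else
    vapply(st$large, function(x) poisson_tail_p(x, med_l) >= 1e-3, TRUE)
  flag <- elevated & st$ct_frac > med_ct & comparable
  st$flagged <- flag
  list(flagged = st$isolate[flag], main = st$isolate[!flag], stats = st)
}

#' Per-class rate table for a cohort
#'
#' @param events a combined `EventTable`.
#' @param s,n,generations,genome_bp design constants (see
#'   [mutation_rate()]).
#' @param group group label carried in the output.
#' @return data.frame with one row per class: `group`, `class`, `N`, `s`,
#'   `n`, `per_division`, `per_bp` (NA for LOH/CR/aneuploidy), CI bounds.
#' @export
rate_table <- function(events, s, n, generations = 24L, genome_bp = 23e6,
                       group = "MA") {
  classes <- c("SNV", "InDel", "LOH", "CR", "aneuploidy")
  rows <- lapply(classes, function(cl) {
    r <- mutation_rate(sum(events$class == cl), s, n, generations, genome_bp,
                       class_label = cl)
    data.frame(group = group, class = cl, N = r$N, s = s, n = n,
               per_division = r$per_division,
               per_bp = if (cl %in% c("SNV", "InDel")) r$per_bp else NA_real_,
               ci_lo = r$ci_per_division[1], ci_hi = r$ci_per_division[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
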