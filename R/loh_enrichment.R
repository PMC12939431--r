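#' Expected element count inside LOH windows
#'
#' Under a uniform null, the expected number of elements falling inside the
#' LOH windows is the genomic length fraction covered by those windows times
#' the total number of elements in the sequenced region:
#' expected = (loh_total_len / genome_len) * total_elements.
#'
#' @param loh_total_len total unioned LOH window length in bp.
#' @param genome_len total assayed genome length in bp (> 0).
#' @param total_elements total element count (>= 0).
#' @return expected count (real).
#' @export
expected_count <- function(loh_total_len, genome_len, total_elements) {
  if (genome_len <= 0) stop("genome_len must be > 0")
  if (loh_total_len < 0 || loh_total_len > genome_len)
    stop("loh_total_len must lie in [0, genome_len]")
  (loh_total_len / genome_len) * total_elements
}

#' Observed element count inside LOH windows
#'
#' Counts elements whose interval overlaps the union of LOH windows by at
#' least one bp; each element is counted at most once, and the result is
#' invariant to how the window union is split into adjacent pieces.
#'
#' @param loh_windows an [element_track()] of LOH windows.
#' @param elements an [element_track()] of elements.
#' @return integer count.
#' @export
observed_count <- function(loh_windows, elements) {
  if (!nrow(elements) || !nrow(loh_windows)) return(0L)
  merged <- merge_track(loh_windows)
  n <- 0L
  for (ch in unique(elements$chrom)) {
    e <- elements[elements$chrom == ch, ]
    w <- merged[merged$chrom == ch, ]
    if (!nrow(w)) next
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(start = e$start + 1, end = e$end),
      IRanges::IRanges(start = w$start + 1, end = w$end))
    n <- n + sum(hits > 0L)
  }
  n
}

#' Chi-square enrichment test for one element class
#'
#' One-degree-of-freedom chi-square (no continuity correction) comparing the
#' observed split of elements inside/outside the LOH windows with the
#' expected split: chi2 = (obs - exp)^2 / exp +
#' ((total - obs) - (total - exp))^2 / (total - exp).
#'
#' @param observed observed count inside windows.
#' @param expected expected count from [expected_count()] (> 0 and <
#'   `total_elements`).
#' @param total_elements total element count.
#' @param element name label carried in the result.
#' @param group group label carried in the result.
#' @return data.frame of class `EnrichmentResult`: `element`, `group`,
#'   `observed`, `expected`, `ratio`, `chi2`, `p`, `direction`,
#'   `low_expected` (TRUE when expected < 1: test unreliable, still
#'   computed).
#' @export
enrichment_test <- function(observed, expected, total_elements,
                            element = "element", group = "MA") {
  if (expected <= 0 || expected >= total_elements)
    stop("enrichment_test requires 0 < expected < total_elements")
  chi2 <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (total_elements - expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- data.frame(
    element = element, group = group, observed = observed,
    expected = expected, ratio = observed / expected, chi2 = chi2, p = p,
    direction = if (observed >= expected) "enriched" else "depleted",
    low_expected = expected < 1, untestable = FALSE,
    stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Extract the unioned LOH window track from an event table
#'
#' LOH rows of all isolates (of one group) are pooled and their spans
#' unioned, so overlapping windows from different isolates are not counted
#' twice in the length fraction.
#'
#' @param events an `EventTable`.
#' @return an [element_track()] named `"LOH"`.
#' @export
loh_windows_from_events <- function(events) {
  l <- events[events$class == "LOH", , drop = FALSE]
  if (!nrow(l))
    return(element_track(character(), numeric(), numeric(), name = "LOH"))
  merge_track(element_track(l$chrom, l$start, l$end, name = "LOH"))
}

#' Run the LOH-element enrichment panel
#'
#' For each element track, computes the expected count from the LOH length
#' fraction, the observed overlap count, the observed/expected ratio and the
#' chi-square significance. A cohort (or group) with no LOH events yields
#' untestable rows.
#'
#' @param events an `EventTable` containing LOH rows for one group.
#' @param tracks a list of [element_track()] objects (named or carrying
#'   their own `name` attributes).
#' @param layout a [genome_layout()] providing the total genome length.
#' @param group group label for the output rows.
#' @return data.frame of `EnrichmentResult` rows, one per track.
#' @export
run_enrichment_panel <- function(events, tracks, layout, group = "MA") {
  if (!length(tracks)) stop("need at least one element track")
  nm <- names(tracks)
  if (is.null(nm)) nm <- rep(NA_character_, length(tracks))
  loh <- loh_windows_from_events(events)
  loh_len <- track_length(loh)
  glen <- genome_size(layout)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    label <- if (!is.na(nm[i]) && nzchar(nm[i])) nm[i]
             else attr(tr, "name")
    tot <- track_count(tr)
    exp_ct <- expected_count(loh_len, glen, tot)
    if (loh_len == 0 || tot == 0L || exp_ct >= tot) {
      out <- data.frame(element = label, group = group,
                        observed = NA_integer_, expected = exp_ct,
                        ratio = NA_real_, chi2 = NA_real_, p = NA_real_,
                        direction = NA_character_, low_expected = exp_ct < 1,
                        untestable = TRUE, stringsAsFactors = FALSE)
      return(out)
    }
    obs <- observed_count(loh, tr)
    enrichment_test(obs, exp_ct, tot, element = label, group = group)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
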