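#' Read a replication-origin map from BED
#'
#' Origin intervals are reduced to their midpoints; the analysis treats
#' origins as points from which forks diverge bidirectionally.
#'
#' @param path BED file of origins.
#' @return data.frame of class `OriginMap` with `chrom`, `pos` (1-based
#'   midpoints, sorted per chromosome).
#' @export
read_origin_bed <- function(path) {
  tr <- read_bed_track(path, name = "origin")
  om <- data.frame(chrom = tr$chrom,
                   pos = as.integer(floor((tr$start + tr$end) / 2)) + 1L,
                   stringsAsFactors = FALSE)
  om <- om[order(om$chrom, om$pos), ]
  rownames(om) <- NULL
  class(om) <- c("OriginMap", "data.frame")
  om
}

#' Classify a mutation as an APOBEC3B signature type
#'
#' A3B deaminates cytosines in ssDNA; on the top strand the readout is C>T,
#' and a deamination on the bottom strand reads as G>A. All other
#' substitutions are `other`.
#'
#' @param ref,alt single bases (vectorized).
#' @return character vector over `{"C>T", "G>A", "other"}`.
#' @export
classify_a3b <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1) ||
      any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T")))
    stop("classify_a3b expects single-base SNVs")
  out <- rep("other", length(ref))
  out[ref == "C" & alt == "T"] <- "C>T"
  out[ref == "G" & alt == "A"] <- "G>A"
  out
}

#' Fractional position of mutations between adjacent replication origins
#'
#' For each position finds the flanking origins O_L <= pos < O_R on its
#' chromosome and computes f = (pos - O_L) / (O_R - O_L). Positions before
#' the first or at/after the last origin are outside any inter-origin
#' interval and get `NA` (fork direction there depends on unannotated
#' flanking origins).
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param origins an `OriginMap`.
#' @return data.frame with `interval` (chromosome-local interval id, NA when
#'   outside) and `f` in [0, 1).
#' @export
assign_fractional_position <- function(chrom, pos, origins) {
  interval <- rep(NA_integer_, length(pos))
  f <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    o <- origins$pos[origins$chrom == ch]
    sel <- which(chrom == ch)
    if (length(o) < 2L) next
    i <- findInterval(pos[sel], o)
    ok <- i >= 1L & pos[sel] < o[length(o)]
    ii <- i[ok]
    interval[sel[ok]] <- ii
    f[sel[ok]] <- (pos[sel][ok] - o[ii]) / (o[ii + 1L] - o[ii])
  }
  data.frame(interval = interval, f = f)
}

#' Infer the replicational template strand of an A3B mutation
#'
#' Model: forks diverge from each origin and meet at the interval midpoint.
#' Left of the midpoint (f < 0.5) the rightward-moving fork replicates the
#' region and the top strand is the lagging-strand template; right of the
#' midpoint the leftward fork makes the bottom strand the lagging template.
#' A C>T mutation marks a deaminated C on the top strand, G>A on the bottom
#' strand, so: C>T is lagging for f < 0.5 and leading for f > 0.5; G>A is
#' the mirror image. Exactly at f = 0.5 the assignment is ambiguous.
#'
#' @param class character vector over `{"C>T", "G>A"}`.
#' @param f fractional positions in [0, 1].
#' @return character vector over `{"lagging", "leading", "ambiguous"}`.
#' @export
infer_template <- function(class, f) {
  stopifnot(all(class %in% c("C>T", "G>A")), all(f >= 0 & f <= 1))
  out <- rep("ambiguous", length(class))
  left <- f < 0.5; right <- f > 0.5
  out[class == "C>T" & left] <- "lagging"
  out[class == "C>T" & right] <- "leading"
  out[class == "G>A" & left] <- "leading"
  out[class == "G>A" & right] <- "lagging"
  out
}

#' Build A3B mutation records from variant calls
#'
#' Classifies SNVs as C>T / G>A / other, keeps the two A3B signature
#' classes, assigns inter-origin fractional positions, and infers the
#' template strand. Mutations outside the outermost origins are dropped.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (indels are
#'   ignored).
#' @param origins an `OriginMap`.
#' @return data.frame of class `A3BMutationSet` with `chrom`, `pos`,
#'   `class`, `interval`, `f`, `template`.
#' @export
a3b_mutations <- function(variants, origins) {
  v <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                drop = FALSE]
  empty <- data.frame(chrom = character(), pos = integer(),
                      class = character(), interval = integer(),
                      f = numeric(), template = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(v)) { class(empty) <- c("A3BMutationSet", "data.frame"); return(empty) }
  cls <- classify_a3b(v$ref, v$alt)
  v <- v[cls != "other", , drop = FALSE]
  cls <- cls[cls != "other"]
  if (!nrow(v)) { class(empty) <- c("A3BMutationSet", "data.frame"); return(empty) }
  fp <- assign_fractional_position(v$chrom, v$pos, origins)
  keep <- !is.na(fp$f)
  out <- data.frame(chrom = v$chrom[keep], pos = v$pos[keep],
                    class = cls[keep], interval = fp$interval[keep],
                    f = fp$f[keep],
                    template = infer_template(cls[keep], fp$f[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("A3BMutationSet", "data.frame")
  out
}

#' Binned C>T / G>A profile across inter-origin intervals
#'
#' Histograms the fractional positions of the two signature classes into
#' `n_bins` half-open bins `[i/n, (i+1)/n)` (last bin closed) and normalizes
#' each class to frequencies. The crossing of the two profiles near f = 0.5
#' is the visual signature of lagging-strand-biased ssDNA exposure.
#'
#' @param mutations an [a3b_mutations()] result.
#' @param n_bins number of bins (>= 2; default 10).
#' @return data.frame of class `FractionalPositionProfile` with `bin_lo`,
#'   `bin_hi`, `n_ct`, `n_ga`, `freq_ct`, `freq_ga`; attribute `empty` is
#'   TRUE when no in-interval mutations exist.
#' @export
build_profile <- function(mutations, n_bins = 10L) {
  stopifnot(n_bins >= 2L)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin_of <- function(f) pmin(floor(f * n_bins) + 1L, n_bins)
  ct <- tabulate(bin_of(mutations$f[mutations$class == "C>T"]), n_bins)
  ga <- tabulate(bin_of(mutations$f[mutations$class == "G>A"]), n_bins)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n_ct = ct, n_ga = ga,
                    freq_ct = if (sum(ct)) ct / sum(ct) else 0,
                    freq_ga = if (sum(ga)) ga / sum(ga) else 0)
  attr(out, "empty") <- sum(ct) + sum(ga) == 0L
  class(out) <- c("FractionalPositionProfile", "data.frame")
  out
}

#' Lagging-strand asymmetry of A3B mutations
#'
#' Fraction of unambiguous signature mutations inferred to mark the
#' lagging-strand template, with a two-sided exact binomial test against
#' 0.5 (no asymmetry).
#'
#' @param mutations an [a3b_mutations()] result.
#' @return list with `n`, `n_lagging`, `fraction`, `p`.
#' @export
lagging_asymmetry <- function(mutations) {
  m <- mutations[mutations$template != "ambiguous", , drop = FALSE]
  if (!nrow(m)) stop("no unambiguous signature mutations")
  n_lag <- sum(m$template == "lagging")
  bt <- stats::binom.test(n_lag, nrow(m), p = 0.5)
  list(n = nrow(m), n_lagging = n_lag, fraction = n_lag / nrow(m),
       p = bt$p.value)
}
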