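#' Genome layout for a hybrid diploid assembly
#'
#' A `GenomeLayout` is the coordinate authority shared by the simulator, the
#' event caller and the enrichment analysis. It records the ordered
#' chromosomes of the assayed genome, their lengths, and the centromere
#' midpoint of each chromosome.
#'
#' All intervals handled by this package are 0-based, half-open
#' (BED convention); 1-based VCF positions are converted at the boundary.
#'
#' @param chrom character vector of unique chromosome names, in karyotype
#'   order.
#' @param length integer vector of chromosome lengths in bp (all > 0).
#' @param centromere integer vector of centromere midpoint positions in bp
#'   (1 <= centromere <= length).
#'
#' @return A data.frame of class `GenomeLayout` with columns `chrom`,
#'   `length`, `centromere`, and attribute `total_length`.
#' @export
genome_layout <- function(chrom, length, centromere) {
  chrom <- as.character(chrom)
  length <- as.integer(length)
  centromere <- as.integer(centromere)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0L)) stop("chromosome lengths must be positive")
  if (any(centromere < 1L | centromere > length))
    stop("centromere positions must lie within [1, length]")
  layout <- data.frame(chrom = chrom, length = length,
                       centromere = centromere, stringsAsFactors = FALSE)
  attr(layout, "total_length") <- sum(as.numeric(length))
  class(layout) <- c("GenomeLayout", "data.frame")
  layout
}

#' Total genome length of a layout
#' @param layout a [genome_layout()] object.
#' @return total length in bp (numeric scalar).
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(as.numeric(layout$length))
}

#' Default 16-chromosome hybrid diploid layout (~23 Mb)
#'
#' Emulates the assayed genome of a W303 x YJM789-style hybrid diploid:
#' sixteen chromosomes whose relative lengths and centromere positions follow
#' the S. cerevisiae karyotype, scaled so the assayed (diploid) genome totals
#' 23,000,000 bp -- the constant used by the per-bp mutation-rate formula.
#'
#' @return A [genome_layout()].
#' @export
default_genome_layout <- function() {
  # haploid S288C chromosome lengths / CEN midpoints, scaled to sum to 23 Mb
  len <- c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
           439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066)
  cen <- c(151465, 238207, 114385, 449711, 151987, 148510, 496920, 105586,
           355629, 436307, 440129, 150828, 268031, 628758, 326584, 555957)
  scale <- 23e6 / sum(len)
  slen <- round(len * scale)
  slen[16] <- slen[16] + (23000000L - sum(slen))  # absorb rounding residue
  genome_layout(chrom = sprintf("chr%02d", 1:16),
                length = slen,
                centromere = pmin(round(cen * scale), slen))
}

#' Construct an element track
#'
#' An `ElementTrack` holds genomic intervals for one element class
#' (centromeres, G4 motifs, Rrm3p sites, GC classes, LOH windows, ...).
#' Intervals are 0-based half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer interval bounds, `start < end`.
#' @param name single label for the element class.
#' @param layout optional [genome_layout()]; when supplied, intervals are
#'   checked against chromosome bounds.
#' @return data.frame of class `ElementTrack` (columns `chrom`, `start`,
#'   `end`) with attribute `name`.
#' @export
element_track <- function(chrom, start, end, name = "element", layout = NULL) {
  track <- data.frame(chrom = as.character(chrom),
                      start = as.numeric(start), end = as.numeric(end),
                      stringsAsFactors = FALSE)
  if (nrow(track) && any(track$start < 0 | track$start >= track$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(layout) && nrow(track)) {
    idx <- match(track$chrom, layout$chrom)
    if (anyNA(idx)) stop("interval on chromosome absent from layout")
    if (any(track$end > layout$length[idx]))
      stop("interval exceeds chromosome length")
  }
  attr(track, "name") <- name
  class(track) <- c("ElementTrack", "data.frame")
  track
}

#' Number of elements in a track
#' @param track an [element_track()].
#' @return integer count.
#' @export
track_count <- function(track) nrow(track)

#' Total interval length of a track in bp
#' @param track an [element_track()].
#' @return numeric bp.
#' @export
track_length <- function(track) {
  if (!nrow(track)) return(0)
  sum(track$end - track$start)
}

#' Merge overlapping or touching intervals of a track
#'
#' Union semantics per chromosome; idempotent.
#'
#' @param track an [element_track()].
#' @return a merged [element_track()] with the same name.
#' @export
merge_track <- function(track) {
  nm <- attr(track, "name")
  if (!nrow(track)) return(track)
  parts <- lapply(split(track, track$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(match(out$chrom, unique(track$chrom)), out$start), ]
  rownames(out) <- NULL
  element_track(out$chrom, out$start, out$end, name = nm)
}

## ---- sequence input -------------------------------------------------------

# Accept a named character vector or a Biostrings::DNAStringSet; return a
# named uppercase character vector, validating the alphabet.
as_sequence_set <- function(sequence) {
  if (methods::is(sequence, "DNAStringSet")) {
    seqs <- as.character(sequence)
  } else if (is.character(sequence)) {
    seqs <- sequence
  } else stop("sequence must be a character vector or DNAStringSet")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence contains non-DNA characters (allowed: A, C, G, T, N)")
  seqs
}

#' Read a genome FASTA into a named sequence set
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  as_sequence_set(Biostrings::readDNAStringSet(path))
}

## ---- G-quadruplex scanning ------------------------------------------------

# all (possibly overlapping) match start/width pairs of a G4-type pattern,
# found by a zero-width lookahead so every start position is probed
g4_hits_one_strand <- function(seq, base, min_g_run, max_loop) {
  pat <- sprintf("(?=(%s{%d,}(?:[ACGT]{1,%d}%s{%d,}){3}))",
                 base, min_g_run, max_loop, base, min_g_run)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  cs <- attr(m, "capture.start")
  if (is.null(cs) || m[1] == -1L) return(NULL)
  data.frame(start = as.integer(cs[, 1]) - 1L,
             end = as.integer(cs[, 1]) - 1L + as.integer(attr(m, "capture.length")[, 1]))
}

#' Scan a genome for G-quadruplex (G4) motifs
#'
#' Finds intervals matching the quadruplex consensus: four runs of at least
#' `min_g_run` guanines separated by loops of 1..`max_loop` arbitrary bases,
#' on both strands (the minus strand is scanned as the equivalent C-run
#' pattern on the plus strand). Overlapping hits, including hits overlapping
#' between strands, are merged. N bases never match.
#'
#' @param sequence named character vector of chromosome sequences (A/C/G/T/N)
#'   or a `DNAStringSet`.
#' @param min_g_run minimum G-run length (>= 2; default 3).
#' @param max_loop maximum loop length in bases (>= 1; default 7).
#' @return an [element_track()] named `"G4"` with merged motif intervals.
#' @export
scan_g4_motifs <- function(sequence, min_g_run = 3L, max_loop = 7L) {
  stopifnot(min_g_run >= 2L, max_loop >= 1L)
  seqs <- as_sequence_set(sequence)
  rows <- list()
  for (chrom in names(seqs)) {
    hits <- rbind(g4_hits_one_strand(seqs[[chrom]], "G", min_g_run, max_loop),
                  g4_hits_one_strand(seqs[[chrom]], "C", min_g_run, max_loop))
    if (!is.null(hits) && nrow(hits))
      rows[[chrom]] <- data.frame(chrom = chrom, hits,
                                  stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(element_track(character(), integer(), integer(), name = "G4"))
  out <- do.call(rbind, rows)
  merge_track(element_track(out$chrom, out$start, out$end, name = "G4"))
}

## ---- GC windows -----------------------------------------------------------

#' Per-window GC content of a genome
#'
#' Tiles each chromosome with windows of `window_size` bp advanced by `step`
#' bp and reports the GC fraction of each window, computed over non-N bases:
#' (G+C) / (window_size - N count). All-N windows are flagged missing
#' (`gc = NA`).
#'
#' @param sequence named character vector or `DNAStringSet`.
#' @param window_size window width in bp (default 500).
#' @param step window step in bp (default 500; equal to `window_size` for
#'   non-overlapping tiles).
#' @return data.frame of class `GCWindowTrack` with columns `chrom`, `start`,
#'   `end`, `gc`, `n_frac`; attributes `window_size`, `step`.
#' @export
compute_gc_windows <- function(sequence, window_size = 500L, step = 500L) {
  stopifnot(window_size >= 1L, step >= 1L)
  seqs <- as_sequence_set(sequence)
  rows <- list()
  for (chrom in names(seqs)) {
    len <- nchar(seqs[[chrom]])
    if (window_size > len) {
      warning(sprintf("window_size %d exceeds length of %s (%d); no windows",
                      window_size, chrom, len))
      next
    }
    n_win <- (len - window_size) %/% step + 1L
    starts <- (seq_len(n_win) - 1L) * step
    r <- charToRaw(seqs[[chrom]])
    is_gc <- cumsum(c(0L, as.integer(r == charToRaw("G") | r == charToRaw("C"))))
    is_n  <- cumsum(c(0L, as.integer(r == charToRaw("N"))))
    gc_ct <- is_gc[starts + window_size + 1L] - is_gc[starts + 1L]
    n_ct  <- is_n[starts + window_size + 1L] - is_n[starts + 1L]
    denom <- window_size - n_ct
    gc <- ifelse(denom > 0L, gc_ct / denom, NA_real_)
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                end = starts + window_size, gc = gc,
                                n_frac = n_ct / window_size,
                                stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               gc = numeric(), n_frac = numeric())
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("GCWindowTrack", "data.frame")
  out
}

#' Classify high- and low-GC regions from a GC window track
#'
#' Windows with GC strictly above the `high_q` quantile become high-GC
#' intervals and windows strictly below the `low_q` quantile become low-GC
#' intervals (strict inequalities, so a constant-GC genome yields two empty
#' tracks). Adjacent qualifying windows are merged. Windows with more than
#' half N bases are excluded from both the quantile computation and the
#' classification.
#'
#' @param track a [compute_gc_windows()] result.
#' @param high_q upper quantile cutoff (default 0.9, i.e. top decile).
#' @param low_q lower quantile cutoff (default 0.1).
#' @return list with [element_track()] components `high` and `low`.
#' @export
classify_gc_regions <- function(track, high_q = 0.9, low_q = 0.1) {
  stopifnot(inherits(track, "GCWindowTrack"), 0 < low_q, low_q < high_q,
            high_q < 1)
  usable <- !is.na(track$gc) & track$n_frac <= 0.5
  if (!any(usable)) stop("no usable (non-N) windows to classify")
  gc <- track$gc[usable]
  hi_cut <- stats::quantile(gc, high_q, names = FALSE)
  lo_cut <- stats::quantile(gc, low_q, names = FALSE)
  pick <- function(sel, nm) {
    d <- track[usable, ][sel, , drop = FALSE]
    merge_track(element_track(d$chrom, d$start, d$end, name = nm))
  }
  list(high = pick(gc > hi_cut, "high-GC"), low = pick(gc < lo_cut, "low-GC"))
}

#' Centromere element track
#'
#' Represents each centromere midpoint as a fixed-width window, clipped to
#' chromosome bounds. Point features need width for overlap counting.
#'
#' @param layout a [genome_layout()].
#' @param halfwidth half-window in bp around the midpoint (default 2000).
#' @return an [element_track()] named `"centromere"`, one interval per
#'   chromosome.
#' @export
centromere_track <- function(layout, halfwidth = 2000L) {
  element_track(layout$chrom,
                pmax(0, layout$centromere - halfwidth),
                pmin(layout$length, layout$centromere + halfwidth),
                name = "centromere", layout = layout)
}

## ---- BED I/O --------------------------------------------------------------

#' Read an element track from a BED file
#'
#' BED is 0-based half-open, matching this package's internal convention.
#'
#' @param path BED file (>= 3 columns).
#' @param name label for the track (default: file basename without extension).
#' @return an [element_track()].
#' @export
read_bed_track <- function(path, name = sub("\\.bed$", "", basename(path))) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, fill = TRUE)
  element_track(as.character(d[[1]]), as.numeric(d[[2]]), as.numeric(d[[3]]),
                name = name)
}

#' Write an element track as BED
#' @param track an [element_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  d <- as.data.frame(track)[, c("chrom", "start", "end")]
  d$name <- attr(track, "name")
  utils::write.table(format(d, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
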