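#' Event-calling parameters
#'
#' Thresholds used to segment LOH tracts, copy-number segments and
#' aneuploidy calls from marker genotypes and normalized depth. Defaults are
#' midpoints between the copy-ratio expectations at diploid baseline
#' (1 copy = 0.5x, 3 copies = 1.5x, 4 copies = 2.0x).
#'
#' @param min_run minimum homozygous markers in an LOH segment (default 10).
#' @param max_gap heterozygous miscalls tolerated between consecutive
#'   homozygous markers inside a run (default 1).
#' @param del_max depth ratio below which a window supports a deletion
#'   (default 0.65, strict).
#' @param dup_min depth ratio above which a window supports a duplication
#'   (default 1.35, strict).
#' @param min_span minimum CNV segment span in bp (default 5000).
#' @param smooth_k running-median window (odd; default 15) applied to the
#'   depth track before thresholding; window values within `(smooth_k-1)/2`
#'   of a chromosome end are left unsmoothed so terminal segments keep exact
#'   boundaries. A median filter passes any plateau of at least
#'   `(smooth_k+1)/2` windows through unchanged, so the effective detection
#'   floor is `max(min_span, (smooth_k+1)/2 windows)`.
#' @param cnv_max_gap non-qualifying windows bridged inside a CNV run
#'   (default 5).
#' @param min_windows minimum qualifying (not bridged) windows per CNV
#'   segment (default 4); suppresses spurious segments from unsmoothed
#'   chromosome-end windows.
#' @param whole_chrom_frac fraction of a chromosome's windows above which a
#'   CNV run is treated as whole-chromosome and routed to the aneuploidy
#'   caller (default 0.95).
#' @param mono_max,tri_min,tri_max,tet_min mean-ratio thresholds for
#'   monosomy (< 0.65), trisomy ((1.35, 1.75)) and 4-5 copies (> 1.85); ties
#'   resolve toward the euploid state.
#' @param upd_hom_min minimum whole-chromosome homozygous-marker fraction for
#'   a uniparental-diploid call at disomic depth (default 0.9).
#' @return list of class `CallerParams`.
#' @export
caller_params <- function(min_run = 10L, max_gap = 1L, del_max = 0.65,
                          dup_min = 1.35, min_span = 5000, smooth_k = 15L,
                          cnv_max_gap = 5L, min_windows = 4L,
                          whole_chrom_frac = 0.9,
                          mono_max = 0.65, tri_min = 1.35, tri_max = 1.75,
                          tet_min = 1.85, upd_hom_min = 0.9) {
  stopifnot(min_run >= 2, max_gap >= 0, del_max < 1, dup_min > 1,
            smooth_k %% 2 == 1, min_windows >= 1)
  p <- list(min_run = min_run, max_gap = max_gap, del_max = del_max,
            dup_min = dup_min, min_span = min_span, smooth_k = smooth_k,
            cnv_max_gap = cnv_max_gap, min_windows = min_windows,
            whole_chrom_frac = whole_chrom_frac,
            mono_max = mono_max, tri_min = tri_min, tri_max = tri_max,
            tet_min = tet_min, upd_hom_min = upd_hom_min)
  class(p) <- "CallerParams"
  p
}

#' Remove background mutations shared with the wild type
#'
#' Variants present in both the isolate and the wild-type call set (matched
#' on chromosome, position, ref and alt) are pre-existing background
#' mutations and are excluded; marker genotypes and the depth track are left
#' untouched. An empty wild-type set is the identity.
#'
#' @param isolate_calls,wt_calls `IsolateCallSet` objects on the same
#'   reference coordinates.
#' @return `isolate_calls` with background variants removed.
#' @export
filter_background <- function(isolate_calls, wt_calls) {
  v <- isolate_calls$variants
  w <- wt_calls$variants
  if (is.null(w) || !nrow(w) || is.null(v) || !nrow(v)) return(isolate_calls)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  keep <- !(key(v) %in% key(w))
  isolate_calls$variants <- v[keep, , drop = FALSE]
  rownames(isolate_calls$variants) <- NULL
  isolate_calls
}

#' Classify an SNV into one of six strand-collapsed types
#'
#' Maps a ref/alt base pair onto the six pyrimidine-reference substitution
#' classes; purine-reference mutations are reported by their pyrimidine-
#' strand equivalent (e.g. G>A is reported as C>T).
#'
#' @param ref,alt single bases (vectorized; equal lengths).
#' @return character vector over `{"C>T","C>A","C>G","T>C","T>A","T>G"}`.
#' @export
classify_snv <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases) ||
      any(nchar(ref) != 1) || any(nchar(alt) != 1))
    stop("classify_snv expects single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  paste0(r, ">", a)
}

#' Segment LOH tracts from marker genotypes
#'
#' Finds maximal runs of homozygous markers (at least `min_run` of them,
#' tolerating up to `max_gap` consecutive heterozygous miscalls between
#' successive homozygous markers). A run including a chromosome's first or
#' last marker is terminal (`T-LOH`); otherwise interstitial (`I-LOH`). The
#' genomic span runs from the first to the last homozygous marker of the
#' run.
#'
#' @param markers a [build_marker_map()] result (or data.frame with `chrom`,
#'   `pos`).
#' @param genotypes character vector aligned to `markers` rows; values
#'   containing `hom` are homozygous (e.g. `homA`, `homB`).
#' @param min_run,max_gap see [caller_params()].
#' @return data.frame with one row per segment: `chrom`, `start`, `end`
#'   (0-based half-open bp span), `first_marker`, `last_marker` (chromosome-
#'   local indices), `n_hom`, `subtype`, `parent` (majority homozygous
#'   parent, `A`/`B`, or `NA` when genotypes carry no parent-of-origin).
#' @export
call_loh_segments <- function(markers, genotypes, min_run = 10L,
                              max_gap = 1L) {
  if (length(genotypes) != nrow(markers))
    stop("genotype vector length must equal marker count")
  res <- list()
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    g <- genotypes[sel]
    hom <- grepl("hom", g)
    hi <- which(hom)
    if (!length(hi)) next
    grp <- cumsum(c(1L, diff(hi) - 1L > max_gap))
    for (gg in split(hi, grp)) {
      if (length(gg) < min_run) next
      nA <- sum(g[gg] == "homA"); nB <- sum(g[gg] == "homB")
      parent <- if (nA + nB == 0) NA_character_ else if (nA >= nB) "A" else "B"
      subtype <- if (gg[1] == 1L || gg[length(gg)] == length(sel)) "T-LOH"
                 else "I-LOH"
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = markers$pos[sel[gg[1]]] - 1,
        end = markers$pos[sel[gg[length(gg)]]],
        first_marker = gg[1], last_marker = gg[length(gg)],
        n_hom = length(gg), subtype = subtype, parent = parent,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), first_marker = integer(),
                      last_marker = integer(), n_hom = integer(),
                      subtype = character(), parent = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Recenter a depth track on its euploid baseline
#'
#' Median normalization of read depth misbehaves in highly aneuploid
#' genomes: when a large fraction of windows sits at 0.5x (several monosomic
#' chromosomes, long terminal deletions) the genome median no longer equals
#' the disomic coverage and every ratio is inflated. The caller therefore
#' recenters tracks on the modal (most common) window ratio -- the euploid
#' baseline -- before thresholding: the mode is located on a binned
#' histogram and refined as the median of ratios within +/- 0.15 of it.
#' Exact on noise-free data and idempotent up to floating-point error.
#'
#' @param depth data.frame with `chrom`, `start`, `end`, `ratio`.
#' @return the depth track with rescaled `ratio`.
#' @export
recenter_depth <- function(depth) {
  r <- depth$ratio[is.finite(depth$ratio)]
  med <- stats::median(r)
  if (!is.finite(med) || med < 0.5 || med > 2)
    stop(sprintf(paste0("depth track median is %.3f; normalize ratios to a ",
                        "genome median near 1 before calling"), med))
  use <- r >= 0.25 & r <= 2.5
  h <- graphics::hist(pmin(pmax(r[use], 0.25), 2.5),
                      breaks = seq(0.25, 2.5, by = 0.025), plot = FALSE)
  mode_ctr <- h$mids[which.max(h$counts)]
  base <- stats::median(r[abs(r - mode_ctr) < 0.15])
  depth$ratio <- depth$ratio / base
  depth
}

#' Segment copy-number variants from a normalized depth track
#'
#' Smooths each chromosome's window depth ratios with a running median, then
#' finds maximal runs of windows strictly below `del_max` (deletions) or
#' strictly above `dup_min` (duplications), bridging up to `cnv_max_gap`
#' non-qualifying windows. Runs spanning at least `min_span` bp are
#' reported; runs covering (nearly) the whole chromosome are excluded here
#' and left to the aneuploidy caller. A deletion reaching within one window
#' of a chromosome end is terminal (`T-Del`), otherwise interstitial
#' (`I-Del`); duplications are `Dup`.
#'
#' @param depth data.frame with `chrom`, `start`, `end`, `ratio`, windows
#'   sorted by position, normalized so the genome median is 1.
#' @param params a [caller_params()].
#' @return data.frame with `chrom`, `start`, `end`, `subtype`,
#'   `mean_ratio`, `n_windows`.
#' @export
call_cnv_segments <- function(depth, params = caller_params()) {
  depth <- recenter_depth(depth)
  res <- list()
  for (ch in unique(depth$chrom)) {
    d <- depth[depth$chrom == ch, ]
    r <- d$ratio
    sm <- if (length(r) >= params$smooth_k)
      stats::runmed(r, params$smooth_k, endrule = "keep") else r
    # a trailing window shorter than half the tile is too noisy to anchor
    # the terminal test; the previous window is the effective end
    W <- nrow(d)
    W_eff <- if (W > 1L &&
                 d$end[W] - d$start[W] < (d$end[1] - d$start[1]) / 2)
      W - 1L else W
    for (state in c("del", "dup")) {
      qual <- if (state == "del") sm < params$del_max else sm > params$dup_min
      qi <- which(qual)
      if (!length(qi)) next
      # windows of this state covering (nearly) the whole chromosome mean a
      # copy-number change of the chromosome itself, even when noise splits
      # the run: leave those to the aneuploidy caller
      if (length(qi) >= params$whole_chrom_frac * nrow(d)) next
      grp <- cumsum(c(1L, diff(qi) - 1L > params$cnv_max_gap))
      raw_qual <- if (state == "del") r < params$del_max else r > params$dup_min
      for (gg in split(qi, grp)) {
        if (length(gg) < params$min_windows) next
        w1 <- gg[1]; w2 <- gg[length(gg)]
        # smoothing erodes segment edges: refine boundaries outward on the
        # raw track, bridging isolated noisy windows (no-op on noise-free
        # data)
        walk_out <- function(w, dir) {
          j <- w + dir; gap <- 0L
          while (j >= 1L && j <= nrow(d) && gap <= params$cnv_max_gap) {
            if (raw_qual[j]) { w <- j; gap <- 0L } else gap <- gap + 1L
            j <- j + dir
          }
          w
        }
        w1 <- walk_out(w1, -1L)
        w2 <- walk_out(w2, 1L)
        if (w2 - w1 + 1L >= params$whole_chrom_frac * nrow(d)) next
        span_start <- d$start[w1]; span_end <- d$end[w2]
        if (span_end - span_start < params$min_span) next
        subtype <- if (state == "dup") "Dup"
                   else if (w1 <= 2L || w2 >= W_eff - 2L) "T-Del"
                   else "I-Del"
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = span_start, end = span_end, subtype = subtype,
          mean_ratio = mean(r[w1:w2]), n_windows = w2 - w1 + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), subtype = character(),
                      mean_ratio = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(match(out$chrom, unique(depth$chrom)), out$start), ]
}

#' Call whole-chromosome aneuploidy
#'
#' Classifies each chromosome from its mean normalized depth (computed over
#' windows outside called CNV segments) and its whole-chromosome
#' homozygous-marker fraction: monosomy (`Mon`) below `mono_max`, trisomy
#' (`Tri`) inside `(tri_min, tri_max)`, 4-5 copies (`Tet/Pen`) above
#' `tet_min`, and uniparental diploid (`UPD`) at disomic depth with a
#' homozygous fraction of at least `upd_hom_min`. Values exactly on a
#' threshold resolve toward euploid. Chromosomes with fewer than three
#' usable windows are flagged uncallable.
#'
#' @param depth normalized depth track (as in [call_cnv_segments()]).
#' @param markers,genotypes marker map and aligned genotype vector.
#' @param cnv_segments optional [call_cnv_segments()] result to mask.
#' @param params a [caller_params()].
#' @return data.frame with `chrom`, `subtype` (`euploid` when no call),
#'   `mean_ratio`, `hom_frac`, `uncallable`.
#' @export
call_aneuploidy <- function(depth, markers, genotypes,
                            cnv_segments = NULL, params = caller_params()) {
  depth <- recenter_depth(depth)
  res <- list()
  for (ch in unique(depth$chrom)) {
    d <- depth[depth$chrom == ch, ]
    use <- rep(TRUE, nrow(d))
    if (!is.null(cnv_segments) && nrow(cnv_segments)) {
      seg <- cnv_segments[cnv_segments$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(seg)))
        use <- use & !(d$start < seg$end[j] & d$end > seg$start[j])
    }
    msel <- markers$chrom == ch
    hom_frac <- if (any(msel)) mean(grepl("hom", genotypes[msel])) else NA_real_
    if (sum(use) < 3L) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, subtype = NA_character_, mean_ratio = NA_real_,
        hom_frac = hom_frac, uncallable = TRUE, stringsAsFactors = FALSE)
      next
    }
    m <- mean(d$ratio[use])
    subtype <-
      if (m < params$mono_max) "Mon"
      else if (m > params$tri_min && m < params$tri_max) "Tri"
      else if (m > params$tet_min) "Tet/Pen"
      else if (m > params$mono_max && m < params$tri_min &&
               !is.na(hom_frac) && hom_frac >= params$upd_hom_min) "UPD"
      else "euploid"
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch, subtype = subtype, mean_ratio = m, hom_frac = hom_frac,
      uncallable = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Assemble a classified event table for one isolate
#'
#' Aggregates filtered variant records, LOH segments, CNV segments and
#' aneuploidy calls into one row per event. SNVs carry the six-type
#' strand-collapsed subtype, InDels `ins`/`del` (ref/alt length difference,
#' capped at 50 bp -- larger losses must show in depth and belong to CRs).
#' To keep classes exclusive, LOH segments that overlap a called deletion,
#' or that lie on a chromosome called `Mon` or `UPD`, are absorbed into the
#' corresponding CR/aneuploidy event; CNV segments and LOH segments on
#' aneuploid chromosomes other than those are kept. Duplicate spans within
#' a class are deduplicated with a warning.
#'
#' @param isolate isolate identifier.
#' @param variants filtered variant records (data.frame as in
#'   `IsolateCallSet`).
#' @param loh [call_loh_segments()] result.
#' @param cnv [call_cnv_segments()] result.
#' @param aneuploidy [call_aneuploidy()] result.
#' @param layout a [genome_layout()] (for aneuploidy spans and ordering).
#' @return data.frame of class `EventTable` with columns `isolate`, `class`,
#'   `subtype`, `chrom`, `start`, `end`, `support`.
#' @export
build_event_table <- function(isolate, variants = NULL, loh = NULL,
                              cnv = NULL, aneuploidy = NULL, layout = NULL) {
  rows <- list()
  if (!is.null(variants) && nrow(variants)) {
    is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
    if (any(is_snv)) {
      v <- variants[is_snv, ]
      rows$snv <- data.frame(
        isolate = isolate, class = "SNV",
        subtype = classify_snv(v$ref, v$alt), chrom = v$chrom,
        start = v$pos - 1, end = as.numeric(v$pos), support = v$af,
        stringsAsFactors = FALSE)
    }
    if (any(!is_snv)) {
      v <- variants[!is_snv, ]
      del <- nchar(v$ref) > nchar(v$alt)
      len <- abs(nchar(v$ref) - nchar(v$alt))
      if (any(len > 50L))
        warning("indel longer than 50 bp in variant records; kept as InDel")
      rows$indel <- data.frame(
        isolate = isolate, class = "InDel",
        subtype = ifelse(del, "del", "ins"), chrom = v$chrom,
        start = ifelse(del, v$pos, v$pos - 1),
        end = ifelse(del, v$pos + len, v$pos), support = v$af,
        stringsAsFactors = FALSE)
    }
  }
  an_absorb <- character()
  if (!is.null(aneuploidy) && nrow(aneuploidy)) {
    an <- aneuploidy[!aneuploidy$uncallable &
                     !aneuploidy$subtype %in% c("euploid", NA), , drop = FALSE]
    an_absorb <- an$chrom[an$subtype %in% c("Mon", "UPD")]
    if (nrow(an)) {
      len <- if (!is.null(layout)) layout$length[match(an$chrom, layout$chrom)]
             else NA_real_
      rows$an <- data.frame(
        isolate = isolate, class = "aneuploidy", subtype = an$subtype,
        chrom = an$chrom, start = 0, end = as.numeric(len),
        support = an$mean_ratio, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cnv) && nrow(cnv)) {
    rows$cnv <- data.frame(
      isolate = isolate, class = "CR", subtype = cnv$subtype,
      chrom = cnv$chrom, start = cnv$start, end = cnv$end,
      support = cnv$mean_ratio, stringsAsFactors = FALSE)
  }
  if (!is.null(loh) && nrow(loh)) {
    keep <- !(loh$chrom %in% an_absorb)
    if (!is.null(cnv) && nrow(cnv)) {
      dels <- cnv[cnv$subtype %in% c("T-Del", "I-Del"), , drop = FALSE]
      for (j in seq_len(nrow(dels)))
        keep <- keep & !(loh$chrom == dels$chrom[j] &
                         loh$start < dels$end[j] & loh$end > dels$start[j])
    }
    l <- loh[keep, , drop = FALSE]
    if (nrow(l))
      rows$loh <- data.frame(
        isolate = isolate, class = "LOH", subtype = l$subtype,
        chrom = l$chrom, start = l$start, end = l$end, support = l$n_hom,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(isolate = character(), class = character(),
               subtype = character(), chrom = character(), start = numeric(),
               end = numeric(), support = numeric(), stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("class", "chrom", "start", "end")])
  if (any(dup)) {
    warning(sprintf("%d duplicate event span(s) deduplicated", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("EventTable", "data.frame")
  out
}

#' Call all events for one isolate
#'
#' Convenience wrapper: background filtering, LOH segmentation, CNV
#' segmentation, aneuploidy classification, and event-table assembly.
#'
#' @param callset an `IsolateCallSet` with `variants`, `marker_geno`,
#'   `depth`.
#' @param wt wild-type `IsolateCallSet` for background filtering (or NULL).
#' @param markers the marker map the genotype vector is aligned to.
#' @param layout a [genome_layout()].
#' @param params a [caller_params()].
#' @return an `EventTable` for the isolate.
#' @export
call_isolate_events <- function(callset, wt, markers, layout,
                                params = caller_params()) {
  filt <- if (is.null(wt)) callset else filter_background(callset, wt)
  loh <- call_loh_segments(markers, callset$marker_geno,
                           min_run = params$min_run, max_gap = params$max_gap)
  cnv <- call_cnv_segments(callset$depth, params)
  an <- call_aneuploidy(callset$depth, markers, callset$marker_geno,
                        cnv_segments = cnv, params = params)
  build_event_table(callset$id, filt$variants, loh, cnv, an, layout)
}

#' Call events for every isolate of a simulation or cohort
#'
#' @param sim an `MASimulation` (or a list with `isolates`, `wt`, `markers`,
#'   `layout`).
#' @param params a [caller_params()].
#' @return a combined `EventTable` across isolates.
#' @export
call_cohort_events <- function(sim, params = caller_params()) {
  tabs <- lapply(sim$isolates, call_isolate_events, wt = sim$wt,
                 markers = sim$markers, layout = sim$layout, params = params)
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  class(out) <- c("EventTable", "data.frame")
  out
}

#' Write / read an event table as TSV
#'
#' Fixed column order: isolate, class, subtype, chrom, start, end, support.
#'
#' @param events an `EventTable`.
#' @param path file path.
#' @return `path` (writer) or the `EventTable` (reader).
#' @export
write_event_table <- function(events, path) {
  cols <- c("isolate", "class", "subtype", "chrom", "start", "end", "support")
  utils::write.table(as.data.frame(events)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(isolate = "character",
                                        chrom = "character"))
  class(d) <- c("EventTable", "data.frame")
  d
}
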