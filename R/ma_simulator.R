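#' Simulation configuration for mutation-accumulation lineages
#'
#' Defines the conditions of a simulated MA experiment on a hybrid diploid:
#' the passaging design (`isolates` x `passages` x `generations_per_passage`
#' cell divisions), per-division event rates for the five variation classes,
#' subtype spectra, sequencing-noise parameters, and APOBEC3B (A3B)
#' mutagenesis parameters.
#'
#' Default rates and subtype weights emulate an RFA-depleted hybrid diploid
#' cohort: per-division rates of 4.28e-2 (SNV), 1.45e-2 (InDel), 3.13e-2
#' (LOH) and 1.41e-2 (CR); deletions 65.7% of InDels, terminal LOH 65.8% of
#' LOH, terminal deletions 48.6% of CRs, and monosomy 83.7% of aneuploidy
#' events.
#'
#' @param seed integer RNG seed; all simulator output is deterministic given
#'   the full configuration.
#' @param isolates number of MA isolates (s).
#' @param passages number of subculture passages (n).
#' @param generations_per_passage generations per passage (default 24).
#' @param rates named numeric vector of per-division event rates for classes
#'   `SNV`, `InDel`, `LOH`, `CR`, `aneuploidy`.
#' @param snv_weights spectrum over the six strand-collapsed SNV types.
#' @param indel_weights weights for `ins` vs `del`.
#' @param loh_weights weights for `T-LOH` vs `I-LOH`.
#' @param cr_weights weights for `T-Del`, `I-Del`, `Dup`.
#' @param aneuploidy_weights weights for `Mon`, `UPD`, `Tri`, `Tet/Pen`.
#' @param marker_density heterozygous markers per bp (default 1/400).
#' @param mean_depth mean sequencing depth per window (default 50).
#' @param depth_dispersion negative-binomial overdispersion of window read
#'   counts (variance = m + dispersion * m^2); 0 means noise-free depth.
#' @param marker_miscall per-marker genotype miscall probability; 0 means
#'   exact genotypes.
#' @param af_noise 1 = allele fractions resampled binomially given depth;
#'   0 = exact.
#' @param a3b_rate per-division rate of A3B-signature mutations (default 0;
#'   set > 0 to emulate the A3B ssDNA-exposure assay).
#' @param lagging_bias probability in [0.5, 1] that an A3B mutation falls on
#'   the lagging-strand template of the nearest-origin fork.
#' @param background_variants number of shared pre-existing variants injected
#'   into every isolate and the wild-type call set (exercises the
#'   background-mutation filter).
#' @param depth_window depth-track window size in bp (default 1000).
#' @param origin_spacing mean replication-origin spacing in bp (default
#'   40000).
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       isolates = 31L,
                       passages = 5L,
                       generations_per_passage = 24L,
                       rates = c(SNV = 4.28e-2, InDel = 1.45e-2,
                                 LOH = 3.13e-2, CR = 1.41e-2,
                                 aneuploidy = 1.2e-2),
                       snv_weights = c("C>T" = 0.40, "C>A" = 0.12,
                                       "C>G" = 0.08, "T>C" = 0.25,
                                       "T>A" = 0.08, "T>G" = 0.07),
                       indel_weights = c(ins = 0.343, del = 0.657),
                       loh_weights = c("T-LOH" = 0.658, "I-LOH" = 0.342),
                       cr_weights = c("T-Del" = 0.486, "I-Del" = 0.30,
                                      "Dup" = 0.214),
                       aneuploidy_weights = c(Mon = 0.837, UPD = 0.06,
                                              Tri = 0.07, "Tet/Pen" = 0.033),
                       marker_density = 1 / 400,
                       mean_depth = 50,
                       depth_dispersion = 0.005,
                       marker_miscall = 0.002,
                       af_noise = 1,
                       a3b_rate = 0,
                       lagging_bias = 0.9,
                       background_variants = 30L,
                       depth_window = 1000L,
                       origin_spacing = 40000L) {
  stopifnot(isolates >= 1, passages >= 1, generations_per_passage >= 1,
            all(rates >= 0), marker_density > 0, mean_depth > 0,
            depth_dispersion >= 0, marker_miscall >= 0, marker_miscall < 1,
            a3b_rate >= 0, lagging_bias >= 0.5, lagging_bias <= 1,
            depth_window >= 100)
  need <- c("SNV", "InDel", "LOH", "CR", "aneuploidy")
  if (!all(need %in% names(rates))) stop("rates must name all five classes")
  norm1 <- function(w) {
    if (any(w < 0) || sum(w) <= 0) stop("subtype weights must be >= 0, sum > 0")
    w / sum(w)
  }
  cfg <- list(seed = as.integer(seed), isolates = as.integer(isolates),
              passages = as.integer(passages),
              generations_per_passage = as.integer(generations_per_passage),
              rates = rates[need],
              snv_weights = norm1(snv_weights),
              indel_weights = norm1(indel_weights),
              loh_weights = norm1(loh_weights),
              cr_weights = norm1(cr_weights),
              aneuploidy_weights = norm1(aneuploidy_weights),
              marker_density = marker_density, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              marker_miscall = marker_miscall, af_noise = af_noise,
              a3b_rate = a3b_rate, lagging_bias = lagging_bias,
              background_variants = as.integer(background_variants),
              depth_window = as.integer(depth_window),
              origin_spacing = as.integer(origin_spacing))
  class(cfg) <- "SimConfig"
  cfg
}

#' Set all noise parameters of a configuration to zero
#'
#' Convenience for end-to-end recovery checks: depth becomes the exact
#' expected copy ratio, marker genotypes are exact, and allele fractions are
#' exact.
#'
#' @param config a [sim_config()].
#' @return the modified configuration.
#' @export
zero_noise <- function(config) {
  config$depth_dispersion <- 0
  config$marker_miscall <- 0
  config$af_noise <- 0
  config
}

# prefix-stable per-stream seeds so isolate k is reproducible independently
# of the number of isolates
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

#' Build a heterozygous marker map for a hybrid diploid
#'
#' Places markers along each chromosome as a Poisson process with the given
#' mean density and assigns each a pair of parental alleles (the two alleles
#' distinguishing the parental haplotypes).
#'
#' @param layout a [genome_layout()].
#' @param density markers per bp (> 0).
#' @param seed RNG seed.
#' @return data.frame of class `MarkerMap` with columns `chrom`, `pos`
#'   (1-based, strictly increasing per chromosome), `a`, `b` (parental
#'   alleles).
#' @export
build_marker_map <- function(layout, density, seed = 1L) {
  if (density <= 0) stop("marker density must be > 0")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    m <- stats::rpois(1, len * density)
    if (m < 2)
      stop(sprintf("chromosome %s received %d markers; increase density",
                   layout$chrom[i], m))
    pos <- sort(sample.int(len, m))
    a <- sample(bases, m, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), "")
    data.frame(chrom = layout$chrom[i], pos = pos, a = a, b = b,
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, rows)
  rownames(mk) <- NULL
  class(mk) <- c("MarkerMap", "data.frame")
  mk
}

#' Build a replication-origin map
#'
#' Places origins at roughly regular spacing with uniform jitter; every
#' chromosome receives at least two origins so inter-origin intervals exist.
#'
#' @param layout a [genome_layout()].
#' @param spacing mean inter-origin distance in bp.
#' @param seed RNG seed.
#' @return data.frame of class `OriginMap` with columns `chrom`, `pos`
#'   (1-based midpoints, strictly increasing per chromosome).
#' @export
build_origin_map <- function(layout, spacing = 40000L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    m <- max(2L, round(len / spacing))
    base <- seq(spacing / 2, len - spacing / 2, length.out = m)
    pos <- round(base + stats::runif(m, -spacing / 4, spacing / 4))
    pos <- sort(unique(pmin(pmax(pos, 1), len)))
    data.frame(chrom = layout$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  om <- do.call(rbind, rows)
  rownames(om) <- NULL
  class(om) <- c("OriginMap", "data.frame")
  om
}

## ---- internal planting helpers --------------------------------------------

sample_weighted <- function(values, weights, n = 1) {
  values[sample.int(length(values), n, replace = TRUE, prob = weights)]
}

# sample one element of a vector (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

# does [start, end) overlap any occupied interval (inflated by pad)?
overlaps_occupied <- function(start, end, occ, pad) {
  if (is.null(occ) || !nrow(occ)) return(FALSE)
  any(start < occ$end + pad & end > occ$start - pad)
}

random_snv_pair <- function(type) {
  # type is a strand-collapsed class like "C>T"; emit the pyrimidine- or
  # purine-reference representation with equal probability
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- substr(type, 1, 1); alt <- substr(type, 3, 3)
  if (stats::runif(1) < 0.5) c(ref, alt) else c(comp[[ref]], comp[[alt]])
}

random_indel <- function(subtype, len) {
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, 1)
  extra <- paste(sample(bases, len, replace = TRUE), collapse = "")
  if (subtype == "del") c(paste0(anchor, extra), anchor)
  else c(anchor, paste0(anchor, extra))
}

## ---- lineage simulation ----------------------------------------------------

#' Simulate mutation-accumulation lineages
#'
#' Generates, for each isolate, a ground-truth event log and the rendered
#' sequencing observables: variant records (SNVs, InDels, A3B mutations,
#' shared background variants), a marker genotype vector, and a normalized
#' window depth track. Event counts per class are Poisson with mean
#' rate x passages x generations_per_passage. Events are rendered as:
#'
#' * SNV / A3B mutation: heterozygous variant record, allele fraction 0.5;
#' * InDel: 1-50 bp insertion or deletion record;
#' * I-LOH / T-LOH: a run of homozygous markers (internal, or anchored at a
#'   chromosome end);
#' * I-Del / Dup: 0.5x / 1.5x depth over an internal window-aligned span
#'   (deletions also render hemizygous markers as homozygous);
#' * T-Del: 0.5x depth from a breakpoint to the chromosome end, with
#'   homozygous markers in the span;
#' * Mon / UPD / Tri / Tet/Pen: whole-chromosome depth 0.5x / 1.0x / 1.5x /
#'   2.0-2.5x, with fully homozygous markers for Mon and UPD.
#'
#' Span collisions on the same homolog are resampled up to a retry cap, then
#' skipped. A shared background-variant set is injected into every isolate
#' and into the returned wild-type call set.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()] (default [default_genome_layout()]).
#' @param markers a [build_marker_map()] result; built from the
#'   configuration's density when omitted.
#' @return list of class `MASimulation` with elements `config`, `layout`,
#'   `markers`, `origins`, `truth` (the true event log), `a3b_truth`,
#'   `isolates` (list of `IsolateCallSet`), `wt` (wild-type call set) and
#'   `n_skipped`.
#' @export
simulate_lineages <- function(config, layout = default_genome_layout(),
                              markers = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(markers))
    markers <- build_marker_map(layout, config$marker_density,
                                seed = derive_seed(config$seed, 900001))
  origins <- build_origin_map(layout, config$origin_spacing,
                              seed = derive_seed(config$seed, 900002))
  bg <- simulate_background_variants(config, layout)
  mk_idx <- split(seq_len(nrow(markers)), markers$chrom)
  res <- lapply(seq_len(config$isolates), function(k)
    simulate_one_isolate(k, config, layout, markers, mk_idx, origins, bg))
  truth <- do.call(rbind, c(lapply(res, `[[`, "truth"),
                            list(make.row.names = FALSE)))
  a3b <- do.call(rbind, c(lapply(res, `[[`, "a3b"),
                          list(make.row.names = FALSE)))
  wt <- list(id = "WT", variants = bg,
             marker_geno = rep("het", nrow(markers)),
             depth = render_depth(layout, config,
                                  seed = derive_seed(config$seed, 900003),
                                  ratios = NULL))
  class(wt) <- "IsolateCallSet"
  out <- list(config = config, layout = layout, markers = markers,
              origins = origins, truth = truth, a3b_truth = a3b,
              isolates = lapply(res, `[[`, "callset"), wt = wt,
              n_skipped = sum(vapply(res, `[[`, 0L, "skipped")))
  class(out) <- "MASimulation"
  out
}

simulate_background_variants <- function(config, layout) {
  set.seed(derive_seed(config$seed, 900004))
  n <- config$background_variants
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), af = numeric(),
                      depth = numeric(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ch <- sample(layout$chrom, n, replace = TRUE,
               prob = layout$length / sum(layout$length))
  pos <- vapply(match(ch, layout$chrom),
                function(i) sample.int(layout$length[i], 1), 0L)
  pairs <- t(vapply(sample_weighted(names(config$snv_weights),
                                    config$snv_weights, n),
                    random_snv_pair, c("", "")))
  data.frame(chrom = ch, pos = pos, ref = pairs[, 1], alt = pairs[, 2],
             genotype = "het", af = 0.5, depth = config$mean_depth,
             stringsAsFactors = FALSE)
}

# expected copy-ratio per depth window for one chromosome given a base
# multiplier and CNV spans
simulate_one_isolate <- function(k, config, layout, markers, mk_idx,
                                 origins, bg) {
  set.seed(derive_seed(config$seed, k))
  divisions <- config$passages * config$generations_per_passage
  counts <- vapply(config$rates, function(r) stats::rpois(1, r * divisions), 0L)
  n_a3b <- stats::rpois(1, config$a3b_rate * divisions)
  win <- config$depth_window
  pad <- 5000                      # bp margin kept clear around planted spans
  retry_cap <- 20L

  n_chr <- nrow(layout)
  W <- ceiling(layout$length / win)        # windows per chromosome
  ratio_mult <- rep(1, n_chr)              # whole-chromosome multiplier
  cnv <- vector("list", n_chr)             # per-chrom CNV spans (bp + ratio)
  occupied <- vector("list", n_chr)        # planted spans, bp
  geno <- rep("het", nrow(markers))
  hom_frac_budget <- rep(0, n_chr)         # keep chroms distinguishable from UPD
  id <- sprintf("iso%03d", k)
  truth <- list(); skipped <- 0L

  add_truth <- function(class, subtype, chrom, start, end) {
    truth[[length(truth) + 1L]] <<- data.frame(
      isolate = id, class = class, subtype = subtype, chrom = chrom,
      start = start, end = end, stringsAsFactors = FALSE)
  }
  set_hom <- function(idx) {
    parent <- sample(c("homA", "homB"), 1)
    geno[idx] <<- parent
    parent
  }

  ## -- aneuploidy: whole chromosomes, at most one event per chromosome
  n_an <- min(counts[["aneuploidy"]], n_chr)
  if (n_an < counts[["aneuploidy"]]) skipped <- skipped + counts[["aneuploidy"]] - n_an
  an_chr <- if (n_an > 0) sample.int(n_chr, n_an) else integer()
  for (ci in an_chr) {
    sub <- sample_weighted(names(config$aneuploidy_weights),
                           config$aneuploidy_weights)
    ratio_mult[ci] <- switch(sub, Mon = 0.5, UPD = 1.0, Tri = 1.5,
                             "Tet/Pen" = sample(c(2.0, 2.5), 1))
    if (sub %in% c("Mon", "UPD")) set_hom(mk_idx[[layout$chrom[ci]]])
    occupied[[ci]] <- data.frame(start = 0, end = layout$length[ci])
    add_truth("aneuploidy", sub, layout$chrom[ci], 0, layout$length[ci])
  }
  free_chr <- setdiff(seq_len(n_chr), an_chr)

  ## -- chromosomal rearrangements (window-aligned spans)
  for (e in seq_len(counts[["CR"]])) {
    sub <- sample_weighted(names(config$cr_weights), config$cr_weights)
    placed <- FALSE
    for (try in seq_len(if (length(free_chr)) retry_cap else 0L)) {
      ci <- sample_weighted(free_chr, layout$length[free_chr])
      Wc <- W[ci]
      if (sub == "T-Del") {
        w1 <- sample1(seq(max(3L, floor(Wc * 0.3)), Wc - 10L))
        w2 <- Wc
      } else {
        span_w <- sample1(10:60)
        if (Wc - span_w - 4L < 3L) next
        w1 <- sample1(3:(Wc - span_w - 2L))
        w2 <- w1 + span_w - 1L
      }
      start <- (w1 - 1) * win
      end <- min(w2 * win, layout$length[ci])
      mk <- mk_idx[[layout$chrom[ci]]]
      in_span <- mk[markers$pos[mk] > start & markers$pos[mk] <= end]
      hom_load <- if (sub == "Dup") 0 else length(in_span) / length(mk)
      if (overlaps_occupied(start, end, occupied[[ci]], pad)) next
      if (hom_frac_budget[ci] + hom_load > 0.6) next
      occupied[[ci]] <- rbind(occupied[[ci]],
                              data.frame(start = start, end = end))
      hom_frac_budget[ci] <- hom_frac_budget[ci] + hom_load
      cnv[[ci]] <- rbind(cnv[[ci]],
                         data.frame(w1 = w1, w2 = w2,
                                    ratio = if (sub == "Dup") 1.5 else 0.5))
      if (sub != "Dup" && length(in_span)) set_hom(in_span)
      add_truth("CR", sub, layout$chrom[ci], start, end)
      placed <- TRUE
      break
    }
    if (!placed) skipped <- skipped + 1L
  }

  ## -- LOH events: runs of homozygous markers
  for (e in seq_len(counts[["LOH"]])) {
    sub <- sample_weighted(names(config$loh_weights), config$loh_weights)
    placed <- FALSE
    for (try in seq_len(if (length(free_chr)) retry_cap else 0L)) {
      ci <- sample_weighted(free_chr, layout$length[free_chr])
      mk <- mk_idx[[layout$chrom[ci]]]
      M <- length(mk)
      if (M < 40L) next
      if (sub == "T-LOH") {
        run <- sample1(10:max(10L, floor(M * 0.3)))
        at_end <- stats::runif(1) < 0.5
        sel <- if (at_end) mk[(M - run + 1L):M] else mk[1:run]
      } else {
        run <- sample1(10:max(10L, floor(M * 0.2)))
        if (M - run - 2L < 2L) next
        i1 <- sample1(2:(M - run))
        sel <- mk[i1:(i1 + run - 1L)]
      }
      start <- markers$pos[sel[1]] - 1
      end <- markers$pos[sel[length(sel)]]
      if (overlaps_occupied(start, end, occupied[[ci]], pad)) next
      if (hom_frac_budget[ci] + length(sel) / M > 0.6) next
      occupied[[ci]] <- rbind(occupied[[ci]],
                              data.frame(start = start, end = end))
      hom_frac_budget[ci] <- hom_frac_budget[ci] + length(sel) / M
      set_hom(sel)
      add_truth("LOH", sub, layout$chrom[ci], start, end)
      placed <- TRUE
      break
    }
    if (!placed) skipped <- skipped + 1L
  }

  ## -- point variants: SNVs, InDels, A3B-signature mutations
  variants <- list()
  used_pos <- character()
  fresh_position <- function(ci) {
    for (try in 1:50) {
      p <- sample.int(layout$length[ci], 1)
      key <- paste(layout$chrom[ci], p)
      if (!key %in% used_pos) {
        used_pos <<- c(used_pos, key)
        return(p)
      }
    }
    stop("could not sample a fresh variant position")
  }
  for (e in seq_len(counts[["SNV"]])) {
    typ <- sample_weighted(names(config$snv_weights), config$snv_weights)
    ci <- sample_weighted(seq_len(n_chr), layout$length)
    p <- fresh_position(ci)
    pair <- random_snv_pair(typ)
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = layout$chrom[ci], pos = p, ref = pair[1], alt = pair[2],
      genotype = "het", af = 0.5, depth = config$mean_depth,
      stringsAsFactors = FALSE)
    add_truth("SNV", typ, layout$chrom[ci], p - 1, p)
  }
  for (e in seq_len(counts[["InDel"]])) {
    sub <- sample_weighted(names(config$indel_weights), config$indel_weights)
    len <- sample.int(50L, 1)
    ci <- sample_weighted(seq_len(n_chr), layout$length)
    p <- fresh_position(ci)
    ra <- random_indel(sub, len)
    span <- if (sub == "del") c(p, p + len) else c(p - 1, p)
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = layout$chrom[ci], pos = p, ref = ra[1], alt = ra[2],
      genotype = "het", af = 0.5, depth = config$mean_depth,
      stringsAsFactors = FALSE)
    add_truth("InDel", sub, layout$chrom[ci], span[1], span[2])
  }
  a3b <- list()
  org_idx <- split(seq_len(nrow(origins)), origins$chrom)
  for (e in seq_len(n_a3b)) {
    ci <- sample_weighted(seq_len(n_chr), layout$length)
    op <- origins$pos[org_idx[[layout$chrom[ci]]]]
    ivl <- sample_weighted(seq_len(length(op) - 1L), diff(op))
    f <- stats::runif(1)
    lagging <- stats::runif(1) < config$lagging_bias
    # top-strand class implied by template and fork side (forks meet at the
    # interval midpoint): lagging template is the top strand left of the
    # midpoint and the bottom strand right of it
    cls <- if (lagging) (if (f < 0.5) "C>T" else "G>A")
           else         (if (f < 0.5) "G>A" else "C>T")
    p <- op[ivl] + floor(f * (op[ivl + 1L] - op[ivl]))
    key <- paste(layout$chrom[ci], p)
    if (key %in% used_pos) next
    used_pos <- c(used_pos, key)
    pair <- if (cls == "C>T") c("C", "T") else c("G", "A")
    variants[[length(variants) + 1L]] <- data.frame(
      chrom = layout$chrom[ci], pos = p, ref = pair[1], alt = pair[2],
      genotype = "het", af = 0.5, depth = config$mean_depth,
      stringsAsFactors = FALSE)
    # truth log carries the strand-collapsed six-type label; the A3B log
    # keeps the top-strand class
    add_truth("SNV", "C>T", layout$chrom[ci], p - 1, p)
    a3b[[length(a3b) + 1L]] <- data.frame(
      isolate = id, chrom = layout$chrom[ci], pos = p, class = cls,
      f = f, template = if (lagging) "lagging" else "leading",
      stringsAsFactors = FALSE)
  }

  ## -- render observables
  variants <- if (length(variants))
    rbind(bg, do.call(rbind, variants)) else bg
  variants <- variants[order(match(variants$chrom, layout$chrom),
                             variants$pos), ]
  rownames(variants) <- NULL
  if (config$af_noise > 0 && nrow(variants)) {
    dp <- pmax(1, stats::rpois(nrow(variants), variants$depth))
    variants$depth <- dp
    variants$af <- stats::rbinom(nrow(variants), dp, variants$af) / dp
  }
  geno_obs <- geno
  if (config$marker_miscall > 0) {
    flip <- stats::runif(length(geno)) < config$marker_miscall
    if (any(flip)) {
      states <- c("het", "homA", "homB")
      geno_obs[flip] <- vapply(geno[flip],
                               function(g) sample(setdiff(states, g), 1), "")
    }
  }
  depth <- render_depth(layout, config, seed = NULL,
                        ratios = list(mult = ratio_mult, cnv = cnv))
  callset <- list(id = id, variants = variants, marker_geno = geno_obs,
                  depth = depth)
  class(callset) <- "IsolateCallSet"
  truth <- if (length(truth))
    do.call(rbind, c(truth, list(make.row.names = FALSE))) else
    data.frame(isolate = character(), class = character(),
               subtype = character(), chrom = character(), start = numeric(),
               end = numeric(), stringsAsFactors = FALSE)
  a3b <- if (length(a3b))
    do.call(rbind, c(a3b, list(make.row.names = FALSE))) else
    data.frame(isolate = character(), chrom = character(), pos = integer(),
               class = character(), f = numeric(), template = character(),
               stringsAsFactors = FALSE)
  list(callset = callset, truth = truth, a3b = a3b, skipped = skipped)
}

# window depth track: expected copy ratio per window, negative-binomial read
# sampling (dispersion 0 = deterministic), normalized to genome median
render_depth <- function(layout, config, seed = NULL, ratios = NULL) {
  if (!is.null(seed)) set.seed(seed)
  win <- config$depth_window
  rows <- lapply(seq_len(nrow(layout)), function(ci) {
    len <- layout$length[ci]
    Wc <- ceiling(len / win)
    starts <- (seq_len(Wc) - 1) * win
    ends <- pmin(starts + win, len)
    cw <- rep(if (is.null(ratios)) 1 else ratios$mult[ci], Wc)
    if (!is.null(ratios) && !is.null(ratios$cnv[[ci]])) {
      for (j in seq_len(nrow(ratios$cnv[[ci]]))) {
        s <- ratios$cnv[[ci]][j, ]
        cw[s$w1:s$w2] <- s$ratio
      }
    }
    data.frame(chrom = layout$chrom[ci], start = starts, end = ends,
               ratio = cw, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  if (config$depth_dispersion > 0) {
    mu <- d$ratio * config$mean_depth * (d$end - d$start) / win
    counts <- stats::rnbinom(nrow(d), mu = mu,
                             size = 1 / config$depth_dispersion)
    d$ratio <- counts / (config$mean_depth * (d$end - d$start) / win)
  }
  med <- stats::median(d$ratio)
  if (med <= 0) stop("degenerate depth track: non-positive median")
  d$ratio <- d$ratio / med
  d
}
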