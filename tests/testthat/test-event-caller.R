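test_that("background filtering is a keyed set difference", {
  mkset <- function(n, seed) {
    set.seed(seed)
    data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
               pos = sample.int(5000, n, TRUE),
               ref = sample(c("A", "C"), n, TRUE),
               alt = sample(c("G", "T"), n, TRUE),
               genotype = "het", af = 0.5, depth = 50,
               stringsAsFactors = FALSE)
  }
  iso <- list(id = "x", variants = mkset(200, 1))
  wt <- list(id = "WT", variants = mkset(150, 2))
  out <- filter_background(iso, wt)$variants
  # brute-force oracle on (chrom, pos, ref, alt)
  k <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  expect_setequal(k(out), setdiff(k(iso$variants), k(wt$variants)))
  # identity and annihilation
  expect_equal(nrow(filter_background(iso, list(variants = NULL))$variants),
               nrow(iso$variants))
  expect_equal(nrow(filter_background(iso, iso)$variants), 0)
})

test_that("SNV classification collapses strands into six types", {
  expect_equal(classify_snv("G", "A"), "C>T")
  expect_equal(classify_snv("T", "C"), "T>C")
  # all 12 ordered pairs: exactly two per class
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_snv(pairs$ref, pairs$alt)
  expect_equal(sort(unique(cls)),
               sort(c("C>T", "C>A", "C>G", "T>C", "T>A", "T>G")))
  expect_true(all(table(cls) == 2))
  expect_error(classify_snv("A", "A"), "differ")
  expect_error(classify_snv("AC", "A"), "single")
})

test_that("LOH segmentation matches a regex run-length oracle", {
  # oracle: encode genotypes as H/E, find maximal runs bridging single-E
  # gaps with a greedy regex, keep runs with enough H
  loh_oracle <- function(geno, min_run, max_gap) {
    s <- paste(ifelse(grepl("hom", geno), "H", "E"), collapse = "")
    pat <- sprintf("H(?:E{1,%d}H|H)*", max_gap)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    res <- NULL
    for (i in seq_along(m)) {
      a <- m[i]; b <- m[i] + attr(m, "match.length")[i] - 1L
      nh <- sum(strsplit(substr(s, a, b), "")[[1]] == "H")
      if (nh >= min_run) res <- rbind(res, c(a, b, nh))
    }
    res
  }
  set.seed(31)
  mk <- data.frame(chrom = "c1", pos = cumsum(sample.int(500, 120, TRUE)))
  for (rep in 1:200) {
    geno <- sample(c("het", "homA", "homB"), 120, TRUE,
                   prob = c(0.55, 0.25, 0.20))
    got <- call_loh_segments(mk, geno, min_run = 4, max_gap = 1)
    want <- loh_oracle(geno, 4, 1)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$first_marker, want[, 1])
      expect_equal(got$last_marker, want[, 2])
      expect_equal(got$n_hom, want[, 3])
      expect_equal(got$start, mk$pos[want[, 1]] - 1)
      expect_equal(got$end, mk$pos[want[, 2]])
    }
  }
})

test_that("LOH subtype and edge cases behave", {
  mk <- data.frame(chrom = "c1", pos = seq(1000, 100000, by = 1000))
  n <- nrow(mk)
  expect_equal(nrow(call_loh_segments(mk, rep("het", n))), 0)
  g <- rep("het", n); g[(n - 29):n] <- "homB"
  seg <- call_loh_segments(mk, g, min_run = 10)
  expect_equal(seg$subtype, "T-LOH")
  expect_equal(seg$parent, "B")
  g2 <- rep("het", n); g2[20:40] <- "homA"
  expect_equal(call_loh_segments(mk, g2, min_run = 10)$subtype, "I-LOH")
  expect_error(call_loh_segments(mk, rep("het", 5)), "length")
})

test_that("CNV segmentation finds planted runs and rejects raw counts", {
  win <- 1000
  mkdepth <- function(ratio_by_chrom) {
    do.call(rbind, lapply(names(ratio_by_chrom), function(ch) {
      r <- ratio_by_chrom[[ch]]
      data.frame(chrom = ch, start = (seq_along(r) - 1) * win,
                 end = seq_along(r) * win, ratio = r,
                 stringsAsFactors = FALSE)
    }))
  }
  flat <- mkdepth(list(c1 = rep(1, 300), c2 = rep(1, 250)))
  expect_equal(nrow(call_cnv_segments(flat)), 0)
  # 0.5x from window 200 to the end of c1: one terminal deletion
  td <- flat; td$ratio[td$chrom == "c1"][200:300] <- 0.5
  seg <- call_cnv_segments(td)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$subtype, "T-Del")
  expect_equal(seg$start, 199 * win)
  expect_equal(seg$end, 300 * win)
  # interior duplication
  dup <- flat; dup$ratio[dup$chrom == "c2"][100:140] <- 1.5
  seg <- call_cnv_segments(dup)
  expect_equal(seg$subtype, "Dup")
  expect_equal(seg$start, 99 * win)
  expect_equal(seg$end, 140 * win)
  # whole-chromosome run is routed to aneuploidy, not CR
  mono <- flat; mono$ratio[mono$chrom == "c2"] <- 0.5
  expect_equal(nrow(call_cnv_segments(mono)), 0)
  # unnormalized (raw count scale) track is rejected with instruction
  raw <- flat; raw$ratio <- raw$ratio * 50
  expect_error(call_cnv_segments(raw), "normalize")
})

test_that("aneuploidy rules classify the canonical cases", {
  win <- 1000
  d <- data.frame(chrom = rep(c("c1", "c2", "c3"), each = 100),
                  start = rep((0:99) * win, 3), end = rep((1:100) * win, 3),
                  ratio = 1, stringsAsFactors = FALSE)
  mk <- data.frame(chrom = rep(c("c1", "c2", "c3"), each = 99),
                   pos = rep(seq(500, 98500, by = 1000), 3),
                   stringsAsFactors = FALSE)
  geno <- rep("het", nrow(mk))
  c1d <- function(r) { d$ratio[d$chrom == "c1"] <- r; d }
  c1g <- function(g) { geno[mk$chrom == "c1"] <- g; geno }
  # c1 at 0.5x with all-hom markers -> monosomy; others stay euploid
  an <- call_aneuploidy(c1d(0.5), mk, c1g("homA"))
  expect_equal(an$subtype[an$chrom == "c1"], "Mon")
  expect_true(all(an$subtype[an$chrom != "c1"] == "euploid"))
  # c1 at disomic depth but fully homozygous -> uniparental diploid
  an <- call_aneuploidy(d, mk, c1g("homB"))
  expect_equal(an$subtype[an$chrom == "c1"], "UPD")
  expect_equal(an$hom_frac[an$chrom == "c1"], 1)
  # trisomy and higher ploidy by depth
  expect_equal(call_aneuploidy(c1d(1.5), mk, geno)$subtype[1], "Tri")
  expect_equal(call_aneuploidy(c1d(2.0), mk, geno)$subtype[1], "Tet/Pen")
  # het disome -> euploid
  expect_true(all(call_aneuploidy(d, mk, geno)$subtype == "euploid"))
  # chromosome with too few usable windows is uncallable
  d4 <- rbind(d, data.frame(chrom = "c4", start = c(0, win),
                            end = c(win, 2 * win), ratio = 1))
  an <- call_aneuploidy(d4, mk, geno)
  expect_true(an$uncallable[an$chrom == "c4"])
})

test_that("depth recentering restores the euploid baseline", {
  win <- 1000
  # half the assayed windows monosomic: the median sits below the disome
  d <- data.frame(chrom = rep(c("c1", "c2", "c3"), each = 200),
                  start = rep((0:199) * win, 3), end = rep((1:200) * win, 3),
                  ratio = c(rep(0.5, 200), rep(1, 400)))
  # heavy monosomy load dragged the median normalization 12% low: the modal
  # (euploid) windows no longer sit at 1
  skew <- d; skew$ratio <- skew$ratio / 0.88
  rc <- recenter_depth(skew)
  expect_equal(rc$ratio[rc$chrom == "c2"], rep(1, 200))
  expect_equal(rc$ratio[rc$chrom == "c1"], rep(0.5, 200))
  expect_error(recenter_depth(transform(d, ratio = ratio * 50)), "normalize")
})

test_that("event table assembly conserves rows and keeps classes exclusive", {
  gl <- tiny_layout()
  expect_equal(nrow(build_event_table("i1", layout = gl)), 0)
  v <- data.frame(chrom = "c1", pos = c(100, 200, 300),
                  ref = c("C", "G", "AT"), alt = c("T", "A", "A"),
                  genotype = "het", af = 0.5, depth = 50,
                  stringsAsFactors = FALSE)
  loh <- data.frame(chrom = "c2", start = 1000, end = 5000,
                    first_marker = 1, last_marker = 12, n_hom = 12,
                    subtype = "I-LOH", parent = "A",
                    stringsAsFactors = FALSE)
  tab <- build_event_table("i1", v, loh, layout = gl)
  expect_equal(nrow(tab), 4)  # 2 SNVs + 1 InDel + 1 LOH
  expect_equal(sort(unique(tab$class)), c("InDel", "LOH", "SNV"))
  expect_equal(tab$subtype[tab$class == "InDel"], "del")
  # LOH inside a called deletion is absorbed into the CR
  cnv <- data.frame(chrom = "c2", start = 0, end = 20000, subtype = "I-Del",
                    mean_ratio = 0.5, n_windows = 20,
                    stringsAsFactors = FALSE)
  tab2 <- build_event_table("i1", v, loh, cnv, layout = gl)
  expect_equal(sum(tab2$class == "LOH"), 0)
  expect_equal(sum(tab2$class == "CR"), 1)
  # LOH on a UPD chromosome is absorbed into the aneuploidy call
  an <- data.frame(chrom = "c2", subtype = "UPD", mean_ratio = 1,
                   hom_frac = 1, uncallable = FALSE, stringsAsFactors = FALSE)
  tab3 <- build_event_table("i1", v, loh, aneuploidy = an, layout = gl)
  expect_equal(sum(tab3$class == "LOH"), 0)
  expect_equal(sum(tab3$class == "aneuploidy"), 1)
  # duplicate spans deduplicate with a warning
  expect_warning(build_event_table("i1", rbind(v[1, ], v[1, ]), layout = gl),
                 "duplicate")
})

test_that("no chromosome is reported as both CR and aneuploidy", {
  sim <- quick_sim(seed = 17, isolates = 6, passages = 3, noise = TRUE)
  ev <- suppressWarnings(call_cohort_events(sim))
  expect_gt(sum(ev$class == "aneuploidy"), 0)
  for (id in unique(ev$isolate)) {
    e <- ev[ev$isolate == id, ]
    an_chr <- e$chrom[e$class == "aneuploidy"]
    cr <- e[e$class == "CR" & e$chrom %in% an_chr, ]
    if (nrow(cr)) {
      len <- sim$layout$length[match(cr$chrom, sim$layout$chrom)]
      expect_true(all((cr$end - cr$start) / len < 0.9))
    }
  }
})

test_that("event tables round-trip as TSV", {
  sim <- quick_sim(seed = 19, isolates = 2)
  ev <- call_cohort_events(sim)
  f <- tempfile(fileext = ".tsv")
  write_event_table(ev, f)
  back <- read_event_table(f)
  expect_equal(names(back),
               c("isolate", "class", "subtype", "chrom", "start", "end",
                 "support"))
  expect_equal(back$class, ev$class)
  expect_equal(back$start, ev$start)
  expect_equal(back$support, ev$support, tolerance = 1e-6)
  unlink(f)
})
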