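test_that("marker map is Poisson-spaced, deterministic, and validated", {
  gl <- default_genome_layout()
  mk <- build_marker_map(gl, density = 1 / 400, seed = 3)
  lambda <- 23e6 / 400
  expect_lt(abs(nrow(mk) - lambda), 3 * sqrt(lambda))
  expect_identical(mk, build_marker_map(gl, density = 1 / 400, seed = 3))
  expect_error(build_marker_map(gl, density = 0), "> 0")
  expect_error(build_marker_map(tiny_layout(), density = 1e-6, seed = 1),
               "increase density")
  # positions strictly increasing per chromosome
  for (ch in unique(mk$chrom))
    expect_true(all(diff(mk$pos[mk$chrom == ch]) > 0))
})

test_that("origin maps are sorted with at least two origins per chromosome", {
  om <- build_origin_map(tiny_layout(), spacing = 40000, seed = 5)
  for (ch in c("c1", "c2", "c3")) {
    p <- om$pos[om$chrom == ch]
    expect_gte(length(p), 2)
    expect_true(all(diff(p) > 0))
  }
})

test_that("all-zero rates yield a quiet genome", {
  cfg <- zero_noise(sim_config(seed = 2, isolates = 2, passages = 2,
                               rates = c(SNV = 0, InDel = 0, LOH = 0,
                                         CR = 0, aneuploidy = 0),
                               background_variants = 0L))
  sim <- simulate_lineages(cfg)
  expect_equal(nrow(sim$truth), 0)
  for (iso in sim$isolates) {
    expect_equal(nrow(iso$variants), 0)
    expect_true(all(iso$marker_geno == "het"))
    expect_true(all(iso$depth$ratio == 1))
  }
})

test_that("simulation is deterministic and per-isolate streams are stable", {
  cfg <- sim_config(seed = 9, isolates = 3, passages = 2)
  s1 <- simulate_lineages(cfg)
  s2 <- simulate_lineages(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$isolates, s2$isolates)
  # isolate k does not depend on how many isolates follow it
  cfg5 <- sim_config(seed = 9, isolates = 5, passages = 2)
  s5 <- simulate_lineages(cfg5)
  expect_identical(s1$isolates[[2]], s5$isolates[[2]])
})

test_that("event counts follow the Poisson design", {
  r <- 0.05
  cfg <- zero_noise(sim_config(seed = 4, isolates = 20, passages = 3,
                               rates = c(SNV = r, InDel = 0, LOH = 0,
                                         CR = 0, aneuploidy = 0),
                               background_variants = 0L))
  sim <- simulate_lineages(cfg)
  lambda <- r * 20 * 3 * 24
  n <- sum(sim$truth$class == "SNV")
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("a planted monosomy halves that chromosome's depth", {
  cfg <- sim_config(seed = 6, isolates = 1, passages = 5,
                    rates = c(SNV = 0, InDel = 0, LOH = 0, CR = 0,
                              aneuploidy = 0.05),
                    aneuploidy_weights = c(Mon = 1, UPD = 0, Tri = 0,
                                           "Tet/Pen" = 0),
                    background_variants = 0L)
  sim <- simulate_lineages(cfg)
  mon <- subset(sim$truth, subtype == "Mon")
  expect_gt(nrow(mon), 0)
  d <- sim$isolates[[1]]$depth
  for (ch in mon$chrom) {
    m <- mean(d$ratio[d$chrom == ch])
    expect_gt(m, 0.45)
    expect_lt(m, 0.55)
  }
})

test_that("every truth event leaves a detectable footprint at zero noise", {
  sim <- quick_sim(seed = 13, isolates = 3)
  mk <- sim$markers
  for (i in seq_len(nrow(sim$truth))) {
    ev <- sim$truth[i, ]
    iso <- sim$isolates[[as.integer(sub("iso", "", ev$isolate))]]
    if (ev$class %in% c("SNV", "InDel")) {
      expect_true(any(iso$variants$chrom == ev$chrom &
                        iso$variants$pos - 1 >= ev$start - 50 &
                        iso$variants$pos - 1 <= ev$end))
    } else if (ev$class == "LOH") {
      sel <- mk$chrom == ev$chrom & mk$pos > ev$start & mk$pos <= ev$end
      expect_true(all(grepl("hom", iso$marker_geno[sel])))
    } else {
      d <- iso$depth
      sel <- d$chrom == ev$chrom & d$start >= ev$start & d$end <= ev$end
      if (ev$subtype %in% c("Mon", "T-Del", "I-Del"))
        expect_true(mean(d$ratio[sel]) < 0.8)
      if (ev$subtype %in% c("Tri", "Dup", "Tet/Pen"))
        expect_true(mean(d$ratio[sel]) > 1.2)
      if (ev$subtype %in% c("Mon", "UPD")) {
        sel_m <- mk$chrom == ev$chrom
        expect_true(all(grepl("hom", iso$marker_geno[sel_m])))
      }
    }
  }
})

test_that("VCF writing round-trips through the reader", {
  gl <- default_genome_layout()
  # empty call set: header-only file, empty read-back
  empty <- list(id = "iso000",
                variants = data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      genotype = character(), af = numeric(),
                                      depth = numeric()))
  f <- tempfile(fileext = ".vcf")
  write_isolate_vcf(empty, f, layout = gl)
  expect_true(any(grepl("^##fileformat", readLines(f))))
  back <- read_isolate_vcf(f)
  expect_equal(nrow(back$variants), 0)
  # 1000 random records: field-by-field agreement
  set.seed(21)
  n <- 1000
  ch <- sample(gl$chrom, n, replace = TRUE)
  pos <- sample.int(2e5, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  dp <- sample(30:80, n, replace = TRUE)
  v <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                  genotype = sample(c("het", "hom-alt"), n, replace = TRUE),
                  af = round(runif(n), 6), depth = dp,
                  stringsAsFactors = FALSE)
  v <- v[!duplicated(v[, c("chrom", "pos")]), ]
  calls <- list(id = "iso042", variants = v)
  write_isolate_vcf(calls, f, layout = gl)
  back <- read_isolate_vcf(f)
  expect_equal(back$id, "iso042")
  ord <- order(match(v$chrom, gl$chrom), v$pos)
  expect_equal(back$variants$chrom, v$chrom[ord])
  expect_equal(back$variants$pos, v$pos[ord])
  expect_equal(back$variants$ref, v$ref[ord])
  expect_equal(back$variants$alt, v$alt[ord])
  expect_equal(back$variants$genotype, v$genotype[ord])
  expect_equal(back$variants$af, v$af[ord], tolerance = 1e-9)
  expect_equal(back$variants$depth, v$depth[ord])
  unlink(f)
})

test_that("marker genotype and depth tracks round-trip as TSV/bedGraph", {
  sim <- quick_sim(seed = 3, isolates = 1)
  iso <- sim$isolates[[1]]
  f1 <- tempfile(fileext = ".tsv")
  write_marker_genotypes(sim$markers, iso$marker_geno, f1)
  g <- read_marker_genotypes(f1)
  expect_equal(g$genotype, iso$marker_geno)
  f2 <- tempfile(fileext = ".bedgraph")
  write_depth_bedgraph(iso$depth, f2)
  d <- read_depth_bedgraph(f2)
  expect_equal(d$ratio, iso$depth$ratio, tolerance = 1e-9)
  expect_equal(d$start, iso$depth$start)
  unlink(c(f1, f2))
})
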