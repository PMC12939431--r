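test_that("mutation rate follows the MA design formula", {
  r0 <- mutation_rate(0, 31, 5)
  expect_equal(r0$per_division, 0)
  expect_equal(r0$per_bp, 0)
  # identity: N equal to the full denominator gives per-bp rate 1
  rid <- mutation_rate(31 * 5 * 24 * 23e6, 31, 5)
  expect_equal(rid$per_bp, 1)
  r <- mutation_rate(100, 31, 5)
  expect_equal(r$per_division, 100 / 3720)
  expect_equal(r$per_bp, 100 / 3720 / 23e6)
  # Poisson CI brackets the point estimate
  expect_lt(r$ci_per_division[1], r$per_division)
  expect_gt(r$ci_per_division[2], r$per_division)
})

test_that("mutation rate is linear in N and inverse-linear in the design", {
  set.seed(5)
  for (i in 1:25) {
    N <- sample.int(500, 1); s <- sample.int(60, 1)
    n <- sample.int(10, 1); g <- sample.int(40, 1)
    base <- mutation_rate(N, s, n, g)
    expect_equal(mutation_rate(3 * N, s, n, g)$per_division,
                 3 * base$per_division)
    expect_equal(mutation_rate(N, 2 * s, n, g)$per_division,
                 base$per_division / 2)
    expect_equal(mutation_rate(N, s, 2 * n, g)$per_division,
                 base$per_division / 2)
    expect_equal(mutation_rate(N, s, n, 2 * g)$per_division,
                 base$per_division / 2)
    expect_equal(base$per_bp * 23e6, base$per_division)
  }
})

test_that("fold change handles equal, large, and undefined references", {
  a <- mutation_rate(102, 10, 1, 1)
  b <- mutation_rate(1, 10, 1, 1)
  expect_equal(fold_change(a, a), 1)
  expect_equal(fold_change(a, b), 102)
  z <- mutation_rate(0, 10, 1, 1)
  fc <- fold_change(a, z)
  expect_true(is.infinite(fc))
  expect_true(attr(fc, "undefined_reference"))
})

test_that("rank-sum test: exact enumeration and its oracles", {
  # same multiset in both groups: central, p = 1
  expect_equal(compare_rate_distributions(c(3, 1, 2), c(1, 2, 3))$p, 1)
  # fully separated 3 vs 3: the most extreme of C(6,3)=20 partitions,
  # doubled tail -> 2/20
  expect_equal(compare_rate_distributions(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  # agreement with the exact distribution for all group sizes <= 6 (no ties)
  set.seed(8)
  for (na in 2:6) for (nb in 2:6) {
    a <- sample.int(1000, na); b <- sample.int(1000, nb)
    got <- compare_rate_distributions(a, b)
    want <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p, want, tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  # ties: p is symmetric in the groups and lies in (0, 1]
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:4, 5, TRUE); b <- sample(1:4, 6, TRUE)
    p1 <- compare_rate_distributions(a, b)$p
    p2 <- compare_rate_distributions(b, a)$p
    expect_equal(p1, p2)
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
  # strongly shifted large samples are detected by the approximation
  set.seed(10)
  big <- compare_rate_distributions(rnorm(40), rnorm(40, 3))
  expect_lt(big$p, 1e-3)
  expect_equal(big$method, "normal approximation")
  expect_error(compare_rate_distributions(numeric(0), 1), "non-empty")
})

test_that("composition test reproduces hypergeometric closed forms", {
  expect_equal(composition_test(rbind(c(5, 5), c(5, 5)))$p, 1)
  # diagonal 2x2: p = 2 / C(20,10)
  expect_equal(composition_test(rbind(c(10, 0), c(0, 10)))$p,
               2 / choose(20, 10), tolerance = 1e-12)
  # closed-form oracle: sum of hypergeometric probabilities <= observed
  tab <- rbind(c(3, 1), c(1, 3))
  dh <- dhyper(0:4, 4, 4, 4)
  want <- sum(dh[dh <= dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(composition_test(tab)$p, want, tolerance = 1e-9)
  expect_equal(round(composition_test(tab)$p, 4), 0.4857)
  # large tables switch to seeded Monte Carlo and stay reproducible
  big <- rbind(c(150, 80, 40), c(60, 120, 90))
  m1 <- composition_test(big); m2 <- composition_test(big)
  expect_equal(m1$method, "monte-carlo")
  expect_equal(m1$p, m2$p)
  expect_error(composition_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("composition tables count subtypes per group", {
  ev <- data.frame(group = rep(c("A", "B"), each = 4),
                   class = "SNV",
                   subtype = c("C>T", "C>T", "T>C", "C>A",
                               "C>T", "T>C", "T>C", "T>C"),
                   stringsAsFactors = FALSE)
  tab <- composition_table(ev, "SNV")
  expect_equal(tab["A", "C>T"], 2L)
  expect_equal(tab["B", "T>C"], 3L)
  pr <- attr(tab, "proportions")
  expect_equal(rowSums(pr), c(A = 1, B = 1))
})

test_that("hypermutator detection flags the right isolates", {
  mk_events <- function(id, n_snv, n_large, ct_frac) {
    subtypes <- sample(c("C>T", "T>C", "C>A"), n_snv, TRUE,
                       prob = c(ct_frac, (1 - ct_frac) / 2,
                                (1 - ct_frac) / 2))
    rbind(
      data.frame(isolate = id, class = "SNV", subtype = subtypes,
                 stringsAsFactors = FALSE),
      if (n_large > 0)
        data.frame(isolate = id, class = "LOH", subtype = "T-LOH",
                   stringsAsFactors = FALSE)[rep(1, n_large), ])
  }
  set.seed(12)
  # homogeneous cohort: nothing flagged
  ev <- do.call(rbind, lapply(sprintf("i%02d", 1:12), function(id)
    mk_events(id, rpois(1, 10) + 3, rpois(1, 3), 0.3)))
  expect_equal(length(detect_hypermutators(ev)$flagged), 0)
  # two planted outliers with C>T-skewed spectra
  ev2 <- rbind(ev, mk_events("h1", 200, 3, 0.85),
               mk_events("h2", 260, 2, 0.85))
  det <- detect_hypermutators(ev2)
  expect_setequal(det$flagged, c("h1", "h2"))
  # elevated SNVs but also elevated large-scale events: not flagged
  ev3 <- rbind(ev, mk_events("x1", 200, 60, 0.85))
  expect_false("x1" %in% detect_hypermutators(ev3)$flagged)
  expect_error(detect_hypermutators(ev[ev$isolate %in%
                                         c("i01", "i02"), ]), "at least 5")
})

test_that("rate tables cover the five classes with design constants", {
  sim <- quick_sim(seed = 23, isolates = 4, passages = 2)
  ev <- call_cohort_events(sim)
  rt <- rate_table(ev, s = 4, n = 2, group = "demo")
  expect_equal(rt$class, c("SNV", "InDel", "LOH", "CR", "aneuploidy"))
  expect_equal(rt$N, as.integer(table(factor(ev$class, levels = rt$class))))
  expect_equal(rt$per_division, rt$N / (4 * 2 * 24))
  expect_true(all(is.na(rt$per_bp[3:5])))
  expect_equal(rt$per_bp[1], rt$per_division[1] / 23e6)
})
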