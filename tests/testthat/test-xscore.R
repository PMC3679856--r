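test_that("paralog weight is the reciprocal harmonic number", {
  expect_equal(paralogWeight(0:3), c(0, 1, 2 / 3, 6 / 11))
  expect_error(paralogWeight(-1), "non-negative")
})

test_that("per-experiment minima respect measured-gene semantics", {
  members <- list(hs = c("a", "b"), dr = c("c"))
  tabs <- list(
    PValueTable("e1", "hs", gene = c("a", "b"), p = c(0.3, 0.01)),
    PValueTable("e2", "dr", gene = c("zz"), p = 0.5))   # c unmeasured
  mm <- minPvaluePerExperiment(members, tabs)
  expect_equal(mm$ptilde[mm$experiment == "e1"], 0.01)
  expect_equal(mm$l, c(2L, 0L))
  expect_true(is.na(mm$ptilde[mm$experiment == "e2"]))

  # a homolog absent from the array contributes nothing but the
  # measured one still counts (grey-square semantics)
  tabs2 <- list(PValueTable("e1", "hs", gene = "a", p = 0.3))
  mm2 <- minPvaluePerExperiment(members, tabs2)
  expect_equal(mm2$ptilde, 0.3)
  expect_equal(mm2$l, 1L)
})

test_that("cross-species score matches the closed-form examples", {
  expect_equal(crossSpeciesScore(c(e = exp(-1)), c(e = 1L)), 1)
  expect_equal(crossSpeciesScore(c(a = 0.05, b = 0.1), c(a = 1L, b = 1L)),
               (-log(0.05) - log(0.1)) / 2)
  expect_equal(crossSpeciesScore(c(a = 0.01), c(a = 2L)),
               (2 / 3) * (-log(0.01)))
  expect_error(crossSpeciesScore(c(a = NA_real_), c(a = 0L)), "untestable")
})

test_that("Gamma null parameters match analytic values and a Monte-Carlo variance", {
  expect_equal(gammaNullParams(stats::setNames(rep(1L, 5), letters[1:5]))$alpha, 5)
  expect_equal(gammaNullParams(c(a = 2L))$alpha, 9 / 5)
  prm <- gammaNullParams(c(a = 1L, b = 2L))
  expect_equal(prm$alpha, 18 / 7)
  expect_equal(prm$alpha, prm$beta)

  # independent oracle: variance of simulated null scores
  s <- sampleNullScores(c(a = 1L, b = 2L), nDraws = 2e5, seed = 12)
  expect_lt(abs(stats::var(s) - 7 / 18), 4 * sqrt(2 / 2e5))  # se ~ sqrt(2/n)*var
  expect_lt(abs(mean(s) - 1), 4 * stats::sd(s) / sqrt(2e5))
})

test_that("combined p-value recovers the exponential and Fisher cases", {
  # one experiment, l = 1: the combination is the identity
  prm1 <- gammaNullParams(c(a = 1L))
  expect_equal(combineGroup(-log(0.05), prm1), 0.05)

  # all l = 1, uniform weights: exact Fisher equivalence
  ps <- c(0.01, 0.04)
  ls <- c(a = 1L, b = 1L)
  s <- crossSpeciesScore(c(a = ps[1], b = ps[2]), ls)
  expect_equal(combineGroup(s, gammaNullParams(ls)), fisherCombine(ps),
               tolerance = 1e-12)

  # single species, l = 2: Gamma approximation vs the exact
  # order-statistic tail 1 - (1 - p)^2
  s2 <- crossSpeciesScore(c(a = 0.01), c(a = 2L))
  g2 <- combineGroup(s2, gammaNullParams(c(a = 2L)))
  exact <- 1 - (1 - 0.01)^2
  expect_lt(abs(g2 / exact - 1), 0.25)   # documented approximation budget
})

test_that("Fisher combination matches its closed form for two p-values", {
  expect_equal(fisherCombine(0.05), 0.05)
  expect_equal(fisherCombine(c(1, 1)), 1)
  # closed form for m = 2: q (1 - log q) with q = p1 p2
  q <- 0.01 * 0.04
  expect_equal(fisherCombine(c(0.01, 0.04)), q * (1 - log(q)),
               tolerance = 1e-12)
  expect_error(fisherCombine(numeric()), "empty")
  expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Monte-Carlo exact null matches closed-form tails", {
  # l = 1: exponential case
  est <- exactNullSurvival(c(a = 1L), score = -log(0.05), nDraws = 1e5,
                           seed = 2)
  expect_lt(abs(est - 0.05), 3 * attr(est, "se"))

  # single species l in 2:4: order-statistic closed form
  for (l in 2:4) {
    pt <- 0.1
    ls <- stats::setNames(as.integer(l), "a")
    sc <- crossSpeciesScore(c(a = pt), ls)
    est <- exactNullSurvival(ls, score = sc, nDraws = 1e5, seed = 3)
    expect_lt(abs(est - (1 - (1 - pt)^l)), 3 * attr(est, "se") + 1e-4)
  }

  # m = 4, all l = 1, uniform: chi-square with 8 df
  ps <- c(0.02, 0.3, 0.15, 0.08)
  ls <- stats::setNames(rep(1L, 4), letters[1:4])
  sc <- crossSpeciesScore(stats::setNames(ps, letters[1:4]), ls)
  est <- exactNullSurvival(ls, score = sc, nDraws = 2e5, seed = 4)
  expect_lt(abs(est - fisherCombine(ps)), 3 * attr(est, "se"))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(c(0.04, 0.5)), c(0.08, 0.5))
  expect_equal(bhFdr(numeric()), numeric())
  p <- stats::runif(50)
  expect_true(all(bhFdr(p) >= p))
})

test_that("combineAll equals per-group Fisher on all-l=1 structures", {
  st <- synthesizeStructure(3, 40, c("1" = 1), seed = 2)
  tabs <- uniformTables(st, seed = 9)
  res <- combineAll(st, tabs)
  expect_equal(nrow(res), 40L)
  for (gid in res$group[1:10]) {
    m <- groupMembers(st, gid)
    ps <- vapply(tabs, function(tb) {
      d <- pvalues(tb)
      d$p[d$gene %in% m[[speciesNames(tb)]]]
    }, numeric(1))
    expect_equal(res$p_combined[res$group == gid], fisherCombine(ps),
                 tolerance = 1e-12)
  }
})

test_that("combineAll handles missing data, weights and untested groups", {
  st <- HomologyStructure(
    data.frame(group = c("g1", "g1", "g2"), species = c("hs", "dr", "hs"),
               gene = c("a", "b", "c")),
    groupIds = c("g1", "g2", "g3"))
  tabs <- list(PValueTable("e1", "hs", gene = c("a", "c"), p = c(0.02, 0.5)),
               PValueTable("e2", "dr", gene = "b", p = 0.1))
  res <- combineAll(st, tabs, weights = c(e1 = 0.75, e2 = 0.25))
  expect_setequal(res$group, c("g1", "g2"))
  expect_equal(attr(res, "untested"), "g3")
  # g2 is measured only in e1 with l = 1: its combined p is the input p
  expect_equal(res$p_combined[res$group == "g2"], 0.5)
  expect_equal(res$q_bh, bhFdr(res$p_combined))

  # a table whose species is absent from the structure warns
  tabs3 <- c(tabs, PValueTable("e3", "mm", gene = "zz", p = 0.5))
  expect_warning(combineAll(st, tabs3, weights = c(e1 = .5, e2 = .25, e3 = .25)),
                 "absent")
  suppressWarnings(
    expect_error(combineAll(st, list(PValueTable("e9", "mm", gene = "q", p = .5))),
                 "no overlap"))
})

test_that("decreasing an input p-value never increases the combined p", {
  set.seed(41)
  for (trial in 1:60) {
    m <- sample(1:5, 1)
    ls <- stats::setNames(sample(1:4, m, replace = TRUE), paste0("e", 1:m))
    ps <- stats::setNames(stats::runif(m), names(ls))
    prm <- gammaNullParams(ls)
    p0 <- combineGroup(crossSpeciesScore(ps, ls), prm)
    j <- sample(m, 1)
    ps[j] <- ps[j] * stats::runif(1)
    p1 <- combineGroup(crossSpeciesScore(ps, ls), prm)
    expect_lte(p1, p0)
  }
})

test_that("under the null, group size does not bias the ranking", {
  set.seed(17)
  n <- 2e4
  p1 <- stats::runif(n)   # l = 1 stratum: combined p is the input p
  prm <- gammaNullParams(c(a = 4L))
  pm <- matrix(stats::runif(4 * n), n)
  s4 <- paralogWeight(4) * -log(do.call(pmin, as.data.frame(pm)))
  p4 <- stats::pgamma(s4, prm$alpha, rate = prm$beta, lower.tail = FALSE)
  expect_gt(stats::wilcox.test(p1, p4)$p.value, 0.001)
})

test_that("best-one-sided selection behaves as documented under the null", {
  # selection without correction roughly doubles the nominal level
  set.seed(23)
  n <- 5000; m <- 3
  pu <- matrix(stats::runif(n * m), n)
  prm <- gammaNullParams(stats::setNames(rep(1L, m), paste0("e", 1:m)))
  comb <- function(P) stats::pgamma(rowMeans(-log(P)), prm$alpha,
                                    rate = prm$beta, lower.tail = FALSE)
  best <- pmin(comb(pu), comb(1 - pu))
  expect_gt(mean(best < 0.05), 0.08)
  expect_lt(mean(best < 0.05), 0.13)

  # factor-2 correction: exactly uniform for a single experiment,
  # tail-calibrated for several
  u <- stats::runif(2e4)
  oneExp <- pmin(1, 2 * pmin(u, 1 - u))
  expect_lt(suppressWarnings(
    stats::ks.test(oneExp, "punif"))$statistic, 0.02)
  dbl <- pmin(1, 2 * best)
  expect_gt(mean(dbl < 0.05), 0.035)
  expect_lt(mean(dbl < 0.05), 0.07)
})

test_that("directional combination picks the supported direction", {
  st <- synthesizeStructure(2, 6, c("1" = 1), seed = 6)
  pl <- placements(st)
  set.seed(7)
  tabs <- lapply(speciesNames(st), function(s) {
    g <- pl$gene[pl$species == s]
    up <- stats::runif(length(g), 0.0005, 0.002)   # strongly up everywhere
    PValueTable(paste0("e_", s), s, gene = g, p_up = up, p_down = 1 - up)
  })
  members <- groupMembers(st, "g1")
  dc <- directionalCombine(members, tabs)
  expect_equal(dc$direction, "up")
  expect_equal(dc$p, dc$p_up)
  expect_equal(min(1, 2 * dc$p),
               directionalCombine(members, tabs, double = TRUE)$p)

  res <- combineAll(st, tabs, direction = "best-one-sided")
  expect_true(all(res$direction == "up"))
  expect_equal(res$p_combined[res$group == "g1"], dc$p)

  # missing one-sided values are rejected
  bad <- list(PValueTable("e_sp1", "sp1", gene = pl$gene[pl$species == "sp1"],
                          p = rep(0.5, sum(pl$species == "sp1"))))
  expect_error(combineAll(st, bad, direction = "best-one-sided"),
               "one-sided")
})

test_that("subset significance counts summarize configurations", {
  st <- synthesizeStructure(3, 30, c("1" = 1), seed = 8)
  pl <- placements(st)
  # one shared strong group, the rest null
  set.seed(9)
  tabs <- lapply(speciesNames(st), function(s) {
    g <- pl$gene[pl$species == s]
    p <- stats::runif(length(g), 0.2, 1)
    p[match(pl$gene[pl$group == "g1" & pl$species == s], g)] <- 1e-6
    PValueTable(paste0("e_", s), s, gene = g, p = p)
  })
  sc <- subsetSignificanceCounts(st, tabs, threshold = 1e-4)
  expect_equal(sc$n_experiments, 1:3)
  expect_equal(sc$sd_count[3], 0)                    # full set: one config
  expect_true(all(diff(sc$mean_count) >= 0))         # shared signal accumulates
  all1 <- subsetSignificanceCounts(st, tabs, threshold = 1, subsetSizes = 3)
  expect_equal(all1$mean_count, 30)                  # every testable group
  expect_error(subsetSignificanceCounts(st, tabs, subsetSizes = 4), "sizes")
})

test_that("p-value containers validate their contents", {
  expect_warning(PValueTable("e", "s", gene = "a", p = 0),
                 "clamped")
  expect_error(PValueTable("e", "s", gene = c("a", "b"), p = c(0.5, 1.5)),
               "outside")
  expect_error(PValueTable("e", "s", gene = "a", p = 0.5, p_up = 0.2),
               "together")
  expect_warning(PValueTable("e", "s", gene = "a", p_up = 0.2, p_down = 0.3),
                 "deviates")
})
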