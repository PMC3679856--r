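# Power / FDR benchmark: simulate two-arm expression for every gene of
# a homology structure, add an effect to the treated arm of DE groups
# (on one in-paralog per species, optionally shared with or opposed by
# a second), then rank the groups with the cross-species score and the
# three baseline strategies.

# sub-seeds so that DE selection, in-paralog selection and noise are
# independent streams that differ only where intended
.subSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a two-arm expression dataset over a homology structure
#'
#' Every gene of every species receives `nReplicates` control and
#' `nReplicates` treated observations from the noise distribution
#' (standard Gaussian or Student t with 5 df).  A seeded fraction of
#' groups is differentially expressed: within each such group and
#' species, `effect` is added to the treated-arm mean of one randomly
#' selected in-paralog; in `"concordant"` mode a second in-paralog
#' (where one exists) receives the same effect, in `"discordant"` mode
#' half the effect is subtracted from it.  Groups whose species all
#' have a single gene behave identically in the three modes.
#'
#' @param scenario a [SimulationScenario-class] (carries the structure,
#'   replicate counts, DE fraction, noise and in-paralog mode).
#' @param effect non-negative effect size.
#' @param seed integer seed (defaults to the scenario seed).
#' @return list with `placements` (data.table `group`, `species`,
#'   `gene`, `eff` — the mean shift applied to the treated arm),
#'   `control` and `treated` (numeric matrices, one row per placement),
#'   `deGroups` (character) and `effect`.
#' @export
simulateDataset <- function(scenario, effect, seed = scenario@seed) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (effect < 0) stop("effect must be non-negative")
  pl <- data.table::copy(scenario@structure@placements)
  if (!nrow(pl)) stop("structure has no gene placements")
  n <- scenario@nReplicates
  seeds <- .subSeeds(seed, 3L)

  testable <- unique(pl$group)
  set.seed(seeds[1L])
  deGroups <- sample(testable, round(scenario@deFraction * length(testable)))

  set.seed(seeds[2L])
  pl[, eff := 0]
  de <- pl$group %in% deGroups
  rk <- pl[, .(I = .I, r = sample(.N)), by = .(group, species)]
  rank1 <- rk$I[rk$r == 1L]
  pl$eff[intersect(rank1, which(de))] <- effect
  if (scenario@inparalogMode != "single") {
    rank2 <- rk$I[rk$r == 2L]
    second <- intersect(rank2, which(de))
    pl$eff[second] <- if (scenario@inparalogMode == "concordant")
      effect else -effect / 2
  }

  set.seed(seeds[3L])
  draw <- function(k) {
    if (scenario@noise == "gaussian") stats::rnorm(k) else stats::rt(k, df = 5)
  }
  np <- nrow(pl)
  control <- matrix(draw(np * n), nrow = np)
  treated <- matrix(draw(np * n), nrow = np) + pl$eff
  list(placements = pl, control = control, treated = treated,
       deGroups = deGroups, effect = effect)
}

# Fisher combination per group of one per-(group, species) p-value
# column; vectorized over all groups
.fisherByGroup <- function(sp) {
  res <- sp[, .(stat = -2 * sum(log(p)), df = 2 * .N), by = group]
  res[, p := pmax(stats::pchisq(stat, df = df, lower.tail = FALSE),
                  .Machine$double.xmin)]
  res[, .(group, p)]
}

# one benchmark pass: per-gene t-tests, the proposed combination and
# the three baselines; analysisPl may be a corrupted version of the
# generating placements
.rankMethods <- function(ds, analysisPl, seed) {
  pl <- ds$placements
  n <- ncol(ds$control)
  pgene <- .rowTPvalues(ds$control, ds$treated)

  # analysis looks genes up by (species, gene): reorder the data rows
  key <- paste(pl$species, pl$gene, sep = "\r")
  akey <- paste(analysisPl$species, analysisPl$gene, sep = "\r")
  ix <- match(akey, key)
  stopifnot(!anyNA(ix))
  ctrl <- ds$control[ix, , drop = FALSE]
  trt <- ds$treated[ix, , drop = FALSE]

  dt <- data.table(group = analysisPl$group, species = analysisPl$species,
                   p = pgene[ix])

  obs <- data.table(group = dt$group, experiment = dt$species, p = dt$p)
  w <- stats::setNames(rep(1, length(unique(dt$species))), unique(dt$species))
  proposed <- .scoreGroups(obs, w / sum(w), "p")$groups[, .(group, p = p_combined)]

  # combined: pool all in-paralog cells per (group, species)
  agg <- data.table(group = dt$group, species = dt$species,
                    sc = rowSums(ctrl), ssc = rowSums(ctrl^2),
                    st = rowSums(trt), sst = rowSums(trt^2))
  agg <- agg[, .(l = .N, sc = sum(sc), ssc = sum(ssc),
                 st = sum(st), sst = sum(sst)), by = .(group, species)]
  agg[, `:=`(nC = l * n, nT = l * n)]
  agg[, `:=`(mC = sc / nC, mT = st / nT)]
  agg[, sp2 := ((ssc - nC * mC^2) + (sst - nT * mT^2)) / (nC + nT - 2)]
  agg[, tt := (mT - mC) / sqrt(sp2 * (1 / nC + 1 / nT))]
  agg[, p := 2 * stats::pt(abs(tt), df = nC + nT - 2, lower.tail = FALSE)]
  agg[is.nan(p), p := 1]
  agg[, p := pmax(p, .Machine$double.xmin)]
  combined <- .fisherByGroup(agg[, .(group, species, p)])

  # average: per-sample mean across in-paralogs, then a row t-test
  gs <- paste(analysisPl$group, analysisPl$species, sep = "\r")
  gsf <- factor(gs, levels = unique(gs))
  mc <- rowsum(ctrl, gsf)
  cnt <- as.vector(table(gsf)[rownames(mc)])
  mt <- rowsum(trt, gsf) / cnt
  mc <- mc / cnt
  pAvg <- .rowTPvalues(mc, mt)
  avgDt <- data.table(gs = rownames(mc), p = pAvg)
  firsts <- !duplicated(gsf)
  avgDt <- merge(avgDt,
                 data.table(gs = gs[firsts], group = analysisPl$group[firsts],
                            species = analysisPl$species[firsts]),
                 by = "gs")
  average <- .fisherByGroup(avgDt[, .(group, species, p)])

  # random: keep one uniformly chosen in-paralog per (group, species)
  set.seed(as.integer(seed))
  ord <- sample(length(gs))
  pick <- ord[!duplicated(gsf[ord])]
  randomP <- data.table(group = analysisPl$group[pick],
                        species = analysisPl$species[pick],
                        p = pgene[ix][pick])
  random <- .fisherByGroup(randomP)

  out <- Reduce(function(a, b) merge(a, b, by = "group"),
                list(setnames(proposed, "p", "proposed"),
                     setnames(combined, "p", "combined"),
                     setnames(average, "p", "average"),
                     setnames(random, "p", "random")))
  out[, truth := group %in% ds$deGroups]
  setorder(out, group)
  out
}

#' Run the power / FDR benchmark over an effect grid
#'
#' For each effect size in the scenario, simulates one dataset over the
#' whole structure, derives per-gene equal-variance t-test p-values,
#' and ranks the homology groups four ways: the harmonic-weighted
#' cross-species score (`proposed`) and the three baselines
#' (`combined`, `average`, `random`) followed by Fisher's combined
#' probability test.  When `structureErrorRate > 0`, the analysis
#' methods see a correspondingly corrupted copy of the structure while
#' the data are generated on the true one.
#'
#' @param scenario a [SimulationScenario-class].
#' @param threshold rejection threshold for the power summary
#'   (default 0.05).
#' @param topFraction ranking fraction for the FDR summary
#'   (default 0.05).
#' @return object of class `"ScenarioResult"`: list with `detail` (one
#'   data.table per effect: `group`, method p-value columns, `truth`)
#'   and `summary` (data.frame `effect`, `method`, `power`,
#'   `fdr_top`).
#' @export
runBenchmark <- function(scenario, threshold = 0.05, topFraction = 0.05) {
  stopifnot(is(scenario, "SimulationScenario"))
  effects <- scenario@effects
  seeds <- .subSeeds(scenario@seed + 1L, 2L * length(effects) + 1L)
  analysisPl <- if (scenario@structureErrorRate > 0)
    injectHomologyErrors(scenario@structure, scenario@structureErrorRate,
                         seed = seeds[1L])@placements
  else scenario@structure@placements

  methods <- c("proposed", "combined", "average", "random")
  detail <- vector("list", length(effects))
  summ <- vector("list", length(effects))
  for (i in seq_along(effects)) {
    ds <- simulateDataset(scenario, effects[i], seed = seeds[2L * i])
    tab <- .rankMethods(ds, analysisPl, seed = seeds[2L * i + 1L])
    detail[[i]] <- tab
    summ[[i]] <- do.call(rbind, lapply(methods, function(m) {
      data.frame(effect = effects[i], method = m,
                 power = powerAtThreshold(tab[[m]], tab$truth, threshold),
                 fdr_top = fdrAmongTop(tab[[m]], tab$truth, topFraction))
    }))
  }
  structure(list(detail = stats::setNames(detail, paste0("effect_", effects)),
                 summary = do.call(rbind, summ),
                 threshold = threshold, topFraction = topFraction),
            class = "ScenarioResult")
}

#' @export
print.ScenarioResult <- function(x, ...) {
  cat("ScenarioResult over", length(x$detail), "effect size(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' False discovery rate among the top-ranked groups
#'
#' Sorts the groups by p-value (stable ascending), keeps the
#' `ceiling(fraction * n)` most significant, and returns the proportion
#' of truly null groups among them — the error measure of the
#' simulation study.
#'
#' @param p p-values.
#' @param truth logical vector, `TRUE` for truly DE groups.
#' @param fraction top fraction of the ranking in (0, 1].
#' @return estimated FDR in \[0, 1\].
#' @export
fdrAmongTop <- function(p, truth, fraction) {
  stopifnot(length(p) == length(truth), fraction > 0, fraction <= 1)
  if (!length(p)) stop("empty input")
  k <- ceiling(fraction * length(p))
  top <- order(p)[seq_len(k)]
  mean(!truth[top])
}

#' Power at a fixed rejection threshold
#'
#' Fraction of truly DE groups with `p <= threshold`.
#'
#' @inheritParams fdrAmongTop
#' @param threshold rejection threshold in (0, 1).
#' @return estimated power in \[0, 1\].
#' @export
powerAtThreshold <- function(p, truth, threshold = 0.05) {
  stopifnot(length(p) == length(truth), threshold > 0, threshold < 1)
  if (!any(truth)) stop("no truly DE groups: power undefined")
  mean(p[truth] <= threshold)
}
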