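# Core statistic: per-species minimum p-values de-biased by a
# reciprocal harmonic-number weight, summed across experiments, with a
# moment-matched Gamma null.  Under the complete null the score is a
# weighted sum of unit-rate exponentials with mean exactly 1.

# harmonic sums H(l) = sum 1/k and A(l) = sum 1/k^2, vectorized over l
.harmonic <- function(l, squared = FALSE) {
  l <- as.integer(l)
  if (!length(l)) return(numeric())
  mx <- max(l, 1L)
  cs <- cumsum(1 / (if (squared) seq_len(mx)^2 else seq_len(mx)))
  out <- numeric(length(l))
  out[l > 0L] <- cs[l[l > 0L]]
  out
}

#' Reciprocal harmonic-number paralog weight
#'
#' `K(l) = 1 / (1 + 1/2 + ... + 1/l)`, with `K(0) = 0`.  Dividing the
#' log of the minimum p-value over `l` in-paralogs by the harmonic
#' number removes the advantage that large homology groups would
#' otherwise gain from minimum-p selection: under the null the
#' contribution of every species has unit mean regardless of `l`.
#'
#' @param l non-negative integer (vectorized).
#' @return numeric vector of weights in \[0, 1\].
#' @examples
#' paralogWeight(0:3)  # 0, 1, 2/3, 6/11
#' @export
paralogWeight <- function(l) {
  if (any(l < 0)) stop("l must be non-negative")
  H <- .harmonic(l)
  ifelse(l == 0L, 0, 1 / H)
}

# renormalize experiment weights over the contributing experiments
# (those with at least one measured gene) so that E[S] = 1
.renormWeights <- function(w, contributing) {
  stopifnot(all(w >= 0))
  w <- w[contributing]
  tot <- sum(w)
  if (tot <= 0) stop("contributing experiments carry zero total weight")
  w / tot
}

#' Most significant p-value per experiment for one homology group
#'
#' For each experiment, the in-paralogs of the group in that
#' experiment's species are looked up in its p-value table; `l` counts
#' only the genes with an observed p-value (a homolog absent from the
#' array contributes nothing), and `ptilde` is the minimum over those.
#' Experiments measuring none of the genes are reported with `l = 0`
#' and no `ptilde`.
#'
#' @param members named list species -> character vector of gene ids
#'   (as returned by [groupMembers()]).
#' @param tables list of [PValueTable-class] objects.
#' @param column which p-value column to minimize (`"p"`, `"p_up"` or
#'   `"p_down"`).
#' @return `data.frame` with columns `experiment`, `species`, `ptilde`,
#'   `l` (one row per experiment; `ptilde` is `NA` when `l = 0`).
#' @export
minPvaluePerExperiment <- function(members, tables, column = "p") {
  rows <- lapply(tables, function(tab) {
    genes <- members[[tab@species]]
    d <- tab@data[tab@data$gene %in% genes, ]
    if (nrow(d) && !column %in% names(d))
      stop(sprintf("table %s lacks column %s", tab@experiment, column))
    v <- if (nrow(d)) d[[column]] else numeric()
    data.frame(experiment = tab@experiment, species = tab@species,
               ptilde = if (length(v)) min(v) else NA_real_,
               l = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-species score of one homology group
#'
#' `S = sum_j w_j K(l_j) (-log ptilde_j)` over the contributing
#' experiments (those with `l_j >= 1`), with the experiment weights
#' renormalized over the contributors so that the null mean of `S` is
#' exactly 1.  Natural logarithms throughout: the exponential
#' order-statistic null forces base e.
#'
#' @param minPs named numeric vector of per-experiment minimum p-values
#'   (names = experiment ids; `NA` allowed where `l = 0`).
#' @param ls named integer vector of measured in-paralog counts,
#'   aligned with `minPs`.
#' @param weights named non-negative experiment weights (any scale;
#'   renormalized internally).  Default uniform.
#' @return the non-negative score (large = significant).
#' @examples
#' crossSpeciesScore(c(e1 = exp(-1)), c(e1 = 1L))  # exactly 1
#' @export
crossSpeciesScore <- function(minPs, ls, weights = NULL) {
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(ls)), names(ls))
  contributing <- names(ls)[ls >= 1L]
  if (!length(contributing))
    stop("no contributing experiment (all l = 0): group untestable")
  p <- minPs[contributing]
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("minimum p-values must lie in (0, 1]")
  wn <- .renormWeights(weights, contributing)
  sum(wn * paralogWeight(ls[contributing]) * (-log(p)))
}

#' Gamma parameters of the null distribution of the score
#'
#' Under the complete null the score is a weighted sum of independent
#' unit exponentials with mean 1 and variance
#' `sum_j w_j^2 * A(l_j) / H(l_j)^2` where `H(l) = sum 1/k` and
#' `A(l) = sum 1/k^2`.  Matching both moments gives a Gamma law with
#' shape = rate = 1/Var (shape/rate parameterization, so the null mean
#' stays 1).  The approximation is exact when every `l = 1` and the
#' weights are uniform (the Fisher case: shape = number of
#' experiments).
#'
#' @inheritParams crossSpeciesScore
#' @return list with elements `alpha` (shape) and `beta` (rate),
#'   always equal.
#' @examples
#' gammaNullParams(c(a = 1L, b = 1L, c = 1L))$alpha  # 3
#' @export
gammaNullParams <- function(ls, weights = NULL) {
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(ls)), names(ls))
  contributing <- names(ls)[ls >= 1L]
  if (!length(contributing)) stop("all l = 0: null undefined")
  wn <- .renormWeights(weights, contributing)
  l <- ls[contributing]
  v <- sum(wn^2 * .harmonic(l, squared = TRUE) / .harmonic(l)^2)
  list(alpha = 1 / v, beta = 1 / v)
}

#' Combined p-value from the Gamma null
#'
#' Upper-tail probability of Gamma(shape `alpha`, rate `beta`) at the
#' observed score; a result underflowing to zero is clamped to the
#' smallest positive double so downstream logs stay finite.
#'
#' @param score non-negative observed score.
#' @param params list with `alpha`, `beta` from [gammaNullParams()].
#' @return combined p-value in (0, 1].
#' @export
combineGroup <- function(score, params) {
  stopifnot(score >= 0, params$alpha > 0, params$beta > 0)
  p <- stats::pgamma(score, shape = params$alpha, rate = params$beta,
                     lower.tail = FALSE)
  max(p, .Machine$double.xmin)
}

#' Fisher's combined probability test
#'
#' `-2 sum log p` compared with chi-square on `2m` degrees of freedom;
#' the degenerate case of the cross-species score when every group has
#' one gene per species and weights are uniform.
#'
#' @param ps p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisherCombine(c(0.05))        # 0.05
#' fisherCombine(c(0.01, 0.04))
#' @export
fisherCombine <- function(ps) {
  if (!length(ps)) stop("empty p-value list")
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1))
    stop("p-values must lie in (0, 1]")
  max(stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                    lower.tail = FALSE),
      .Machine$double.xmin)
}

#' Draw scores from the exact null
#'
#' Samples the null score directly from its definition as
#' `sum_jk wtilde_jk Z_jk` with `Z ~ Exp(1)` and
#' `wtilde_jk = w_j / (k H(l_j))`.  The sampler is the reference for
#' the null distribution — it is exact for every weight configuration,
#' including ties, where the closed-form hypoexponential density does
#' not apply.
#'
#' @inheritParams crossSpeciesScore
#' @param nDraws number of draws.
#' @param seed integer seed.
#' @return numeric vector of `nDraws` null scores.
#' @export
sampleNullScores <- function(ls, weights = NULL, nDraws = 1e5, seed = 1L) {
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(ls)), names(ls))
  contributing <- names(ls)[ls >= 1L]
  if (!length(contributing)) stop("all l = 0: null undefined")
  wn <- .renormWeights(weights, contributing)
  l <- as.integer(ls[contributing])
  wtilde <- unlist(lapply(seq_along(l), function(j) {
    k <- seq_len(l[j])
    wn[j] / (k * .harmonic(l[j]))
  }), use.names = FALSE)
  set.seed(as.integer(seed))
  # block the draws to bound memory at ~8 MB per weight column
  out <- numeric(nDraws)
  block <- max(1L, min(nDraws, as.integer(1e6 / length(wtilde))))
  done <- 0L
  while (done < nDraws) {
    nb <- min(block, nDraws - done)
    Z <- matrix(stats::rexp(nb * length(wtilde)), nrow = nb)
    out[(done + 1L):(done + nb)] <- as.numeric(Z %*% wtilde)
    done <- done + nb
  }
  out
}

#' Monte-Carlo survival probability of the exact null
#'
#' Estimates `P(S >= score)` under the exact null by simulation; used
#' as the oracle against which the Gamma approximation is validated.
#'
#' @inheritParams sampleNullScores
#' @param score observed score.
#' @return estimated tail probability, with attribute `"se"` (binomial
#'   Monte-Carlo standard error) and `"nDraws"`.
#' @export
exactNullSurvival <- function(ls, weights = NULL, score, nDraws = 1e5,
                              seed = 1L) {
  stopifnot(nDraws >= 1e4)
  s <- sampleNullScores(ls, weights, nDraws = nDraws, seed = seed)
  est <- mean(s >= score)
  structure(est, se = sqrt(est * (1 - est) / nDraws), nDraws = nDraws)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate over
#' the tested groups (thin wrapper over [stats::p.adjust()]).
#'
#' @param ps p-values in (0, 1].
#' @return q-values: monotone in the ranking, `q >= p`, capped at 1.
#' @export
bhFdr <- function(ps) {
  if (!length(ps)) return(numeric())
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(ps, method = "BH")
}

# ---- grouped engine -------------------------------------------------

# obs: data.table(group, experiment, p); weights: named vector over all
# experiments (raw, any scale).  Returns one row per group with the
# score, Gamma shape and combined p.
.scoreGroups <- function(obs, weights, pcol = "p") {
  st <- obs[, .(ptilde = min(.SD[[1L]]), l = .N),
            by = .(group, experiment), .SDcols = pcol]
  st[, w := weights[experiment]]
  st[, w := w / sum(w), by = group]
  st[, H := .harmonic(l)]
  st[, A := .harmonic(l, squared = TRUE)]
  res <- st[, .(score = sum(w * (-log(ptilde)) / H),
                varS = sum(w^2 * A / H^2),
                n_experiments = .N), by = group]
  res[, alpha := 1 / varS]
  res[, p_combined := pmax(stats::pgamma(score, shape = alpha, rate = alpha,
                                         lower.tail = FALSE),
                           .Machine$double.xmin)]
  res[, varS := NULL]
  list(groups = res, perExperiment = st)
}

# build the long observation table (group, experiment, gene, p[, p_up,
# p_down]) by joining each table with the placements of its species
.observationTable <- function(structure, tables, needOneSided = FALSE) {
  pl <- structure@placements
  rows <- lapply(tables, function(tab) {
    if (!tab@species %in% structure@species) {
      warning(sprintf("experiment %s: species %s absent from the homology structure",
                      tab@experiment, tab@species))
      return(NULL)
    }
    d <- tab@data
    if (needOneSided && !all(c("p_up", "p_down") %in% names(d)))
      stop(sprintf("experiment %s lacks one-sided p-value columns", tab@experiment))
    sp <- pl[species == tab@species]
    m <- merge(sp, d, by = "gene", allow.cartesian = TRUE)
    if (!nrow(m)) return(NULL)
    m[, experiment := tab@experiment]
    m
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  rbindlist(rows, fill = TRUE)
}

#' Combine p-values across experiments for every homology group
#'
#' The full pipeline: per (group, experiment) minimum p-value over the
#' measured in-paralogs, harmonic de-biasing, weighted cross-species
#' score, Gamma null, combined p-value, and Benjamini-Hochberg
#' q-values over the tested groups.  Groups with no measured gene in
#' any experiment are excluded from testing (and from the FDR) and
#' reported in the `"untested"` attribute.
#'
#' With `direction = "best-one-sided"` the combination is run once on
#' the up- and once on the down-regulation p-values and the smaller
#' combined p is reported with its direction.  This reproduces the
#' common select-the-best practice and is anti-conservative under the
#' null (roughly doubling the nominal level); `doubleOneSided = TRUE`
#' applies the factor-2 correction (capped at 1).
#'
#' @param structure a [HomologyStructure-class].
#' @param tables list of [PValueTable-class] objects (one per
#'   experiment; several experiments may share a species).
#' @param weights named non-negative vector of experiment weights, or
#'   `NULL` for uniform.  Normalized to sum 1 over all experiments;
#'   renormalized per group over the contributing experiments.
#' @param direction `"two-sided"` or `"best-one-sided"`.
#' @param doubleOneSided logical; apply the factor-2 correction to the
#'   best-one-sided p (default `FALSE`).
#' @return `data.frame`, one row per tested group, sorted by group id:
#'   columns `group`, `score`, `alpha`, `p_combined`, `q_bh`,
#'   `direction`, `n_experiments`, then `ptilde.<exp>` and `l.<exp>`
#'   per experiment.  Attribute `"untested"` lists groups with no
#'   data.
#' @export
combineAll <- function(structure, tables,
                       weights = NULL,
                       direction = c("two-sided", "best-one-sided"),
                       doubleOneSided = FALSE) {
  direction <- match.arg(direction)
  expIds <- vapply(tables, function(t) t@experiment, "")
  if (anyDuplicated(expIds)) stop("duplicate experiment ids")
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(tables)), expIds)
  if (is.null(names(weights)) || !all(expIds %in% names(weights)))
    stop("weights must be named by experiment id")
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)

  obs <- .observationTable(structure, tables,
                           needOneSided = direction == "best-one-sided")
  if (is.null(obs) || !nrow(obs))
    stop("no overlap between the homology structure and any p-value table")

  if (direction == "two-sided") {
    if (!"p" %in% names(obs) || anyNA(obs$p))
      stop("two-sided combination requires a p column in every table")
    eng <- .scoreGroups(obs, weights, "p")
    res <- eng$groups
    res[, direction := "two-sided"]
    st <- eng$perExperiment
  } else {
    if (anyNA(obs$p_up) || anyNA(obs$p_down))
      stop(sprintf("missing one-sided p-values for genes: %s",
                   paste(utils::head(obs$gene[is.na(obs$p_up) | is.na(obs$p_down)], 5),
                         collapse = ", ")))
    up <- .scoreGroups(obs, weights, "p_up")$groups
    down <- .scoreGroups(obs, weights, "p_down")$groups
    stopifnot(identical(up$group, down$group))
    pickUp <- up$p_combined <= down$p_combined
    res <- data.table::copy(up)
    res[, score := ifelse(pickUp, up$score, down$score)]
    res[, p_combined := pmin(up$p_combined, down$p_combined)]
    if (doubleOneSided) res[, p_combined := pmin(1, 2 * p_combined)]
    res[, direction := ifelse(pickUp, "up", "down")]
    st <- .scoreGroups(obs, weights, "p_up")$perExperiment
    st[, ptilde := NA_real_]   # per-direction minima not meaningful here
  }

  setorder(res, group)
  res[, q_bh := bhFdr(p_combined)]

  wide <- data.table::dcast(st, group ~ experiment,
                            value.var = c("ptilde", "l"), sep = ".")
  lcols <- grep("^l\\.", names(wide), value = TRUE)
  for (cc in lcols) data.table::set(wide, i = which(is.na(wide[[cc]])),
                                    j = cc, value = 0L)
  out <- merge(res, wide, by = "group")
  setorder(out, group)
  out <- as.data.frame(out)
  attr(out, "untested") <- setdiff(structure@groupIds, out$group)
  out
}

#' Significant-group counts over experiment subsets
#'
#' Re-runs the cross-species combination on every subset of `n`
#' experiments, for each requested `n`, and counts the homology groups
#' whose combined p-value falls below `threshold`; summarizes the
#' counts by subset size.  Shows how evidence accumulates as species
#' are added (and, on a randomized structure, that it does not).
#'
#' @inheritParams combineAll
#' @param threshold combined-p cutoff in (0, 1).
#' @param subsetSizes integer vector of subset sizes (default 1..m).
#' @return `data.frame` with columns `n_experiments`, `n_subsets`,
#'   `mean_count`, `sd_count` (sd is 0 for a single configuration).
#' @export
subsetSignificanceCounts <- function(structure, tables, weights = NULL,
                                     threshold = 1e-6,
                                     subsetSizes = seq_along(tables)) {
  stopifnot(threshold > 0, threshold <= 1)
  m <- length(tables)
  if (any(subsetSizes < 1L) || any(subsetSizes > m))
    stop("subset sizes must lie in 1..number of experiments")
  expIds <- vapply(tables, function(t) t@experiment, "")
  rows <- lapply(subsetSizes, function(n) {
    combos <- utils::combn(m, n, simplify = FALSE)
    counts <- vapply(combos, function(ix) {
      w <- if (is.null(weights)) NULL else weights[expIds[ix]]
      res <- tryCatch(combineAll(structure, tables[ix], weights = w),
                      error = function(e) NULL)
      if (is.null(res)) 0L else sum(res$p_combined < threshold)
    }, integer(1))
    data.frame(n_experiments = n, n_subsets = length(combos),
               mean_count = mean(counts),
               sd_count = if (length(counts) > 1L) stats::sd(counts) else 0)
  })
  do.call(rbind, rows)
}

#' Best-one-sided combination for a single homology group
#'
#' Runs the score and Gamma null once on the up-regulation p-values and
#' once on the down-regulation p-values of one group and returns the
#' smaller combined p with its direction label; `double = TRUE`
#' applies the factor-2 selection correction.
#'
#' @inheritParams minPvaluePerExperiment
#' @param weights named experiment weights or `NULL` for uniform.
#' @param double apply the factor-2 correction (default `FALSE`).
#' @return list with `p` (combined p-value), `direction` (`"up"` or
#'   `"down"`) and the two directional p-values `p_up`, `p_down`.
#' @export
directionalCombine <- function(members, tables, weights = NULL,
                               double = FALSE) {
  oneSide <- function(col) {
    mm <- minPvaluePerExperiment(members, tables, column = col)
    ls <- stats::setNames(as.integer(mm$l), mm$experiment)
    ps <- stats::setNames(mm$ptilde, mm$experiment)
    s <- crossSpeciesScore(ps, ls, weights)
    combineGroup(s, gammaNullParams(ls, weights))
  }
  pu <- oneSide("p_up")
  pd <- oneSide("p_down")
  p <- min(pu, pd)
  if (double) p <- min(1, 2 * p)
  list(p = p, direction = if (pu <= pd) "up" else "down",
       p_up = pu, p_down = pd)
}
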