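# Previously suggested in-paralog handling strategies: pool the raw
# observations ("combined"), average them per sample ("average"), or
# keep one random in-paralog ("random"); each followed by an
# equal-variance two-sample t-test and Fisher combination across
# species.

#' Equal-variance two-sample t-test p-value
#'
#' Classical pooled-variance t-test with `length(x) + length(y) - 2`
#' degrees of freedom, implemented directly from the pooled-variance
#' formula so it can also be applied row-wise to large simulated
#' matrices.
#'
#' @param x control observations (>= 2).
#' @param y treated observations (>= 2).
#' @param alternative `"two.sided"`, `"greater"` (mean(y) > mean(x)) or
#'   `"less"`.
#' @return p-value in (0, 1].
#' @examples
#' twoSampleTPvalue(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleTPvalue <- function(x, y,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) {
    if (mean(x) == mean(y)) return(1)  # identical constant arrays: t = 0
    stop("zero pooled variance with unequal means: degenerate input")
  }
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  switch(alternative,
    two.sided = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
    greater = stats::pt(tt, df, lower.tail = FALSE),
    less = stats::pt(tt, df))
}

# vectorized row-wise pooled t-test over matrices (rows = genes)
.rowTPvalues <- function(ctrl, trt, alternative = "two.sided") {
  nx <- ncol(ctrl); ny <- ncol(trt)
  df <- nx + ny - 2
  mx <- rowMeans(ctrl); my <- rowMeans(trt)
  vx <- rowSums((ctrl - mx)^2) / (nx - 1)
  vy <- rowSums((trt - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
  tt <- (my - mx) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
    greater = stats::pt(tt, df, lower.tail = FALSE),
    less = stats::pt(tt, df))
  # identical constant rows give 0/0; the t statistic is 0 there
  p[is.nan(p)] <- 1
  pmax(p, .Machine$double.xmin)
}

#' Reduce in-paralog observations to one per-species p-value
#'
#' The three baseline strategies for a group's in-paralogs within one
#' species, given their raw expression observations:
#' \describe{
#'   \item{combined}{all in-paralog observations pooled into one
#'     control and one treated array — the pseudo-replication the
#'     pooled test inherits is intentional, the strategy is evaluated
#'     as proposed.}
#'   \item{average}{observations averaged across in-paralogs within
#'     each sample index (requires equal replicate counts).}
#'   \item{random}{one in-paralog kept (uniformly, seeded), the rest
#'     discarded.}
#' }
#' followed by [twoSampleTPvalue()].
#'
#' @param control,treated observations for the in-paralogs: numeric
#'   matrices (one row per in-paralog, one column per sample) or lists
#'   of numeric vectors (possibly of unequal length, except in average
#'   mode).
#' @param mode `"combined"`, `"average"` or `"random"`.
#' @param seed integer seed (used by `"random"` only).
#' @param alternative passed to [twoSampleTPvalue()].
#' @return per-species p-value.
#' @export
reduceInparalogs <- function(control, treated,
                             mode = c("combined", "average", "random"),
                             seed = 1L, alternative = "two.sided") {
  mode <- match.arg(mode)
  asRows <- function(z) if (is.list(z)) z else
    lapply(seq_len(nrow(rbind(z))), function(i) rbind(z)[i, ])
  ctrl <- asRows(control); trt <- asRows(treated)
  stopifnot(length(ctrl) >= 1L, length(ctrl) == length(trt))
  if (mode == "average" &&
      (length(unique(lengths(ctrl))) > 1L ||
       length(unique(lengths(trt))) > 1L))
    stop("average mode undefined: unequal replicate counts across in-paralogs")
  xy <- switch(mode,
    combined = list(unlist(ctrl), unlist(trt)),
    average = list(colMeans(do.call(rbind, ctrl)),
                   colMeans(do.call(rbind, trt))),
    random = {
      set.seed(as.integer(seed))
      i <- sample.int(length(ctrl), 1L)
      list(ctrl[[i]], trt[[i]])
    })
  twoSampleTPvalue(xy[[1L]], xy[[2L]], alternative = alternative)
}

#' Fisher combination of per-species p-values
#'
#' Cross-species p-value of the baseline strategies: delegates to
#' [fisherCombine()].
#'
#' @param ps per-species p-values in (0, 1].
#' @return combined p-value.
#' @export
baselineCombine <- function(ps) fisherCombine(ps)
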