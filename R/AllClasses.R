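#' @import methods
#' @importFrom data.table data.table setkey := .N .SD setorder rbindlist setnames as.data.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "group", "species", "gene", "experiment", "p", "ptilde", "l",
  "w", "wsum", "K", "H", "A", "score", "alpha", "p_combined", "q_bh",
  "direction", "n_measured", "truth", "arm", "value", "J"
))

setOldClass(c("data.table", "data.frame"))

#' Homology structure linking genes across species
#'
#' A `HomologyStructure` describes `n` homology groups over `m` species
#' (taxa).  Each group maps a species to an ordered set of gene
#' identifiers; several genes for one species are in-paralogs, genes in
#' different species are (co-)orthologs.  Internally the placements are
#' held as a long-format table with columns `group`, `species`, `gene`;
#' groups without any placement (allowed, e.g. an OrthoMCL line with no
#' members) are tracked through `groupIds`.
#'
#' Gene identifiers are opaque strings scoped per species: the same
#' string in two species refers to two different genes, and a gene may
#' not occur twice within one (group, species) cell.
#'
#' @slot species character vector of taxon identifiers, in order of
#'   first appearance.
#' @slot groupIds character vector of group identifiers (unique).
#' @slot placements a `data.table` with character columns `group`,
#'   `species`, `gene`, one row per gene placement.
#'
#' @seealso [readHomologene()], [readOrthomclGroups()],
#'   [synthesizeStructure()], [homologyCounts()]
#' @export
setClass("HomologyStructure",
  representation(
    species = "character",
    groupIds = "character",
    placements = "data.table"
  )
)

setValidity("HomologyStructure", function(object) {
  pl <- object@placements
  msgs <- character()
  if (!all(c("group", "species", "gene") %in% names(pl)))
    return("placements must have columns group, species, gene")
  if (anyDuplicated(object@groupIds))
    msgs <- c(msgs, "group ids must be unique")
  if (nrow(pl)) {
    if (!all(pl$species %in% object@species))
      msgs <- c(msgs, "all placement species must appear in the species list")
    if (!all(pl$group %in% object@groupIds))
      msgs <- c(msgs, "all placement groups must appear in groupIds")
    if (any(!nzchar(pl$gene)))
      msgs <- c(msgs, "gene identifiers must be non-empty")
    if (anyDuplicated(pl[, c("group", "species", "gene")]))
      msgs <- c(msgs, "duplicate gene within a (group, species) cell")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HomologyStructure from a placement table
#'
#' @param placements data.frame with columns `group`, `species`, `gene`
#'   (coerced to character).
#' @param species optional character vector fixing the species order;
#'   defaults to order of first appearance in `placements`.
#' @param groupIds optional character vector of group ids (to keep
#'   empty groups); defaults to the distinct groups in `placements`.
#' @return A [HomologyStructure-class] object.
#' @examples
#' hs <- HomologyStructure(data.frame(
#'   group = c("g1", "g1", "g1"), species = c("9606", "9606", "10090"),
#'   gene = c("a", "b", "c")))
#' homologyCounts(hs)
#' @export
HomologyStructure <- function(placements, species = NULL, groupIds = NULL) {
  pl <- data.table(
    group = as.character(placements$group),
    species = as.character(placements$species),
    gene = as.character(placements$gene)
  )
  if (is.null(species)) species <- unique(pl$species)
  if (is.null(groupIds)) groupIds <- unique(pl$group)
  new("HomologyStructure",
    species = as.character(species),
    groupIds = as.character(groupIds),
    placements = pl)
}

#' Per-experiment table of differential-expression p-values
#'
#' One `PValueTable` holds the gene-level p-values of a single
#' experiment performed in a single species.  Two-sided p-values live in
#' `p`; optionally, one-sided p-values for up- and down-regulation live
#' in `p_up` / `p_down` (both or neither).  All p-values must lie in
#' (0, 1]; exact zeros are clamped to the smallest positive double with
#' a warning at construction.
#'
#' @slot experiment character scalar, experiment identifier.
#' @slot species character scalar, taxon of the experiment.
#' @slot data `data.table` with column `gene` plus `p` and/or
#'   `p_up`,`p_down`.
#' @export
setClass("PValueTable",
  representation(
    experiment = "character",
    species = "character",
    data = "data.table"
  )
)

setValidity("PValueTable", function(object) {
  d <- object@data
  msgs <- character()
  if (length(object@experiment) != 1L || !nzchar(object@experiment))
    msgs <- c(msgs, "experiment must be a non-empty scalar")
  if (length(object@species) != 1L || !nzchar(object@species))
    msgs <- c(msgs, "species must be a non-empty scalar")
  if (!"gene" %in% names(d))
    return("data must have a gene column")
  if (anyDuplicated(d$gene))
    msgs <- c(msgs, "duplicate gene identifiers")
  has_two <- "p" %in% names(d)
  has_one <- all(c("p_up", "p_down") %in% names(d))
  if (!has_two && !has_one)
    msgs <- c(msgs, "need column p or columns p_up and p_down")
  for (col in intersect(c("p", "p_up", "p_down"), names(d))) {
    v <- d[[col]]
    if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
      msgs <- c(msgs, sprintf("column %s has p-values outside (0, 1]", col))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PValueTable
#'
#' @param experiment experiment identifier (scalar).
#' @param species taxon identifier of the experiment (scalar).
#' @param gene character vector of gene ids.
#' @param p two-sided p-values in (0, 1] (optional if one-sided given).
#' @param p_up,p_down one-sided p-values (both or neither).
#' @return A [PValueTable-class] object.
#' @examples
#' pv <- PValueTable("exp1", "9606", gene = c("a", "b"), p = c(0.01, 0.3))
#' @export
PValueTable <- function(experiment, species, gene, p = NULL,
                        p_up = NULL, p_down = NULL) {
  d <- data.table(gene = as.character(gene))
  clamp <- function(v, what) {
    v <- as.numeric(v)
    bad <- !is.finite(v) | v < 0 | v > 1
    if (any(bad))
      stop(sprintf("%s: %d p-value(s) outside [0, 1] (first offending gene: %s)",
                   what, sum(bad), d$gene[which(bad)[1L]]))
    if (any(v == 0)) {
      warning(sprintf("%s: %d zero p-value(s) clamped to smallest positive double",
                      what, sum(v == 0)))
      v[v == 0] <- .Machine$double.xmin
    }
    v
  }
  if (!is.null(p)) d[, p := clamp(p, "p")]
  if (xor(is.null(p_up), is.null(p_down)))
    stop("p_up and p_down must be given together")
  if (!is.null(p_up)) {
    d[, p_up := clamp(p_up, "p_up")]
    d[, p_down := clamp(p_down, "p_down")]
    # one-sided pairs from one symmetric statistic are complementary
    if (max(abs(d$p_up + d$p_down - 1)) > 1e-3)
      warning("p_up + p_down deviates from 1 for some genes; are the one-sided tests from the same statistic?")
  }
  new("PValueTable", experiment = as.character(experiment),
      species = as.character(species), data = d)
}

#' Scenario for the power / FDR simulation benchmark
#'
#' Captures every knob of the simulation study: the homology structure
#' over which expression is simulated, replicate counts per arm, the
#' fraction of differentially expressed (DE) groups, the grid of effect
#' sizes added to the treated arm, the noise model, how in-paralogs
#' share the effect, an optional homology-error rate applied to the
#' analysis structure, and the master seed.
#'
#' @slot structure a [HomologyStructure-class].
#' @slot nReplicates observations per arm (control = treated), >= 2.
#' @slot deFraction fraction of groups that are DE, in (0, 1).
#' @slot effects non-negative effect sizes added to the treated mean.
#' @slot noise `"gaussian"` (N(0,1)) or `"t5"` (Student t, 5 df).
#' @slot inparalogMode `"single"` (effect on one random in-paralog per
#'   species), `"concordant"` (same effect also on a second in-paralog
#'   where one exists) or `"discordant"` (half the effect subtracted
#'   from a second in-paralog).
#' @slot structureErrorRate fraction of placements scrambled in the
#'   structure handed to the analysis methods.
#' @slot seed integer master seed.
#' @export
setClass("SimulationScenario",
  representation(
    structure = "HomologyStructure",
    nReplicates = "integer",
    deFraction = "numeric",
    effects = "numeric",
    noise = "character",
    inparalogMode = "character",
    structureErrorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationScenario", function(object) {
  msgs <- character()
  if (object@nReplicates < 2L)
    msgs <- c(msgs, "nReplicates must be >= 2")
  if (object@deFraction <= 0 || object@deFraction >= 1)
    msgs <- c(msgs, "deFraction must be in (0, 1)")
  if (any(object@effects < 0))
    msgs <- c(msgs, "effects must be non-negative")
  if (!object@noise %in% c("gaussian", "t5"))
    msgs <- c(msgs, "noise must be 'gaussian' or 't5'")
  if (!object@inparalogMode %in% c("single", "concordant", "discordant"))
    msgs <- c(msgs, "inparalogMode must be single, concordant or discordant")
  if (object@structureErrorRate < 0 || object@structureErrorRate > 1)
    msgs <- c(msgs, "structureErrorRate must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationScenario-class
#' @param structure a [HomologyStructure-class] to simulate over.
#' @param nReplicates observations per arm (default 3).
#' @param deFraction fraction of DE groups (default 0.10).
#' @param effects effect-size grid (default 0:10).
#' @param noise `"gaussian"` or `"t5"`.
#' @param inparalogMode `"single"`, `"concordant"` or `"discordant"`.
#' @param structureErrorRate homology-error rate (default 0).
#' @param seed integer master seed.
#' @return A `SimulationScenario` object.
#' @export
simulationScenario <- function(structure, nReplicates = 3L,
                               deFraction = 0.10, effects = 0:10,
                               noise = c("gaussian", "t5"),
                               inparalogMode = c("single", "concordant",
                                                 "discordant"),
                               structureErrorRate = 0, seed = 1L) {
  new("SimulationScenario",
    structure = structure,
    nReplicates = as.integer(nReplicates),
    deFraction = as.numeric(deFraction),
    effects = as.numeric(effects),
    noise = match.arg(noise),
    inparalogMode = match.arg(inparalogMode),
    structureErrorRate = as.numeric(structureErrorRate),
    seed = as.integer(seed))
}

setMethod("show", "HomologyStructure", function(object) {
  cat(sprintf("HomologyStructure: %d groups, %d species, %d gene placements\n",
              length(object@groupIds), length(object@species),
              nrow(object@placements)))
  cat("  species:", paste(utils::head(object@species, 8), collapse = ", "),
      if (length(object@species) > 8) "..." else "", "\n")
})

setMethod("show", "PValueTable", function(object) {
  cat(sprintf("PValueTable '%s' (species %s): %d genes [%s]\n",
              object@experiment, object@species, nrow(object@data),
              paste(setdiff(names(object@data), "gene"), collapse = ", ")))
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(paste0("SimulationScenario: %d groups, n=%d/arm, DE fraction ",
                     "%.2f, %d effects, %s noise, %s mode, error rate %.2f, ",
                     "seed %d\n"),
              length(object@structure@groupIds), object@nReplicates,
              object@deFraction, length(object@effects), object@noise,
              object@inparalogMode, object@structureErrorRate, object@seed))
})
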