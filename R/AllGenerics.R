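#' @rdname HomologyStructure-class
#' @param x a `HomologyStructure` or `PValueTable`.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname HomologyStructure-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname HomologyStructure-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname HomologyStructure-class
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' Matrix of in-paralog counts l\[i, j\]
#'
#' Number of genes each homology group holds per species: the count
#' that drives the paralog weight and the Gamma null parameters.
#'
#' @param x a [HomologyStructure-class].
#' @return integer matrix, groups x species (dimnames set).
#' @export
setGeneric("homologyCounts", function(x) standardGeneric("homologyCounts"))

#' @rdname HomologyStructure-class
#' @param id group identifier.
#' @export
setGeneric("groupMembers", function(x, id) standardGeneric("groupMembers"))

#' @rdname PValueTable-class
#' @param x a `PValueTable`.
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))

#' @rdname PValueTable-class
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

setMethod("speciesNames", "HomologyStructure", function(x) x@species)
setMethod("speciesNames", "PValueTable", function(x) x@species)
setMethod("groupIds", "HomologyStructure", function(x) x@groupIds)
setMethod("nGroups", "HomologyStructure", function(x) length(x@groupIds))
setMethod("placements", "HomologyStructure",
          function(x) data.table::copy(x@placements))

setMethod("homologyCounts", "HomologyStructure", function(x) {
  counts <- matrix(0L, nrow = length(x@groupIds), ncol = length(x@species),
                   dimnames = list(x@groupIds, x@species))
  if (nrow(x@placements)) {
    tab <- x@placements[, .N, by = .(group, species)]
    counts[cbind(match(tab$group, x@groupIds),
                 match(tab$species, x@species))] <- tab$N
  }
  counts
})

setMethod("groupMembers", "HomologyStructure", function(x, id) {
  stopifnot(id %in% x@groupIds)
  pl <- x@placements[group == id]
  split(pl$gene, factor(pl$species, levels = unique(pl$species)))
})

setMethod("experimentId", "PValueTable", function(x) x@experiment)
setMethod("pvalues", "PValueTable", function(x) data.table::copy(x@data))
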