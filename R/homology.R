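#' Read a Homologene flat file
#'
#' Parses the tab-delimited NCBI Homologene dump (group id, taxonomy
#' id, gene id, gene symbol, protein gi, protein accession; no header).
#' Only the first three columns are semantically required; extra
#' columns are tolerated and ignored, which keeps the reader robust to
#' minor release-format drift.
#'
#' @param path path to the flat file.
#' @param taxa optional character/numeric vector of taxonomy ids; when
#'   given, placements of other taxa are dropped (groups left with no
#'   placement are kept as empty groups only if `keepEmpty`).
#' @param keepEmpty keep groups emptied by the taxon filter
#'   (default FALSE).
#' @return A [HomologyStructure-class]; genes appear in file order,
#'   species in order of first appearance.
#' @examples
#' f <- tempfile()
#' writeLines(c("3\t9606\t34", "3\t10090\t11946"), f)
#' readHomologene(f)
#' @export
readHomologene <- function(path, taxa = NULL, keepEmpty = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(HomologyStructure(
      data.frame(group = character(), species = character(),
                 gene = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed Homologene line %d: fewer than 3 tab-separated fields",
                 which(nf < 3L)[1L]))
  pl <- data.table(
    group = vapply(fields, `[[`, "", 1L),
    species = vapply(fields, `[[`, "", 2L),
    gene = vapply(fields, `[[`, "", 3L)
  )
  allGroups <- unique(pl$group)
  if (!is.null(taxa)) {
    pl <- pl[species %in% as.character(taxa)]
  }
  HomologyStructure(pl,
    groupIds = if (keepEmpty) allGroups else unique(pl$group))
}

#' Read an OrthoMCL groups file
#'
#' Each line is `group_id: taxon|gene taxon|gene ...` with
#' whitespace-separated members; member tokens are split on the first
#' `|`.  Empty lines are skipped; a line with no members yields an
#' empty group.
#'
#' @param path path to the groups file.
#' @return A [HomologyStructure-class].
#' @examples
#' f <- tempfile()
#' writeLines("g1: hs|a hs|b dr|c", f)
#' readOrthomclGroups(f)
#' @export
readOrthomclGroups <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(HomologyStructure(
      data.frame(group = character(), species = character(),
                 gene = character())))
  colon <- regexpr(":", lines, fixed = TRUE)
  if (any(colon < 0L))
    stop(sprintf("line %d: missing ':' after group id",
                 lineno[which(colon < 0L)[1L]]))
  gid <- trimws(substr(lines, 1L, colon - 1L))
  if (anyDuplicated(gid))
    stop(sprintf("duplicate group id '%s'", gid[anyDuplicated(gid)]))
  rest <- substring(lines, colon + 1L)
  members <- strsplit(trimws(rest), "\\s+")
  members <- lapply(members, function(x) x[nzchar(x)])
  rows <- vector("list", length(gid))
  for (i in seq_along(gid)) {
    toks <- members[[i]]
    if (!length(toks)) next
    bar <- regexpr("|", toks, fixed = TRUE)
    if (any(bar < 0L))
      stop(sprintf("line %d: member '%s' lacks the taxon|gene separator",
                   lineno[i], toks[which(bar < 0L)[1L]]))
    rows[[i]] <- data.table(
      group = gid[i],
      species = substr(toks, 1L, bar - 1L),
      gene = substring(toks, bar + 1L))
  }
  pl <- rbindlist(rows)
  if (is.null(pl) || !nrow(pl))
    pl <- data.table(group = character(), species = character(),
                     gene = character())
  HomologyStructure(pl, groupIds = gid)
}

#' Write a structure in the OrthoMCL groups dialect
#'
#' Inverse of [readOrthomclGroups()]; used for round-tripping
#' structures (including Homologene-derived ones) through a plain-text
#' format.
#'
#' @param structure a [HomologyStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOrthomclGroups <- function(structure, path) {
  pl <- structure@placements
  toks <- if (nrow(pl)) {
    sp <- split(paste0(pl$species, "|", pl$gene), pl$group)
    vapply(sp, paste, "", collapse = " ")
  } else character()
  body <- toks[match(structure@groupIds, names(toks))]
  body[is.na(body)] <- ""
  writeLines(paste0(structure@groupIds, ": ", body), path)
  invisible(path)
}

#' Permute genes across homology groups
#'
#' Within each species, gene identifiers are permuted uniformly at
#' random across all placements, destroying the evolutionary
#' relationships between species while keeping every group's size
#' profile: l\[i,j\] is unchanged for every group and species, and the
#' per-species gene multiset is conserved.  This is the negative
#' control used to show that cross-species signal depends on true
#' homology.
#'
#' @param structure a non-empty [HomologyStructure-class].
#' @param seed integer seed (required; one generator per call).
#' @return A new [HomologyStructure-class].
#' @export
randomizeGroups <- function(structure, seed) {
  stopifnot(nrow(structure@placements) > 0L)
  pl <- data.table::copy(structure@placements)
  set.seed(as.integer(seed))
  for (s in structure@species) {
    idx <- which(pl$species == s)
    pl$gene[idx] <- pl$gene[idx[sample.int(length(idx))]]
  }
  new("HomologyStructure", species = structure@species,
      groupIds = structure@groupIds, placements = pl)
}

#' Corrupt a homology structure at a given error rate
#'
#' Emulates imperfect homology inference: each gene placement is,
#' independently with probability `rate`, exchanged with a gene of the
#' same species from a different group.  Exchanges (rather than
#' overwrites) keep l\[i,j\] and the per-species gene multisets exactly
#' conserved.  Within a species the flagged placements trade genes via
#' a random cyclic rotation; a lone flagged placement is swapped with
#' one random placement from another group.  Species whose genes all
#' sit in a single group cannot be corrupted and are skipped with a
#' message.
#'
#' @param structure a [HomologyStructure-class].
#' @param rate per-placement error probability in \[0, 1\].
#' @param seed integer seed.
#' @return A new [HomologyStructure-class].
#' @export
injectHomologyErrors <- function(structure, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  pl <- data.table::copy(structure@placements)
  if (rate == 0 || !nrow(pl))
    return(new("HomologyStructure", species = structure@species,
               groupIds = structure@groupIds, placements = pl))
  set.seed(as.integer(seed))
  for (s in structure@species) {
    idx <- which(pl$species == s)
    if (length(unique(pl$group[idx])) < 2L) {
      message(sprintf("species %s has genes in a single group; no swap possible", s))
      next
    }
    flagged <- idx[stats::runif(length(idx)) < rate]
    if (!length(flagged)) next
    if (length(flagged) == 1L || length(unique(pl$group[flagged])) < 2L) {
      # swap each with a random placement from a different group
      for (i in flagged) {
        partners <- idx[pl$group[idx] != pl$group[i]]
        j <- partners[sample.int(length(partners), 1L)]
        tmp <- pl$gene[i]; pl$gene[i] <- pl$gene[j]; pl$gene[j] <- tmp
      }
    } else {
      ord <- sample(flagged)
      pl$gene[ord] <- pl$gene[c(ord[-1L], ord[1L])]
    }
  }
  new("HomologyStructure", species = structure@species,
      groupIds = structure@groupIds, placements = pl)
}

#' Synthesize a homology structure
#'
#' Draws, for each group and species, the number of in-paralogs
#' independently from a user-given distribution over l = 0, 1, 2, ...
#' and fills the cells with unique synthetic gene ids.  Stands in for
#' database-derived structures in simulations and tests.
#'
#' @param mSpecies number of species (labelled `"sp1"`, `"sp2"`, ...).
#' @param nGroups number of homology groups (> 0).
#' @param paralogDistribution named numeric vector: names are the
#'   supported l values, entries the probabilities (must sum to 1).
#'   Default `c("1" = 1)` gives the classical one-gene-per-species
#'   (Fisher-compatible) structure.
#' @param seed integer seed.
#' @return A [HomologyStructure-class] with groups `"g1"`..`"g<n>"`.
#' @examples
#' synthesizeStructure(2, 5, c("1" = 0.5, "2" = 0.5), seed = 1)
#' @export
synthesizeStructure <- function(mSpecies, nGroups,
                                paralogDistribution = c("1" = 1),
                                seed = 1L) {
  if (nGroups <= 0) stop("nGroups must be positive")
  lvals <- as.integer(names(paralogDistribution))
  probs <- as.numeric(paralogDistribution)
  stopifnot(all(lvals >= 0), abs(sum(probs) - 1) < 1e-8)
  set.seed(as.integer(seed))
  species <- paste0("sp", seq_len(mSpecies))
  gid <- paste0("g", seq_len(nGroups))
  cells <- vector("list", mSpecies)
  for (j in seq_len(mSpecies)) {
    l <- lvals[sample.int(length(lvals), nGroups, replace = TRUE, prob = probs)]
    tot <- sum(l)
    if (tot == 0L) next
    cells[[j]] <- data.table(
      group = rep(gid, l),
      species = species[j],
      gene = paste0(species[j], "_g", seq_len(tot)))
  }
  pl <- rbindlist(cells)
  if (is.null(pl) || !nrow(pl))
    pl <- data.table(group = character(), species = character(),
                     gene = character())
  new("HomologyStructure", species = species, groupIds = gid,
      placements = pl)
}
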