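# TSV interfaces: per-experiment p-value tables, the experiment
# manifest, and the results table.  TSV is the lingua franca of the
# upstream DE tools these p-values come from.

#' Read a per-experiment p-value table
#'
#' TSV with a header containing `gene` and `p`, or `gene`, `p_up`,
#' `p_down` when `oneSided = TRUE` (a two-sided `p` column may be
#' present as well).  Duplicate genes and out-of-range p-values are
#' rejected, naming the offending row.
#'
#' @param path path to the TSV file.
#' @param experiment experiment identifier.
#' @param species taxon of the experiment.
#' @param oneSided require one-sided columns (default `FALSE`).
#' @return A [PValueTable-class].
#' @export
readPvalueTable <- function(path, experiment, species, oneSided = FALSE) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (!nrow(d)) stop(sprintf("%s: empty p-value table", path))
  if (!"gene" %in% names(d))
    stop(sprintf("%s: missing 'gene' column", path))
  need <- if (oneSided) c("p_up", "p_down") else "p"
  if (!all(need %in% names(d)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$gene))
    stop(sprintf("%s: duplicated gene id '%s'", path,
                 d$gene[anyDuplicated(d$gene)]))
  num <- function(col) {
    if (!col %in% names(d)) return(NULL)
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("%s: column %s row %d: p-value '%s' not in [0, 1]",
                   path, col, bad[1L], d[[col]][bad[1L]]))
    v
  }
  PValueTable(experiment, species, gene = d$gene, p = num("p"),
              p_up = num("p_up"), p_down = num("p_down"))
}

#' Read an experiment manifest
#'
#' TSV with header and columns `id`, `species`, `path` and optionally
#' `weight` (non-negative; omitted or all-empty means uniform) and
#' `one_sided` (`TRUE`/`FALSE`).  Relative table paths are resolved
#' against the manifest's directory.  Weights are normalized to sum 1
#' at load.
#'
#' @param path manifest path.
#' @return list with `tables` (list of [PValueTable-class]) and
#'   `weights` (named, summing to 1).
#' @export
readManifest <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  need <- c("id", "species", "path")
  if (!all(need %in% names(d)))
    stop(sprintf("%s: manifest needs columns %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(d$id)) stop("duplicate experiment ids in manifest")
  w <- if ("weight" %in% names(d) && any(nzchar(d$weight))) {
    v <- suppressWarnings(as.numeric(d$weight))
    if (any(!is.finite(v) | v < 0)) stop("manifest weights must be non-negative numbers")
    v
  } else rep(1, nrow(d))
  if (sum(w) <= 0) stop("manifest weights sum to zero")
  oneSided <- if ("one_sided" %in% names(d))
    toupper(d$one_sided) %in% c("TRUE", "1", "YES") else rep(FALSE, nrow(d))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", d$path), d$path,
                  file.path(dirname(path), d$path))
  tables <- lapply(seq_len(nrow(d)), function(i)
    readPvalueTable(paths[i], d$id[i], d$species[i], oneSided = oneSided[i]))
  list(tables = tables,
       weights = stats::setNames(w / sum(w), d$id))
}

#' Write / read the results table
#'
#' Results are written as TSV sorted by combined p-value, numbers with
#' 6 significant digits and p-values in scientific notation; re-reading
#' restores the numeric columns.
#'
#' @param results data.frame from [combineAll()].
#' @param path output path.
#' @return `path` (write) or the restored data.frame (read).
#' @export
writeResultsTable <- function(results, path) {
  out <- results[order(results$p_combined, results$group), , drop = FALSE]
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 6, format = "g") else as.character(v)
  }
  ff <- as.data.frame(lapply(out, fmt), check.names = FALSE,
                      stringsAsFactors = FALSE)
  utils::write.table(ff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  for (cc in setdiff(names(d), c("group", "direction"))) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    if (!all(is.na(v) & nzchar(d[[cc]]))) d[[cc]] <- v
  }
  d
}
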