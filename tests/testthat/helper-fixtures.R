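# in-code fixtures shared across the suite

# one uniform-p table per species covering every gene of the structure
uniformTables <- function(st, seed = 1L, prefix = "e_") {
  pl <- placements(st)
  set.seed(seed)
  lapply(speciesNames(st), function(s) {
    g <- pl$gene[pl$species == s]
    PValueTable(paste0(prefix, s), s, gene = g, p = stats::runif(length(g)))
  })
}

# small Homologene-dialect fixture file; returns its path
homologeneFixture <- function(lines) {
  f <- tempfile(fileext = ".data")
  writeLines(lines, f)
  f
}

# l_ij matrix of a structure restricted to groups present in placements
lMatrix <- function(st) homologyCounts(st)

# gene multiset per species as a sorted vector, for conservation checks
speciesMultiset <- function(st, s) {
  pl <- placements(st)
  sort(pl$gene[pl$species == s])
}
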