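# Packaged encoding of the published Euplotes data: the 38-species genus
# tree (15 monophyletic subclades grouped into major clades A-E, outgroup
# omitted), the species-level character matrix (dargyrome type,
# frontoventral cirri count, habitat, ecozone), sampling-site salinities of
# E. curdsi, and the six comparative trait profiles.  Every cell carries a
# provenance tag: "text" (stated in prose), "table" (printed table) or
# "figure" (transcribed from tree figures; these cells cannot be verified
# against printed text and are therefore a reconstruction).

.fixture_dir <- function() {
  d <- system.file("extdata", package = "euplotia")
  if (!nzchar(d)) stop("fixture directory not found; is euplotia installed?")
  d
}

.fixture_chardefs <- function() {
  list(
    char_def("dargyrome_type",
             c("double-eurystomus", "double-patella", "single",
               "multiple", "complex")),
    char_def("FVC_count", c("7", "8", "9", "10")),
    char_def("habitat", c("freshwater", "brackish", "marine", "hypersaline")),
    char_def("ecozone", c("polar", "temperate", "tropical")))
}

#' Load a packaged fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{species_tree}{38-species genus phylogeny (\code{phylo}),
#'     polytomies preserved, node labels = bootstrap/posterior pairs.}
#'   \item{subclade_tree}{15-subclade synopsis tree (\code{phylo}).}
#'   \item{characters}{species-level \code{\link{char_matrix}} with
#'     dargyrome_type, FVC_count, habitat, ecozone (declared state spaces;
#'     "?" = missing, "|" = polymorphic).}
#'   \item{provenance}{per-cell provenance tags (data.frame).}
#'   \item{taxa_meta}{clade (A-E) and subclade membership plus free-text
#'     notes per species.}
#'   \item{subclade_map}{named vector species -> subclade.}
#'   \item{table1}{list of 6 \code{\link{species_profile}} objects for the
#'     comparative identification table.}
#'   \item{curdsi_sites}{the three sampling sites of E. curdsi with
#'     salinities (12, 32, 25 per mille).}
#'   \item{metadata}{fixture bookkeeping: taxon/subclade counts, the
#'     proportion of figure-transcribed cells, checksum status.}
#' }
#'
#' File checksums are verified against the packaged manifest; a mismatch
#' raises a warning.
#'
#' @param name one of the fixture names above.
#' @return the corresponding object.
#' @examples
#' tr <- load_fixture("species_tree")
#' cm <- load_fixture("characters")
#' @export
load_fixture <- function(name = c("species_tree", "subclade_tree",
                                  "characters", "provenance", "taxa_meta",
                                  "subclade_map", "table1", "curdsi_sites",
                                  "metadata")) {
  name <- match.arg(name)
  d <- .fixture_dir()
  switch(name,
    species_tree = read_newick(file = file.path(d, "species_tree.nwk")),
    subclade_tree = read_newick(file = file.path(d, "subclade_tree.nwk")),
    characters = read_char_matrix(file.path(d, "characters.tsv"),
                                  characters = .fixture_chardefs()),
    provenance = utils::read.table(file.path(d, "provenance.tsv"),
                                   header = TRUE, sep = "\t",
                                   colClasses = "character"),
    taxa_meta = utils::read.table(file.path(d, "taxa_meta.tsv"),
                                  header = TRUE, sep = "\t",
                                  colClasses = "character", quote = ""),
    subclade_map = {
      tm <- load_fixture("taxa_meta")
      stats::setNames(tm$subclade, tm$taxon)
    },
    table1 = {
      js <- jsonlite::fromJSON(file.path(d, "table1.json"),
                               simplifyVector = FALSE)
      lapply(js$profiles, function(p) {
        traits <- lapply(p$traits, function(tr) {
          if (is.null(tr)) return(NULL)
          v <- unlist(tr)
          if (is.numeric(v)) as.numeric(v) else as.character(v)
        })
        species_profile(p$name, traits, provenance = p$provenance)
      })
    },
    curdsi_sites = utils::read.table(file.path(d, "curdsi_sites.tsv"),
                                     header = TRUE, sep = "\t"),
    metadata = .fixture_metadata())
}

.fixture_metadata <- function() {
  d <- .fixture_dir()
  manifest <- jsonlite::fromJSON(file.path(d, "fixtures_manifest.json"))
  status <- vapply(names(manifest), function(f) {
    path <- file.path(d, f)
    file.exists(path) && unname(tools::md5sum(path)) == manifest[[f]]
  }, logical(1))
  if (!all(status))
    warning("fixture checksum mismatch: ",
            paste(names(status)[!status], collapse = ", "))
  prov <- load_fixture("provenance")
  tags <- unlist(prov[, -1L])
  tm <- load_fixture("taxa_meta")
  list(n_taxa = nrow(tm),
       n_subclades = length(unique(tm$subclade)),
       clades = sort(unique(tm$clade)),
       provenance_proportions = as.list(prop.table(table(tags))),
       figure_transcribed_fraction = unname(mean(tags == "figure")),
       checksums_ok = all(status))
}
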