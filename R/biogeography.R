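#' Classify water salinity into habitat classes
#'
#' Bins salinity (per mille) into the four habitat classes used for
#' \emph{Euplotes} biogeography: freshwater 0-5, brackish 5-25, marine
#' 25-35, hypersaline above 35.  Interval edges are resolved upward
#' (half-open bins \code{[0,5)}, \code{[5,25)}, \code{[25,35]},
#' \code{(35,Inf)}): a 25 permille site is marine, matching the usage for
#' White Sea sampling sites.
#'
#' @param salinity numeric vector of salinities in per mille (>= 0).
#' @return character vector of classes, one of \code{"freshwater"},
#'   \code{"brackish"}, \code{"marine"}, \code{"hypersaline"}.
#' @examples
#' classify_salinity(c(12, 32, 25))  # brackish, marine, marine
#' @export
classify_salinity <- function(salinity) {
  salinity <- as.numeric(salinity)
  if (anyNA(salinity)) stop("salinity must be numeric and non-missing")
  if (any(salinity < 0)) stop("negative salinity")
  out <- character(length(salinity))
  out[salinity < 5] <- "freshwater"
  out[salinity >= 5 & salinity < 25] <- "brackish"
  out[salinity >= 25 & salinity <= 35] <- "marine"
  out[salinity > 35] <- "hypersaline"
  out
}

#' Majority-rule consensus of states within a subclade
#'
#' Applies the majority rule used to colour subclade branches on the genus
#' synopsis tree: missing values are dropped, and a state is the consensus
#' only if it holds a strict majority (> 50 percent) of the remaining
#' votes.  A plurality without majority is an explicit tie listing the
#' top-voted states.  The result is invariant under permutation of the
#' input.
#'
#' @param states character vector (multiset) of states; \code{NA} = missing.
#' @return list with \code{state} (the consensus, or \code{NA} on a tie),
#'   \code{tie} (logical), \code{tied_states}, \code{counts}.
#' @export
subclade_consensus <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) stop("all values missing: no consensus possible")
  tab <- table(states)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) == 1L && top > sum(tab) / 2) {
    list(state = winners, tie = FALSE, tied_states = character(0),
         counts = tab)
  } else {
    list(state = NA_character_, tie = TRUE, tied_states = sort(winners),
         counts = tab)
  }
}

#' Collapse a species-level matrix to subclade level
#'
#' Derives the subclade-level character matrix (the synopsis-tree view)
#' from the species matrix by majority-rule consensus within each subclade.
#' Ties become polymorphic cells; subclades with only missing values stay
#' missing.  Polymorphic species cells contribute one vote per state.
#'
#' @param data a \code{\link{char_matrix}} at species level.
#' @param mapping named character vector: species -> subclade label.
#' @return a \code{char_matrix} with one row per subclade (character state
#'   spaces are carried over).
#' @export
collapse_to_subclades <- function(data, mapping) {
  stopifnot(inherits(data, "char_matrix"))
  sub <- mapping[data$taxa]
  if (anyNA(sub))
    stop("no subclade mapping for: ",
         paste(data$taxa[is.na(sub)], collapse = ", "))
  subclades <- unique(unname(sub))
  nc <- length(data$characters)
  enc <- matrix("?", length(subclades), nc,
                dimnames = list(subclades, names(data$characters)))
  for (j in seq_len(nc)) {
    for (sc in subclades) {
      votes <- unlist(data$cells[sub == sc, j])
      if (is.null(votes) || !length(votes)) next
      cons <- subclade_consensus(votes)
      enc[sc, j] <- if (cons$tie) paste(cons$tied_states, collapse = "|")
                    else cons$state
    }
  }
  char_matrix(enc, characters = data$characters)
}

#' Count independent invasions of a habitat (or other) state
#'
#' Delegates to the parsimony machinery: fits the character on the tree and
#' returns the min-max interval, over all most-parsimonious
#' reconstructions, of independent origins of \code{state} -- e.g. how many
#' times freshwater was invaded, or how often polar waters were colonised.
#'
#' @param tree a rooted \code{phylo}.
#' @param data a \code{\link{char_matrix}} holding the habitat/ecozone
#'   character.
#' @param state target state label.
#' @param character character name (default \code{"habitat"}).
#' @return integer vector \code{c(min, max)}.
#' @export
count_invasions <- function(tree, data, state, character = "habitat") {
  fit <- ancestral_parsimony(tree, data, character)
  count_origins(fit, state)
}
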