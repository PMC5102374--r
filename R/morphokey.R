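#' Define a morphospecies trait profile
#'
#' A profile maps trait names to either a numeric interval (ranges from the
#' literature; point estimates are conventionally widened to +/- 10 percent
#' before being stored) or a set of categorical states.  The fixed schema
#' used for \emph{Euplotes} comparisons is: \code{size_length_um},
#' \code{shape}, \code{peristome_extent_pct}, \code{AZM_membranelles},
#' \code{dorsal_ridges}, \code{dargyrome_type}, \code{FVC_count},
#' \code{dorsolateral_kineties}, \code{middorsal_dikinetids}.
#'
#' @param name species label.
#' @param traits named list; numeric traits as length-2 \code{c(min, max)},
#'   categorical traits as character vectors, missing traits as \code{NULL}
#'   or omitted.
#' @param provenance citation string.
#' @return an object of class \code{species_profile}.
#' @export
species_profile <- function(name, traits, provenance = "") {
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    if (is.null(tr)) next
    if (is.numeric(tr)) {
      if (length(tr) != 2L || tr[1L] > tr[2L])
        stop("profile '", name, "', trait '", tn,
             "': numeric trait must be c(min, max) with min <= max")
    } else if (!is.character(tr)) {
      stop("profile '", name, "', trait '", tn,
           "': must be numeric interval or character states")
    }
  }
  structure(list(name = name, traits = traits, provenance = provenance),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("species_profile:", x$name, "\n")
  for (tn in names(x$traits)) {
    tr <- x$traits[[tn]]
    val <- if (is.null(tr)) "?" else if (is.numeric(tr))
      sprintf("[%g, %g]", tr[1L], tr[2L]) else paste(tr, collapse = " | ")
    cat(sprintf("  %-24s %s\n", tn, val))
  }
  invisible(x)
}

#' Is a measured value compatible with a profile trait?
#'
#' Numeric values are compatible when inside the interval (inclusive);
#' categorical values when contained in the profile's state set.  A missing
#' value on either side is compatible by convention -- absence of an
#' observation is never evidence of mismatch.
#'
#' @param value a single measured value (number or state), or \code{NA}.
#' @param trait the profile trait (interval, state set, or \code{NULL}).
#' @return logical.
#' @export
trait_compatible <- function(value, trait) {
  if (is.null(trait) || length(value) == 0L || all(is.na(value))) return(TRUE)
  if (is.numeric(trait)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("numeric trait compared against non-numeric value")
    return(v >= trait[1L] && v <= trait[2L])
  }
  as.character(value) %in% trait
}

#' Identify a specimen against a set of species profiles
#'
#' Scores every profile by the number of measured traits incompatible with
#' it, and reports candidates sorted by (incompatibility count, name).  A
#' unique candidate with zero incompatibilities is reported as the
#' identification; ties at zero mean the measured traits cannot separate
#' the candidates.  The result is invariant under permutation of the
#' profile list and idempotent.
#'
#' @param specimen named list/vector of measured trait values (missing
#'   traits omitted or \code{NA}).
#' @param profiles list of \code{\link{species_profile}}.
#' @return object of class \code{morpho_id}: list with \code{table}
#'   (data.frame species, incompatible, checked, mismatched_traits),
#'   \code{identified} (species name or \code{NA}), \code{unique} (logical).
#' @export
identify_specimen <- function(specimen, profiles) {
  if (!length(profiles)) stop("empty profile list")
  specimen <- as.list(specimen)
  rows <- lapply(profiles, function(p) {
    shared <- intersect(names(specimen), names(p$traits))
    bad <- character(0); checked <- 0L
    for (tn in shared) {
      v <- specimen[[tn]]
      if (is.null(v) || all(is.na(v))) next
      if (is.null(p$traits[[tn]])) next
      checked <- checked + 1L
      if (!trait_compatible(v, p$traits[[tn]])) bad <- c(bad, tn)
    }
    data.frame(species = p$name, incompatible = length(bad),
               checked = checked,
               mismatched_traits = paste(bad, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$incompatible, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  zero <- tab$species[tab$incompatible == 0L]
  structure(list(table = tab,
                 identified = if (length(zero) == 1L) zero else NA_character_,
                 unique = length(zero) == 1L),
            class = "morpho_id")
}

#' @export
print.morpho_id <- function(x, ...) {
  if (x$unique) {
    cat("Identification:", x$identified, "(unique zero-mismatch candidate)\n")
  } else {
    cat("No unique identification.\n")
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Traits that unambiguously separate two species profiles
#'
#' Returns the trait names whose values cannot overlap between the two
#' profiles: disjoint numeric intervals (an interval touching at a single
#' shared endpoint still counts as overlapping) or disjoint categorical
#' state sets.  A trait missing from either profile is never
#' discriminating.  This reproduces the "unambiguously different" notion
#' used to bold cells in comparative tables of Euplotes morphospecies.
#'
#' @param a,b \code{\link{species_profile}} objects.
#' @return character vector of trait names (possibly empty).
#' @export
discriminating_characters <- function(a, b) {
  stopifnot(inherits(a, "species_profile"), inherits(b, "species_profile"))
  shared <- intersect(names(a$traits), names(b$traits))
  out <- character(0)
  for (tn in shared) {
    ta <- a$traits[[tn]]; tb <- b$traits[[tn]]
    if (is.null(ta) || is.null(tb)) next
    disjoint <- if (is.numeric(ta) && is.numeric(tb)) {
      ta[2L] < tb[1L] || tb[2L] < ta[1L]
    } else if (!is.numeric(ta) && !is.numeric(tb)) {
      length(intersect(ta, tb)) == 0L
    } else {
      stop("trait '", tn, "': numeric/categorical type mismatch between profiles")
    }
    if (disjoint) out <- c(out, tn)
  }
  out
}
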