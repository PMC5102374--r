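#' Define a categorical character and its cost model
#'
#' A character is a named, ordered list of state labels plus a change-cost
#' model: either unordered (every change costs 1, the Fitch model) or a
#' custom square cost matrix (zero diagonal, non-negative entries) for
#' Sankoff reconstruction, e.g. a loss-biased model for cirral counts.
#'
#' @param name character scalar.
#' @param states character vector of >= 2 unique state labels.
#' @param cost optional numeric matrix, \code{length(states)} square, zero
#'   diagonal, non-negative; \code{NULL} means unordered unit costs.
#' @return an object of class \code{char_def}.
#' @export
char_def <- function(name, states, cost = NULL) {
  states <- as.character(states)
  if (length(states) < 2L) stop("character '", name, "': need >= 2 states")
  if (anyDuplicated(states)) stop("character '", name, "': duplicate states")
  if (!is.null(cost)) {
    cost <- as.matrix(cost)
    k <- length(states)
    if (nrow(cost) != k || ncol(cost) != k)
      stop("character '", name, "': cost matrix must be ", k, "x", k)
    if (any(diag(cost) != 0)) stop("character '", name, "': cost diagonal must be 0")
    if (any(cost < 0)) stop("character '", name, "': negative cost")
    dimnames(cost) <- list(states, states)
  }
  structure(list(name = name, states = states, cost = cost),
            class = "char_def")
}

#' Loss-only cost matrix for ordered count characters
#'
#' For integer-valued states (e.g. frontoventral cirri counts) builds a cost
#' matrix where any decrease costs 1 (a single loss event, whether one or
#' several cirri are lost at once) and any increase (a regain) costs
#' \code{gain_penalty}.  With a large penalty this encodes an
#' effectively irreversible, Dollo-like reading of cirral evolution.
#'
#' @param states character or numeric vector of states, ordered by value.
#' @param gain_penalty cost of any increase (default 10).
#' @return a numeric cost matrix with state dimnames.
#' @export
loss_cost_matrix <- function(states, gain_penalty = 10) {
  v <- as.numeric(states)
  if (anyNA(v)) stop("states must be numeric-valued for a loss-only model")
  k <- length(v)
  cost <- matrix(0, k, k, dimnames = list(as.character(states), as.character(states)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (v[j] < v[i]) cost[i, j] <- 1
    if (v[j] > v[i]) cost[i, j] <- gain_penalty
  }
  cost
}

#' Construct a taxon-by-character state matrix
#'
#' Cells hold a single state, a set of states (a polymorphic taxon, e.g. a
#' euryhaline species recorded from both brackish and marine samples), or
#' missing.  Missing is a first-class value: in parsimony it contributes no
#' constraint (the tip is allowed every state at zero cost).
#'
#' @param cells a data.frame or character matrix with taxa as rownames and
#'   characters as colnames; cell syntax \code{"state"},
#'   \code{"state1|state2"} or \code{"?"}.
#' @param characters list of \code{\link{char_def}}; by default state spaces
#'   are inferred from the observed states of each column.
#' @return an object of class \code{char_matrix}: list with \code{taxa},
#'   \code{characters}, and \code{cells} (list-matrix of state vectors,
#'   \code{NULL} = missing).
#' @export
char_matrix <- function(cells, characters = NULL) {
  cells <- as.matrix(cells)
  mode(cells) <- "character"
  taxa <- rownames(cells)
  if (is.null(taxa)) stop("cells must have taxon rownames")
  if (anyDuplicated(taxa))
    stop("duplicate taxon row: ", taxa[duplicated(taxa)][1L])
  cnames <- colnames(cells)
  if (is.null(cnames)) stop("cells must have character colnames")
  parsed <- matrix(vector("list", length(cells)), nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
  for (j in seq_along(cnames)) {
    for (i in seq_along(taxa)) {
      raw <- trimws(cells[i, j])
      if (is.na(raw) || raw == "?" || raw == "") next  # missing
      parsed[[i, j]] <- trimws(strsplit(raw, "|", fixed = TRUE)[[1L]])
    }
  }
  if (is.null(characters)) {
    characters <- lapply(seq_along(cnames), function(j) {
      obs <- sort(unique(unlist(parsed[, j])))
      char_def(cnames[j], obs)
    })
  }
  names(characters) <- vapply(characters, `[[`, "", "name")
  if (!setequal(names(characters), cnames))
    stop("character definitions do not match matrix columns")
  characters <- characters[cnames]
  for (j in seq_along(cnames)) {
    space <- characters[[j]]$states
    for (i in seq_along(taxa)) {
      st <- parsed[[i, j]]
      bad <- setdiff(st, space)
      if (length(bad))
        stop(sprintf("unrecognized state '%s' for taxon '%s', character '%s'",
                     bad[1L], taxa[i], cnames[j]))
    }
  }
  structure(list(taxa = taxa, characters = characters, cells = parsed),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), length(x$characters),
              paste(names(x$characters), collapse = ", ")))
  miss <- sum(vapply(x$cells, is.null, logical(1)))
  cat(sprintf("  missing cells: %d; polymorphic cells: %d\n", miss,
              sum(vapply(x$cells, function(s) length(s) > 1L, logical(1)))))
  invisible(x)
}

#' Read a character matrix from a TSV file
#'
#' First column = taxon label; header row names the characters; cell syntax
#' as in \code{\link{char_matrix}} (\code{"|"}-separated sets for
#' polymorphism, \code{"?"} for missing).
#'
#' @param path TSV file path.
#' @param characters optional list of \code{\link{char_def}} declaring state
#'   spaces; states are inferred when omitted.
#' @return a \code{char_matrix}.
#' @export
read_char_matrix <- function(path, characters = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  taxa <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- taxa
  char_matrix(m, characters = characters)
}

#' Write a character matrix to TSV
#'
#' Inverse of \code{\link{read_char_matrix}}; read-write-read is the
#' identity on matrix content.
#'
#' @param x a \code{char_matrix}.
#' @param path output TSV path.
#' @export
write_char_matrix <- function(x, path) {
  stopifnot(inherits(x, "char_matrix"))
  enc <- vapply(x$cells, function(s)
    if (is.null(s)) "?" else paste(s, collapse = "|"), character(1))
  m <- matrix(enc, length(x$taxa), length(x$characters))
  df <- data.frame(taxon = x$taxa, m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("taxon", names(x$characters))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export characters as a NEXUS-style block
#'
#' Minimal CHARACTERS/DATA block export (symbols = state indices) for
#' interoperability with parsimony programs.
#'
#' @param x a \code{char_matrix}.
#' @param path output path.
#' @export
write_nexus_characters <- function(x, path) {
  stopifnot(inherits(x, "char_matrix"))
  nt <- length(x$taxa); nc <- length(x$characters)
  rows <- vapply(seq_len(nt), function(i) {
    codes <- vapply(seq_len(nc), function(j) {
      st <- x$cells[[i, j]]
      space <- x$characters[[j]]$states
      if (is.null(st)) return("?")
      idx <- match(st, space) - 1L
      if (length(idx) > 1L) paste0("(", paste(idx, collapse = ""), ")")
      else as.character(idx)
    }, character(1))
    sprintf("    %s  %s", x$taxa[i], paste(codes, collapse = ""))
  }, character(1))
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
           "  FORMAT DATATYPE=STANDARD MISSING=? GAP=-;",
           "  MATRIX", rows, "  ;", "END;")
  writeLines(out, path)
  invisible(path)
}

#' Check taxon agreement between a matrix and a tree
#'
#' Reporting operation: lists tree tips absent from the matrix and matrix
#' taxa absent from the tree, with an overall pass flag (pass = every tree
#' tip has a matrix row; extra matrix rows are reported but tolerated).
#'
#' @param matrix a \code{char_matrix}.
#' @param tree a \code{phylo}.
#' @return list with \code{pass}, \code{missing_from_matrix},
#'   \code{missing_from_tree}.
#' @export
validate_against_tree <- function(matrix, tree) {
  stopifnot(inherits(matrix, "char_matrix"))
  validate_tree(tree)
  mm <- setdiff(tree$tip.label, matrix$taxa)
  mt <- setdiff(matrix$taxa, tree$tip.label)
  list(pass = length(mm) == 0L && length(mt) == 0L,
       missing_from_matrix = mm, missing_from_tree = mt)
}

# internal: allowed-state logical matrix (tips x states) for one character
.allowed_states <- function(matrix, tree, character) {
  if (!character %in% names(matrix$characters))
    stop("character not found: ", character)
  def <- matrix$characters[[character]]
  absent <- setdiff(tree$tip.label, matrix$taxa)
  if (length(absent))
    stop("taxa in tree but not in matrix: ",
         paste(absent, collapse = ", "),
         " (see validate_against_tree())")
  k <- length(def$states)
  tips <- tree$tip.label
  allowed <- matrix(FALSE, length(tips), k,
                    dimnames = list(tips, def$states))
  j <- match(character, names(matrix$characters))
  for (i in seq_along(tips)) {
    st <- matrix$cells[[match(tips[i], matrix$taxa), j]]
    if (is.null(st)) allowed[i, ] <- TRUE else allowed[i, match(st, def$states)] <- TRUE
  }
  allowed
}
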