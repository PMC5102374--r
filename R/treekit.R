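#' Read a rooted phylogenetic tree from Newick
#'
#' Parses a Newick string or file into an \code{ape} \code{phylo} object and
#' validates the invariants this package relies on: a single root, unique
#' non-empty tip labels, and no reticulation.  Polytomies are allowed and
#' preserved.  Internal node labels are kept verbatim; numeric labels (or
#' \code{"NN/0.MM"} bootstrap/posterior pairs, as printed on published
#' \emph{Euplotes} SSU rRNA trees) can be decoded with
#' \code{\link{node_support}}.
#'
#' Trees are treated as rooted exactly as written; no rerooting is attempted.
#'
#' @param text a Newick string (must end in \code{";"}), or \code{NULL} if
#'   \code{file} is given.
#' @param file path to a Newick file.
#' @return an object of class \code{phylo}.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("supply either `text` or `file`")
  if (is.null(text)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unparsable string")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
  tr
}

# Pre-parse scan so malformed input is reported with a character offset,
# which ape's parser does not provide.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error at character %d: unbalanced ')'", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 nchar(text), depth))
  if (!grepl(";\\s*$", text))
    stop(sprintf("Newick parse error at character %d: missing terminal ';'",
                 nchar(text)))
  invisible(TRUE)
}

#' Validate a phylo object against the package's tree invariants
#'
#' Checks that the tree is rooted (in the sense of having a unique basal
#' node), that tip labels are unique and non-empty, and that every non-root
#' node has exactly one parent.
#'
#' @param tree a \code{phylo} object.
#' @return the tree, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tips <- tree$tip.label
  if (anyNA(tips) || any(!nzchar(tips)))
    stop("tree validation error: empty tip label")
  if (anyDuplicated(tips))
    stop("tree validation error: duplicate tip label(s): ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  kids <- tree$edge[, 2L]
  if (anyDuplicated(kids))
    stop("tree validation error: node with more than one parent")
  root <- setdiff(tree$edge[, 1L], kids)
  if (length(root) != 1L)
    stop("tree validation error: tree must have exactly one root")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' Inverse of \code{\link{read_newick}}: branch lengths and internal node
#' labels (support annotations) are emitted when present, so that
#' parse -> write -> parse preserves topology, tip labels, supports and
#' lengths (up to child order, which carries no meaning).
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Decode node support annotations
#'
#' Internal Newick labels are interpreted as supports when numeric, and as
#' "bootstrap/posterior" pairs when of the form \code{"NN/0.MM"} (e.g.
#' \code{"95/1.00"}).  Non-numeric labels are returned as clade name
#' annotations.
#'
#' @param tree a \code{phylo} object.
#' @return a data.frame with one row per internal node: \code{node} (ape
#'   node number), \code{label}, \code{bootstrap} (percent), \code{posterior}
#'   (fraction), \code{clade_name}.
#' @export
node_support <- function(tree) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep(NA_character_, n_int)
  out <- data.frame(node = n_tip + seq_len(n_int), label = labs,
                    bootstrap = NA_real_, posterior = NA_real_,
                    clade_name = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_int)) {
    lab <- labs[i]
    if (is.na(lab) || !nzchar(lab)) next
    if (grepl("^[0-9.]+/[0-9.]+$", lab)) {
      parts <- as.numeric(strsplit(lab, "/", fixed = TRUE)[[1L]])
      out$bootstrap[i] <- parts[1L]
      out$posterior[i] <- parts[2L]
    } else if (grepl("^[0-9.eE+-]+$", lab) && !is.na(suppressWarnings(as.numeric(lab)))) {
      v <- as.numeric(lab)
      # bare numeric: a fraction is read as a posterior/support fraction,
      # anything larger as a bootstrap percentage
      if (v <= 1) out$posterior[i] <- v else out$bootstrap[i] <- v
    } else {
      out$clade_name[i] <- lab
    }
  }
  out
}

#' Most recent common ancestor and its clade
#'
#' Returns the unique lowest node whose descendant tip set contains the
#' query tips, together with all tips descending from it.  Used to address
#' the major clades (A-E) and subclades of the genus tree.
#'
#' @param tree a \code{phylo} object.
#' @param tips character vector of tip labels (one or more).
#' @return list with \code{node} (ape node number) and \code{tips}
#'   (character vector of all descendant tip labels).
#' @export
mrca_clade <- function(tree, tips) {
  validate_tree(tree)
  tips <- unique(as.character(tips))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) {
    return(list(node = match(tips, tree$tip.label), tips = tips))
  }
  node <- ape::getMRCA(tree, tips)
  desc <- ape::extract.clade(tree, node)$tip.label
  list(node = node, tips = sort(desc))
}

#' Dump a tree as JSON node records (debugging aid)
#'
#' @param tree a \code{phylo} object.
#' @param file optional output path.
#' @return JSON string describing nodes, parents, labels, branch lengths.
#' @export
tree_to_json <- function(tree, file = NULL) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen <- rep(NA_real_, n_all)
  if (!is.null(tree$edge.length)) blen[tree$edge[, 2L]] <- tree$edge.length
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
            else tree$node.label)
  rec <- data.frame(id = seq_len(n_all), label = labs, parent = parent,
                    branch_length = blen, is_tip = seq_len(n_all) <= n_tip,
                    stringsAsFactors = FALSE)
  js <- jsonlite::toJSON(rec, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) writeLines(js, file)
  as.character(js)
}

# internal: root node number of a phylo object
.tree_root <- function(tree) {
  setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
}

# internal: unordered bipartition fingerprint, used by tests and fixture
# checks to compare topologies irrespective of child order/rotation
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  parts <- vapply(desc[(n_tip + 1L):(n_tip + tree$Nnode)],
                  function(x) paste(sort(x), collapse = "|"), character(1))
  sort(unique(parts))
}
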