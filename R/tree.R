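#' @importFrom ape read.tree write.tree
NULL

#' Phylogeny with foreground-branch labels
#'
#' Wraps an [ape::read.tree()] `phylo` object together with a logical
#' foreground flag per edge.  Foreground branches are the ones on which the
#' branch-site alternative model allows a class of positively selected
#' sites; all other branches are background.
#'
#' @param phy A `phylo` object with branch lengths (`edge.length`),
#'   interpreted as expected substitutions per codon.
#' @param foreground Logical vector over the rows of `phy$edge` (one flag
#'   per branch).  Defaults to all background.
#' @return An object of class `selection_tree` with fields `phy` and
#'   `foreground`.
#' @export
selection_tree <- function(phy, foreground = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths")
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  ne <- nrow(phy$edge)
  if (is.null(foreground)) foreground <- rep(FALSE, ne)
  stopifnot(is.logical(foreground), length(foreground) == ne)
  structure(list(phy = phy, foreground = foreground),
            class = "selection_tree")
}

#' @export
print.selection_tree <- function(x, ...) {
  cat("selection_tree:", length(x$phy$tip.label), "tips,",
      sum(x$foreground), "foreground branch(es)\n")
  invisible(x)
}

#' Number of foreground branches
#' @param tree A `selection_tree`.
#' @export
n_foreground <- function(tree) sum(tree$foreground)

# crude structural check so parse failures report a character offset
.newick_offset_check <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(nchar(txt))
  NA_integer_
}

#' Read a Newick tree with "#1" foreground tags
#'
#' The branch-site foreground is marked with the conventional `#1` suffix
#' on a tip or internal-node label; the flag applies to the branch leading
#' to that node.  Unlabeled branches are background.  A tree with no `#1`
#' tag is valid (usable for null-model fits only).
#'
#' @param path Path to a Newick file (or a literal Newick string via
#'   `text`).
#' @param text Optional Newick string; overrides `path`.
#' @return A [selection_tree()].
#' @export
read_labeled_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  off <- .newick_offset_check(text)
  if (!is.na(off)) {
    stop("malformed Newick: unbalanced parenthesis at offset ", off)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick: parse error")
  tags <- function(labs) !is.na(labs) & grepl("#1\\s*$", labs)
  strip <- function(labs) sub("\\s*#1\\s*$", "", labs)
  tip_fg <- tags(phy$tip.label)
  phy$tip.label <- strip(phy$tip.label)
  node_fg <- rep(FALSE, phy$Nnode)
  if (!is.null(phy$node.label)) {
    node_fg <- tags(phy$node.label)
    phy$node.label <- strip(phy$node.label)
    if (all(!nzchar(phy$node.label))) phy$node.label <- NULL
  }
  ntip <- length(phy$tip.label)
  fg_nodes <- c(which(tip_fg), ntip + which(node_fg))
  foreground <- phy$edge[, 2] %in% fg_nodes
  selection_tree(phy, foreground)
}

#' Write a `selection_tree` to Newick with "#1" tags
#'
#' @param tree A `selection_tree`.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @export
write_labeled_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "selection_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  fg_nodes <- phy$edge[tree$foreground, 2]
  tip_hit <- fg_nodes[fg_nodes <= ntip]
  phy$tip.label[tip_hit] <- paste0(phy$tip.label[tip_hit], "#1")
  node_hit <- fg_nodes[fg_nodes > ntip] - ntip
  if (length(node_hit)) {
    if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
    phy$node.label[node_hit] <- paste0(phy$node.label[node_hit], "#1")
  }
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Flag every branch inside (and including the stem of) a clade as
#' foreground
#'
#' @param tree A `selection_tree`.
#' @param tips Tip labels spanning the clade (their MRCA's subtree).
#' @param include_stem Include the branch subtending the clade
#'   (default `TRUE`).
#' @return A `selection_tree` with updated foreground flags.
#' @export
label_clade_foreground <- function(tree, tips, include_stem = TRUE) {
  stopifnot(inherits(tree, "selection_tree"))
  phy <- tree$phy
  miss <- setdiff(tips, phy$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  ntip <- length(phy$tip.label)
  tipn <- match(tips, phy$tip.label)
  if (length(tipn) == 1L) {
    mrca <- tipn
  } else {
    mrca <- ape::getMRCA(phy, tipn)
  }
  desc <- .descendant_nodes(phy, mrca)
  fg_nodes <- if (include_stem) c(mrca, desc) else desc
  fg <- tree$foreground | (phy$edge[, 2] %in% fg_nodes)
  selection_tree(phy, fg)
}

.descendant_nodes <- function(phy, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- phy$edge[phy$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(phy$tip.label)])
  }
  out
}

# fit-time consistency check between alignment and tree
.check_taxon_match <- function(aln_taxa, tree) {
  tips <- tree$phy$tip.label
  miss <- setdiff(aln_taxa, tips)
  extra <- setdiff(tips, aln_taxa)
  if (length(miss) || length(extra)) {
    stop("alignment/tree taxon mismatch",
         if (length(miss)) paste0("; missing from tree: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; missing from alignment: ",
                                   paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}
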