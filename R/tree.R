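# LabeledTree: phylogeny + per-branch omega-class labels + bootstrap support,
# with Newick I/O in the PAML `#k` branch-tag dialect.

#' Construct a labeled tree
#'
#' @param tree a `phylo` object (or Newick string) with branch lengths.
#' @param branchClass integer vector of omega-class labels, one per row of
#'   `tree$edge`; defaults to all 0 (a single background class).
#' @param support optional numeric vector of bootstrap supports in [0, 1],
#'   one per internal node.
#' @return a [LabeledTree].
#' @export
LabeledTree <- function(tree, branchClass = NULL, support = numeric(0)) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (is.null(branchClass)) branchClass <- rep(0L, nrow(tree$edge))
  new("LabeledTree", tree = tree, branchClass = as.integer(branchClass),
      support = as.numeric(support))
}

#' @describeIn LabeledTree the underlying `phylo` object.
#' @param x a [LabeledTree].
#' @export
treePhylo <- function(x) x@tree

#' @describeIn LabeledTree per-edge omega-class labels (parallel to
#'   `treePhylo(x)$edge`).
#' @export
branchClasses <- function(x) x@branchClass

#' @describeIn LabeledTree per-internal-node bootstrap supports.
#' @export
branchSupport <- function(x) x@support

#' @describeIn LabeledTree number of omega classes (K).
#' @export
nOmegaClasses <- function(x) max(x@branchClass) + 1L

setMethod("show", "LabeledTree", function(object) {
  tr <- object@tree
  cat("LabeledTree:", length(tr$tip.label), "tips,",
      nOmegaClasses(object), "branch class(es)")
  if (length(object@support)) cat(", with bootstrap support")
  cat("\n  ", writeNewickTags(object), "\n", sep = "")
})

# tips descending from each node (list indexed by node number)
.descTips <- function(tr) {
  ntip <- length(tr$tip.label)
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  desc
}

#' Label the branches of a clade with an omega class
#'
#' Assigns `class` to the branches associated with the clade spanned by
#' `tips` (as represented by the tree's current rooting): either every
#' branch inside the clade plus its stem (`type = "clade"`), or the stem
#' branch only (`type = "stem"`).
#'
#' @param x a [LabeledTree].
#' @param tips character vector of leaf labels defining the clade.
#' @param class integer class to assign (> 0; 0 is background).
#' @param type `"clade"` or `"stem"`.
#' @return a new [LabeledTree] with updated branch classes.
#' @export
labelClade <- function(x, tips, class = 1L, type = c("clade", "stem")) {
  type <- match.arg(type)
  tr <- x@tree
  tipIdx <- match(tips, tr$tip.label)
  if (anyNA(tipIdx)) stop("unknown tips: ",
                          paste(tips[is.na(tipIdx)], collapse = ", "))
  desc <- .descTips(tr)
  inClade <- vapply(desc, function(d) all(d %in% tipIdx), logical(1))
  bc <- x@branchClass
  if (type == "stem") {
    # the edge whose descendant tip set is exactly `tips`
    hit <- which(vapply(seq_len(nrow(tr$edge)), function(k) {
      setequal(desc[[tr$edge[k, 2]]], tipIdx)
    }, logical(1)))
    if (!length(hit)) stop("no branch subtends exactly that tip set")
    bc[hit] <- as.integer(class)
  } else {
    bc[inClade[tr$edge[, 2]]] <- as.integer(class)
  }
  # keep class labels contiguous: recode used classes to 0..K-1
  used <- sort(unique(bc))
  bc <- match(bc, used) - 1L
  LabeledTree(tr, bc, x@support)
}

# --- Newick with PAML-style #k tags -----------------------------------------

#' Write and read Newick with branch-class tags
#'
#' `writeNewickTags` serializes a [LabeledTree] to Newick, appending the
#' PAML-style tag `#k` (before the colon) to every branch with class k > 0,
#' and writing bootstrap supports, when present, as internal node labels in
#' percent. `readNewickTags` parses that dialect back.
#'
#' @param x a [LabeledTree].
#' @param path optional file to write to.
#' @return `writeNewickTags`: the Newick string, invisibly when `path` is
#'   given; `readNewickTags`: a [LabeledTree].
#' @export
writeNewickTags <- function(x, path = NULL) {
  tr <- x@tree
  ntip <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  sup <- x@support
  fmtNode <- function(node, edgeIdx) {
    tag <- if (!is.null(edgeIdx) && x@branchClass[edgeIdx] > 0)
      paste0(" #", x@branchClass[edgeIdx]) else ""
    blen <- if (!is.null(edgeIdx) && !is.null(tr$edge.length))
      sprintf(":%.10g", tr$edge.length[edgeIdx]) else ""
    if (node <= ntip)
      return(paste0(tr$tip.label[node], tag, blen))
    inner <- paste(vapply(kids[[as.character(node)]], function(k)
      fmtNode(tr$edge[k, 2], k), character(1)), collapse = ",")
    lab <- if (length(sup)) {
      s <- sup[node - ntip]
      if (is.na(s)) "" else sprintf("%d", round(100 * s))
    } else ""
    paste0("(", inner, ")", lab, tag, blen)
  }
  root <- ntip + 1L
  txt <- paste0(fmtNode(root, NULL), ";")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname writeNewickTags
#' @param text Newick string (used when `path` is `NULL`).
#' @export
readNewickTags <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  # encode " #k" tags into labels so ape's parser accepts them
  enc <- gsub("[ \t]*#([0-9]+)", "@@\\1", text)
  tr <- ape::read.tree(text = enc)
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label, if (!is.null(tr$node.label)) tr$node.label
            else rep("", tr$Nnode))
  cls <- rep(0L, ntip + tr$Nnode)
  tagged <- grepl("@@[0-9]+$", labs)
  cls[tagged] <- as.integer(sub(".*@@([0-9]+)$", "\\1", labs[tagged]))
  labs <- sub("@@[0-9]+$", "", labs)
  tr$tip.label <- labs[seq_len(ntip)]
  nodeLabs <- labs[(ntip + 1):(ntip + tr$Nnode)]
  sup <- suppressWarnings(as.numeric(nodeLabs)) / 100
  tr$node.label <- NULL
  bc <- cls[tr$edge[, 2]]
  used <- sort(unique(bc))
  bc <- match(bc, used) - 1L
  LabeledTree(tr, bc,
              if (all(is.na(sup))) numeric(0) else sup)
}
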