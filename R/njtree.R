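# Neighbor-joining phylogeny on JTT maximum-likelihood protein distances
# with pairwise deletion and nonparametric bootstrap support.

# aligned proteins (AAStringSet / named character / character matrix)
# -> character matrix, rows = sequences
.protMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "AAStringSet")) aln <- as.character(aln)
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise ML protein distances under the JTT model
#'
#' Maximum-likelihood pairwise distances (expected substitutions/site)
#' under the Jones-Taylor-Thornton amino-acid model, computed with
#' `phangorn::dist.ml`. Gaps and ambiguity codes contribute no information
#' for a pair, which is exactly pairwise deletion; a pair must share at
#' least one informative site. Distances are capped (saturated pairs
#' otherwise blow up), with a warning.
#'
#' @param aln aligned proteins: [Biostrings::AAStringSet], named character
#'   vector, or character matrix.
#' @param cap distance ceiling in substitutions/site (default 10).
#' @return a [DistanceMatrix].
#' @export
jttDistanceMatrix <- function(aln, cap = 10) {
  m <- .protMatrix(aln)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  n <- nrow(m)
  shared <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      ns <- length(pairwiseSharedSites(paste(m[i, ], collapse = ""),
                                       paste(m[j, ], collapse = "")))
      if (ns == 0)
        stop("no shared sites between ", rownames(m)[i], " and ",
             rownames(m)[j])
      shared[i, j] <- shared[j, i] <- ns
    }
  }
  pd <- phangorn::phyDat(m, type = "AA")
  d <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  d <- d[rownames(m), rownames(m)]
  if (any(d > cap)) {
    warning("capping ", sum(d > cap & upper.tri(d)),
            " saturated distance(s) at ", cap)
    d[d > cap] <- cap
  }
  new("DistanceMatrix", d = d, sharedSites = shared)
}

#' @describeIn jttDistanceMatrix ML distance between two aligned rows.
#' @param rowA,rowB equal-length aligned protein strings.
#' @param ... passed to `jttDistanceMatrix`.
#' @export
jttDistance <- function(rowA, rowB, ...) {
  jttDistanceMatrix(c(a = as.character(rowA), b = as.character(rowB)),
                    ...)@d["a", "b"]
}

#' @describeIn jttDistanceMatrix distance matrix of a [DistanceMatrix].
#' @param dm a [DistanceMatrix].
#' @export
distances <- function(dm) dm@d

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix:", nrow(object@d), "taxa; max distance",
      sprintf("%.4g", max(object@d)), "\n")
})

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via `ape::nj`); negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero.
#' On an additive matrix the true tree and its branch lengths are recovered
#' exactly.
#'
#' @param dm a [DistanceMatrix] (or plain symmetric matrix) over >= 3 taxa.
#' @return a [LabeledTree] (all branches class 0).
#' @export
neighborJoining <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else dm
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  LabeledTree(tr)
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' JTT distances for each replicate, and reports for each internal node of
#' the original tree the fraction of replicates containing that split.
#' Deterministic for a fixed seed.
#'
#' @param aln aligned proteins (as in [jttDistanceMatrix()]).
#' @param nReps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param cap distance cap, as in [jttDistanceMatrix()].
#' @return a [LabeledTree] with per-internal-node `support` in [0, 1]
#'   (`NA` for the root of the unrooted representation).
#' @export
bootstrapSupport <- function(aln, nReps = 1000, seed = 1, cap = 10) {
  m <- .protMatrix(aln)
  orig <- neighborJoining(jttDistanceMatrix(m, cap = cap))
  set.seed(seed)
  trees <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    trees[[r]] <- suppressWarnings(
      neighborJoining(jttDistanceMatrix(m[, cols, drop = FALSE],
                                        cap = cap)))@tree
  }
  cnt <- ape::prop.clades(orig@tree, trees, rooted = FALSE)
  sup <- cnt / nReps
  sup[1] <- NA  # root of the unrooted representation carries no split
  LabeledTree(orig@tree, orig@branchClass, sup)
}

#' Export a distance matrix as a PHYLIP-style table
#'
#' @param dm a [DistanceMatrix].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
exportDistanceMatrix <- function(dm, path) {
  d <- dm@d
  con <- file(path, "w")
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i], sprintf("%.8g", d[i, ])),
                     collapse = "\t"), con)
  close(con)
  invisible(path)
}
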