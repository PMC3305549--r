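#' @import methods
#' @importFrom stats optim optimize pchisq plogis qlogis rnorm rpois runif
#'   setNames quantile median rbinom
#' @importFrom utils head read.delim write.table combn
NULL

setOldClass("phylo")

#' Multi-genome gene set
#'
#' Container for the protein and coding sequences of several genomes, the
#' input to ortholog-family detection. Every gene carries a unique identifier
#' (the names of the sequence sets) and belongs to exactly one genome.
#'
#' @slot proteins [Biostrings::AAStringSet] of protein sequences, one per gene.
#' @slot cds [Biostrings::DNAStringSet] of coding sequences, parallel to
#'   `proteins`; each CDS translates to its paired protein.
#' @slot genome character vector mapping each gene to its genome identifier.
#'
#' @exportClass GenomeSet
setClass("GenomeSet",
  representation(proteins = "AAStringSet", cds = "DNAStringSet",
                 genome = "character"))

setValidity("GenomeSet", function(object) {
  n <- length(object@proteins)
  msg <- character()
  if (length(object@cds) != n || length(object@genome) != n)
    msg <- c(msg, "proteins, cds and genome must have equal length")
  nm <- names(object@proteins)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (!identical(nm, names(object@cds)))
    msg <- c(msg, "protein and CDS names must match")
  if (length(msg)) msg else TRUE
})

#' Gap-free-capable codon alignment
#'
#' Aligned coding sequences over codon columns. Rows have equal length, a
#' multiple of three; gaps (and ambiguity codes) occupy whole codon columns.
#' After [stripGapColumns()] the alignment is strictly gap-free over the 61
#' sense codons, the form required by all likelihood machinery.
#'
#' @slot seqs [Biostrings::DNAStringSet] of equal-width aligned CDS rows.
#' @slot columnMap integer vector mapping current codon-column indices to the
#'   codon columns of the alignment the object was derived from (identity for
#'   freshly built alignments); used to report site positions in original
#'   coordinates.
#'
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", columnMap = "integer"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character()
  if (length(w) == 0) msg <- c(msg, "alignment has no sequences")
  if (length(unique(w)) > 1) msg <- c(msg, "rows must have equal length")
  if (length(w) && w[1] %% 3 != 0)
    msg <- c(msg, "row length must be a multiple of 3")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "sequence names must be present and unique")
  if (length(w) && length(object@columnMap) != w[1] %/% 3)
    msg <- c(msg, "columnMap length must equal the number of codon columns")
  if (length(msg)) msg else TRUE
})

#' Tree with per-branch rate-class labels
#'
#' An `ape` phylogeny augmented with an integer omega-class label per edge
#' (0 = background) and optional per-internal-node bootstrap supports in
#' [0, 1]. Branch classes select which omega applies to each branch in
#' branch-specific codon models, and class > 0 marks foreground branches in
#' branch-site tests.
#'
#' @slot tree a `phylo` object with branch lengths.
#' @slot branchClass integer vector, one label per row of `tree$edge`.
#' @slot support numeric vector of bootstrap supports (one per internal node,
#'   `NA` where undefined), or length 0 when absent.
#'
#' @exportClass LabeledTree
setClass("LabeledTree",
  representation(tree = "phylo", branchClass = "integer", support = "numeric"))

setValidity("LabeledTree", function(object) {
  tr <- object@tree
  msg <- character()
  if (length(object@branchClass) != nrow(tr$edge))
    msg <- c(msg, "branchClass must have one entry per edge")
  if (anyDuplicated(tr$tip.label))
    msg <- c(msg, "leaf labels must be unique")
  bc <- object@branchClass
  if (length(bc) && (any(bc < 0) ||
      !all((seq_len(max(bc) + 1) - 1) %in% unique(bc))))
    msg <- c(msg, "branch classes must form a contiguous 0..K-1 set")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    msg <- c(msg, "branch lengths must be >= 0")
  if (length(object@support) &&
      length(object@support) != tr$Nnode)
    msg <- c(msg, "support must have one entry per internal node")
  if (length(object@support) &&
      any(!is.na(object@support) &
          (object@support < 0 | object@support > 1)))
    msg <- c(msg, "supports must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GY94 codon-model parameters
#'
#' @slot kappa transition/transversion rate ratio, > 0.
#' @slot omega nonsynonymous/synonymous rate ratios, one per branch class
#'   (class k uses `omega[k + 1]`); all >= 0.
#' @slot codonFreqs named 61-vector of equilibrium sense-codon frequencies,
#'   strictly positive, summing to 1.
#' @slot freqModel `"F3x4"` (positional nucleotide frequencies) or `"F61"`
#'   (empirical codon frequencies).
#'
#' @exportClass GY94Params
setClass("GY94Params",
  representation(kappa = "numeric", omega = "numeric",
                 codonFreqs = "numeric", freqModel = "character"))

setValidity("GY94Params", function(object) {
  msg <- character()
  if (length(object@kappa) != 1 || object@kappa <= 0)
    msg <- c(msg, "kappa must be a single positive number")
  if (!length(object@omega) || any(object@omega < 0))
    msg <- c(msg, "omega values must be >= 0")
  p <- object@codonFreqs
  if (length(p) != 61 || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "codonFreqs must be 61 positive values summing to 1")
  if (!object@freqModel %in% c("F3x4", "F61"))
    msg <- c(msg, "freqModel must be F3x4 or F61")
  if (length(msg)) msg else TRUE
})

#' Fitted codon model
#'
#' @slot params fitted [GY94Params].
#' @slot tree [LabeledTree] carrying the fitted branch lengths
#'   (expected substitutions per codon).
#' @slot lnL maximized log-likelihood.
#' @slot nFreeParams number of independently optimized quantities.
#' @slot convergence list of optimizer diagnostics (per-start results,
#'   monotone best-so-far trace, convergence codes).
#'
#' @exportClass ModelFit
setClass("ModelFit",
  representation(params = "GY94Params", tree = "LabeledTree", lnL = "numeric",
                 nFreeParams = "integer", convergence = "list"))

#' Fitted branch-site model A
#'
#' Four site classes: conserved (omega0 on all branches), neutral (omega1 = 1
#' everywhere), and two selected classes where foreground branches switch to
#' omega2 while background branches keep omega0 (class 2a) or 1 (class 2b).
#'
#' @slot p0,p1 proportions of the conserved and neutral classes.
#' @slot omega0 conserved-class ratio in (0, 1).
#' @slot omega2 foreground ratio; fixed at 1 in the null model.
#' @slot kappa fitted transition/transversion ratio.
#' @slot null logical; `TRUE` for the omega2 = 1 null fit.
#' @slot lnL maximized log-likelihood.
#' @slot tree [LabeledTree] with branch lengths used (class 1 = foreground).
#' @slot codonFreqs equilibrium codon frequencies used.
#' @slot nFreeParams number of optimized parameters.
#' @slot convergence optimizer diagnostics.
#'
#' @exportClass ModelAFit
setClass("ModelAFit",
  representation(p0 = "numeric", p1 = "numeric", omega0 = "numeric",
                 omega2 = "numeric", kappa = "numeric", null = "logical",
                 lnL = "numeric", tree = "LabeledTree", codonFreqs = "numeric",
                 nFreeParams = "integer", convergence = "list"))

setValidity("ModelAFit", function(object) {
  msg <- character()
  if (object@p0 < 0 || object@p1 < 0 || object@p0 + object@p1 > 1 + 1e-8)
    msg <- c(msg, "p0, p1 must be >= 0 with p0 + p1 <= 1")
  if (object@omega0 <= 0 || object@omega0 >= 1)
    msg <- c(msg, "omega0 must lie in (0, 1)")
  if (object@null && abs(object@omega2 - 1) > 1e-10)
    msg <- c(msg, "null fit must have omega2 = 1")
  if (!object@null && object@omega2 < 1 - 1e-8)
    msg <- c(msg, "alternative fit requires omega2 >= 1")
  if (length(msg)) msg else TRUE
})

#' Likelihood ratio test result
#'
#' @slot lnLNull,lnLAlt log-likelihoods of the nested and the richer model.
#' @slot statistic 2 * (lnLAlt - lnLNull), clamped at 0.
#' @slot df degrees of freedom.
#' @slot pValue upper-tail chi-squared probability.
#'
#' @exportClass LRTResult
setClass("LRTResult",
  representation(lnLNull = "numeric", lnLAlt = "numeric",
                 statistic = "numeric", df = "integer", pValue = "numeric"))

#' All-against-all similarity hit table
#'
#' @slot hits data.frame with columns `query`, `subject`, `score` holding
#'   every ordered gene pair at or above the score threshold (no self pairs).
#' @slot genomeMap named character vector: gene id -> genome id; covers every
#'   gene appearing in `hits` (and typically all input genes).
#'
#' @exportClass HitTable
setClass("HitTable",
  representation(hits = "data.frame", genomeMap = "character"))

setValidity("HitTable", function(object) {
  h <- object@hits
  msg <- character()
  if (!all(c("query", "subject", "score") %in% names(h)))
    msg <- c(msg, "hits needs columns query, subject, score")
  else {
    if (any(h$query == h$subject)) msg <- c(msg, "self hits are not allowed")
    if (any(!is.finite(h$score))) msg <- c(msg, "scores must be finite")
    genes <- unique(c(h$query, h$subject))
    if (!all(genes %in% names(object@genomeMap)))
      msg <- c(msg, "all genes in hits must appear in genomeMap")
  }
  if (length(msg)) msg else TRUE
})

#' Best-hit (BeT) graph
#'
#' Undirected cross-genome best-hit network. An edge is symmetric when each
#' endpoint is the other's best hit in its genome, asymmetric when the
#' relation holds in one direction only.
#'
#' @slot nodes character vector of gene (or paralog-group representative) ids.
#' @slot edges data.frame with columns `from`, `to`, `kind`
#'   (`"symmetric"`/`"asymmetric"`), each unordered pair at most once.
#' @slot genomeMap named character vector: node -> genome.
#' @slot paralogs named list: representative -> all members of its collapsed
#'   within-genome paralog group.
#'
#' @exportClass BeTGraph
setClass("BeTGraph",
  representation(nodes = "character", edges = "data.frame",
                 genomeMap = "character", paralogs = "list"))

setValidity("BeTGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "kind") %in% names(e)))
    msg <- c(msg, "edges needs columns from, to, kind")
  else if (nrow(e)) {
    if (!all(e$kind %in% c("symmetric", "asymmetric")))
      msg <- c(msg, "edge kind must be symmetric or asymmetric")
    gm <- object@genomeMap
    if (any(gm[e$from] == gm[e$to]))
      msg <- c(msg, "edge endpoints must lie in different genomes")
  }
  if (length(msg)) msg else TRUE
})

#' Cluster of orthologous groups (COG)
#'
#' One orthologous family: the genes linked through best-hit triangles that
#' span three genomes, merged across triangles sharing an edge, together with
#' the inducing BeT subgraph.
#'
#' @slot clusterId character identifier.
#' @slot members character vector of member genes.
#' @slot edges data.frame (`from`, `to`, `kind`) of the inducing subgraph.
#' @slot genomeMap named character vector for the members.
#'
#' @exportClass COGCluster
setClass("COGCluster",
  representation(clusterId = "character", members = "character",
                 edges = "data.frame", genomeMap = "character"))

#' Pairwise ML distance matrix with shared-site counts
#'
#' @slot d symmetric nonnegative matrix of ML distances
#'   (substitutions/site), zero diagonal, entries capped (see
#'   [jttDistanceMatrix()]).
#' @slot sharedSites matrix of per-pair counts of sites ungapped and
#'   unambiguous in both sequences (pairwise deletion).
#'
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(d = "matrix", sharedSites = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  msg <- character()
  if (nrow(d) != ncol(d) || is.null(rownames(d)))
    msg <- c(msg, "d must be square with labels")
  else {
    if (any(abs(d - t(d)) > 1e-12)) msg <- c(msg, "d must be symmetric")
    if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(!is.finite(d)) || any(d < 0))
      msg <- c(msg, "entries must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Per-site posterior probabilities of positive selection
#'
#' @slot posterior numeric vector, per codon site, of the posterior
#'   probability that the site belongs to the positively selected classes
#'   (2a or 2b) on the foreground branches.
#' @slot site integer vector of site indices in original alignment
#'   coordinates (via the alignment's column map).
#' @slot method `"NEB"` (posteriors at the MLEs) or `"BEB"` (averaged over a
#'   prior grid on the mixture parameters).
#'
#' @exportClass SitePosterior
setClass("SitePosterior",
  representation(posterior = "numeric", site = "integer", method = "character"))

setValidity("SitePosterior", function(object) {
  msg <- character()
  if (any(object@posterior < -1e-10 | object@posterior > 1 + 1e-10))
    msg <- c(msg, "posteriors must lie in [0, 1]")
  if (!object@method %in% c("NEB", "BEB"))
    msg <- c(msg, "method must be NEB or BEB")
  if (length(object@site) != length(object@posterior))
    msg <- c(msg, "site and posterior must be parallel")
  if (length(msg)) msg else TRUE
})
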