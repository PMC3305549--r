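# COG-style ortholog family detection: all-against-all local-alignment
# scoring, paralog collapsing, best-hit (BeT) graphs, seed expansion to
# closure, and triangle-merged cluster formation.

#' All-against-all protein similarity search
#'
#' Scores every unordered gene pair (within and across genomes) by local
#' Smith-Waterman alignment with an affine gap model, and keeps ordered
#' pairs at or above `minScore`. Only score rankings matter downstream:
#' best-hit detection relies on the consistency between genome-specific
#' best hits rather than absolute similarity levels, so raw alignment
#' scores are used without bit-score calibration.
#'
#' @param genomes a [GenomeSet] with >= 2 genomes and non-empty proteomes.
#' @param substitutionMatrix scoring matrix name or matrix
#'   (default `"BLOSUM62"`).
#' @param gapOpening,gapExtension affine gap penalties (defaults 11 and 1).
#' @param minScore score threshold; `NULL` (default) estimates the
#'   background level with [backgroundScoreThreshold()].
#' @return a [HitTable].
#' @export
allAgainstAll <- function(genomes, substitutionMatrix = "BLOSUM62",
                          gapOpening = 11, gapExtension = 1,
                          minScore = NULL) {
  stopifnot(is(genomes, "GenomeSet"))
  if (length(unique(genomes@genome)) < 2)
    stop("need at least 2 genomes")
  if (any(Biostrings::width(genomes@proteins) == 0))
    stop("empty protein sequence in input")
  prot <- genomes@proteins
  n <- length(prot)
  if (is.null(minScore))
    minScore <- backgroundScoreThreshold(
      genomes, substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension)
  ids <- names(prot)
  qs <- ss <- character(0); sc <- numeric(0)
  for (j in 2:n) {
    scores <- Biostrings::pairwiseAlignment(
      prot[seq_len(j - 1)], prot[[j]], type = "local",
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension,
      scoreOnly = TRUE)
    keep <- which(scores >= minScore)
    qs <- c(qs, ids[keep]); ss <- c(ss, rep(ids[j], length(keep)))
    sc <- c(sc, scores[keep])
  }
  hits <- data.frame(query = c(qs, ss), subject = c(ss, qs),
                     score = c(sc, sc))
  new("HitTable", hits = hits, genomeMap = geneGenomes(genomes))
}

#' Background similarity threshold from shuffled sequences
#'
#' Scores local alignments between residue-shuffled versions of randomly
#' chosen input proteins and returns a high quantile of that null score
#' distribution, the default cutoff separating homology from background in
#' [allAgainstAll()].
#'
#' @inheritParams allAgainstAll
#' @param nPairs number of shuffled pairs to score.
#' @param probs quantile of the null distribution (default 0.99).
#' @param seed RNG seed for shuffling.
#' @return a single score threshold.
#' @export
backgroundScoreThreshold <- function(genomes, substitutionMatrix = "BLOSUM62",
                                     gapOpening = 11, gapExtension = 1,
                                     nPairs = 100, probs = 0.99, seed = 1) {
  prot <- as.character(genomes@proteins)
  set.seed(seed)
  shuffle <- function(s) paste(sample(strsplit(s, "")[[1]]), collapse = "")
  a <- vapply(sample(prot, nPairs, replace = TRUE), shuffle, character(1))
  b <- vapply(sample(prot, nPairs, replace = TRUE), shuffle, character(1))
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b), type = "local",
    substitutionMatrix = substitutionMatrix, gapOpening = gapOpening,
    gapExtension = gapExtension, scoreOnly = TRUE)
  unname(quantile(scores, probs))
}

#' @describeIn allAgainstAll hit entries as a data.frame.
#' @param hits a [HitTable].
#' @export
hitEntries <- function(hits) hits@hits

setMethod("show", "HitTable", function(object) {
  cat("HitTable:", nrow(object@hits), "ordered hits over",
      length(object@genomeMap), "genes in",
      length(unique(object@genomeMap)), "genomes\n")
})

# score lookup table: named vector on "query|subject"
.scoreLookup <- function(hits) {
  setNames(hits@hits$score, paste(hits@hits$query, hits@hits$subject,
                                  sep = "\u1f"))
}

.getScore <- function(lk, a, b) {
  s <- lk[paste(a, b, sep = "\u1f")]
  ifelse(is.na(s), -Inf, s)
}

#' Collapse obvious within-genome paralogs
#'
#' Two genes of one genome are grouped when each scores higher with the
#' other than with any gene of any other genome (mutual within-genome
#' dominance — the direct reading of the COG notion that orthologs are more
#' similar across genomes than any other same-genome protein is). Groups
#' are the connected components of the mutual-dominance relation; each is
#' represented downstream by its member with the highest cross-genome
#' score (ties broken lexicographically).
#'
#' @param hits a [HitTable].
#' @param genes gene ids, all from one genome (default: every gene of each
#'   genome in turn when called via [bestHits()]).
#' @return named list of character vectors (representative -> group
#'   members, singletons included).
#' @export
collapseParalogs <- function(hits, genes) {
  gm <- hits@genomeMap
  if (length(unique(gm[genes])) > 1)
    stop("genes must all come from one genome")
  lk <- .scoreLookup(hits)
  h <- hits@hits
  genomeOf <- unname(gm[genes[1]])
  cross <- h[h$query %in% genes & gm[h$subject] != genomeOf, , drop = FALSE]
  maxCross <- vapply(genes, function(g) {
    s <- cross$score[cross$query == g]
    if (length(s)) max(s) else -Inf
  }, numeric(1))
  # mutual dominance graph
  adj <- lapply(genes, function(g) character(0))
  names(adj) <- genes
  if (length(genes) > 1) {
    for (i in seq_len(length(genes) - 1)) {
      for (j in (i + 1):length(genes)) {
        a <- genes[i]; b <- genes[j]
        s <- .getScore(lk, a, b)
        if (is.finite(s) && s > maxCross[a] && s > maxCross[b]) {
          adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
        }
      }
    }
  }
  # connected components
  seen <- character(0); groups <- list()
  for (g in genes) {
    if (g %in% seen) next
    comp <- g; frontier <- g
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), comp)
      comp <- c(comp, nxt); frontier <- nxt
    }
    seen <- c(seen, comp)
    comp <- sort(comp)
    best <- comp[order(-maxCross[comp], comp)][1]
    groups[[best]] <- comp
  }
  groups[order(names(groups))]
}

#' Cross-genome best hits (BeTs)
#'
#' For every gene (or collapsed paralog-group representative) and every
#' other genome, finds the top-scoring subject in that genome. An edge is
#' symmetric when the relation is reciprocal, asymmetric otherwise. Ties
#' are broken by lexicographic gene identifier, making the result
#' deterministic.
#'
#' @param hits a [HitTable].
#' @param collapse collapse within-genome paralog groups first
#'   (default `TRUE`).
#' @return a [BeTGraph].
#' @export
bestHits <- function(hits, collapse = TRUE) {
  if (!nrow(hits@hits)) stop("empty hit table")
  gm <- hits@genomeMap
  genes <- sort(names(gm))
  paralogs <- list()
  if (collapse) {
    for (g in unique(gm)) {
      paralogs <- c(paralogs, collapseParalogs(hits, sort(genes[gm[genes] == g])))
    }
    reps <- names(paralogs)
  } else {
    reps <- genes
    paralogs <- setNames(as.list(genes), genes)
  }
  h <- hits@hits
  h <- h[h$query %in% reps & h$subject %in% reps &
           gm[h$query] != gm[h$subject], , drop = FALSE]
  # per (query, subject genome) argmax with lexicographic tie-break
  h <- h[order(h$query, gm[h$subject], -h$score, h$subject), , drop = FALSE]
  key <- paste(h$query, gm[h$subject], sep = "\u1f")
  top <- h[!duplicated(key), , drop = FALSE]
  bet <- setNames(top$subject, paste(top$query, gm[top$subject],
                                     sep = "\u1f"))
  edges <- data.frame(from = character(0), to = character(0),
                      kind = character(0))
  if (nrow(top)) {
    a <- pmin(top$query, top$subject); b <- pmax(top$query, top$subject)
    sym <- vapply(seq_len(nrow(top)), function(k) {
      back <- bet[paste(top$subject[k], gm[top$query[k]], sep = "\u1f")]
      !is.na(back) && back == top$query[k]
    }, logical(1))
    edges <- data.frame(from = a, to = b,
                        kind = ifelse(sym, "symmetric", "asymmetric"))
    edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("BeTGraph", nodes = reps, edges = edges, genomeMap = gm[reps],
      paralogs = paralogs)
}

#' @describeIn bestHits edge list of a [BeTGraph].
#' @param bets a [BeTGraph].
#' @export
betEdges <- function(bets) bets@edges

setMethod("show", "BeTGraph", function(object) {
  cat("BeTGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (",
      sum(object@edges$kind == "symmetric"), "symmetric )\n")
})

#' Expand an orthologous set from a seed gene
#'
#' Iteratively adds the best hits of all current members and the members of
#' their collapsed paralog groups until no new gene is found (the fixed
#' point of the search-and-requery procedure; the member set is monotone
#' nondecreasing and bounded, so iteration terminates).
#'
#' @param seedGene gene identifier present in `hits`.
#' @param hits a [HitTable].
#' @param collapse collapse paralogs (default `TRUE`).
#' @return sorted character vector of member genes (including the seed).
#' @export
expandFromSeed <- function(seedGene, hits, collapse = TRUE) {
  if (!seedGene %in% names(hits@genomeMap))
    stop("seed gene not found: ", seedGene)
  bets <- bestHits(hits, collapse = collapse)
  repOf <- setNames(rep(names(bets@paralogs),
                        lengths(bets@paralogs)),
                    unlist(bets@paralogs))
  nbr <- split(c(bets@edges$to, bets@edges$from),
               c(bets@edges$from, bets@edges$to))
  members <- seedGene
  repeat {
    reps <- unique(repOf[members])
    grown <- unique(c(members,
                      unlist(bets@paralogs[reps], use.names = FALSE),
                      unlist(nbr[reps], use.names = FALSE)))
    grown <- grown[!is.na(grown)]
    if (setequal(grown, members)) break
    members <- grown
  }
  sort(unique(members))
}

#' Form COG clusters by triangle merging
#'
#' Keeps the BeT edges that belong to at least one best-hit triangle and
#' merges triangles that share an edge into one cluster (the classic COG
#' construction rule); triangles sharing only a vertex remain separate.
#' Every BeT edge crosses genomes, so each triangle automatically spans
#' three genomes. Output is deterministic and invariant to input gene
#' ordering (clusters and members are sorted).
#'
#' @param bets a [BeTGraph].
#' @param minGenomes minimum genomes per reported cluster (default 3,
#'   guaranteed by triangle formation).
#' @return list of [COGCluster] objects.
#' @export
formCOGs <- function(bets, minGenomes = 3) {
  e <- bets@edges
  if (!nrow(e)) return(list())
  nbr <- lapply(split(c(e$to, e$from), c(e$from, e$to)), unique)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\u1f")
  keys <- ekey(e$from, e$to)
  # union-find over edges, merging within each triangle
  parent <- new.env(parent = emptyenv())
  for (k in keys) assign(k, k, envir = parent)
  find <- function(x) {
    while ((p <- get(x, envir = parent)) != x) {
      assign(x, get(p, envir = parent), envir = parent)  # path halving
      x <- p
    }
    x
  }
  inTri <- character(0)
  for (k in seq_len(nrow(e))) {
    a <- e$from[k]; b <- e$to[k]
    common <- intersect(nbr[[a]], nbr[[b]])
    if (!length(common)) next
    inTri <- c(inTri, keys[k])
    for (cc in common) {
      assign(find(ekey(a, cc)), find(keys[k]), envir = parent)
      assign(find(ekey(b, cc)), find(keys[k]), envir = parent)
    }
  }
  inTri <- unique(inTri)
  if (!length(inTri)) return(list())
  comp <- split(inTri, vapply(inTri, find, character(1)))
  membership <- lapply(comp, function(ks)
    sort(unique(unlist(strsplit(ks, "\u1f")))))
  membership <- membership[order(vapply(membership, paste,
                                        character(1), collapse = "|"))]
  out <- list()
  for (i in seq_along(membership)) {
    mem <- membership[[i]]
    if (length(unique(bets@genomeMap[mem])) < minGenomes) next
    sub <- e[e$from %in% mem & e$to %in% mem, , drop = FALSE]
    rownames(sub) <- NULL
    out[[length(out) + 1]] <- new("COGCluster",
      clusterId = paste0("COG", sprintf("%03d", length(out) + 1)),
      members = mem, edges = sub, genomeMap = bets@genomeMap[mem])
  }
  out
}

#' @describeIn formCOGs member genes of a cluster.
#' @param cluster a [COGCluster].
#' @export
clusterMembers <- function(cluster) cluster@members

setMethod("show", "COGCluster", function(object) {
  cat("COGCluster", object@clusterId, ":", length(object@members),
      "genes in", length(unique(object@genomeMap)), "genomes,",
      nrow(object@edges), "BeT edges\n")
})

#' Per-cluster diagnostics
#'
#' Replaces manual case-by-case curation with a reported diagnostic table:
#' genome coverage and the range of within-cluster similarity scores. No
#' clusters are deleted automatically.
#'
#' @param clusters list of [COGCluster].
#' @param hits the [HitTable] used to form them.
#' @return data.frame with one row per cluster.
#' @export
cogDiagnostics <- function(clusters, hits) {
  lk <- .scoreLookup(hits)
  do.call(rbind, lapply(clusters, function(cl) {
    prs <- if (length(cl@members) > 1) combn(cl@members, 2) else
      matrix(character(0), 2, 0)
    sc <- .getScore(lk, prs[1, ], prs[2, ])
    sc <- sc[is.finite(sc)]
    data.frame(cluster = cl@clusterId, nGenes = length(cl@members),
               nGenomes = length(unique(cl@genomeMap)),
               minScore = if (length(sc)) min(sc) else NA_real_,
               maxScore = if (length(sc)) max(sc) else NA_real_)
  }))
}

#' Export and import a cluster's BeT network
#'
#' Writes the edge list with its symmetric/asymmetric kind attribute as TSV
#' (lossless round trip via `readNetworkTSV`) or GraphML (via igraph).
#'
#' @param cluster a [COGCluster] (or [BeTGraph]).
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(cluster, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  e <- cluster@edges
  if (format == "tsv") {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(e, directed = FALSE)
    igraph::E(g)$kind <- e$kind
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportNetwork
#' @export
readNetworkTSV <- function(path) {
  read.delim(path, colClasses = c("character", "character", "character"))
}

#' Write cluster membership table
#'
#' @param clusters list of [COGCluster].
#' @param path output TSV (`cluster`, `genome`, `gene`).
#' @return the path, invisibly.
#' @export
exportClusterTable <- function(clusters, path) {
  tab <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster = cl@clusterId, genome = unname(cl@genomeMap),
               gene = cl@members)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
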