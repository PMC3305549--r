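# Shared fixtures and independent oracles used across the suite.

# deterministic random unrooted tree with tip labels t1..tn
randomTestTree <- function(n, seed, lo = 0.05, hi = 0.3) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, lo, hi)))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

uniformPi <- function() cogselect::uniformCodonFreqs()

randomCodonAln <- function(nseq, nsites, seed, names = NULL) {
  set.seed(seed)
  codons <- names(uniformPi())
  rows <- vapply(seq_len(nseq), function(i)
    paste(sample(codons, nsites, replace = TRUE), collapse = ""),
    character(1))
  names(rows) <- names %||% paste0("t", seq_len(nseq))
  CodonAlignment(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------------

# matrix exponential by scaling-and-squaring with a long Taylor series:
# slow but accurate to near machine precision, and independent of the
# package's eigendecomposition path
taylorExpm <- function(A) {
  k <- max(0L, ceiling(log2(max(1e-12, norm(A, "1")) / 1e-3)))
  B <- A / 2^k
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (m in 1:20) {
    term <- term %*% B / m
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# brute-force log-likelihood by enumerating internal-node states; transition
# matrices come from transitionProbs (itself checked against taylorExpm), so
# this oracle isolates the pruning recursion
bruteForceLogLik <- function(aln, tree, params) {
  tr <- tree@tree
  ntip <- length(tr$tip.label)
  pi <- params@codonFreqs
  states <- sapply(seq_len(codonLength(aln)), function(k) {
    m <- substring(as.character(alignedSeqs(aln)), 3 * k - 2, 3 * k)
    match(m, names(pi))
  })
  states <- matrix(states, nrow = length(aln))
  rownames(states) <- names(alignedSeqs(aln))
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    Q <- buildRateMatrix(params, tree@branchClass[e])
    transitionProbs(Q, tr$edge.length[e])
  })
  internals <- (ntip + 1):(ntip + tr$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:61), tr$Nnode)))
  nodeState <- function(assign, v, s) {
    if (v <= ntip) states[tr$tip.label[v], s] else assign[v - ntip]
  }
  total <- 0
  for (s in seq_len(ncol(states))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      a <- grid[g, ]
      term <- pi[a[1]]    # root = ntip + 1 under ape numbering
      for (e in seq_len(nrow(tr$edge))) {
        term <- term * Ps[[e]][nodeState(a, tr$edge[e, 1], s),
                               nodeState(a, tr$edge[e, 2], s)]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# brute-force COG clusters: enumerate all triangles over the edge set,
# merge triangles sharing an edge via union-find over edges
bruteForceCogs <- function(edges, genomeOf) {
  if (!nrow(edges)) return(list())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- key(edges$from, edges$to)
  nodes <- unique(c(edges$from, edges$to))
  adj <- lapply(setNames(nodes, nodes), function(v)
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  triangles <- list()
  if (length(nodes) >= 3) {
    trip <- combn(sort(nodes), 3)
    for (t in seq_len(ncol(trip))) {
      a <- trip[1, t]; b <- trip[2, t]; c <- trip[3, t]
      if (b %in% adj[[a]] && c %in% adj[[a]] && c %in% adj[[b]])
        triangles[[length(triangles) + 1]] <- c(a, b, c)
    }
  }
  if (!length(triangles)) return(list())
  # union-find over triangle edges
  parent <- setNames(ek, ek)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  union2 <- function(x, y) parent[[find(x)]] <<- find(y)
  triEdges <- character(0)
  for (tri in triangles) {
    e1 <- key(tri[1], tri[2]); e2 <- key(tri[1], tri[3])
    e3 <- key(tri[2], tri[3])
    union2(e1, e2); union2(e2, e3)
    triEdges <- unique(c(triEdges, e1, e2, e3))
  }
  comps <- split(triEdges, vapply(triEdges, find, character(1)))
  out <- lapply(comps, function(es)
    sort(unique(unlist(strsplit(es, " ")))))
  unname(out[order(vapply(out, paste, character(1), collapse = "|"))])
}

# random BeT-graph edge list over nGenomes genomes with nGenes genes
randomBetGraph <- function(nGenes, nGenomes, seed, pEdge = 0.3) {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  genomeOf <- setNames(sample(paste0("G", seq_len(nGenomes)), nGenes,
                              replace = TRUE), genes)
  pairs <- t(combn(genes, 2))
  cross <- genomeOf[pairs[, 1]] != genomeOf[pairs[, 2]]
  keep <- cross & runif(nrow(pairs)) < pEdge
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      kind = sample(c("symmetric", "asymmetric"),
                                    sum(keep), replace = TRUE))
  list(edges = edges, genomeOf = genomeOf)
}
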