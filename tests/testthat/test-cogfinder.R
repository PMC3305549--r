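# helper: HitTable from an explicit score list; symmetric = TRUE mirrors
# every ordered pair (the shape allAgainstAll produces)
makeHits <- function(scores, genomeOf, symmetric = TRUE) {
  hits <- do.call(rbind, lapply(scores, function(s)
    data.frame(query = s[[1]], subject = s[[2]],
               score = as.numeric(s[[3]]))))
  if (symmetric)
    hits <- unique(rbind(hits, data.frame(query = hits$subject,
                                          subject = hits$query,
                                          score = hits$score)))
  new("HitTable", hits = hits, genomeMap = genomeOf)
}

test_that("self-alignment score equals the diagonal BLOSUM62 path", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(41)
  aas <- rownames(BLOSUM62)[1:20]
  s <- paste(sample(aas, 100, replace = TRUE), collapse = "")
  gs <- GenomeSet(c(g1 = s, g2 = s), c(g1 = strrep("AAA", 100),
                                       g2 = strrep("AAA", 100)),
                  c("A", "B"))
  ht <- allAgainstAll(gs, minScore = 1)
  diagScore <- sum(BLOSUM62[cbind(strsplit(s, "")[[1]],
                                  strsplit(s, "")[[1]])])
  expect_equal(hitEntries(ht)$score[1], diagScore)
})

test_that("alignment scores are symmetric and thresholded", {
  sim <- simulateGenomes(3, 1, 2, seed = 43, nCodons = 50)
  ht <- allAgainstAll(sim$genomes, minScore = 1)
  h <- hitEntries(ht)
  key <- paste(h$query, h$subject)
  rev <- paste(h$subject, h$query)
  expect_setequal(key, rev)
  m <- setNames(h$score, key)
  expect_equal(unname(m[key]), unname(m[rev]))
  # the background threshold removes (almost) all cross-family pairs while
  # keeping every within-family pair
  bg <- backgroundScoreThreshold(sim$genomes)
  ht2 <- allAgainstAll(sim$genomes, minScore = bg)
  h2 <- hitEntries(ht2)
  sameFam <- sub("^G[0-9]+_", "", h2$query) ==
    sub("^G[0-9]+_", "", h2$subject)
  famIds <- sub("^G[0-9]+_", "", geneIds(sim$genomes))
  nWithin <- sum(outer(famIds, famIds, "==") &
                 upper.tri(diag(length(famIds))))
  nCross <- choose(length(famIds), 2) - nWithin
  expect_equal(sum(sameFam) / 2, nWithin)        # no homolog lost
  expect_lte(sum(!sameFam) / 2 / nCross, 0.2)    # background mostly gone
})

test_that("best hits follow reciprocal-top-hit classification", {
  # reciprocal top hit: a1 <-> b1; the lower-scoring b2 gets no edge
  gm <- c(a1 = "A", b1 = "B", b2 = "B")
  ht <- makeHits(list(list("a1", "b1", 100), list("a1", "b2", 90),
                      list("b1", "a1", 100)), gm, symmetric = FALSE)
  e <- betEdges(bestHits(ht, collapse = FALSE))
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "a1"); expect_equal(e$to, "b1")
  expect_equal(e$kind, "symmetric")

  # non-reciprocal: b1 prefers a2, so (a1, b1) is asymmetric
  gm2 <- c(a1 = "A", a2 = "A", b1 = "B")
  ht2 <- makeHits(list(list("a1", "b1", 100), list("b1", "a2", 120),
                       list("b1", "a1", 100)), gm2, symmetric = FALSE)
  e2 <- betEdges(bestHits(ht2, collapse = FALSE))
  expect_equal(e2$kind[e2$from == "a1" & e2$to == "b1"], "asymmetric")
  expect_equal(e2$kind[e2$from == "a2" & e2$to == "b1"], "asymmetric")
})

test_that("best hits agree with a per-(gene, genome) argmax oracle", {
  for (rep in 1:10) {
    set.seed(400 + rep)
    genes <- paste0("g", 1:20)
    gm <- setNames(sample(paste0("G", 1:3), 20, replace = TRUE), genes)
    prs <- t(combn(genes, 2))
    sc <- round(runif(nrow(prs), 10, 100), 1)
    hits <- data.frame(query = c(prs[, 1], prs[, 2]),
                       subject = c(prs[, 2], prs[, 1]),
                       score = c(sc, sc))
    ht <- new("HitTable", hits = hits, genomeMap = gm)
    bg <- bestHits(ht, collapse = FALSE)
    # oracle
    bet <- function(g, G) {
      cand <- hits[hits$query == g & gm[hits$subject] == G, ]
      if (!nrow(cand)) return(NA_character_)
      cand <- cand[order(-cand$score, cand$subject), ]
      cand$subject[1]
    }
    oracleEdges <- character(0); oracleKind <- character(0)
    for (g in genes) for (G in setdiff(unique(gm), gm[g])) {
      h <- bet(g, G)
      if (is.na(h)) next
      k <- paste(min(g, h), max(g, h))
      sym <- identical(bet(h, unname(gm[g])), g)
      if (!k %in% oracleEdges) {
        oracleEdges <- c(oracleEdges, k)
        oracleKind <- c(oracleKind, if (sym) "symmetric" else "asymmetric")
      }
    }
    e <- betEdges(bg)
    expect_setequal(paste(e$from, e$to), oracleEdges)
    expect_equal(e$kind[match(oracleEdges, paste(e$from, e$to))],
                 oracleKind)
  }
})

test_that("paralog collapsing requires mutual within-genome dominance", {
  gm <- c(a1 = "A", a2 = "A", b1 = "B")
  ht <- makeHits(list(list("a1", "a2", 200), list("a1", "b1", 150),
                      list("a2", "b1", 140)), gm)
  groups <- collapseParalogs(ht, c("a1", "a2"))
  expect_equal(length(groups), 1)
  expect_setequal(groups[[1]], c("a1", "a2"))

  ht2 <- makeHits(list(list("a1", "a2", 120), list("a1", "b1", 150),
                       list("a2", "b1", 100)), gm)
  groups2 <- collapseParalogs(ht2, c("a1", "a2"))
  expect_equal(length(groups2), 2)
  expect_error(collapseParalogs(ht, c("a1", "b1")), "one genome")
})

test_that("paralog collapsing matches brute-force dominance evaluation", {
  for (rep in 1:10) {
    set.seed(500 + rep)
    nA <- sample(3:6, 1)
    genesA <- paste0("a", seq_len(nA))
    others <- c("b1", "b2", "c1")
    gm <- setNames(c(rep("A", nA), "B", "B", "C"), c(genesA, others))
    allg <- names(gm)
    prs <- t(combn(allg, 2))
    sc <- round(runif(nrow(prs), 10, 100), 1)
    hits <- data.frame(query = c(prs[, 1], prs[, 2]),
                       subject = c(prs[, 2], prs[, 1]),
                       score = c(sc, sc))
    ht <- new("HitTable", hits = hits, genomeMap = gm)
    groups <- collapseParalogs(ht, genesA)
    # oracle: mutual dominance graph, components
    sLook <- setNames(hits$score, paste(hits$query, hits$subject))
    maxCross <- vapply(genesA, function(g)
      max(hits$score[hits$query == g & gm[hits$subject] != "A"]),
      numeric(1))
    dominated <- matrix(FALSE, nA, nA, dimnames = list(genesA, genesA))
    for (x in genesA) for (y in genesA) if (x != y) {
      s <- sLook[[paste(x, y)]]
      dominated[x, y] <- s > maxCross[x] && s > maxCross[y]
    }
    g <- igraph::graph_from_adjacency_matrix(dominated, "undirected")
    comps <- split(genesA, igraph::components(g)$membership)
    expect_setequal(lapply(unname(groups), sort), lapply(unname(comps), sort))
  }
})

test_that("seed expansion reaches the BeT closure", {
  gm <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  # chain a1 - b1 - c1, d1 isolated (no hits involving d1)
  ht <- makeHits(list(list("a1", "b1", 100), list("b1", "c1", 90),
                      list("a1", "c1", 10)), gm)
  expect_setequal(expandFromSeed("b1", ht), c("a1", "b1", "c1"))
  # seed with no cross-genome hits
  gm2 <- c(a1 = "A", a2 = "A", b1 = "B")
  ht2 <- makeHits(list(list("a1", "b1", 50)), c(gm2))
  expect_equal(expandFromSeed("a2", ht2, collapse = FALSE), "a2")
  expect_error(expandFromSeed("zz", ht), "not found")
})

test_that("seed expansion equals graph reachability on random instances", {
  for (rep in 1:10) {
    set.seed(600 + rep)
    genes <- paste0("g", 1:12)
    gm <- setNames(sample(paste0("G", 1:4), 12, replace = TRUE), genes)
    prs <- t(combn(genes, 2))
    keep <- runif(nrow(prs)) < 0.4
    prs <- prs[keep, , drop = FALSE]
    sc <- round(runif(nrow(prs), 10, 100), 1)
    hits <- data.frame(query = c(prs[, 1], prs[, 2]),
                       subject = c(prs[, 2], prs[, 1]),
                       score = c(sc, sc))
    ht <- new("HitTable", hits = hits, genomeMap = gm)
    bg <- bestHits(ht, collapse = FALSE)
    e <- betEdges(bg)
    seed <- genes[1]
    got <- expandFromSeed(seed, ht, collapse = FALSE)
    # oracle: BFS over BeT edges
    nbr <- function(v) unique(c(e$to[e$from == v], e$from[e$to == v]))
    reach <- seed; frontier <- seed
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(lapply(frontier, nbr))), reach)
      reach <- c(reach, nxt); frontier <- nxt
    }
    expect_setequal(got, reach)
  }
})

test_that("triangles form clusters and shared edges merge them", {
  gm <- c(a = "A", b = "B", c = "C", d = "D")
  tri <- makeHits(list(list("a", "b", 9), list("b", "c", 9),
                       list("a", "c", 9)), gm)
  bg <- bestHits(tri, collapse = FALSE)
  cl <- formCOGs(bg)
  expect_equal(length(cl), 1)
  expect_setequal(clusterMembers(cl[[1]]), c("a", "b", "c"))
  expect_true(all(cl[[1]]@edges$kind == "symmetric"))

  two <- makeHits(list(list("a", "b", 9), list("b", "c", 9),
                       list("a", "c", 9), list("a", "d", 8),
                       list("b", "d", 8)), gm)
  cl2 <- formCOGs(bestHits(two, collapse = FALSE))
  expect_equal(length(cl2), 1)
  expect_setequal(clusterMembers(cl2[[1]]), c("a", "b", "c", "d"))
})

test_that("cluster formation is invariant to input gene ordering", {
  rb <- randomBetGraph(15, 4, seed = 71, pEdge = 0.35)
  mk <- function(edges) {
    new("BeTGraph", nodes = sort(unique(c(edges$from, edges$to))),
        edges = edges, genomeMap = rb$genomeOf,
        paralogs = list())
  }
  cl1 <- formCOGs(mk(rb$edges))
  perm <- rb$edges[sample(nrow(rb$edges)), ]
  cl2 <- formCOGs(mk(perm))
  expect_equal(lapply(cl1, clusterMembers), lapply(cl2, clusterMembers))
})

test_that("network export round-trips edges with their kind", {
  gm <- c(a = "A", b = "B", c = "C", d = "D")
  ht <- makeHits(list(list("a", "b", 9), list("b", "c", 9),
                      list("a", "c", 9)), gm)
  cl <- formCOGs(bestHits(ht, collapse = FALSE))[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(cl, f)
  back <- readNetworkTSV(f)
  expect_equal(back, cl@edges, ignore_attr = TRUE)
  g <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(cl, g, format = "graphml")
  ig <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(cl@edges))
  expect_setequal(igraph::E(ig)$kind, cl@edges$kind)
})
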