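test_that("the GY94 generator has the stated structure", {
  set.seed(61)
  p <- runif(61); p <- p / sum(p)
  params <- GY94Params(kappa = 2.5, omega = 0.3,
                       codonFreqs = setNames(p, names(uniformPi())))
  Q <- buildRateMatrix(params)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(unname(-sum(p * diag(Q))), 1, tolerance = 1e-12)
  expect_equal(Q["AAA", "GGG"], 0)          # two differences
  expect_equal(Q["AAA", "AGG"], 0)
  expect_gt(Q["AAA", "AAG"], 0)             # one difference (syn, K->K)
  # detailed balance / reversibility: pi_i q_ij = pi_j q_ji
  expect_lt(max(abs(p * Q - t(p * Q))), 1e-14)
  # stationarity: pi Q = 0
  expect_lt(max(abs(p %*% Q)), 1e-14)
  expect_error(buildRateMatrix(params, 3L), "invalid branch class")
})

test_that("transition probabilities satisfy the chain properties", {
  params <- GY94Params(kappa = 2, omega = 0.5)
  Q <- buildRateMatrix(params)
  expect_equal(transitionProbs(Q, 0), diag(61), ignore_attr = TRUE)
  P1 <- transitionProbs(Q, 0.3); P2 <- transitionProbs(Q, 0.45)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_lt(max(abs(P1 %*% transitionProbs(Q, 0.15) - P2)), 1e-8)
  # long time: every row approaches the stationary distribution
  Pinf <- transitionProbs(Q, 500)
  expect_lt(max(abs(sweep(Pinf, 2, attr(Q, "pi"), "-"))), 1e-8)
  # independent matrix-exponential oracles: scaling-and-squaring Taylor
  # (helper) and Matrix::expm
  expect_lt(max(abs(P1 - taylorExpm(Q * 0.3))), 1e-9)
  expect_lt(max(abs(P1 - as.matrix(Matrix::expm(Q * 0.3)))), 1e-9)
  expect_error(transitionProbs(Q, -1), "finite")
})

test_that("pruning equals brute-force state enumeration on small trees", {
  params <- GY94Params(kappa = 2, omega = 0.3)
  aln3 <- randomCodonAln(3, 5, seed = 63, names = c("a", "b", "c"))
  lt3 <- LabeledTree("(a:0.2,b:0.3,c:0.4);")
  expect_lt(abs(codonLogLikelihood(aln3, lt3, params) -
                bruteForceLogLik(aln3, lt3, params)), 1e-10)
  # two omega classes on a 4-taxon tree
  aln4 <- randomCodonAln(4, 5, seed = 64, names = c("a", "b", "c", "d"))
  lt4 <- LabeledTree("((a:0.15,b:0.2):0.1,c:0.3,d:0.25);",
                     branchClass = c(1L, 1L, 0L, 0L, 0L))
  params2 <- GY94Params(kappa = 2, omega = c(0.3, 2))
  expect_lt(abs(codonLogLikelihood(aln4, lt4, params2) -
                bruteForceLogLik(aln4, lt4, params2)), 1e-10)
})

test_that("likelihood respects root placement, site order and taxon order", {
  params <- GY94Params(kappa = 2, omega = 0.4)
  aln <- randomCodonAln(4, 20, seed = 65, names = c("a", "b", "c", "d"))
  lt <- LabeledTree("((a:0.15,b:0.2):0.1,c:0.3,d:0.25);")
  base <- codonLogLikelihood(aln, lt, params)
  # reroot on another branch (pulley principle)
  rr <- ape::root(treePhylo(lt), "c", resolve.root = TRUE)
  expect_lt(abs(codonLogLikelihood(aln, LabeledTree(rr), params) - base),
            1e-8)
  # permute sites
  chunk <- function(s) substring(s, seq(1, nchar(s), 3),
                                 seq(3, nchar(s), 3))
  rows <- as.character(alignedSeqs(aln))
  set.seed(1); ordr <- sample(20)
  perm <- vapply(rows, function(s)
    paste(chunk(s)[ordr], collapse = ""), character(1))
  expect_equal(codonLogLikelihood(CodonAlignment(perm), lt, params), base)
  # permute taxa (alignment row order)
  expect_equal(codonLogLikelihood(CodonAlignment(rows[c(3, 1, 4, 2)]),
                                  lt, params), base)
})

test_that("single-sequence likelihood is the equilibrium product", {
  aln <- randomCodonAln(1, 10, seed = 66, names = "x")
  pi <- codonFrequencies(aln, "F3x4")
  params <- GY94Params(kappa = 2, omega = 0.3, codonFreqs = pi)
  st <- match(substring(as.character(alignedSeqs(aln))[1],
                        seq(1, 30, 3), seq(3, 30, 3)), names(pi))
  expect_equal(codonLogLikelihood(aln, NULL, params), sum(log(pi[st])))
})

test_that("gapped alignments are rejected by the likelihood machinery", {
  aln <- CodonAlignment(c(a = "ATG---", b = "ATGAAA"))
  lt <- LabeledTree("(a:0.1,b:0.1);")
  expect_error(codonLogLikelihood(aln, lt, GY94Params(2, 0.3)), "gaps")
})

test_that("fitting never does worse than the generating parameters", {
  lt <- LabeledTree(randomTestTree(5, seed = 67))
  reg <- simRegime(lt, 150, kappa = 2,
                   siteClasses = list(list(prop = 1, omega = 0.25)),
                   seed = 68)
  sim <- simulateCodonAlignment(reg)
  fit <- fitCodonModel(sim$aln, lt, nStarts = 1)
  pi <- codonFrequencies(sim$aln, "F3x4")
  truthLnL <- codonLogLikelihood(
    sim$aln, lt, GY94Params(2, 0.25, codonFreqs = pi))
  expect_gte(logLik0(fit) + 1e-6, truthLnL)
  # optimizer trace is monotone non-decreasing
  expect_true(all(diff(convergenceInfo(fit)$trace) >= 0))
  # two-ratio never fits worse than one-ratio on the same data
  lt2 <- labelClade(lt, c("t1", "t2"), 1L, type = "clade")
  fit2 <- fitCodonModel(sim$aln, lt2, nStarts = 1)
  expect_gte(logLik0(fit2) + 1e-4, logLik0(fit))
  expect_equal(nFreeParams(fit2), nFreeParams(fit) + 1L)
  # JSON serialization preserves the fitted quantities
  f <- withr::local_tempfile(fileext = ".json")
  writeModelFit(fit, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$lnL, logLik0(fit), tolerance = 1e-12)
  expect_equal(obj$kappa, fitParams(fit)@kappa, tolerance = 1e-12)
  expect_equal(nrow(obj$branches), nrow(treePhylo(fit@tree)$edge))
})

test_that("pairwise dN/dS equals omega and flags saturation", {
  # identical sequences
  p0 <- pairwiseOmega("ATGAAACCCTTT", "ATGAAACCCTTT")
  expect_equal(p0@dN, 0, ignore_attr = TRUE)
  expect_equal(p0@dS, 0, ignore_attr = TRUE)
  expect_true(p0@retained)
  # simulated divergent pair: algebraic identity dN/dS = omega
  reg <- simRegime(LabeledTree("(a:0.3,b:0.3);"), 200,
                   siteClasses = list(list(prop = 1, omega = 0.6)),
                   seed = 71)
  sim <- simulateCodonAlignment(reg)
  po <- pairwiseOmega(sim$aln)
  expect_lt(abs(po@dN / po@dS - po@omega), 1e-8)
  expect_true(po@retained)
  # saturated construction
  regS <- simRegime(LabeledTree("(a:10,b:10);"), 200,
                    siteClasses = list(list(prop = 1, omega = 0.3)),
                    seed = 72)
  poS <- pairwiseOmega(simulateCodonAlignment(regS)$aln)
  expect_gt(poS@dS, 2)
  expect_false(poS@retained)
  expect_error(pairwiseOmega("ATGAAA", "ATGAAACCC"), "equal length")
})

test_that("codon frequency models are proper distributions", {
  aln <- randomCodonAln(4, 50, seed = 73)
  for (m in c("F3x4", "F61")) {
    p <- codonFrequencies(aln, m)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(length(p), 61L)
  }
})
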