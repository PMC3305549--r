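test_that("the LRT computes the chi-squared upper tail with clamping", {
  r <- lrt(-100, -95, df = 1)
  expect_equal(lrtStatistic(r), 10)
  expect_equal(lrtPValue(r), pchisq(10, 1, lower.tail = FALSE))
  r0 <- lrt(-100, -100, df = 2)
  expect_equal(lrtStatistic(r0), 0)
  expect_equal(lrtPValue(r0), 1)
  expect_warning(rneg <- lrt(-100, -100.01, df = 1), "clamped")
  expect_equal(lrtStatistic(rneg), 0)
  expect_error(lrt(NA, -1, 1), "finite")
  expect_error(lrt(-1, -1, 0), "df")
})

test_that("a K = 1 branch spec reduces to the one-ratio model", {
  lt <- LabeledTree(randomTestTree(4, seed = 81))
  reg <- simRegime(lt, 100, seed = 82)
  sim <- simulateCodonAlignment(reg)
  f1 <- fitCodonModel(sim$aln, lt, nStarts = 1)
  f2 <- fitBranchModel(sim$aln, lt,
                       spec = list(name = "one", classes = rep(0L, 5)),
                       nStarts = 1)
  expect_equal(logLik0(f1), logLik0(f2), tolerance = 1e-4)
  expect_error(
    fitBranchModel(sim$aln, lt, spec = list(name = "bad",
                                            classes = c(0L, 1L))),
    "cover")
})

test_that("two-class fits preserve the simulated omega ordering", {
  tr <- ape::read.tree(text = paste0(
    "((t1:0.15,t2:0.15):0.1,(t3:0.15,t4:0.15):0.1,",
    "(t5:0.15,t6:0.15):0.1);"))
  lt <- LabeledTree(tr)
  ltC <- labelClade(lt, c("t1", "t2"), 1L, type = "clade")
  wins <- 0
  for (r in 1:5) {
    reg <- simRegime(ltC, 300, siteClasses = list(
      list(prop = 1, omega = c(0.2, 0.6))), seed = 830 + r)
    sim <- simulateCodonAlignment(reg)
    fit <- fitCodonModel(sim$aln, ltC, nStarts = 1)
    om <- fitParams(fit)@omega
    if (om[2] > om[1]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("model A fits satisfy their constraints and detect planted signal", {
  tr <- ape::read.tree(
    text = "((t1:0.2,t2:0.2):0.15,t3:0.25,t4:0.3);")
  lt <- LabeledTree(tr)
  ltF <- labelClade(lt, c("t1", "t2"), 1L, type = "clade")
  reg <- modelARegime(ltF, 300, p0 = 0.55, p1 = 0.35, omega0 = 0.2,
                      omega2 = 8, seed = 85)
  sim <- simulateCodonAlignment(reg)
  m0 <- fitCodonModel(sim$aln, lt, nStarts = 1)
  ltFit <- LabeledTree(m0@tree@tree, ltF@branchClass)
  bst <- branchSiteTest(sim$aln, ltFit, fixBranchLengths = TRUE,
                        nStarts = 1)
  # proportions of the four classes always sum to 1
  expect_equal(sum(modelAProportions(bst$null)), 1, tolerance = 1e-10)
  expect_equal(sum(modelAProportions(bst$alt)), 1, tolerance = 1e-10)
  expect_equal(bst$null@omega2, 1)
  expect_gte(bst$alt@omega2, 1)
  # nesting and detection
  expect_gte(bst$alt@lnL, bst$null@lnL)
  expect_lt(lrtPValue(bst$test), 0.05)
  expect_gt(bst$alt@omega2, 2)
  expect_error(fitModelA(sim$aln, lt), "foreground")
  # a foreground covering every branch collapses to a single class
  expect_error(fitModelA(sim$aln, lt,
                         foreground = paste0("t", 1:4),
                         foregroundType = "clade"),
               "foreground")
})

test_that("site posteriors are calibrated to the planted site classes", {
  tr <- ape::read.tree(
    text = "((t1:0.25,t2:0.25):0.2,t3:0.3,t4:0.3);")
  ltF <- labelClade(LabeledTree(tr), c("t1", "t2"), 1L, type = "clade")
  reg <- modelARegime(ltF, 300, p0 = 0.55, p1 = 0.35, omega0 = 0.15,
                      omega2 = 8, seed = 87)
  sim <- simulateCodonAlignment(reg)
  alt <- fitModelA(sim$aln, ltF, null = FALSE,
                   init = list(omega2 = 6), nStarts = 1)
  for (method in c("NEB", "BEB")) {
    sp <- sitePosteriors(alt, sim$aln, method = method)
    post <- posteriorProbs(sp)
    expect_true(all(post >= 0 & post <= 1))
    selected <- sim$siteClass %in% c(3, 4)
    expect_gt(mean(post[selected]), mean(post[!selected]))
  }
  # posterior invariant to site order (BEB)
  ord <- sample(300)
  chunk <- function(s) substring(s, seq(1, nchar(s), 3),
                                 seq(3, nchar(s), 3))
  rows <- as.character(alignedSeqs(sim$aln))
  perm <- CodonAlignment(vapply(rows, function(s)
    paste(chunk(s)[ord], collapse = ""), character(1)))
  spPerm <- sitePosteriors(alt, perm, method = "NEB")
  sp0 <- sitePosteriors(alt, sim$aln, method = "NEB")
  expect_equal(unname(posteriorProbs(spPerm)),
               unname(posteriorProbs(sp0)[ord]), tolerance = 1e-10)
  expect_error(sitePosteriors(fitModelA(sim$aln, ltF, null = TRUE,
                                        nStarts = 1), sim$aln),
               "alternative")
})

test_that("no-signal alignments yield no confidently selected sites", {
  # identical sequences: posterior driven by the prior proportions only
  rows <- setNames(rep(paste(rep("ATGAAACCCGGG", 10), collapse = ""), 4),
                   c("t1", "t2", "t3", "t4"))
  aln <- CodonAlignment(rows)
  lt <- LabeledTree("((t1:0.1,t2:0.1):0.1,t3:0.1,t4:0.1);")
  ltF <- labelClade(lt, c("t1", "t2"), 1L, type = "clade")
  alt <- fitModelA(aln, ltF, null = FALSE, nStarts = 1)
  sp <- sitePosteriors(alt, aln, method = "BEB")
  expect_true(all(posteriorProbs(sp) <= 0.5))
})

test_that("NEB class posteriors are normalized", {
  tr <- ape::read.tree(text = "((t1:0.2,t2:0.2):0.1,t3:0.2,t4:0.2);")
  ltF <- labelClade(LabeledTree(tr), c("t1", "t2"), 1L, type = "clade")
  reg <- modelARegime(ltF, 60, omega2 = 3, seed = 89)
  sim <- simulateCodonAlignment(reg)
  alt <- fitModelA(sim$aln, ltF, null = FALSE, nStarts = 1)
  # recompute the full class posterior matrix the way NEB does
  pi <- alt@codonFreqs
  states <- cogselect:::codonStateMatrix(sim$aln)
  pat <- cogselect:::compressPatterns(states)
  ti <- cogselect:::treeIndex(alt@tree, rownames(states))
  p <- modelAProportions(alt)
  lmat <- cogselect:::modelAClassLogLik(ti, pat, pi, alt@kappa,
                                        alt@omega0, alt@omega2, p)
  lp <- sweep(lmat, 2, log(p), "+")
  post <- exp(lp - apply(lp, 1, max)); post <- post / rowSums(post)
  expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
})

test_that("the report table renders fits and tests and round-trips JSON", {
  lt <- LabeledTree(randomTestTree(4, seed = 91))
  reg <- simRegime(lt, 80, seed = 92)
  sim <- simulateCodonAlignment(reg)
  f1 <- fitCodonModel(sim$aln, lt, nStarts = 1)
  tab1 <- makeSelectionTable(list("one-ratio" = f1))
  expect_equal(nrow(tab1), 1)
  expect_null(attr(tab1, "tests"))
  lt2 <- labelClade(lt, c("t1", "t2"), 1L, type = "clade")
  f2 <- fitCodonModel(sim$aln, lt2, nStarts = 1)
  tab <- makeSelectionTable(list("one-ratio" = f1, "two-ratio" = f2),
                            list("two vs one" = lrt(f1, f2, 1)))
  expect_equal(nrow(attr(tab, "tests")), 1)
  f <- withr::local_tempfile(fileext = ".json")
  writeSelectionTable(tab, f, format = "json")
  back <- readSelectionTable(f)
  expect_equal(back$negLnL, tab$negLnL, tolerance = 1e-12)
  expect_equal(attr(back, "tests")$statistic,
               attr(tab, "tests")$statistic, tolerance = 1e-12)
})
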