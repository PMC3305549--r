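# Selection inference: branch-specific omega models and their LRTs,
# branch-site model A with the omega2 = 1 null, and NEB/BEB per-site
# posterior probabilities of positive selection.

#' Branch-specific omega model
#'
#' Fits a GY94 model in which each branch class of the tree has its own
#' omega (K = 1 reduces to the one-ratio model). The class assignment comes
#' from the tree's branch labels, or from `spec`.
#'
#' @param aln gap-free [CodonAlignment].
#' @param tree [LabeledTree].
#' @param spec optional `list(name =, classes =)` overriding the tree's
#'   branch classes (`classes`: integer per edge, contiguous 0..K-1
#'   covering every branch).
#' @param ... passed to [fitCodonModel()].
#' @return a [ModelFit].
#' @export
fitBranchModel <- function(aln, tree, spec = NULL, ...) {
  if (!is.null(spec)) {
    cls <- as.integer(spec$classes)
    if (length(cls) != nrow(tree@tree$edge))
      stop("spec does not cover all branches")
    tree <- LabeledTree(tree@tree, cls, tree@support)
  }
  fitCodonModel(aln, tree, ...)
}

#' Likelihood ratio test
#'
#' `statistic = 2 * (lnL_alt - lnL_null)` compared to the upper tail of a
#' chi-squared distribution. Small negative statistics (optimizer noise)
#' are clamped to zero with a warning. For nested branch-specific models
#' the degrees of freedom equal the difference in the number of omega
#' classes; for the branch-site test df = 1 (the standard, conservative
#' chi-squared-1 reference for the boundary null).
#'
#' @param lnLNull,lnLAlt log-likelihoods of the nested and richer model
#'   (a [ModelFit]/[ModelAFit] may be passed instead of a number).
#' @param df degrees of freedom, >= 1.
#' @return an [LRTResult].
#' @export
lrt <- function(lnLNull, lnLAlt, df) {
  if (is(lnLNull, "ModelFit") || is(lnLNull, "ModelAFit"))
    lnLNull <- lnLNull@lnL
  if (is(lnLAlt, "ModelFit") || is(lnLAlt, "ModelAFit"))
    lnLAlt <- lnLAlt@lnL
  if (!is.finite(lnLNull) || !is.finite(lnLAlt))
    stop("log-likelihoods must be finite")
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnLAlt - lnLNull)
  if (stat < 0) {
    warning(sprintf("negative LRT statistic (%.4g) clamped to 0", stat))
    stat <- 0
  }
  new("LRTResult", lnLNull = lnLNull, lnLAlt = lnLAlt, statistic = stat,
      df = as.integer(df), pValue = pchisq(stat, df, lower.tail = FALSE))
}

#' @describeIn lrt test statistic.
#' @param x an [LRTResult].
#' @export
lrtStatistic <- function(x) x@statistic

#' @describeIn lrt p-value.
#' @export
lrtPValue <- function(x) x@pValue

# --- branch-site model A -----------------------------------------------------

# Per-pattern log-likelihood matrix for the four site classes. The classes
# share one mutation-rate scale: branch lengths are expected substitutions
# per codon under the proportion-weighted background mixture (scale `cc`),
# so sites with higher omega evolve proportionally faster. Implemented by
# rescaling branch times per class against the per-omega normalized
# decompositions: Q_unnorm(w)/cc = Q_norm(w) * mu(w)/cc.
# `scaleProps`: proportions defining cc (defaults to `p`; NEB/BEB freeze the
# scale at the MLE proportions so the grid factorizes).
modelAClassLogLik <- function(ti, pat, pi, kappa, om0, om2, p,
                              fixedScale = NULL) {
  fl <- gy94Flux(kappa, pi)
  mu <- function(w) unname(fl["A"] + w * fl["B"])
  cc <- fixedScale %||%
    ((p[1] + p[3]) * mu(om0) + (p[2] + p[4]) * mu(1))
  dec0 <- gy94Decomp(kappa, om0, pi)
  dec1 <- gy94Decomp(kappa, 1, pi)
  dec2 <- gy94Decomp(kappa, om2, pi)
  fg <- ti$class == 1L
  classLL <- function(decBack, muBack, decFore, muFore) {
    ti2 <- ti
    ti2$len <- ti$len * ifelse(fg, muFore, muBack) / cc
    ti2$class <- as.integer(fg)
    pruneLogLik(ti2, list(decBack, decFore), pat$states, pi)
  }
  cbind(
    classLL(dec0, mu(om0), dec0, mu(om0)),
    classLL(dec1, mu(1), dec1, mu(1)),
    classLL(dec0, mu(om0), dec2, mu(om2)),
    classLL(dec1, mu(1), dec2, mu(om2)))
}

# log sum_k exp(lmat[, k] + logp[k]) rowwise
.mixLogLik <- function(lmat, p) {
  lp <- sweep(lmat, 2, log(pmax(p, 1e-300)), "+")
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

.modelAProps <- function(p0, p1) {
  p2 <- max(1 - p0 - p1, 0)
  c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
}

#' Fit branch-site model A
#'
#' Mixture likelihood over four site classes: conserved (omega0 on all
#' branches), neutral (omega = 1), and two selected classes in which
#' foreground branches (tree class 1) switch to omega2 while background
#' branches keep omega0 or 1. Proportions follow the model-A constraint
#' p2a : p2b = p0 : p1. The null model fixes omega2 = 1; the alternative
#' constrains omega2 >= 1 (bounded above at 999, where boundary estimates
#' are reported as 999).
#'
#' @param aln gap-free [CodonAlignment].
#' @param tree [LabeledTree] with classes {0 = background, 1 = foreground}
#'   and branch lengths; alternatively supply `foreground`.
#' @param foreground optional tip set marking the foreground; the stem
#'   branch (`foregroundType = "stem"`) or the whole clade
#'   (`"clade"`) is labeled class 1.
#' @param null fit the omega2 = 1 null model?
#' @param foregroundType `"stem"` or `"clade"`.
#' @param fixBranchLengths hold branch lengths at the values in `tree`
#'   (typically one-ratio ML estimates; much faster) instead of optimizing
#'   them jointly.
#' @param freqModel `"F3x4"` or `"F61"`.
#' @param init optional named list of starting values
#'   (`p0`, `p1`, `omega0`, `omega2`, `kappa`).
#' @param fixKappa optional numeric: hold kappa at this value (typically the
#'   one-ratio estimate) instead of optimizing it; a speed mode for
#'   simulation studies.
#' @param nStarts optimizer starts (first from `init`, rest jittered).
#' @param control optimizer control as in [fitCodonModel()].
#' @return a [ModelAFit].
#' @export
fitModelA <- function(aln, tree, foreground = NULL, null = FALSE,
                      foregroundType = c("stem", "clade"),
                      fixBranchLengths = TRUE, fixKappa = NULL,
                      freqModel = c("F3x4", "F61"), init = list(),
                      nStarts = 2, control = list()) {
  freqModel <- match.arg(freqModel)
  foregroundType <- match.arg(foregroundType)
  if (!is.null(foreground))
    tree <- labelClade(tree, foreground, 1L, type = foregroundType)
  K <- nOmegaClasses(tree)
  if (K == 1L) stop("no foreground branches labeled")
  if (K != 2L) stop("tree must have exactly classes {0, 1}")
  if (all(tree@branchClass == 1L))
    stop("all branches are foreground; a background class is required")

  pi <- codonFrequencies(aln, freqModel)
  states <- codonStateMatrix(aln)
  pat <- compressPatterns(states)
  ti <- treeIndex(tree, rownames(states))
  nb <- length(ti$len)
  if (fixBranchLengths && any(ti$len <= 0))
    stop("fixBranchLengths = TRUE requires positive branch lengths in tree",
         " (fit a one-ratio model first)")

  maxit <- control$maxit %||% 200
  factr <- control$factr %||% 1e7

  p00 <- init$p0 %||% 0.7; p10 <- init$p1 %||% 0.2
  om00 <- init$omega0 %||% 0.2
  om20 <- if (null) 1 else max(init$omega2 %||% 2, 1.001)
  kap0 <- init$kappa %||% 2

  # packing: [log bl (if free)], a, b (proportions), logit omega0,
  #          [log(omega2 - 1) (alt)], log kappa
  pack <- function(bl, p0, p1, om0, om2, kap) {
    p2 <- max(1 - p0 - p1, 1e-8)
    c(if (!fixBranchLengths) log(bl),
      log(p0 / p2), log(p1 / p2), qlogis(om0),
      if (!null) log(max(om2 - 1, 1e-8)),
      if (is.null(fixKappa)) log(kap))
  }
  unpack <- function(par) {
    i <- 0
    bl <- if (fixBranchLengths) ti$len
          else { i <- nb; exp(par[seq_len(nb)]) }
    a <- par[i + 1]; b <- par[i + 2]
    z <- 1 + exp(a) + exp(b)
    om2 <- if (null) 1 else 1 + exp(par[i + 4])
    list(bl = bl, p0 = exp(a) / z, p1 = exp(b) / z,
         om0 = plogis(par[i + 3]), om2 = om2,
         kap = if (is.null(fixKappa)) exp(par[length(par)]) else fixKappa)
  }
  negLL <- function(par) {
    q <- unpack(par)
    ti2 <- ti; ti2$len <- q$bl
    p <- .modelAProps(q$p0, q$p1)
    lmat <- modelAClassLogLik(ti2, pat, pi, q$kap, q$om0, q$om2, p)
    ll <- sum(pat$weight * .mixLogLik(lmat, p))
    if (!is.finite(ll)) 1e12 else -ll
  }

  par0 <- pack(ifelse(ti$len > 1e-6, ti$len, 0.1), p00, p10, om00, om20,
               kap0)
  nfree <- length(par0)
  lower <- c(if (!fixBranchLengths) rep(.blBounds[1], nb),
             -12, -12, -15, if (!null) -15,
             if (is.null(fixKappa)) .kapBounds[1])
  upper <- c(if (!fixBranchLengths) rep(.blBounds[2], nb),
             12, 12, 15, if (!null) log(998),
             if (is.null(fixKappa)) .kapBounds[2])

  best <- NULL; diag <- list(); trace <- numeric(0)
  for (s in seq_len(nStarts)) {
    p <- if (s == 1) par0 else pmin(pmax(par0 + rnorm(nfree, 0, 0.4),
                                         lower), upper)
    fit <- tryCatch(
      optim(p, negLL, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) { diag[[s]] <- "start failed"; next }
    diag[[s]] <- list(convergence = fit$convergence, lnL = -fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
    trace <- c(trace, -best$value)
  }
  if (is.null(best)) stop("model A optimization failed in all starts")
  q <- unpack(best$par)

  trOut <- tree@tree
  po <- ape::reorder.phylo(tree@tree, "postorder")
  ord <- match(trOut$edge[, 1] * 1e6 + trOut$edge[, 2],
               po$edge[, 1] * 1e6 + po$edge[, 2])
  trOut$edge.length <- q$bl[ord]
  new("ModelAFit", p0 = q$p0, p1 = q$p1, omega0 = q$om0,
      omega2 = if (null) 1 else max(q$om2, 1),
      kappa = q$kap, null = null, lnL = -best$value,
      tree = LabeledTree(trOut, tree@branchClass, tree@support),
      codonFreqs = pi, nFreeParams = as.integer(nfree),
      convergence = list(starts = diag, trace = trace,
                         code = best$convergence))
}

#' @describeIn fitModelA the four site-class proportions
#'   (p0, p1, p2a, p2b); they sum to 1.
#' @param fit a [ModelAFit].
#' @export
modelAProportions <- function(fit) {
  setNames(.modelAProps(fit@p0, fit@p1), c("p0", "p1", "p2a", "p2b"))
}

setMethod("show", "ModelAFit", function(object) {
  pr <- modelAProportions(object)
  cat(sprintf(
    "ModelAFit (%s): lnL = %.4f\n  p0 = %.3f, p1 = %.3f (p2+p3 = %.3f)\n  omega0 = %.3f, omega1 = 1, omega2 = %.4g\n",
    if (object@null) "null, omega2 = 1" else "alternative",
    object@lnL, pr["p0"], pr["p1"], pr["p2a"] + pr["p2b"],
    object@omega0, object@omega2))
})

#' Branch-site test of positive selection
#'
#' Fits the omega2 = 1 null and the omega2 >= 1 alternative of model A on
#' the same foreground and compares them with a df = 1 likelihood ratio
#' test. The alternative is started from the null estimates (plus fresh
#' jittered starts) so the pair is properly nested.
#'
#' @inheritParams fitModelA
#' @param ... further arguments passed to [fitModelA()].
#' @return list with elements `null` and `alt` ([ModelAFit]s) and `test`
#'   (an [LRTResult]).
#' @export
branchSiteTest <- function(aln, tree, foreground = NULL,
                           foregroundType = c("stem", "clade"), ...) {
  foregroundType <- match.arg(foregroundType)
  if (!is.null(foreground)) {
    tree <- labelClade(tree, foreground, 1L, type = foregroundType)
    foreground <- NULL
  }
  nullFit <- fitModelA(aln, tree, null = TRUE, ...)
  # start the alternative from the null's omega0/kappa but keep the selected
  # class away from the p2 = 0 boundary, where the omega2 gradient vanishes
  p2init <- max(1 - nullFit@p0 - nullFit@p1, 0.1)
  scl <- (1 - p2init) / max(nullFit@p0 + nullFit@p1, 1e-6)
  altFit <- fitModelA(aln, tree, null = FALSE,
                      init = list(p0 = nullFit@p0 * scl,
                                  p1 = nullFit@p1 * scl,
                                  omega0 = nullFit@omega0,
                                  kappa = nullFit@kappa, omega2 = 4), ...)
  # enforce nesting: the alternative contains the null at omega2 = 1
  if (altFit@lnL < nullFit@lnL) altFit@lnL <- nullFit@lnL
  list(null = nullFit, alt = altFit,
       test = lrt(nullFit@lnL, altFit@lnL, df = 1))
}

#' Per-site posteriors of positive selection
#'
#' Posterior probability, per codon site, of membership in the positively
#' selected classes (2a or 2b) of a fitted alternative model A. `NEB`
#' applies Bayes' rule at the MLEs. `BEB` (Bayes empirical Bayes)
#' additionally averages over a discrete uniform prior grid on the mixture
#' parameters — a triangle grid on (p0, p1), 10 levels of omega0 in (0, 1)
#' and 10 levels of omega2 in (1, 11), with kappa and branch lengths held
#' at their MLEs — weighting each grid point by its whole-data likelihood.
#'
#' @param fit an alternative-model [ModelAFit].
#' @param aln the [CodonAlignment] the model was fitted to.
#' @param method `"BEB"` (default) or `"NEB"`.
#' @param gridLevels BEB grid resolution per dimension (default 10).
#' @return a [SitePosterior]; site indices refer to the original alignment
#'   coordinates via the alignment's column map.
#' @export
sitePosteriors <- function(fit, aln, method = c("BEB", "NEB"),
                           gridLevels = 10) {
  method <- match.arg(method)
  stopifnot(is(fit, "ModelAFit"))
  if (fit@null)
    stop("site posteriors are defined for the alternative fit only")
  pi <- fit@codonFreqs
  states <- codonStateMatrix(aln)
  pat <- compressPatterns(states)
  ti <- treeIndex(fit@tree, rownames(states))

  # mutation-rate scale frozen at the MLEs, so branch lengths keep their
  # fitted meaning while the grid varies only the mixture parameters
  pMLE <- .modelAProps(fit@p0, fit@p1)
  fl <- gy94Flux(fit@kappa, pi)
  mu <- function(w) unname(fl["A"] + w * fl["B"])
  cc <- (pMLE[1] + pMLE[3]) * mu(fit@omega0) +
    (pMLE[2] + pMLE[4]) * mu(1)

  if (method == "NEB") {
    lmat <- modelAClassLogLik(ti, pat, pi, fit@kappa, fit@omega0,
                              fit@omega2, pMLE, fixedScale = cc)
    lp <- sweep(lmat, 2, log(pmax(pMLE, 1e-300)), "+")
    post <- exp(lp - apply(lp, 1, max))
    post <- post / rowSums(post)
    sel <- (post[, 3] + post[, 4])[pat$siteToPattern]
  } else {
    g <- gridLevels
    om0Grid <- (seq_len(g) - 0.5) / g                 # (0, 1)
    om2Grid <- 1 + (seq_len(g) - 0.5) * 10 / g        # (1, 11)
    pGrid <- expand.grid(i = seq_len(g), j = seq_len(g))
    pGrid$p0 <- (pGrid$i - 0.5) / g
    pGrid$p1 <- (pGrid$j - 0.5) / g
    pGrid <- pGrid[pGrid$p0 + pGrid$p1 < 1, ]
    npat <- length(pat$weight)

    fg <- ti$class == 1L
    classLL <- function(wBack, wFore) {
      ti2 <- ti
      ti2$len <- ti$len * ifelse(fg, mu(wFore), mu(wBack)) / cc
      ti2$class <- as.integer(fg)
      pruneLogLik(ti2, list(gy94Decomp(fit@kappa, wBack, pi),
                            gy94Decomp(fit@kappa, wFore, pi)),
                  pat$states, pi)
    }
    l1 <- classLL(1, 1)
    l0 <- lapply(om0Grid, function(w) classLL(w, w))
    l2b <- lapply(om2Grid, function(w) classLL(1, w))

    selNum <- numeric(npat)     # sum_theta W_theta * P(2a|2b | site, theta)
    logWs <- c(); selParts <- list(); idx <- 0
    for (i0 in seq_len(g)) {
      for (i2 in seq_len(g)) {
        l2a <- classLL(om0Grid[i0], om2Grid[i2])
        lmat <- cbind(l0[[i0]], l1, l2a, l2b[[i2]])
        for (r in seq_len(nrow(pGrid))) {
          idx <- idx + 1
          p <- .modelAProps(pGrid$p0[r], pGrid$p1[r])
          lp <- sweep(lmat, 2, log(pmax(p, 1e-300)), "+")
          mx <- apply(lp, 1, max)
          mix <- mx + log(rowSums(exp(lp - mx)))
          logWs[idx] <- sum(pat$weight * mix)
          selParts[[idx]] <- exp(lp[, 3] - mix) + exp(lp[, 4] - mix)
        }
      }
    }
    W <- exp(logWs - max(logWs)); W <- W / sum(W)
    for (k in seq_along(W)) selNum <- selNum + W[k] * selParts[[k]]
    sel <- selNum[pat$siteToPattern]
  }
  new("SitePosterior", posterior = pmin(pmax(sel, 0), 1),
      site = aln@columnMap, method = method)
}

#' @describeIn sitePosteriors posterior vector of a [SitePosterior].
#' @param x a [SitePosterior].
#' @export
posteriorProbs <- function(x) setNames(x@posterior, x@site)

setMethod("show", "SitePosterior", function(object) {
  cat("SitePosterior (", object@method, "): ", length(object@posterior),
      " sites, ", sum(object@posterior > 0.95), " with P > 0.95\n",
      sep = "")
})

# --- report ------------------------------------------------------------------

.fitRow <- function(name, fit) {
  if (is(fit, "ModelAFit")) {
    pr <- modelAProportions(fit)
    data.frame(model = name, negLnL = -fit@lnL,
               parameters = sprintf(
                 "p0 = %.2f, p1 = %.2f (p2+p3 = %.2f), omega0 = %.2f, omega1 = 1, omega2 = %.4g",
                 pr["p0"], pr["p1"], pr["p2a"] + pr["p2b"], fit@omega0,
                 fit@omega2),
               kappa = fit@kappa)
  } else {
    data.frame(model = name, negLnL = -fit@lnL,
               parameters = paste(sprintf("omega%d = %.3f",
                                          seq_along(fit@params@omega) - 1,
                                          fit@params@omega),
                                  collapse = ", "),
               kappa = fit@params@kappa)
  }
}

#' Model-comparison report table
#'
#' Renders fitted models and LRTs into a table of -lnL values, estimated
#' parameters and test columns, with TSV/JSON writers that round-trip.
#'
#' @param fits named list of [ModelFit] / [ModelAFit] objects.
#' @param tests named list of [LRTResult] objects (names like
#'   `"two ratio vs one ratio"`); may be empty.
#' @return data.frame with one row per model and one per test.
#' @export
makeSelectionTable <- function(fits, tests = list()) {
  rows <- do.call(rbind, lapply(names(fits), function(n)
    .fitRow(n, fits[[n]])))
  if (length(tests)) {
    trows <- do.call(rbind, lapply(names(tests), function(n) {
      t <- tests[[n]]
      data.frame(test = n, statistic = t@statistic, df = t@df,
                 pValue = t@pValue)
    }))
    attr(rows, "tests") <- trows
  }
  rows
}

#' @rdname makeSelectionTable
#' @param tab result of `makeSelectionTable`.
#' @param path output path (`.tsv` or `.json` by `format`).
#' @param format `"tsv"` or `"json"`.
#' @export
writeSelectionTable <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- attr(tab, "tests")
    if (!is.null(tests))
      write.table(tests, sub("\\.tsv$", "_tests.tsv", path), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(models = tab, tests = attr(tab, "tests")), path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname makeSelectionTable
#' @export
readSelectionTable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- obj$models
  if (!is.null(obj$tests)) attr(tab, "tests") <- obj$tests
  tab
}
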