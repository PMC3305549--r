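# Likelihood computation and ML fitting of GY94 codon models with
# branch-specific omega classes, and pairwise dN/dS estimation.

#' Log-likelihood of a codon alignment under a GY94 model
#'
#' Felsenstein pruning over compressed site patterns. Each branch uses the
#' transition matrix of its omega class; the root is weighted by the
#' equilibrium frequencies (the model is reversible, so root placement does
#' not affect the result).
#'
#' @param aln gap-free [CodonAlignment].
#' @param tree [LabeledTree] whose tips match the alignment names; pass
#'   `NULL` for a single-sequence alignment (the likelihood is then the
#'   product of equilibrium frequencies).
#' @param params [GY94Params]; `omega` must cover every branch class.
#' @return log-likelihood (a single number).
#' @export
codonLogLikelihood <- function(aln, tree, params) {
  stopifnot(is(aln, "CodonAlignment"), is(params, "GY94Params"))
  states <- codonStateMatrix(aln)
  pi <- params@codonFreqs
  if (is.null(tree) || length(aln) == 1L) {
    if (length(aln) != 1L) stop("tree may be NULL only for one sequence")
    return(sum(log(pi[states[1, ]])))
  }
  if (nOmegaClasses(tree) > length(params@omega))
    stop("params@omega does not cover all branch classes")
  pat <- compressPatterns(states)
  ti <- treeIndex(tree, rownames(states))
  decs <- lapply(params@omega, gy94Decomp, kappa = params@kappa, pi = pi)
  sum(pat$weight * pruneLogLik(ti, decs, pat$states, pi))
}

# --- ML fitting --------------------------------------------------------------

# Bounds on the log scale used by the optimizer.
.blBounds <- log(c(1e-6, 50))
.kapBounds <- log(c(0.05, 100))
.omBounds <- log(c(1e-4, 999))

#' Fit a GY94 model by maximum likelihood
#'
#' Jointly maximizes the log-likelihood over branch lengths (optional),
#' kappa, and one omega per branch class of `tree`, using bounded
#' quasi-Newton (L-BFGS-B) on log-transformed parameters with multiple
#' jittered starts. With K = 1 branch classes this is the one-ratio model;
#' trees labeled via [labelClade()] give the two-/three-/multi-ratio
#' branch-specific models.
#'
#' @param aln gap-free [CodonAlignment].
#' @param tree [LabeledTree]; its branch classes define the omega classes,
#'   and its branch lengths serve as initial values when positive.
#' @param freqModel `"F3x4"` (default) or `"F61"` equilibrium frequencies,
#'   computed from the data.
#' @param fixBranchLengths if `TRUE`, branch lengths are held at the values
#'   in `tree` and only kappa and omega are optimized.
#' @param init named list overriding initial values: `kappa`, `omega`
#'   (vector of length K), `bl` (scalar or per-edge vector).
#' @param nStarts number of optimizer starts (the first from `init`, the
#'   rest jittered); the best result is returned.
#' @param control list: `maxit` (default 300) and `factr` passed to
#'   [stats::optim()].
#' @return a [ModelFit]; `convergence(fit)$trace` records the best
#'   log-likelihood after each completed start (non-decreasing).
#' @export
fitCodonModel <- function(aln, tree, freqModel = c("F3x4", "F61"),
                          fixBranchLengths = FALSE, init = list(),
                          nStarts = 3, control = list()) {
  freqModel <- match.arg(freqModel)
  stopifnot(is(aln, "CodonAlignment"), is(tree, "LabeledTree"))
  pi <- codonFrequencies(aln, freqModel)
  states <- codonStateMatrix(aln)
  pat <- compressPatterns(states)
  ti <- treeIndex(tree, rownames(states))
  K <- nOmegaClasses(tree)
  nb <- length(ti$len)

  maxit <- control$maxit %||% 300
  factr <- control$factr %||% 1e7

  bl0 <- if (!is.null(init$bl)) rep(init$bl, length.out = nb)
         else ifelse(ti$len > 1e-6, ti$len, 0.1)
  kap0 <- init$kappa %||% 2
  om0 <- rep(init$omega %||% 0.4, length.out = K)

  negLL <- function(par) {
    if (fixBranchLengths) {
      len <- ti$len; rest <- par
    } else {
      len <- exp(par[seq_len(nb)]); rest <- par[-seq_len(nb)]
    }
    kap <- exp(rest[1]); om <- exp(rest[-1])
    decs <- lapply(om, gy94Decomp, kappa = kap, pi = pi)
    ti2 <- ti; ti2$len <- len
    ll <- sum(pat$weight * pruneLogLik(ti2, decs, pat$states, pi))
    if (!is.finite(ll)) 1e12 else -ll
  }

  par0 <- c(if (!fixBranchLengths) log(bl0), log(kap0), log(om0))
  lower <- c(if (!fixBranchLengths) rep(.blBounds[1], nb),
             .kapBounds[1], rep(.omBounds[1], K))
  upper <- c(if (!fixBranchLengths) rep(.blBounds[2], nb),
             .kapBounds[2], rep(.omBounds[2], K))

  best <- NULL; trace <- numeric(0); diag <- list()
  for (s in seq_len(nStarts)) {
    p <- if (s == 1) par0 else pmin(pmax(par0 + rnorm(length(par0), 0, 0.3),
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
  if (is.null(best)) stop("optimizer failed in all ", nStarts, " starts")

  if (fixBranchLengths) {
    len <- ti$len; rest <- best$par
  } else {
    len <- exp(best$par[seq_len(nb)]); rest <- best$par[-seq_len(nb)]
  }
  # map postorder branch lengths back to the input edge order
  trOut <- tree@tree
  po <- ape::reorder.phylo(tree@tree, "postorder")
  ord <- match(trOut$edge[, 1] * 1e6 + trOut$edge[, 2],
               po$edge[, 1] * 1e6 + po$edge[, 2])
  trOut$edge.length <- len[ord]
  params <- new("GY94Params", kappa = exp(rest[1]), omega = exp(rest[-1]),
                codonFreqs = pi, freqModel = freqModel)
  nfp <- (if (fixBranchLengths) 0L else nb) + 1L + K
  new("ModelFit", params = params,
      tree = LabeledTree(trOut, tree@branchClass, tree@support),
      lnL = -best$value, nFreeParams = as.integer(nfp),
      convergence = list(starts = diag, trace = trace,
                         code = best$convergence))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn fitCodonModel maximized log-likelihood of a fit.
#' @param fit a [ModelFit] or [ModelAFit].
#' @export
logLik0 <- function(fit) fit@lnL

#' @describeIn fitCodonModel fitted parameters ([GY94Params]).
#' @export
fitParams <- function(fit) fit@params

#' @describeIn fitCodonModel number of free parameters of a fit.
#' @export
nFreeParams <- function(fit) fit@nFreeParams

#' @describeIn fitCodonModel optimizer diagnostics of a fit.
#' @export
convergenceInfo <- function(fit) fit@convergence

setMethod("show", "ModelFit", function(object) {
  cat("GY94 ModelFit: lnL =", sprintf("%.4f", object@lnL),
      "| kappa =", sprintf("%.3f", object@params@kappa),
      "| omega =", paste(sprintf("%.4g", object@params@omega),
                         collapse = ", "),
      "\n  ", object@nFreeParams, "free parameters,",
      object@params@freqModel, "frequencies\n")
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf(
    "LRT: 2*(lnL_alt - lnL_null) = %.4f on %d df, p = %.4g\n",
    object@statistic, object@df, object@pValue))
})

#' Serialize a fitted codon model to JSON
#'
#' Writes kappa, the omega vector, codon frequencies, log-likelihood,
#' parameter count and per-branch lengths (parent/child node numbers with
#' class labels) so a fit can be archived alongside pipeline outputs.
#'
#' @param fit a [ModelFit].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeModelFit <- function(fit, path) {
  stopifnot(is(fit, "ModelFit"))
  tr <- fit@tree@tree
  jsonlite::write_json(list(
    kappa = fit@params@kappa,
    omega = fit@params@omega,
    freqModel = fit@params@freqModel,
    codonFreqs = as.list(fit@params@codonFreqs),
    lnL = fit@lnL,
    nFreeParams = fit@nFreeParams,
    branches = data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
                          length = tr$edge.length,
                          class = fit@tree@branchClass)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- pairwise dN/dS ----------------------------------------------------------

setClass("PairwiseOmega",
  representation(pair = "character", t = "numeric", kappa = "numeric",
                 omega = "numeric", dN = "numeric", dS = "numeric",
                 retained = "logical", lnL = "numeric"))

setMethod("show", "PairwiseOmega", function(object) {
  cat(sprintf(
    "PairwiseOmega %s vs %s: t=%.4g kappa=%.3g omega=%.4g dN=%.4g dS=%.4g %s\n",
    object@pair[1], object@pair[2], object@t, object@kappa, object@omega,
    object@dN, object@dS,
    if (object@retained) "(retained)" else "(discarded: dS > 2)"))
})

#' Pairwise dN/dS estimation with saturation filtering
#'
#' ML fit of (t, kappa, omega) for two gap-free coding sequences under GY94,
#' followed by the Goldman-Yang decomposition into dN and dS: expected
#' nonsynonymous (synonymous) substitutions under the fitted model divided
#' by the nonsynonymous (synonymous) site fractions computed from the same
#' mutation process with omega = 1. Under this convention dN/dS equals the
#' fitted omega identically. Pairs with dS > `dsMax` are flagged as
#' saturated (`retained = FALSE`), the standard filter against unreliable
#' synonymous-distance estimates.
#'
#' @param cdsA,cdsB equal-length gap-free coding sequences (character or
#'   `DNAString`), or a 2-sequence [CodonAlignment] as `cdsA`.
#' @param freqModel equilibrium frequency model, as in [fitCodonModel()].
#' @param dsMax saturation threshold on dS (default 2).
#' @param siteCounting `"mutational"` (default; site fractions from the
#'   omega = 1 process, preserving dN/dS = omega) or `"physical"`
#'   (equal-weight counting of synonymous/nonsynonymous target changes).
#' @return a `PairwiseOmega` object.
#' @export
pairwiseOmega <- function(cdsA, cdsB = NULL, freqModel = c("F3x4", "F61"),
                          dsMax = 2,
                          siteCounting = c("mutational", "physical")) {
  freqModel <- match.arg(freqModel)
  siteCounting <- match.arg(siteCounting)
  if (is(cdsA, "CodonAlignment")) {
    stopifnot(length(cdsA) == 2L)
    aln <- cdsA
  } else {
    a <- as.character(cdsA); b <- as.character(cdsB)
    if (nchar(a) != nchar(b)) stop("sequences must have equal length")
    aln <- CodonAlignment(c(seqA = a, seqB = b))
  }
  states <- codonStateMatrix(aln)
  pi <- codonFrequencies(aln, freqModel)
  counts <- table(factor(states[1, ], levels = 1:61),
                  factor(states[2, ], levels = 1:61))
  nz <- which(counts > 0, arr.ind = TRUE)
  w <- counts[nz]

  negLL <- function(par) {
    t <- exp(par[1]); kap <- exp(par[2]); om <- exp(par[3])
    P <- decompProbs(gy94Decomp(kap, om, pi), t)
    ll <- sum(w * log(pmax(pi[nz[, 1]] * P[nz], 1e-300)))
    if (!is.finite(ll)) 1e12 else -ll
  }
  identical_pair <- all(states[1, ] == states[2, ])
  if (identical_pair) {
    t <- 0; kap <- 2; om <- 1e-4; ll <- sum(log(pi[states[1, ]]))
  } else {
    lower <- c(log(1e-6), .kapBounds[1], .omBounds[1])
    upper <- c(log(50), .kapBounds[2], .omBounds[2])
    best <- NULL
    # the high-divergence start comes first: at saturation the likelihood
    # is nearly flat across (t, omega) trade-offs, and keeping the
    # saturation-scale solution on near-ties (strict 1e-6 improvement
    # required to switch) makes the dS > 2 filter fire as intended
    for (p0 in list(log(c(20, 2, 0.5)), log(c(0.3, 2, 0.3)),
                    log(c(1, 2, 1)), log(c(3, 2, 0.1)))) {
      f <- tryCatch(optim(p0, negLL, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 300)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value - 1e-6))
        best <- f
    }
    if (is.null(best)) stop("pairwise optimization failed")
    t <- exp(best$par[1]); kap <- exp(best$par[2]); om <- exp(best$par[3])
    ll <- -best$value
  }
  dnds <- dnDsFromModel(t, kap, om, pi, siteCounting)
  new("PairwiseOmega",
      pair = names(aln@seqs), t = t, kappa = kap, omega = om,
      dN = dnds["dN"], dS = dnds["dS"],
      retained = dnds["dS"] <= dsMax, lnL = ll)
}

# Decompose t (subs/codon) into per-site dN and dS.
dnDsFromModel <- function(t, kappa, omega, pi,
                          siteCounting = "mutational") {
  Q <- gy94Matrix(kappa, omega, pi)
  rhoS <- attr(Q, "rhoS"); rhoN <- attr(Q, "rhoN")
  if (siteCounting == "mutational") {
    Q1 <- gy94Matrix(kappa, 1, pi)
    fS <- attr(Q1, "rhoS"); fN <- attr(Q1, "rhoN")
  } else {
    ct <- codonTable(); pr <- ct$pairs
    nS <- sum(pi[pr$i][pr$syn]) + sum(pi[pr$j][pr$syn])
    nTot <- sum(pi[pr$i]) + sum(pi[pr$j])
    fS <- nS / nTot; fN <- 1 - fS
  }
  c(dN = t * rhoN / (3 * fN), dS = t * rhoS / (3 * fS))
}
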