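# GY94 codon substitution core: genetic-code bookkeeping, rate matrix,
# transition probabilities, and the Felsenstein pruning engine shared by the
# branch-specific and branch-site models.

.pkgenv <- new.env(parent = emptyenv())

# Sense-codon bookkeeping under the universal genetic code: the 61 codons,
# their amino acids, and the set of single-nucleotide codon pairs classified
# as transition/transversion and synonymous/nonsynonymous. Cached.
codonTable <- function() {
  if (!is.null(.pkgenv$codonTable)) return(.pkgenv$codonTable)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)                # 61
  cmat <- do.call(rbind, strsplit(codons, ""))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ii <- jj <- integer(0); ts <- syn <- logical(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffpos <- which(cmat[i, ] != cmat[j, ])
      if (length(diffpos) != 1) next
      x <- cmat[i, diffpos]; y <- cmat[j, diffpos]
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, purine[[x]] == purine[[y]])
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  .pkgenv$codonTable <- list(
    codons = codons, aa = aa, n = n,
    pairs = data.frame(i = ii, j = jj, ts = ts, syn = syn))
  .pkgenv$codonTable
}

#' GY94 parameter constructor
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param omega omega per branch class (>= 0).
#' @param codonFreqs named 61-vector summing to 1; default uniform.
#' @param freqModel `"F3x4"` or `"F61"` (metadata tag).
#' @return a [GY94Params-class] object.
#' @export
GY94Params <- function(kappa, omega, codonFreqs = uniformCodonFreqs(),
                       freqModel = "F3x4") {
  new("GY94Params", kappa = kappa, omega = omega, codonFreqs = codonFreqs,
      freqModel = freqModel)
}

#' @rdname GY94Params
#' @export
uniformCodonFreqs <- function() {
  setNames(rep(1 / 61, 61), codonTable()$codons)
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61 x 61 Goldman-Yang codon rate generator for one branch class.
#' Codons differing at more than one position have rate 0; single-step rates
#' are proportional to the target codon frequency, multiplied by `kappa` for
#' transitions and by the class omega for nonsynonymous changes. The matrix
#' is scaled to one expected substitution per codon per unit time at
#' stationarity, so branch lengths are in substitutions/codon.
#'
#' @param params a [GY94Params] object.
#' @param classId branch class whose omega is used (0-based; default 0).
#' @return 61 x 61 generator with zero row sums; the stationary distribution
#'   is attached as attribute `"pi"`, and attributes `"rhoS"`/`"rhoN"` give
#'   the stationary proportions of synonymous/nonsynonymous substitutions.
#' @export
buildRateMatrix <- function(params, classId = 0L) {
  stopifnot(is(params, "GY94Params"))
  validObject(params)
  if (classId < 0 || classId >= length(params@omega))
    stop("invalid branch class: ", classId)
  gy94Matrix(params@kappa, params@omega[classId + 1L], params@codonFreqs)
}

# Internal unclassed constructor used in optimization loops.
gy94Matrix <- function(kappa, omega, pi) {
  ct <- codonTable()
  n <- ct$n; pr <- ct$pairs
  Q <- matrix(0, n, n, dimnames = list(ct$codons, ct$codons))
  mult <- ifelse(pr$ts, kappa, 1) * ifelse(pr$syn, 1, omega)
  Q[cbind(pr$i, pr$j)] <- mult * pi[pr$j]
  Q[cbind(pr$j, pr$i)] <- mult * pi[pr$i]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # stationary proportions of synonymous / nonsynonymous flux
  flux <- pi[pr$i] * Q[cbind(pr$i, pr$j)] + pi[pr$j] * Q[cbind(pr$j, pr$i)]
  rS <- sum(flux[pr$syn])
  attr(Q, "pi") <- pi
  attr(Q, "rhoS") <- rS
  attr(Q, "rhoN") <- 1 - rS
  Q
}

# Eigendecomposition of the pi-symmetrized generator; P(t) = V1 exp(Lt) V2.
gy94Decomp <- function(kappa, omega, pi) {
  Q <- gy94Matrix(kappa, omega, pi)
  s <- sqrt(pi)
  S <- Q * (s / rep(s, each = length(s)))   # S_ij = Q_ij * s_i / s_j  (col-major: s[i]/s[j])
  S <- (S + t(S)) / 2                       # symmetric up to rounding
  e <- eigen(S, symmetric = TRUE)
  list(lambda = e$values,
       V1 = e$vectors / s,                  # diag(1/s) %*% U
       V2 = t(e$vectors * s),               # t(U) %*% diag(s)
       Q = Q)
}

# Unnormalized total flux of the GY94 generator: mu = A + omega * B, where
# A and B are the synonymous and nonsynonymous flux at omega = 1. Used to
# put the site classes of a mixture on a common mutation-rate scale.
gy94Flux <- function(kappa, pi) {
  ct <- codonTable(); pr <- ct$pairs
  mult <- ifelse(pr$ts, kappa, 1)
  flux <- mult * (pi[pr$i] * pi[pr$j] + pi[pr$j] * pi[pr$i])
  c(A = sum(flux[pr$syn]), B = sum(flux[!pr$syn]))
}

decompProbs <- function(dec, t) {
  P <- dec$V1 %*% (exp(dec$lambda * t) * dec$V2)
  P[P < 0] <- 0
  P
}

#' Codon transition probability matrix
#'
#' `P(t) = exp(Qt)` computed by eigendecomposition of the pi-symmetrized
#' generator (the GY94 matrix is time-reversible).
#'
#' @param Q generator from [buildRateMatrix()] (its `"pi"` attribute is used;
#'   for an arbitrary reversible generator the stationary distribution is
#'   recovered from the left null vector).
#' @param t elapsed time in expected substitutions per codon, >= 0.
#' @return 61 x 61 stochastic matrix.
#' @export
transitionProbs <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) {
    e <- eigen(t(Q))
    v <- abs(Re(e$vectors[, which.min(abs(e$values))]))
    pi <- v / sum(v)
  }
  s <- sqrt(pi)
  S <- Q * (s / rep(s, each = length(s)))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- (e$vectors / s) %*% (exp(e$values * t) * t(e$vectors * s))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Equilibrium codon frequencies from data
#'
#' `F3x4` multiplies the observed nucleotide frequencies at the three codon
#' positions and renormalizes over the 61 sense codons; `F61` uses empirical
#' codon proportions. A small pseudocount keeps all frequencies strictly
#' positive.
#'
#' @param aln a [CodonAlignment] (gaps/ambiguities are ignored in counting).
#' @param model `"F3x4"` or `"F61"`.
#' @return named 61-vector summing to 1.
#' @export
codonFrequencies <- function(aln, model = c("F3x4", "F61")) {
  model <- match.arg(model)
  ct <- codonTable()
  codons <- codonCharMatrix(aln)       # nseq x nsite of codon strings
  obs <- codons[codons %in% ct$codons]
  if (model == "F61") {
    cnt <- table(factor(obs, levels = ct$codons)) + 0.5
    p <- as.numeric(cnt) / sum(cnt)
  } else {
    nts <- c("A", "C", "G", "T")
    chars <- do.call(rbind, strsplit(obs, ""))
    f <- sapply(1:3, function(k)
      (table(factor(chars[, k], levels = nts)) + 0.5) /
        (length(obs) + 2))
    cmat <- do.call(rbind, strsplit(ct$codons, ""))
    p <- f[cbind(match(cmat[, 1], nts), 1)] *
         f[cbind(match(cmat[, 2], nts), 2)] *
         f[cbind(match(cmat[, 3], nts), 3)]
    p <- p / sum(p)
  }
  setNames(p, ct$codons)
}

# --- alignment preprocessing -------------------------------------------------

# nseq x ncodon matrix of codon strings
codonCharMatrix <- function(aln) {
  m <- as.matrix(aln@seqs)
  nc <- ncol(m) %/% 3
  out <- matrix("", nrow = nrow(m), ncol = nc,
                dimnames = list(names(aln@seqs), NULL))
  for (k in seq_len(nc))
    out[, k] <- paste0(m[, 3 * k - 2], m[, 3 * k - 1], m[, 3 * k])
  out
}

# integer codon states (1..61) per sequence x site; error on gap/ambiguity
codonStateMatrix <- function(aln) {
  ct <- codonTable()
  cm <- codonCharMatrix(aln)
  st <- match(cm, ct$codons)
  if (anyNA(st))
    stop("alignment contains gaps, stops or ambiguous codons; ",
         "run stripGapColumns() first")
  matrix(st, nrow = nrow(cm), dimnames = dimnames(cm))
}

# compress identical site columns into patterns with weights
compressPatterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ".")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = states[, first, drop = FALSE],
       weight = as.numeric(tabulate(idx, sum(first))),
       siteToPattern = idx)
}

# --- tree preprocessing ------------------------------------------------------

# Postorder edge traversal data for a LabeledTree, with tips matched to
# alignment row order.
treeIndex <- function(ltree, tipNames) {
  tr <- ape::reorder.phylo(ltree@tree, "postorder")
  ord <- match(ltree@tree$edge[, 1] * 1e6 + ltree@tree$edge[, 2],
               tr$edge[, 1] * 1e6 + tr$edge[, 2])
  bc <- integer(nrow(tr$edge))
  bc[ord] <- ltree@branchClass
  tipIdx <- match(tr$tip.label, tipNames)
  if (anyNA(tipIdx)) stop("tree tips not found in alignment: ",
                          paste(tr$tip.label[is.na(tipIdx)], collapse = ", "))
  list(edge = tr$edge, len = tr$edge.length, class = bc,
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       root = tr$edge[nrow(tr$edge), 1], tipIdx = tipIdx)
}

# Felsenstein pruning. decs: list of eigendecompositions indexed by class+1.
# Returns per-pattern log-likelihood vector.
pruneLogLik <- function(ti, decs, states, pi) {
  npat <- ncol(states)
  nn <- ti$ntip + ti$nnode
  partial <- vector("list", nn)
  logscale <- numeric(npat)
  for (k in seq_along(ti$len)) {
    par <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    P <- decompProbs(decs[[ti$class[k] + 1L]], ti$len[k])
    if (ch <= ti$ntip) {
      contrib <- P[, states[ti$tipIdx[ch], ], drop = FALSE]
    } else {
      contrib <- P %*% partial[[ch]]
    }
    partial[[par]] <- if (is.null(partial[[par]])) contrib
                      else partial[[par]] * contrib
  }
  # scale once at root; intermediate underflow is negligible for the tree
  # sizes this engine targets, but guard against it anyway
  lik <- colSums(pi * partial[[ti$root]])
  if (any(lik <= 0) || any(!is.finite(lik))) {
    # redo with per-node scaling
    partial <- vector("list", nn)
    logscale <- numeric(npat)
    for (k in seq_along(ti$len)) {
      par <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
      P <- decompProbs(decs[[ti$class[k] + 1L]], ti$len[k])
      contrib <- if (ch <= ti$ntip) P[, states[ti$tipIdx[ch], ], drop = FALSE]
                 else P %*% partial[[ch]]
      acc <- if (is.null(partial[[par]])) contrib else partial[[par]] * contrib
      cm <- apply(acc, 2, max)
      cm[cm == 0] <- 1
      logscale <- logscale + log(cm)
      partial[[par]] <- sweep(acc, 2, cm, "/")
    }
    lik <- colSums(pi * partial[[ti$root]])
  }
  log(lik) + logscale
}
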