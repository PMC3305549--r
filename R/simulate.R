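# Synthetic data with known ground truth: codon alignments evolved under
# per-branch / per-site omega regimes, and multi-genome gene families with
# duplications, losses and unrelated decoy families.

#' Codon simulation regime
#'
#' Describes how a codon alignment evolves: a labeled tree, GY94 parameters,
#' and a set of site classes, each with a proportion and one omega per
#' branch class. With one site class this is a branch-specific regime; four
#' classes with a foreground-only elevated omega emulate branch-site
#' model A data.
#'
#' @slot tree [LabeledTree]; branch classes select per-branch omegas.
#' @slot kappa transition/transversion ratio.
#' @slot codonFreqs 61-vector of root/equilibrium codon frequencies.
#' @slot siteClasses list; each element is `list(prop = , omega = )` where
#'   `omega` has one entry per branch class. Proportions sum to 1.
#' @slot nCodons number of codon sites.
#' @slot seed integer RNG seed.
#'
#' @exportClass SimRegime
setClass("SimRegime",
  representation(tree = "LabeledTree", kappa = "numeric",
                 codonFreqs = "numeric", siteClasses = "list",
                 nCodons = "integer", seed = "integer"))

setValidity("SimRegime", function(object) {
  msg <- character()
  props <- vapply(object@siteClasses, function(s) s$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-8)
    msg <- c(msg, "site-class proportions must sum to 1")
  K <- nOmegaClasses(object@tree)
  for (s in object@siteClasses) {
    if (length(s$omega) < K)
      msg <- c(msg, "each site class needs an omega per branch class")
    if (any(s$omega < 0)) msg <- c(msg, "omegas must be >= 0")
  }
  if (object@nCodons < 1) msg <- c(msg, "nCodons must be >= 1")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  p <- object@codonFreqs
  if (length(p) != 61 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "codonFreqs must be a 61-vector summing to 1")
  if (!is.null(object@tree@tree$edge.length) &&
      any(object@tree@tree$edge.length < 0))
    msg <- c(msg, "branch lengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimRegime constructor with sensible defaults: uniform codon
#'   frequencies, kappa = 2, a single site class with omega 0.2 per branch
#'   class.
#' @param tree [LabeledTree] or Newick string.
#' @param kappa,codonFreqs,siteClasses,nCodons,seed see slots.
#' @export
simRegime <- function(tree, nCodons, kappa = 2, codonFreqs = NULL,
                      siteClasses = NULL, seed = 1L) {
  if (!is(tree, "LabeledTree")) tree <- LabeledTree(tree)
  if (is.null(codonFreqs))
    codonFreqs <- setNames(rep(1 / 61, 61), codonTable()$codons)
  if (is.null(siteClasses))
    siteClasses <- list(list(prop = 1,
                             omega = rep(0.2, nOmegaClasses(tree))))
  new("SimRegime", tree = tree, kappa = kappa, codonFreqs = codonFreqs,
      siteClasses = siteClasses, nCodons = as.integer(nCodons),
      seed = as.integer(seed))
}

#' Branch-site (model A) simulation regime
#'
#' Convenience constructor for the four-site-class regime: conserved
#' (omega0 everywhere), neutral (1 everywhere), and two selected classes
#' where foreground branches (class 1 of `tree`) use `omega2`.
#'
#' @param tree [LabeledTree] with foreground branches labeled class 1.
#' @param nCodons number of codon sites.
#' @param p0,p1 proportions of the conserved and neutral classes; the
#'   selected remainder is split between 2a and 2b in ratio p0 : p1.
#' @param omega0 conserved-class omega; `omega2` foreground omega.
#' @param kappa,codonFreqs,seed as in [simRegime()].
#' @return a [SimRegime].
#' @export
modelARegime <- function(tree, nCodons, p0 = 0.6, p1 = 0.3, omega0 = 0.2,
                         omega2 = 1, kappa = 2, codonFreqs = NULL,
                         seed = 1L) {
  if (!is(tree, "LabeledTree")) tree <- LabeledTree(tree)
  if (nOmegaClasses(tree) != 2L)
    stop("tree must have exactly classes {0 = background, 1 = foreground}")
  p2 <- 1 - p0 - p1
  sc <- list(
    list(prop = p0, omega = c(omega0, omega0)),
    list(prop = p1, omega = c(1, 1)),
    list(prop = p2 * p0 / (p0 + p1), omega = c(omega0, omega2)),
    list(prop = p2 * p1 / (p0 + p1), omega = c(1, omega2)))
  simRegime(tree, nCodons, kappa = kappa, codonFreqs = codonFreqs,
            siteClasses = sc, seed = seed)
}

#' Simulate a codon alignment under a GY94 regime
#'
#' Each site evolves independently: its class is drawn from the site-class
#' proportions, the root codon from the equilibrium frequencies, and along
#' every branch the codon transits according to `exp(Qt)` for that branch's
#' omega class (exact endpoint sampling, no indels, so the output is aligned
#' by construction). Deterministic given the regime's seed.
#'
#' @param regime a [SimRegime].
#' @return list with `aln` (a gap-free [CodonAlignment]) and `siteClass`
#'   (integer vector of true per-site class indices, 1-based).
#' @export
simulateCodonAlignment <- function(regime) {
  stopifnot(is(regime, "SimRegime"))
  validObject(regime)
  tr <- regime@tree@tree
  if (length(tr$tip.label) < 2) stop("tree must have at least 2 tips")
  n <- regime@nCodons
  set.seed(regime@seed)
  nsc <- length(regime@siteClasses)
  props <- vapply(regime@siteClasses, function(s) s$prop, numeric(1))
  siteClass <- sample.int(nsc, n, replace = TRUE, prob = props)
  pi <- regime@codonFreqs

  # decompositions per (site class, branch class); P shared across edges.
  # With several site classes the classes share one mutation-rate scale
  # (branch lengths = expected subs/codon under the proportion-weighted
  # background mixture), so high-omega sites evolve proportionally faster;
  # a single site class keeps the per-omega normalization of branch models.
  K <- nOmegaClasses(regime@tree)
  decs <- lapply(regime@siteClasses, function(s)
    lapply(seq_len(K), function(k)
      gy94Decomp(regime@kappa, s$omega[k], pi)))
  fl <- gy94Flux(regime@kappa, pi)
  mu <- function(w) unname(fl["A"] + w * fl["B"])
  tScale <- matrix(1, nsc, K)
  if (nsc > 1) {
    cc <- sum(props * vapply(regime@siteClasses,
                             function(s) mu(s$omega[1]), numeric(1)))
    for (sc in seq_len(nsc)) for (k in seq_len(K))
      tScale[sc, k] <- mu(regime@siteClasses[[sc]]$omega[k]) / cc
  }

  ntip <- length(tr$tip.label)
  po <- ape::reorder.phylo(tr, "postorder")
  ordMap <- match(po$edge[, 1] * 1e6 + po$edge[, 2],
                  tr$edge[, 1] * 1e6 + tr$edge[, 2])
  bc <- regime@tree@branchClass[ordMap]
  nn <- ntip + tr$Nnode
  statesAt <- matrix(NA_integer_, nn, n)
  root <- po$edge[nrow(po$edge), 1]
  statesAt[root, ] <- sample.int(61, n, replace = TRUE, prob = pi)
  for (k in rev(seq_len(nrow(po$edge)))) {        # preorder
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    t <- po$edge.length[k]
    child <- integer(n)
    for (sc in unique(siteClass)) {
      idx <- which(siteClass == sc)
      tEff <- t * tScale[sc, bc[k] + 1L]
      if (tEff == 0) { child[idx] <- statesAt[par, idx]; next }
      P <- decompProbs(decs[[sc]][[bc[k] + 1L]], tEff)
      P <- P / rowSums(P)
      for (st in unique(statesAt[par, idx])) {
        ii <- idx[statesAt[par, idx] == st]
        child[ii] <- sample.int(61, length(ii), replace = TRUE,
                                prob = P[st, ])
      }
    }
    statesAt[ch, ] <- child
  }
  codons <- codonTable()$codons
  rows <- apply(statesAt[seq_len(ntip), , drop = FALSE], 1,
                function(s) paste(codons[s], collapse = ""))
  names(rows) <- tr$tip.label
  list(aln = CodonAlignment(rows), siteClass = siteClass)
}

# --- genome simulation -------------------------------------------------------

#' Ground truth for one simulated gene family
#'
#' @slot familyId family identifier.
#' @slot members data.frame with columns `genome`, `gene`.
#' @slot events data.frame log of duplication/loss events
#'   (`event`, `branch`, `lineage`); replaying it over the species tree
#'   yields exactly the member set.
#' @slot decoy logical; decoy families provide background-level similarity.
#'
#' @exportClass FamilyTruth
setClass("FamilyTruth",
  representation(familyId = "character", members = "data.frame",
                 events = "data.frame", decoy = "logical"))

setMethod("show", "FamilyTruth", function(object) {
  cat("FamilyTruth", object@familyId, ":", nrow(object@members),
      "genes in", length(unique(object@members$genome)), "genomes",
      if (object@decoy) "(decoy)" else "", "\n")
})

#' @describeIn GenomeSet constructor.
#' @param proteins,cds,genome see slots.
#' @export
GenomeSet <- function(proteins, cds, genome) {
  if (!is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  if (!is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  genome <- as.character(genome)
  # canonical gene order makes serialization round trips exact
  ord <- order(names(proteins))
  new("GenomeSet", proteins = proteins[ord], cds = cds[ord],
      genome = genome[ord])
}

#' @describeIn GenomeSet genome identifiers (one per gene).
#' @param x a [GenomeSet].
#' @export
geneGenomes <- function(x) setNames(x@genome, names(x@proteins))

#' @describeIn GenomeSet gene identifiers.
#' @export
geneIds <- function(x) names(x@proteins)

#' @describeIn GenomeSet protein sequences.
#' @export
proteinSeqs <- function(x) x@proteins

#' @describeIn GenomeSet coding sequences.
#' @export
cdsSeqs <- function(x) x@cds

setMethod("show", "GenomeSet", function(object) {
  cat("GenomeSet:", length(object@proteins), "genes in",
      length(unique(object@genome)), "genomes\n")
})

setMethod("length", "GenomeSet", function(x) length(x@proteins))

# balanced species-tree topology over n genomes with fixed branch lengths
balancedSpeciesTree <- function(n, branchLength = 0.2) {
  build <- function(labels) {
    if (length(labels) == 1) return(labels)
    half <- ceiling(length(labels) / 2)
    paste0("(", build(labels[seq_len(half)]), ":", branchLength, ",",
           build(labels[-seq_len(half)]), ":", branchLength, ")")
  }
  labs <- paste0("G", seq_len(n))
  ape::read.tree(text = paste0(build(labs), ";"))
}

#' Simulate genomes containing known gene families
#'
#' Each family starts from an independent random root coding sequence and
#' evolves down a fixed species tree under a one-ratio GY94 regime; on every
#' branch each gene lineage may duplicate (Poisson, rate per unit branch
#' length) or be lost (exponential waiting), with events applied at the
#' start of the branch and all resulting lineages evolving independently
#' along it. Decoy families evolve the same way but always without
#' duplication or loss, providing unrelated background-level similarity.
#' Every simulated CDS is over sense codons only, so its protein is its
#' exact translation.
#'
#' @param nGenomes number of genomes (>= 2); species tree is balanced with
#'   equal branch lengths.
#' @param nFamilies number of target families subject to duplication/loss.
#' @param nDecoyFamilies number of decoy families.
#' @param dupRate,lossRate per-branch-length event rates, >= 0.
#' @param seed integer root seed; per-family seeds are derived as
#'   `(seed * 1000003 + index * 7919) mod (2^31 - 1)`.
#' @param nCodons gene length in codons.
#' @param omega,kappa GY94 parameters of the family regime.
#' @param branchLength species-tree branch length (substitutions/codon).
#' @param selection optional list `(foregroundTips, omega2, p0, p1)`
#'   applying a branch-site regime to the target families (requires
#'   `dupRate = lossRate = 0`): foreground branches are the clade spanned by
#'   `foregroundTips`.
#' @return list with `genomes` (a [GenomeSet]), `truth` (list of
#'   [FamilyTruth]), and `speciesTree` (a [LabeledTree]; class 1 marks the
#'   foreground clade when `selection` is given).
#' @export
simulateGenomes <- function(nGenomes, nFamilies = 1, nDecoyFamilies = 3,
                            dupRate = 0, lossRate = 0, seed = 1L,
                            nCodons = 150, omega = 0.2, kappa = 2,
                            branchLength = 0.2, selection = NULL) {
  if (nGenomes < 2) stop("nGenomes must be >= 2")
  if (dupRate < 0 || lossRate < 0) stop("rates must be >= 0")
  if (!is.null(selection) && (dupRate > 0 || lossRate > 0))
    stop("selection regimes require dupRate = lossRate = 0")
  sp <- balancedSpeciesTree(nGenomes, branchLength)
  ltree <- LabeledTree(sp)
  if (!is.null(selection))
    ltree <- labelClade(ltree, selection$foregroundTips, 1L)

  pi <- setNames(rep(1 / 61, 61), codonTable()$codons)
  famIds <- c(if (nFamilies) paste0("F", seq_len(nFamilies)),
              if (nDecoyFamilies) paste0("D", seq_len(nDecoyFamilies)))
  isDecoy <- grepl("^D", famIds)

  allProt <- character(0); allCds <- character(0); allGenome <- character(0)
  truth <- vector("list", length(famIds))

  for (fi in seq_along(famIds)) {
    childSeed <- as.integer((seed * 1000003 + fi * 7919) %% 2147483647)
    fam <- famIds[fi]
    if (!isDecoy[fi] && !is.null(selection)) {
      reg <- modelARegime(ltree, nCodons,
                          p0 = selection$p0 %||% 0.6,
                          p1 = selection$p1 %||% 0.3,
                          omega0 = omega, omega2 = selection$omega2,
                          kappa = kappa, seed = childSeed)
      sim <- simulateCodonAlignment(reg)
      cds <- as.character(sim$aln@seqs)
      members <- data.frame(genome = names(cds),
                            gene = paste0(names(cds), "_", fam))
      events <- data.frame(event = character(0), branch = character(0),
                           lineage = character(0))
    } else if (isDecoy[fi] || (dupRate == 0 && lossRate == 0)) {
      reg <- simRegime(ltree0 <- LabeledTree(sp), nCodons, kappa = kappa,
                       siteClasses = list(list(prop = 1, omega = omega)),
                       seed = childSeed)
      sim <- simulateCodonAlignment(reg)
      cds <- as.character(sim$aln@seqs)
      members <- data.frame(genome = names(cds),
                            gene = paste0(names(cds), "_", fam))
      events <- data.frame(event = character(0), branch = character(0),
                           lineage = character(0))
    } else {
      bd <- simulateFamilyBirthDeath(sp, dupRate, lossRate, kappa, omega,
                                     pi, nCodons, childSeed)
      cds <- bd$cds
      members <- data.frame(genome = bd$genome,
                            gene = paste0(bd$genome, "_", fam, "_",
                                          bd$copy))
      events <- bd$events
    }
    names(cds) <- members$gene
    allProt <- c(allProt, setNames(translateCDS(cds), members$gene))
    allCds <- c(allCds, cds)
    allGenome <- c(allGenome, members$genome)
    truth[[fi]] <- new("FamilyTruth", familyId = fam, members = members,
                       events = events, decoy = isDecoy[fi])
  }
  list(genomes = GenomeSet(allProt, allCds, allGenome),
       truth = truth, speciesTree = ltree)
}

# Gene birth-death along the species tree: events at branch starts, each
# surviving lineage then evolves independently along the branch.
simulateFamilyBirthDeath <- function(sp, dupRate, lossRate, kappa, omega,
                                     pi, nCodons, seed) {
  set.seed(seed)
  dec <- gy94Decomp(kappa, omega, pi)
  codons <- codonTable()$codons
  evolve <- function(states, t) {
    if (t == 0) return(states)
    P <- decompProbs(dec, t); P <- P / rowSums(P)
    out <- integer(length(states))
    for (st in unique(states)) {
      ii <- which(states == st)
      out[ii] <- sample.int(61, length(ii), replace = TRUE, prob = P[st, ])
    }
    out
  }
  ntip <- length(sp$tip.label)
  po <- ape::reorder.phylo(sp, "postorder")
  root <- po$edge[nrow(po$edge), 1]
  lineages <- vector("list", ntip + sp$Nnode)
  lineages[[root]] <- list(list(id = "L1",
                                states = sample.int(61, nCodons, TRUE, pi)))
  nextId <- 2L
  events <- data.frame(event = character(0), branch = character(0),
                       lineage = character(0))
  nodeName <- function(v) if (v <= ntip) sp$tip.label[v]
                          else paste0("node", v)
  for (k in rev(seq_len(nrow(po$edge)))) {        # preorder
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]; t <- po$edge.length[k]
    out <- list()
    for (lin in lineages[[par]]) {
      if (lossRate > 0 && runif(1) > exp(-lossRate * t)) {
        events <- rbind(events, data.frame(
          event = "loss", branch = nodeName(ch), lineage = lin$id))
        next
      }
      copies <- list(lin)
      if (dupRate > 0) {
        nd <- rpois(1, dupRate * t)
        for (d in seq_len(nd)) {
          newId <- paste0("L", nextId); nextId <- nextId + 1L
          events <- rbind(events, data.frame(
            event = "duplication", branch = nodeName(ch),
            lineage = newId))
          copies <- c(copies, list(list(id = newId, states = lin$states)))
        }
      }
      for (cp in copies) {
        cp$states <- evolve(cp$states, t)
        out <- c(out, list(cp))
      }
    }
    lineages[[ch]] <- out
  }
  genome <- character(0); copy <- character(0); cds <- character(0)
  for (v in seq_len(ntip)) {
    for (lin in lineages[[v]]) {
      genome <- c(genome, sp$tip.label[v])
      copy <- c(copy, lin$id)
      cds <- c(cds, paste(codons[lin$states], collapse = ""))
    }
  }
  list(genome = genome, copy = copy, cds = cds, events = events)
}

# --- fixtures ---------------------------------------------------------------

#' Write and read a genome fixture directory
#'
#' `writeGenomeFixture` writes per-genome protein and CDS FASTA files, a
#' truth table TSV (`genome`, `gene`, `family`, `decoy`) and a JSON manifest
#' listing the files. `readGenomeFixture` reads it back.
#'
#' @param sim result of [simulateGenomes()] (or a list with `genomes` and
#'   `truth`).
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the manifest.
#' @return `writeGenomeFixture`: the manifest (invisibly);
#'   `readGenomeFixture`: list with `genomes` and `truth` (a data.frame).
#' @export
writeGenomeFixture <- function(sim, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- sim$genomes
  files <- character(0)
  for (g in unique(gs@genome)) {
    sel <- gs@genome == g
    pf <- file.path(dir, paste0(g, "_protein.fasta"))
    cf <- file.path(dir, paste0(g, "_cds.fasta"))
    Biostrings::writeXStringSet(gs@proteins[sel], pf)
    Biostrings::writeXStringSet(gs@cds[sel], cf)
    files <- c(files, pf, cf)
  }
  tt <- do.call(rbind, lapply(sim$truth, function(ft)
    cbind(ft@members, family = ft@familyId, decoy = ft@decoy)))
  tf <- file.path(dir, "truth.tsv")
  write.table(tt, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(files = basename(c(files, tf)), seed = seed,
                   nGenomes = length(unique(gs@genome)),
                   nGenes = length(gs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname writeGenomeFixture
#' @export
readGenomeFixture <- function(dir) {
  pfiles <- sort(list.files(dir, "_protein\\.fasta$", full.names = TRUE))
  prot <- character(0); cds <- character(0); genome <- character(0)
  for (pf in pfiles) {
    g <- sub("_protein\\.fasta$", "", basename(pf))
    p <- Biostrings::readAAStringSet(pf)
    d <- Biostrings::readDNAStringSet(file.path(dir, paste0(g, "_cds.fasta")))
    prot <- c(prot, setNames(as.character(p), names(p)))
    cds <- c(cds, setNames(as.character(d), names(d)))
    genome <- c(genome, rep(g, length(p)))
  }
  truth <- if (file.exists(file.path(dir, "truth.tsv")))
    read.delim(file.path(dir, "truth.tsv")) else NULL
  list(genomes = GenomeSet(prot, cds, genome), truth = truth)
}
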