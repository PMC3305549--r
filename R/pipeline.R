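# End-to-end orchestration: simulate or ingest genomes -> COG detection ->
# codon alignment -> NJ tree -> branch and branch-site selection tests ->
# report, with per-stage persisted outputs and a checksum manifest.

#' Build a pipeline configuration
#'
#' @param mode `"synthetic"` (simulate genomes) or `"fasta"` (read a fixture
#'   directory written by [writeGenomeFixture()]).
#' @param outDir output directory.
#' @param inputDir fixture directory (fasta mode).
#' @param nGenomes,nFamilies,nDecoyFamilies,dupRate,lossRate,nCodons,omega,kappa,branchLength,selection
#'   synthetic-mode options, passed to [simulateGenomes()].
#' @param minScore similarity threshold (`NULL`: estimated from shuffled
#'   sequences).
#' @param bootstrapReps NJ bootstrap replicates.
#' @param seedGene optional gene identifier; the analyzed cluster is the
#'   one containing it (mirroring a seed-driven ortholog search). Default:
#'   the largest cluster.
#' @param models named list; each element is
#'   `list(foregroundGenomes = <character>)` defining one foreground clade
#'   to test with a two-ratio branch model and a branch-site test.
#' @param seed master seed for every stochastic stage.
#' @return a `list` of class `cogselectConfig`.
#' @export
pipelineConfig <- function(mode = c("synthetic", "fasta"),
                           outDir = tempfile("cogselect_run_"),
                           inputDir = NULL,
                           nGenomes = 4, nFamilies = 1, nDecoyFamilies = 2,
                           dupRate = 0, lossRate = 0, nCodons = 150,
                           omega = 0.2, kappa = 2, branchLength = 0.2,
                           selection = NULL, minScore = NULL,
                           seedGene = NULL, bootstrapReps = 100,
                           models = list(clade1 = list(
                             foregroundGenomes = c("G1", "G2"))),
                           seed = 1L) {
  cfg <- list(mode = match.arg(mode), outDir = outDir, inputDir = inputDir,
              nGenomes = nGenomes, nFamilies = nFamilies,
              nDecoyFamilies = nDecoyFamilies, dupRate = dupRate,
              lossRate = lossRate, nCodons = nCodons, omega = omega,
              kappa = kappa, branchLength = branchLength,
              selection = selection, minScore = minScore,
              seedGene = seedGene,
              bootstrapReps = bootstrapReps, models = models,
              seed = as.integer(seed))
  class(cfg) <- "cogselectConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns the list of problems that would prevent [runPipeline()] from
#' starting: missing input files in fasta mode, duplicate model names,
#' foreground references that do not resolve against the genome set, and
#' out-of-range rates. An empty result means the run would start.
#'
#' @param config a config from [pipelineConfig()].
#' @return character vector of issues (length 0 when valid).
#' @export
validatePipelineConfig <- function(config) {
  issues <- character(0)
  if (!inherits(config, "cogselectConfig"))
    return("config must be built with pipelineConfig()")
  if (config$mode == "fasta") {
    if (is.null(config$inputDir) || !dir.exists(config$inputDir))
      issues <- c(issues, "fasta mode requires an existing inputDir")
    else if (!length(list.files(config$inputDir, "_cds\\.fasta$")))
      issues <- c(issues, "inputDir contains no *_cds.fasta files")
  }
  nm <- names(config$models)
  if (is.null(nm) || anyDuplicated(nm))
    issues <- c(issues, "model names must be present and unique")
  genomes <- if (config$mode == "synthetic")
    paste0("G", seq_len(config$nGenomes))
  else if (!is.null(config$inputDir) && dir.exists(config$inputDir))
    sub("_cds\\.fasta$", "", list.files(config$inputDir, "_cds\\.fasta$"))
  else NULL
  if (!is.null(genomes)) {
    for (n in names(config$models)) {
      fg <- config$models[[n]]$foregroundGenomes
      if (is.null(fg) || !length(fg))
        issues <- c(issues, paste0("model ", n, ": no foreground genomes"))
      else if (!all(fg %in% genomes))
        issues <- c(issues, paste0("model ", n,
                                   ": unknown foreground genomes ",
                                   paste(setdiff(fg, genomes),
                                         collapse = ", ")))
      else if (all(genomes %in% fg))
        issues <- c(issues, paste0("model ", n,
                                   ": foreground covers every genome"))
    }
  }
  if (config$dupRate < 0 || config$lossRate < 0)
    issues <- c(issues, "rates must be >= 0")
  if (config$mode == "synthetic" && config$nGenomes < 3)
    issues <- c(issues, "COG formation needs at least 3 genomes")
  issues
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (simulation or FASTA ingest), COG detection,
#' codon-alignment construction, NJ tree with bootstrap, one-ratio and
#' two-ratio branch-model fits plus branch-site tests for every configured
#' foreground clade, and report rendering. Every stage persists its output
#' under `outDir`, and a JSON manifest records files, MD5 checksums and the
#' seed; rerunning the same configuration reproduces identical checksums.
#'
#' @param config from [pipelineConfig()].
#' @return invisible list: `clusters`, `alignment`, `tree`, `fits`,
#'   `tests`, `table`, `manifest`.
#' @export
runPipeline <- function(config) {
  issues <- validatePipelineConfig(config)
  if (length(issues))
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  sim <- .stage("input", {
    if (config$mode == "synthetic") {
      s <- simulateGenomes(config$nGenomes, config$nFamilies,
                           config$nDecoyFamilies, dupRate = config$dupRate,
                           lossRate = config$lossRate, seed = config$seed,
                           nCodons = config$nCodons, omega = config$omega,
                           kappa = config$kappa,
                           branchLength = config$branchLength,
                           selection = config$selection)
      writeGenomeFixture(s, file.path(out, "genomes"), seed = config$seed)
      s
    } else {
      readGenomeFixture(config$inputDir)
    }
  })

  clusters <- .stage("cogfind", {
    hits <- allAgainstAll(sim$genomes, minScore = config$minScore)
    bets <- bestHits(hits)
    cl <- formCOGs(bets)
    if (!length(cl)) stop("no COG clusters found")
    exportClusterTable(cl, file.path(out, "clusters.tsv"))
    write.table(cogDiagnostics(cl, hits),
                file.path(out, "cluster_diagnostics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    exportNetwork(cl[[1]], file.path(out, "cog_network.tsv"))
    exportNetwork(cl[[1]], file.path(out, "cog_network.graphml"),
                  format = "graphml")
    cl
  })

  aln <- .stage("align", {
    target <- if (!is.null(config$seedGene)) {
      hit <- which(vapply(clusters, function(x)
        config$seedGene %in% x@members, logical(1)))
      if (!length(hit))
        stop("seed gene ", config$seedGene, " is in no cluster")
      clusters[[hit[1]]]
    } else {
      clusters[[which.max(vapply(clusters, function(x)
        length(x@members), numeric(1)))]]
    }
    cds <- as.character(cdsSeqs(sim$genomes)[target@members])
    if (length(unique(nchar(cds))) > 1)
      stop("cluster CDS lengths differ; supply a protein alignment ",
           "to back-map (indels are not aligned by this pipeline)")
    a <- stripGapColumns(CodonAlignment(cds))
    writeFasta(alignedSeqs(a), file.path(out, "codon_alignment.fasta"))
    a
  })

  njt <- .stage("njtree", {
    prot <- translateCDS(as.character(alignedSeqs(aln)))
    bt <- bootstrapSupport(prot, nReps = config$bootstrapReps,
                           seed = config$seed)
    writeNewickTags(bt, file.path(out, "nj_tree.nwk"))
    bt
  })

  fits <- list(); tests <- list()
  .stage("selection", {
    geneGenome <- geneGenomes(sim$genomes)[njt@tree$tip.label]
    m0 <- fitCodonModel(aln, njt, nStarts = 1)
    fits[["one-ratio"]] <- m0
    for (mn in names(config$models)) {
      fg <- config$models[[mn]]$foregroundGenomes
      tips <- njt@tree$tip.label[geneGenome %in% fg]
      if (!length(tips) || length(tips) == length(njt@tree$tip.label))
        stop("model ", mn, ": foreground clade not represented in cluster")
      labeled <- labelClade(LabeledTree(m0@tree@tree), tips, 1L,
                            type = "clade")
      two <- fitCodonModel(aln, labeled, nStarts = 1,
                           init = list(kappa = m0@params@kappa,
                                       omega = m0@params@omega))
      fits[[paste0("two-ratio:", mn)]] <- two
      tests[[paste0("two-ratio vs one-ratio:", mn)]] <-
        lrt(m0, two, df = 1)
      bst <- branchSiteTest(aln, labeled, fixBranchLengths = TRUE)
      fits[[paste0("modelA-null:", mn)]] <- bst$null
      fits[[paste0("modelA-alt:", mn)]] <- bst$alt
      tests[[paste0("branch-site:", mn)]] <- bst$test
      if (bst$test@pValue < 0.05) {
        post <- sitePosteriors(bst$alt, aln, method = "BEB")
        write.table(data.frame(site = post@site,
                               posterior = post@posterior),
                    file.path(out, paste0("beb_sites_", mn, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  })

  tab <- .stage("report", {
    tb <- makeSelectionTable(fits, tests)
    writeSelectionTable(tb, file.path(out, "selection_table.tsv"))
    writeSelectionTable(tb, file.path(out, "selection_table.json"),
                        format = "json")
    tb
  })

  manifest <- .stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.json"))
    m <- list(seed = config$seed, mode = config$mode,
              package = as.character(utils::packageVersion("cogselect")),
              files = as.list(setNames(
                unname(tools::md5sum(file.path(out, files))), files)))
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  invisible(list(clusters = clusters, alignment = aln, tree = njt,
                 fits = fits, tests = tests, table = tab,
                 manifest = manifest))
}
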