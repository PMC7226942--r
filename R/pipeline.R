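# End-to-end orchestration: from per-cell contact lists, states, genome,
# peaks, PWMs, PPI and expression to EP loops, the 1D matrix, TF lists, the
# fused network, hierarchy, communities, cliques, cross-cell patterns,
# expression coherence, biclusters, and a reproducible run manifest.

#' Assemble a run configuration for a fixture bundle directory
#'
#' @param dir a directory written by [writeFixtureBundle()].
#' @param cellLines cell-line names present in the bundle.
#' @param seed global seed for the stochastic stages.
#' @param outDir output directory (default `file.path(dir, "out")`).
#' @param params named list overriding default stage parameters.
#' @return a run-configuration list for [runPipeline()].
#' @export
bundleRunConfig <- function(dir, cellLines = c("cellA", "cellB"), seed = 1L,
                            outDir = file.path(dir, "out"), params = list()) {
  cells <- lapply(cellLines, function(cell) list(
    loops = file.path(dir, paste0("loops_", cell, ".bedpe")),
    states = file.path(dir, paste0("states_", cell, ".bed")),
    genome = file.path(dir, paste0("genome_", cell, ".fa")),
    tss = file.path(dir, paste0("tss_", cell, ".bed"))))
  names(cells) <- cellLines
  defaults <- list(alpha = 0.05, min_tags = 5L, p_threshold = 1e-10,
                   enrich_alpha = 0.05, string_min_score = 400,
                   L_min = 2L, L_max = 8L, clique_min = 3L, clique_max = 10L,
                   n_factors = 10L, max_iter = 10000L,
                   snf_t = 20L, restarts = 5L, steps_per_node = 100L,
                   permutations = 200L)
  list(seed = seed, out_dir = outDir,
       peaks_dir = file.path(dir, "peaks"),
       pwms = file.path(dir, "motifs.meme"),
       ppi = file.path(dir, "ppi.tsv"),
       expression = file.path(dir, "expression.tsv"),
       cells = cells,
       params = modifyList(defaults, params))
}

#' Read a YAML run configuration
#' @param path YAML file with the fields of [bundleRunConfig()]'s result.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

.preflight <- function(config) {
  paths <- c(config$pwms, config$ppi, config$expression,
             unlist(lapply(config$cells, function(c)
               c(c$loops, c$states, c$genome, c$tss))))
  if (!is.null(config$peaks_dir)) paths <- c(paths, config$peaks_dir)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing input(s):\n%s", paste(" ", missing, collapse = "\n"))
}

.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  cat(sprintf("[%s] %s (%.1fs)\n", format(Sys.time(), "%H:%M:%S"), name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = log, append = TRUE)
  res
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each writes its artifact under
#' `config$out_dir` and the run ends with a manifest recording input/output
#' hashes, parameters and the seed (no timestamps, so reruns with identical
#' config and seed produce byte-identical manifests).
#'
#' @param config configuration list (see [bundleRunConfig()] /
#'   [readRunConfig()]).
#' @return invisibly, a list with the in-memory artifacts of every stage.
#' @export
runPipeline <- function(config) {
  .preflight(config)
  p <- config$params
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat("", file = log)
  cells <- names(config$cells)
  art <- list()

  # --- EP loops per cell ---
  art$ep_loops <- list()
  for (cell in cells) {
    cc <- config$cells[[cell]]
    loopfiles <- cc$loops
    states <- readIntervals(cc$states)
    sets <- lapply(loopfiles, function(f)
      annotateAnchors(readLoops(f, cellLine = cell), states))
    merged <- if (length(sets) > 1L) mergeContacts(sets) else sets[[1]]
    ep <- filterEPLoops(merged, minTags = p$min_tags)
    art$ep_loops[[cell]] <- .stage(log, paste0("ep_loops:", cell), ep)
    writeLoops(ep, file.path(out, paste0("ep_loops_", cell, ".bedpe")))
  }

  # --- 1D similarity matrix (global peak compendium) ---
  peakfiles <- sort(list.files(config$peaks_dir, "\\.bed$", full.names = TRUE))
  peaksets <- setNames(lapply(peakfiles, readIntervals),
                       sub("\\.bed$", "", basename(peakfiles)))
  m1d <- .stage(log, "1d_matrix", build1DMatrix(peaksets, alpha = p$alpha))
  write.table(similarityValues(m1d), file.path(out, "matrix_1d.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  directions <- deriveDirections(m1d)

  # --- motif occupancy and TF lists per cell ---
  pwms <- readPWMs(config$pwms)
  scfg <- scanConfig(p_threshold = p$p_threshold)
  art$tf_lists <- list()
  for (cell in cells) {
    genome <- Biostrings::readDNAStringSet(config$cells[[cell]]$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    tl <- .stage(log, paste0("tf_lists:", cell),
                 buildTFLists(art$ep_loops[[cell]], genome, pwms, scfg,
                              enrichAlpha = p$enrich_alpha))
    art$tf_lists[[cell]] <- tl
    writeJSONArtifact(list(list_A = tl$list_A, list_B = tl$list_B,
                           final = tl$final),
                      file.path(out, paste0("tf_lists_", cell, ".json")))
  }

  # --- fusion and network per cell ---
  ppi <- readEdgeTable(config$ppi)
  fcfg <- fusionConfig(t = p$snf_t)
  art$networks <- list()
  for (cell in cells) {
    final <- art$tf_lists[[cell]]$final
    m3d <- build3DMatrix(final, ppi, minScore = p$string_min_score)
    fused <- snfFuse(m1d, m3d, fcfg)
    net <- binarizeAndOrient(fused$fused, directions, fcfg)
    art$networks[[cell]] <- .stage(log, paste0("network:", cell), net)
    writeJSONArtifact(list(tfs = tfNames(net), edges = networkEdges(net),
                           directed = directedEdges(net)),
                      file.path(out, paste0("network_", cell, ".json")))
  }

  # --- hierarchy, communities, cliques per cell ---
  art$hierarchy <- list(); art$communities <- list(); art$cliques <- list()
  expr <- readExpression(config$expression)
  art$coherence <- list()
  for (cell in cells) {
    net <- art$networks[[cell]]
    acfg <- annealConfig(restarts = p$restarts,
                         steps_per_node = p$steps_per_node,
                         permutations = p$permutations,
                         seed = childSeed(config$seed, match(cell, cells)))
    fit <- .stage(log, paste0("hierarchy:", cell),
                  fitHierarchy(net, Lrange = p$L_min:p$L_max, acfg))
    art$hierarchy[[cell]] <- fit
    writeJSONArtifact(list(L = fit@L, corrected_score = fit@correctedScore,
                           levels = as.list(hierarchyLevels(fit))),
                      file.path(out, paste0("hierarchy_", cell, ".json")))
    write.table(levelLinkRatios(net, fit),
                file.path(out, paste0("level_link_ratios_", cell, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    comms <- .stage(log, paste0("communities:", cell), findCommunities(net))
    art$communities[[cell]] <- comms
    write.table(data.frame(
      community = seq_along(comms),
      members = vapply(comms, function(c) paste(c$members, collapse = ","), ""),
      cohesiveness = vapply(comms, `[[`, 0, "cohesiveness")),
      file.path(out, paste0("communities_", cell, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)
    cl <- .stage(log, paste0("cliques:", cell),
                 maximalCliques(net, p$clique_min, p$clique_max, cell))
    art$cliques[[cell]] <- cl
    write.table(data.frame(
      clique = vapply(cl, .cliqueKey, ""),
      size = lengths(lapply(cl, `[[`, "members"))),
      file.path(out, paste0("cliques_", cell, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)
    cell_expr <- expr[, grep(paste0("^", cell), colnames(expr)), drop = FALSE]
    art$coherence[[cell]] <- if (length(cl) >= 2 && ncol(cell_expr) >= 3)
      .stage(log, paste0("coherence:", cell), suppressWarnings(
        expressionCoherence(cl, cell_expr)))
    else NULL
  }

  # --- cross-cell clique dynamics ---
  art$venn <- compareCliquesAcrossCells(art$cliques)
  art$regulated <- list()
  for (cell in cells) {
    tss <- readIntervals(config$cells[[cell]]$tss)
    occ <- art$tf_lists[[cell]]$occurrences
    art$regulated[[cell]] <- setNames(
      lapply(art$cliques[[cell]], regulatedGenes,
             epLoops = art$ep_loops[[cell]], occurrences = occ, tss = tss),
      vapply(art$cliques[[cell]], .cliqueKey, ""))
  }
  art$patterns <- classifyCliquePatterns(art$cliques, art$regulated)
  writeJSONArtifact(list(venn = art$venn,
                         patterns = art$patterns),
                    file.path(out, "clique_dynamics.json"))

  # --- clique-by-gene biclustering (reference cell = first) ---
  ref <- cells[1]
  genes <- sort(unique(unlist(art$regulated[[ref]])))
  art$biclusters <- NULL
  if (length(art$cliques[[ref]]) >= 2 && length(genes) >= 2) {
    M <- buildCliqueGeneMatrix(art$cliques[[ref]], art$regulated[[ref]], genes)
    nf <- min(p$n_factors, dim(M))
    fit <- .stage(log, "biclusters",
                  fitBiclusters(M, nFactors = nf, maxIter = p$max_iter,
                                seed = childSeed(config$seed, 77)))
    sg <- extractSupercliqueGraph(fit, M)
    art$biclusters <- list(fit = fit, graph = sg)
    writeJSONArtifact(list(supercliques = sg$supercliques,
                           gene_groups = sg$gene_groups, edges = sg$edges),
                      file.path(out, "supercliques.json"))
  }

  # --- manifest (hash-stable across identical reruns) ---
  outputs <- sort(setdiff(list.files(out), c("run.log", "manifest.json")))
  manifest <- list(
    package = "TFloopNet",
    version = as.character(utils::packageVersion("TFloopNet")),
    seed = config$seed,
    params = p,
    inputs = lapply(sort(c(config$pwms, config$ppi, config$expression,
                           unlist(lapply(config$cells, unlist)))),
                    function(f) unname(tools::md5sum(f))),
    outputs = setNames(lapply(file.path(out, outputs), function(f)
      unname(tools::md5sum(f))), outputs))
  writeJSONArtifact(manifest, file.path(out, "manifest.json"))
  art$manifest <- manifest
  invisible(art)
}
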