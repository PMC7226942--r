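# Desk-scale synthetic inputs with planted ground truth for every pipeline
# stage: a regulatory landscape (genome, chromatin states, loops, TF peaks,
# PWMs, TSS) and a network truth bundle (PPI with planted communities and
# maximal cliques, a directed influence list consistent with planted levels,
# clique-correlated expression, and a clique-by-gene matrix with planted
# biclusters).  Fixed seed implies byte-identical outputs.

#' Fixture configuration
#'
#' Defaults define the reference synthetic study conditions: a 2 x 1 Mb
#' genome, 12 TFs in three planted hierarchy levels of four, 60 loops (60%
#' enhancer-promoter), width-18 implanted consensus motifs (so that a perfect
#' match clears a 1e-10 scan p-value), one planted co-localizing TF pair at
#' 90% peak sharing, two planted communities each containing one planted
#' triangle clique, five expression replicates per cell line, and two planted
#' clique-by-gene blocks.
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_len genome shape.
#' @param n_tfs number of TFs.
#' @param n_loops loops per cell line.
#' @param fraction_ep fraction of loops that are enhancer-promoter.
#' @param motif_width implanted consensus width.
#' @param anchor_width,peak_width loop-anchor and ChIP peak widths (bases).
#' @param planted_levels hierarchy level sizes (top first); must sum to
#'   `n_tfs`.
#' @param planted_communities list of TF-name sets.
#' @param planted_cliques list of TF-name sets, each inside some community.
#' @param colocal_pairs list of TF-name pairs planted as 1D co-localizing.
#' @param colocal_share fraction of the first TF's peaks mirrored (within
#'   50 bp) in the second TF's set.
#' @param downward_fraction fraction of directed influences pointing from
#'   lower- to higher-numbered levels.
#' @param n_sim_cliques,n_genes shape of the clique-by-gene matrix.
#' @param planted_biclusters list of `list(cliques=, genes=)` index blocks.
#' @param expression_noise_sd noise sd around the per-clique latent profile.
#' @param samples_per_cell expression replicates per cell line.
#' @param cell_lines cell-line names.
#' @return validated list of class `fixture_config`.
#' @export
fixtureConfig <- function(seed = 1L, n_chroms = 2L, chrom_len = 1000000L,
                          n_tfs = 12L, n_loops = 60L, fraction_ep = 0.6,
                          motif_width = 18L, anchor_width = 500L,
                          peak_width = 200L,
                          planted_levels = c(4L, 4L, 4L),
                          planted_communities = NULL,
                          planted_cliques = NULL,
                          colocal_pairs = NULL,
                          colocal_share = 0.9,
                          downward_fraction = 0.95,
                          n_sim_cliques = 12L, n_genes = 60L,
                          planted_biclusters = NULL,
                          expression_noise_sd = 0.1,
                          samples_per_cell = 5L,
                          cell_lines = c("cellA", "cellB")) {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.null(planted_communities))
    planted_communities <- list(tfs[seq_len(min(6, n_tfs))],
                                tfs[seq(min(7, n_tfs), n_tfs)])
  if (is.null(planted_cliques))
    planted_cliques <- lapply(planted_communities, function(cm)
      cm[seq_len(min(3, length(cm)))])
  if (is.null(colocal_pairs)) colocal_pairs <- list(tfs[1:2])
  if (is.null(planted_biclusters))
    planted_biclusters <- list(
      list(cliques = seq_len(min(4, n_sim_cliques)),
           genes = seq_len(min(15, n_genes))),
      list(cliques = seq(min(7, n_sim_cliques), min(10, n_sim_cliques)),
           genes = seq(min(31, n_genes), min(50, n_genes))))
  cfg <- list(seed = seed, n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), n_tfs = as.integer(n_tfs),
              n_loops = as.integer(n_loops), fraction_ep = fraction_ep,
              motif_width = as.integer(motif_width),
              anchor_width = as.integer(anchor_width),
              peak_width = as.integer(peak_width),
              planted_levels = as.integer(planted_levels),
              planted_communities = planted_communities,
              planted_cliques = planted_cliques,
              colocal_pairs = colocal_pairs, colocal_share = colocal_share,
              downward_fraction = downward_fraction,
              n_sim_cliques = as.integer(n_sim_cliques),
              n_genes = as.integer(n_genes),
              planted_biclusters = planted_biclusters,
              expression_noise_sd = expression_noise_sd,
              samples_per_cell = as.integer(samples_per_cell),
              cell_lines = cell_lines, tfs = tfs)
  counts <- c(cfg$n_chroms, cfg$chrom_len, cfg$n_tfs, cfg$n_loops,
              cfg$motif_width, cfg$n_sim_cliques, cfg$n_genes,
              cfg$samples_per_cell)
  if (any(counts < 1)) stopf("all fixture counts must be >= 1")
  if (cfg$fraction_ep < 0 || cfg$fraction_ep > 1)
    stopf("fraction_ep must lie in [0, 1]")
  if (sum(cfg$planted_levels) != cfg$n_tfs)
    stopf("planted_levels must sum to n_tfs")
  for (cl in cfg$planted_cliques) {
    inside <- vapply(cfg$planted_communities, function(cm)
      all(cl %in% cm), logical(1))
    if (!any(inside))
      stopf("planted clique {%s} is not inside any planted community",
            paste(cl, collapse = ","))
  }
  for (b in cfg$planted_biclusters) {
    if (max(b$cliques) > cfg$n_sim_cliques || max(b$genes) > cfg$n_genes)
      stopf("planted bicluster indices exceed matrix shape")
  }
  structure(cfg, class = "fixture_config")
}

.randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.distinctConsensus <- function(n, width) {
  out <- character(0)
  while (length(out) < n) {
    s <- .randomDNA(width)
    if (!s %in% out) out <- c(out, s)
  }
  out
}

#' Simulate bare TF peak sets
#'
#' Fast generator of uniformly placed, per-chromosome-sorted peak sets,
#' suitable for exercising the 1D similarity matrix at scale.
#'
#' @param nTFs number of peak sets.
#' @param nPeaks peaks per set.
#' @param chromLen chromosome length.
#' @param nChroms number of chromosomes.
#' @param peakWidth peak width in bases.
#' @param seed RNG seed.
#' @return named list of `GRanges`.
#' @export
simulatePeakSets <- function(nTFs, nPeaks = 20L, chromLen = 1000000L,
                             nChroms = 1L, peakWidth = 200L, seed = 1L) {
  withSeed(seed, {
    setNames(lapply(seq_len(nTFs), function(i) {
      chrom <- paste0("chr", sample.int(nChroms, nPeaks, replace = TRUE))
      s <- sample.int(chromLen - peakWidth, nPeaks)
      BiocGenerics::sort(GRanges(chrom, IRanges(s, width = peakWidth)))
    }), sprintf("TF%03d", seq_len(nTFs)))
  })
}

# Lay out loops on the genome: round-robin over chromosomes, fixed slot per
# loop so anchors never collide.
.loopLayout <- function(cfg, nLoops) {
  slot <- 12000L
  cap_per_chrom <- (cfg$chrom_len - 2000L) %/% slot
  if (cap_per_chrom * cfg$n_chroms < nLoops)
    stopf("genome too small for %d loops (capacity %d)", nLoops,
          cap_per_chrom * cfg$n_chroms)
  chrom <- paste0("chr", ((seq_len(nLoops) - 1L) %% cfg$n_chroms) + 1L)
  idx_on_chrom <- ((seq_len(nLoops) - 1L) %/% cfg$n_chroms)
  base <- 1000L + idx_on_chrom * slot
  gap <- sample(5000:9000, nLoops, replace = TRUE)
  aw <- cfg$anchor_width
  data.frame(chrom = chrom, startA = base, endA = base + aw - 1L,
             startB = base + gap, endB = base + gap + aw - 1L)
}

#' Simulate a regulatory landscape with planted truth
#'
#' Generates, per cell line: a genome, chromatin-state segments, a loop list
#' whose enhancer-promoter loops have one anchor in an "Enhancer" segment and
#' one in a "Promoter" segment, a TSS annotation with one gene per EP loop,
#' and implanted consensus motifs for the TFs planted in each anchor.
#' Shared across cell lines: the PWM collection and the TF ChIP peak sets
#' (anchored peaks plus background peaks, with the configured co-localizing
#' pairs mirrored within 50 bp).
#'
#' @param cfg a [fixtureConfig()].
#' @return list with `pwms`, `consensus`, `peaksets`, `cells` (per cell:
#'   `genome`, `states`, `loops`, `tss`, `present_enh`, `present_prom`) and
#'   `truth`.
#' @export
simulateRegulatoryLandscape <- function(cfg = fixtureConfig()) {
  tfs <- cfg$tfs
  consensus <- withSeed(childSeed(cfg$seed, 1),
                        .distinctConsensus(cfg$n_tfs, cfg$motif_width))
  names(consensus) <- tfs
  pwms <- lapply(tfs, function(tf) {
    m <- matrix(0.03, cfg$motif_width, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    bases <- strsplit(consensus[[tf]], "")[[1]]
    m[cbind(seq_len(cfg$motif_width), match(bases, c("A", "C", "G", "T")))] <- 0.91
    list(motif_id = paste0("M_", tf), tf_name = tf, matrix = m)
  })
  names(pwms) <- paste0("M_", tfs)
  cells <- list()
  peak_rows <- list()  # collected from the first cell line
  for (ci in seq_along(cfg$cell_lines)) {
    cell <- cfg$cell_lines[ci]
    bundle <- withSeed(childSeed(cfg$seed, 10 + ci), {
      n_ep <- round(cfg$fraction_ep * cfg$n_loops)
      layout <- .loopLayout(cfg, cfg$n_loops)
      is_ep <- seq_len(cfg$n_loops) <= n_ep
      genome_chars <- lapply(seq_len(cfg$n_chroms), function(c)
        strsplit(.randomDNA(cfg$chrom_len), "")[[1]])
      names(genome_chars) <- paste0("chr", seq_len(cfg$n_chroms))
      # TF presence per EP anchor (each TF in some but never all anchors)
      pres_enh <- matrix(runif(n_ep * cfg$n_tfs) < 0.4, n_ep, cfg$n_tfs,
                         dimnames = list(NULL, tfs))
      pres_prom <- matrix(runif(n_ep * cfg$n_tfs) < 0.4, n_ep, cfg$n_tfs,
                          dimnames = list(NULL, tfs))
      for (t in seq_len(cfg$n_tfs)) {
        if (!any(pres_enh[, t])) pres_enh[sample.int(n_ep, 1L), t] <- TRUE
        if (!any(pres_prom[, t])) pres_prom[sample.int(n_ep, 1L), t] <- TRUE
        if (all(pres_prom[, t])) pres_prom[sample.int(n_ep, 1L), t] <- FALSE
      }
      implant <- function(chrom, anchor_start, present) {
        # place each present TF's consensus at a distinct offset; returns
        # implant site starts per TF
        sites <- setNames(rep(NA_integer_, cfg$n_tfs), tfs)
        slots <- which(present)
        for (k in seq_along(slots)) {
          pos <- anchor_start + 10L + (k - 1L) * (cfg$motif_width + 6L)
          bases <- strsplit(consensus[[slots[k]]], "")[[1]]
          genome_chars[[chrom]][pos:(pos + cfg$motif_width - 1L)] <<- bases
          sites[slots[k]] <- pos
        }
        sites
      }
      sitesA <- matrix(NA_integer_, n_ep, cfg$n_tfs, dimnames = list(NULL, tfs))
      sitesB <- matrix(NA_integer_, n_ep, cfg$n_tfs, dimnames = list(NULL, tfs))
      for (i in seq_len(n_ep)) {
        sitesA[i, ] <- implant(layout$chrom[i], layout$startA[i], pres_enh[i, ])
        sitesB[i, ] <- implant(layout$chrom[i], layout$startB[i], pres_prom[i, ])
      }
      genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                                "", collapse = ""))
      # chromatin states: EP anchors labelled, other loops quiescent, plus
      # filler quiescent segments
      stchrom <- c(layout$chrom, layout$chrom)
      ststart <- c(layout$startA - 50L, layout$startB - 50L)
      stend <- c(layout$endA + 50L, layout$endB + 50L)
      stlab <- c(ifelse(is_ep, "Enhancer", "Quiescent"),
                 ifelse(is_ep, "Promoter", "Quiescent"))
      states <- BiocGenerics::sort(GRanges(stchrom,
                                           IRanges(pmax(1L, ststart), stend),
                                           label = stlab))
      tags <- sample(6:30, cfg$n_loops, replace = TRUE)
      loops <- LoopSet(cell,
                       GRanges(layout$chrom, IRanges(layout$startA, layout$endA)),
                       GRanges(layout$chrom, IRanges(layout$startB, layout$endB)),
                       tags)
      tss <- GRanges(layout$chrom[is_ep],
                     IRanges((layout$startB[is_ep] + layout$endB[is_ep]) %/% 2,
                             width = 1L),
                     label = sprintf("gene%03d", seq_len(n_ep)))
      list(genome = genome, states = states, loops = loops, tss = tss,
           present_enh = pres_enh, present_prom = pres_prom,
           sitesA = sitesA, sitesB = sitesB, layout = layout, is_ep = is_ep)
    })
    cells[[cell]] <- bundle
  }
  # TF peak sets (cell-independent, like a peak compendium): peaks at the
  # first cell's implant sites plus random background peaks
  first <- cells[[1]]
  peaksets <- withSeed(childSeed(cfg$seed, 99), {
    hw <- cfg$peak_width %/% 2
    ps <- lapply(tfs, function(tf) {
      sa <- first$sitesA[, tf]; sb <- first$sitesB[, tf]
      chromA <- first$layout$chrom[seq_along(sa)]
      sites <- data.frame(
        chrom = c(chromA[!is.na(sa)], chromA[!is.na(sb)]),
        mid = c(sa[!is.na(sa)], sb[!is.na(sb)]) + cfg$motif_width %/% 2)
      nbg <- 10L
      bg <- data.frame(
        chrom = paste0("chr", sample.int(cfg$n_chroms, nbg, replace = TRUE)),
        mid = sample.int(cfg$chrom_len - cfg$peak_width, nbg) + hw)
      all <- rbind(sites, bg)
      BiocGenerics::sort(GRanges(all$chrom,
                                 IRanges(pmax(1L, all$mid - hw),
                                         width = cfg$peak_width)))
    })
    names(ps) <- tfs
    for (pr in cfg$colocal_pairs) {
      a <- ps[[pr[1]]]
      keep <- sort(sample.int(length(a), ceiling(cfg$colocal_share * length(a))))
      shift <- sample(-50:50, length(keep), replace = TRUE)
      mirrored <- GenomicRanges::shift(a[keep], shift)
      ps[[pr[2]]] <- BiocGenerics::sort(c(ps[[pr[2]]], mirrored))
    }
    ps
  })
  truth <- list(consensus = as.list(consensus),
                colocal_pairs = cfg$colocal_pairs,
                present_enh = lapply(cells, `[[`, "present_enh"),
                present_prom = lapply(cells, `[[`, "present_prom"))
  list(pwms = pwms, consensus = consensus, peaksets = peaksets,
       cells = cells, truth = truth, config = cfg)
}

#' Simulate network-level ground truth
#'
#' Generates a PPI edge table whose surviving (STRING > 400 and BioGRID
#' experimental) edges form the planted communities with the planted cliques
#' as maximal cliques; a directed influence list with the configured
#' fraction of edges pointing from lower- to higher-numbered planted levels;
#' an expression table with one correlated block per planted clique; and a
#' binary clique-by-gene matrix carrying the planted biclusters.
#'
#' @param cfg a [fixtureConfig()].
#' @return list with `ppi_table` (writable schema), `ppi` (parsed form),
#'   `directed`, `expression`, `clique_gene` and `truth`.
#' @export
simulateNetworkTruth <- function(cfg = fixtureConfig()) {
  tfs <- cfg$tfs
  n <- cfg$n_tfs
  levels <- rep.int(seq_along(cfg$planted_levels), cfg$planted_levels)
  names(levels) <- tfs
  withSeed(childSeed(cfg$seed, 7), {
    # --- PPI with planted communities and maximal cliques ---
    adj <- matrix(FALSE, n, n, dimnames = list(tfs, tfs))
    for (cm in cfg$planted_communities) {
      idx <- match(cm, tfs)
      for (i in idx) for (j in idx) if (i < j && runif(1) < 0.55)
        adj[i, j] <- adj[j, i] <- TRUE
    }
    for (cl in cfg$planted_cliques) {
      idx <- match(cl, tfs)
      adj[idx, idx] <- TRUE
    }
    diag(adj) <- FALSE
    # keep planted cliques maximal: break any common outside neighbour
    for (cl in cfg$planted_cliques) {
      idx <- match(cl, tfs)
      repeat {
        common <- which(apply(adj[idx, , drop = FALSE], 2, all))
        common <- setdiff(common, idx)
        if (!length(common)) break
        adj[common[1], idx[1]] <- adj[idx[1], common[1]] <- FALSE
      }
    }
    ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
    good <- data.frame(a = tfs[ij[, 1]], b = tfs[ij[, 2]])
    # noise edges that must not survive the dual-evidence filter
    noise <- data.frame(
      a = sample(tfs, 8, replace = TRUE), b = sample(tfs, 8, replace = TRUE))
    noise <- noise[noise$a != noise$b, ]
    ppi_table <- rbind(
      data.frame(protein_a = good$a, protein_b = good$b, source = "string_db",
                 score_or_evidence = as.character(sample(450:900, nrow(good),
                                                         replace = TRUE))),
      data.frame(protein_a = good$a, protein_b = good$b, source = "biogrid",
                 score_or_evidence = "experimental"),
      data.frame(protein_a = noise$a, protein_b = noise$b,
                 source = "string_db",
                 score_or_evidence = as.character(sample(100:400, nrow(noise),
                                                         replace = TRUE))))
    # --- directed influences consistent with planted levels ---
    cand <- which(outer(levels, levels, "<"), arr.ind = TRUE)
    pick <- cand[runif(nrow(cand)) < 0.9, , drop = FALSE]
    # every TF must carry at least one influence
    missing <- setdiff(seq_len(n), unique(c(pick)))
    for (v in missing) {
      partner <- sample(setdiff(which(levels != levels[v]), v), 1L)
      pick <- rbind(pick, if (levels[v] < levels[partner]) c(v, partner)
                    else c(partner, v))
    }
    # upward noise edges: flip picked edges spanning >= 2 levels and ensure a
    # conflicting downward path through an intermediate level survives, so
    # the planted assignment remains the score optimum rather than a finer
    # hierarchy explaining the noise away
    n_up <- floor((1 - cfg$downward_fraction) * nrow(pick))
    span2 <- which(levels[pick[, 2]] - levels[pick[, 1]] >= 2)
    flip <- if (n_up > 0 && length(span2))
      sample(span2, min(n_up, length(span2))) else integer(0)
    hasEdge <- function(a, b) any(pick[, 1] == a & pick[, 2] == b)
    for (f in flip) {
      a <- pick[f, 1]; b <- pick[f, 2]
      mids <- which(levels > levels[a] & levels < levels[b])
      mid <- mids[sample.int(length(mids), 1L)]
      if (!hasEdge(a, mid)) pick <- rbind(pick, c(a, mid))
      if (!hasEdge(mid, b)) pick <- rbind(pick, c(mid, b))
    }
    directed <- data.frame(
      from = ifelse(seq_len(nrow(pick)) %in% flip, tfs[pick[, 2]],
                    tfs[pick[, 1]]),
      to = ifelse(seq_len(nrow(pick)) %in% flip, tfs[pick[, 1]],
                  tfs[pick[, 2]]),
      stringsAsFactors = FALSE)
    # --- expression with correlated within-clique blocks ---
    n_samp <- cfg$samples_per_cell * length(cfg$cell_lines)
    expr <- matrix(NA_real_, n, n_samp,
                   dimnames = list(tfs, paste0(rep(cfg$cell_lines,
                                                   each = cfg$samples_per_cell),
                                               "_r",
                                               rep(seq_len(cfg$samples_per_cell),
                                                   length(cfg$cell_lines)))))
    assigned <- rep(FALSE, n)
    for (cl in cfg$planted_cliques) {
      latent <- rnorm(n_samp)
      for (tf in cl) {
        expr[tf, ] <- latent + cfg$expression_noise_sd * rnorm(n_samp)
        assigned[match(tf, tfs)] <- TRUE
      }
    }
    for (i in which(!assigned)) expr[i, ] <- rnorm(n_samp)
    # --- clique-by-gene matrix with planted biclusters ---
    M <- matrix(0L, cfg$n_sim_cliques, cfg$n_genes,
                dimnames = list(sprintf("clique%02d", seq_len(cfg$n_sim_cliques)),
                                sprintf("gene%03d", seq_len(cfg$n_genes))))
    for (b in cfg$planted_biclusters) M[b$cliques, b$genes] <- 1L
    list(ppi_table = ppi_table,
         directed = directed,
         expression = expr,
         clique_gene = M,
         truth = list(levels = as.list(levels),
                      communities = cfg$planted_communities,
                      cliques = cfg$planted_cliques,
                      biclusters = cfg$planted_biclusters))
  })
}

#' Write a fixture bundle to disk
#'
#' Emits every input format the pipeline reads (FASTA, BED, BEDPE, MEME,
#' TSV) plus `truth/*.json` with the planted ground truth.
#'
#' @param landscape result of [simulateRegulatoryLandscape()].
#' @param network result of [simulateNetworkTruth()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(landscape, network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  writePWMs(landscape$pwms, file.path(dir, "motifs.meme"))
  for (tf in names(landscape$peaksets))
    writeIntervals(landscape$peaksets[[tf]],
                   file.path(dir, "peaks", paste0(tf, ".bed")))
  for (cell in names(landscape$cells)) {
    b <- landscape$cells[[cell]]
    Biostrings::writeXStringSet(b$genome,
                                file.path(dir, paste0("genome_", cell, ".fa")))
    writeIntervals(b$states, file.path(dir, paste0("states_", cell, ".bed")))
    writeLoops(b$loops, file.path(dir, paste0("loops_", cell, ".bedpe")))
    writeIntervals(b$tss, file.path(dir, paste0("tss_", cell, ".bed")))
  }
  write.table(network$ppi_table, file.path(dir, "ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeExpression(network$expression, file.path(dir, "expression.tsv"))
  write.table(data.frame(from = network$directed$from,
                         to = network$directed$to),
              file.path(dir, "directed_influences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(clique = rownames(network$clique_gene),
                         network$clique_gene, check.names = FALSE),
              file.path(dir, "clique_gene.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeJSONArtifact(landscape$truth, file.path(dir, "truth", "landscape.json"))
  writeJSONArtifact(network$truth, file.path(dir, "truth", "network.json"))
  invisible(dir)
}
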