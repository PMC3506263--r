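#' Assemble a full pipeline configuration
#'
#' Builds a [simConfig()] wired the way the analysis expects: both
#' parents are wild-type libraries drawing from their own genome with
#' Zipf-profile cluster weights (parent B reversed), and the hybrid
#' draws from both genomes. With `mutant_like = TRUE` (the regime this
#' analysis diagnoses) the hybrid library is reshaped by
#' [mutantLikeParams()] — piRNA share 0.6 -> 0.2, pairing probability
#' scaled by 0.3, and cluster weights set to the parental average times
#' planted multipliers (defaults: 5 clusters x2.5, 5 x1, 5 x0.3, giving
#' over/additive/under-dominant thirds) — and 4-fold mRNA derepression
#' is planted on `n_derepressed` families.
#'
#' @param seed Integer seed.
#' @param n_reads Reads per small-RNA library.
#' @param n_families Number of TE families.
#' @param mutant_like Apply the mutant-like hybrid preset.
#' @param n_derepressed Families given planted log2FC = 2 in the hybrid
#'   mRNA when `mutant_like`.
#' @param cluster_multipliers Multipliers on the parental-average
#'   cluster weights for the mutant-like hybrid.
#' @param ... Further arguments passed to [simConfig()].
#' @return A `simConfig`.
#' @export
pipelineConfig <- function(seed = 1L, n_reads = 15000L, n_families = 20L,
                           mutant_like = TRUE, n_derepressed = 5L,
                           cluster_multipliers = rep(c(2.5, 1, 0.3), each = 5),
                           ...) {
  extra <- list(...)
  n_clusters <- if (!is.null(extra$n_clusters)) extra$n_clusters else 15L
  wA <- defaultClusterWeights(n_clusters, 0.35, reverse = FALSE)
  wB <- defaultClusterWeights(n_clusters, 0.35, reverse = TRUE)
  # per-family interspecific piRNA-pool differences (log2-normal on parent
  # A relative to parent B), drawn deterministically from the run seed
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((seed %% 1000003L) * 101L + 997L)
  mA <- stats::setNames(2^stats::rnorm(n_families, 0, 1),
                        sprintf("TE%02d", seq_len(n_families)))
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  pA <- libraryParams(n_reads = n_reads, genome = "A", cluster_weights = wA,
                      abundance_multiplier = mA)
  pB <- libraryParams(n_reads = n_reads, genome = "B", cluster_weights = wB)
  pH <- libraryParams(n_reads = n_reads, genome = "both",
                      cluster_weights = (wA + wB) / 2,
                      abundance_multiplier = (mA + 1) / 2)
  if (mutant_like)
    pH <- mutantLikeParams(pH, cluster_multipliers =
                                rep_len(cluster_multipliers, n_clusters))
  planted <- if (mutant_like && n_derepressed > 0)
    stats::setNames(rep(2, n_derepressed),
                    sprintf("TE%02d", seq_len(n_derepressed))) else numeric()
  do.call(simConfig, c(list(seed = seed, n_families = n_families,
                            smallrna = list(parentA = pA, parentB = pB,
                                            hybrid = pH),
                            mrna = list(planted_log2fc = planted)),
                       extra))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipelineConfig()] / [simConfig()] arguments;
#' a `smallrna:` section of per-library parameter lists overrides the
#' assembled defaults.
#'
#' @param path YAML file path.
#' @return A `simConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sm <- y$smallrna
  y$smallrna <- NULL
  cfg <- do.call(pipelineConfig, y)
  if (!is.null(sm)) {
    for (lib in names(sm)) {
      base <- cfg$smallrna[[lib]]
      if (is.null(base)) base <- libraryParams()
      base[names(sm[[lib]])] <- sm[[lib]]
      cfg$smallrna[[lib]] <- base
    }
  }
  cfg
}

.stageLog <- function(logFile, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> map -> profile -> ping-pong -> expression -> clusters ->
#' statistics, as one seeded, reproducible run. Every stage writes its
#' table under `outDir`; a JSON manifest records the configuration,
#' seed, package version and MD5 digest of every output, and the
#' returned summary holds the derepressed families, per-library piRNA
#' share, filtered ping-pong table, cluster inheritance classes, and the
#' category-level derepression statistics. Any stage failure aborts
#' with the stage name after writing the partial manifest.
#'
#' @param config A `simConfig`, e.g. from [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param maxMismatch Mismatch ceiling for consensus/genome mapping.
#' @param scheme Cluster counting scheme for the headline inheritance
#'   classification (all three are written).
#' @param excludeClusterUnique Drop reads mapping uniquely inside
#'   clusters before family abundance tallies.
#' @return Invisibly, a list with `summary`, `manifest`, `outDir`.
#' @export
runPipeline <- function(config, outDir, maxMismatch = 0L,
                        scheme = "unique", excludeClusterUnique = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "pipeline.log")
  cat("", file = logFile)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("piRNAhybrids")),
                   config = .configAsList(config),
                   stages = list())
  paths <- character()
  summary <- list()
  stage <- "init"
  writeManifest <- function() {
    manifest$outputs <- lapply(stats::setNames(paths, basename(paths)),
                               function(p) unname(tools::md5sum(p)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  run <- function(name, expr) {
    stage <<- name
    .stageLog(logFile, name, "start")
    out <- tryCatch(expr, error = function(e) {
      writeManifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- format(Sys.time())
    .stageLog(logFile, name, "done")
    out
  }
  emitTsv <- function(x, file) {
    p <- file.path(outDir, file)
    writeTsvTable(x, p)
    paths <<- c(paths, p)
    p
  }

  families <- run("te_library", simulateTELibrary(config))
  fa <- file.path(outDir, "te_consensus.fa")
  Biostrings::writeXStringSet(consensusSeqs(families), fa)
  paths <- c(paths, fa)
  emitTsv(cbind(family = familyNames(families),
                as.data.frame(familyInfo(families))), "te_metadata.tsv")

  genomes <- run("genomes", simulateParentalGenomes(config, families))
  for (g in c("parentA", "parentB")) {
    gp <- file.path(outDir, paste0(g, ".fa"))
    Biostrings::writeXStringSet(genomeSeqs(genomes[[g]]), gp)
    paths <- c(paths, gp)
    if (length(teInsertions(genomes[[g]])))
      paths <- c(paths, writeBedIntervals(teInsertions(genomes[[g]]),
                  file.path(outDir, paste0(g, "_insertions.bed"))))
  }
  if (length(piClusters(genomes$parentA)))
    paths <- c(paths, writeBedIntervals(piClusters(genomes$parentA),
                file.path(outDir, "clusters.bed")))
  emitTsv(genomes$diagnosticSites, "diagnostic_sites.tsv")

  libs <- names(config$smallrna)
  sims <- run("small_rna", {
    out <- list()
    for (lib in libs) {
      s <- simulateSmallRNALibrary(config, families, genomes, lib)
      writeSmallRNAFastq(s$reads, file.path(outDir, paste0(lib, ".fastq")))
      paths <- c(paths, file.path(outDir, paste0(lib, ".fastq")))
      emitTsv(s$truth, paste0(lib, "_truth.tsv"))
      out[[lib]] <- s
    }
    out
  })

  consIdx <- buildConsensusIndex(families, maxMismatch)
  genomeIdxA <- buildConsensusIndex(genomes$parentA, 0L)
  consHits <- run("map_consensus", lapply(sims, function(s)
    assignReads(s$reads, consIdx)))
  genomeHitsA <- run("map_genome", lapply(sims, function(s)
    assignReads(s$reads, genomeIdxA)))

  profile <- run("profile", {
    sizes <- lapply(libs, function(lib)
      sizeDistribution(sims[[lib]]$reads, libraryId = lib))
    names(sizes) <- libs
    emitTsv(do.call(rbind, lapply(sizes, function(s)
      data.frame(library_id = s$library_id, length = names(s$counts),
                 count = as.numeric(s$counts),
                 fraction = as.numeric(s$fractions)))),
      "size_distribution.tsv")
    abun <- lapply(libs, function(lib) {
      excl <- if (excludeClusterUnique)
        clusterUniqueSeqs(genomeHitsA[[lib]], genomes$parentA) else NULL
      familyAbundance(consHits[[lib]], nrow(sims[[lib]]$reads),
                      libraryId = lib, excludeSeqs = excl)
    })
    names(abun) <- libs
    emitTsv(do.call(rbind, abun), "family_abundance.tsv")
    diffAb <- differentialAbundance(abun$parentA, abun$parentB,
                                    librarySizeA = nrow(sims$parentA$reads),
                                    librarySizeB = nrow(sims$parentB$reads))
    emitTsv(diffAb, "differential_abundance.tsv")
    list(sizes = sizes, abundance = abun, differential = diffAb)
  })

  pp <- run("pingpong", {
    tab <- pingPongTable(consHits, families = familyNames(families))
    emitTsv(tab, "pingpong.tsv")
    tab
  })

  expr <- run("expression", {
    m <- simulateMRNACounts(config, families)
    lens <- stats::setNames(Biostrings::width(consensusSeqs(families)),
                            familyNames(families))
    tab <- callExpressionStatus(m$counts, m$librarySizes, lengths = lens)
    emitTsv(tab, "expression.tsv")
    list(table = tab, truth = m$truth)
  })

  clusters <- run("clusters", {
    allTallies <- list()
    for (sc in c("unique", "weighted", "all")) {
      for (lib in libs) {
        allTallies[[paste(sc, lib)]] <- clusterTally(
          genomeHitsA[[lib]], genomes$parentA, scheme = sc, libraryId = lib)
      }
    }
    emitTsv(do.call(rbind, allTallies), "cluster_tallies.tsv")
    fq <- function(lib) allTallies[[paste(scheme, lib)]]$frequency
    inh <- inheritanceClass(fq("parentA"), fq("parentB"), fq("hybrid"),
                            clusterIds = allTallies[[paste(scheme, "parentA")]]$cluster_id)
    emitTsv(inh, "cluster_inheritance.tsv")
    inh
  })

  statsOut <- run("stats", {
    dtab <- merge(profile$differential[, c("family", "category")],
                  expr$table[, c("family", "status")], by = "family")
    derepressionByCategory(dtab$category, dtab$status == "derepressed")
  })

  summary <- list(
    derepressed_families = expr$table$family[expr$table$status == "derepressed"],
    pirna_share = vapply(profile$sizes, function(s) s$pirna_share, 0),
    pingpong = pp,
    cluster_classes = table(clusters$inheritance, useNA = "ifany"),
    category_stats = statsOut)
  manifest$summary <- list(
    derepressed_families = summary$derepressed_families,
    pirna_share = summary$pirna_share,
    cluster_classes = as.list(table(clusters$inheritance)))
  writeManifest()
  .stageLog(logFile, "pipeline", "complete")
  invisible(list(summary = summary, manifest = manifest, outDir = outDir,
                 details = list(profile = profile, expression = expr,
                                clusters = clusters, sims = sims,
                                consHits = consHits,
                                genomeHitsA = genomeHitsA)))
}

.configAsList <- function(config) {
  cfg <- unclass(config)
  cfg$smallrna <- lapply(cfg$smallrna, unclass)
  cfg
}
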