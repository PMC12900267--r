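#' @include chemspace.R subprofiles.R synthetic.R
NULL

.writeNumericCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

.matrixToCsv <- function(m, path, idCol = "id") {
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  .writeNumericCsv(df, path)
}

#' Validate a workbench run configuration
#'
#' Checks the configuration before any computation: referenced input paths
#' must exist, the seed must be a single integer and the analysis block (if
#' present) must produce a valid \linkS4class{AnalysisConfig}.
#'
#' @param config A named list or a path to a JSON configuration file.
#' @return The normalized configuration list, invisibly usable by
#'   \code{\link{runWorkbench}}.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  for (p in c("compounds", "plate", "cluster_model")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("config path for '", p, "' does not exist: ", config[[p]])
    }
  }
  if (is.null(config$compounds) && is.null(config$plate)) {
    stop("config must reference at least a compound collection or a plate")
  }
  a <- config$analysis
  config$analysisConfig <- analysisConfig(
    thetaZ = if (is.null(a$theta_z)) 3 else a$theta_z,
    activityThreshold = if (is.null(a$activity_threshold)) 5 else a$activity_threshold,
    similarityThreshold = if (is.null(a$similarity_threshold)) 75 else a$similarity_threshold,
    robustScale = if (is.null(a$robust_scale)) 1.4826 else a$robust_scale
  )
  if (is.null(config$umap)) config$umap <- list()
  if (is.null(config$umap$n_neighbors)) config$umap$n_neighbors <- 10L
  if (is.null(config$umap$min_dist)) config$umap$min_dist <- 0.1
  if (is.null(config$pca)) config$pca <- list()
  if (is.null(config$pca$k)) config$pca$k <- 2L
  if (is.null(config$descriptors)) config$descriptors <- defaultDescriptors()
  if (is.null(config$smarts)) config$smarts <- aohiSmarts()
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order, the chemistry stage (canonicalization, descriptor
#' table, QED, nSPS, optional NP-likeness), the chemical-space stage (PCA,
#' UMAP, substructure enrichment, Tanimoto matrix), the profile stage
#' (z-scoring, induction, biosimilarity matrix) and the cluster stage
#' (assignment against a cluster model, joint profile UMAP). Every table is
#' written as CSV into \code{output_dir}; a JSON manifest records the
#' package version, seed, thresholds and md5 digests of all inputs and
#' outputs. Runs are deterministic: the same configuration produces
#' byte-identical outputs. If a stage fails, its partially written outputs
#' are renamed with a \code{.partial} suffix and the error names the stage.
#'
#' @param config A named list or path to a JSON configuration file; see
#'   \code{\link{validateRunConfig}} for the recognized fields.
#' @return Invisibly, the manifest list.
#' @export
runWorkbench <- function(config) {
  cfg <- validateRunConfig(config)
  outDir <- cfg$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "PNPWorkbench",
    version = as.character(utils::packageVersion("PNPWorkbench")),
    seed = cfg$seed,
    thresholds = list(
      theta_z = cfg$analysisConfig@thetaZ,
      activity_threshold = cfg$analysisConfig@activityThreshold,
      similarity_threshold = cfg$analysisConfig@similarityThreshold,
      robust_scale = cfg$analysisConfig@robustScale
    ),
    inputs = list(), outputs = list()
  )
  for (p in c("compounds", "plate", "cluster_model")) {
    if (!is.null(cfg[[p]])) {
      manifest$inputs[[p]] <- list(
        path = cfg[[p]], md5 = unname(tools::md5sum(cfg[[p]]))
      )
    }
  }
  stageFiles <- character()
  out <- function(name) {
    f <- file.path(outDir, name)
    stageFiles <<- c(stageFiles, f)
    f
  }
  runStage <- function(name, fn) {
    stageFiles <<- character()
    tryCatch(fn(), error = function(e) {
      for (f in stageFiles) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    for (f in stageFiles) {
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
    }
  }

  state <- new.env(parent = emptyenv())
  if (!is.null(cfg$compounds)) {
    runStage("chem", function() {
      cs <- readCompounds(cfg$compounds, format = "csv",
                          structureCol = cfg$structure_col %||% "smiles")
      state$compounds <- cs
      dt <- descriptorTable(cs, cfg$descriptors)
      state$descriptors <- dt
      .writeNumericCsv(
        data.frame(compound_id = rownames(dt), dt, check.names = FALSE),
        out("descriptors.csv")
      )
      scores <- data.frame(
        compound_id = compoundIds(cs),
        class_label = unname(classLabels(cs)),
        qed = unname(qed(cs)),
        nsps = unname(nsps(cs)),
        stringsAsFactors = FALSE
      )
      np <- cfg$np_likeness
      if (!is.null(np$np_label) && !is.null(np$syn_label)) {
        labs <- classLabels(cs)
        tbl <- trainNPLikeness(
          cs[labs == np$np_label], cs[labs == np$syn_label]
        )
        scores$np_likeness <- unname(npLikeness(cs, tbl))
      }
      .writeNumericCsv(scores, out("compound_scores.csv"))
    })
    runStage("space", function() {
      dt <- state$descriptors
      pca <- pcaEmbed(dt, k = cfg$pca$k)
      co <- embeddingCoords(pca)
      .writeNumericCsv(
        data.frame(compound_id = rownames(co), co, check.names = FALSE),
        out("pca.csv")
      )
      um <- umapEmbed(
        dt, nNeighbors = cfg$umap$n_neighbors, seed = cfg$seed,
        normalize = TRUE, minDist = cfg$umap$min_dist
      )
      cu <- embeddingCoords(um)
      .writeNumericCsv(
        data.frame(compound_id = rownames(cu), cu, check.names = FALSE),
        out("umap.csv")
      )
      .writeNumericCsv(enrichment(state$compounds, cfg$smarts), out("enrichment.csv"))
      .matrixToCsv(tanimotoMatrix(state$compounds), out("tanimoto.csv"),
                   idCol = "compound_id")
    })
  }
  if (!is.null(cfg$plate)) {
    runStage("cpa", function() {
      plate <- readFeatureTable(cfg$plate)
      prof <- zscoreProfiles(plate, cfg$analysisConfig)
      state$profiles <- prof
      writeProfiles(prof, out("profiles.csv"))
      .matrixToCsv(biosimMatrix(prof, cfg$analysisConfig), out("biosim.csv"),
                   idCol = "profile_id")
    })
    runStage("cluster", function() {
      prof <- state$profiles
      if (!is.null(cfg$cluster_model)) {
        model <- readClusterModel(cfg$cluster_model)
        .writeNumericCsv(
          assignClusters(prof, model, cfg$analysisConfig),
          out("cluster_assignments.csv")
        )
      }
      active <- prof[, isActive(prof)]
      if (ncol(active) > cfg$umap$n_neighbors) {
        .writeNumericCsv(
          profileUMAP(active, nNeighbors = cfg$umap$n_neighbors, seed = cfg$seed),
          out("profile_umap.csv")
        )
      }
    })
  }
  manifestPath <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a self-contained demo configuration and its inputs
#'
#' Generates a toy compound CSV, a synthetic plate with planted clusters, a
#' cluster model extracted from the plate's own reference profiles, and a
#' run configuration referencing them — everything \code{\link{runWorkbench}}
#' needs for an end-to-end run.
#'
#' @param dir Directory to populate.
#' @param seed Integer seed.
#' @return The path of the written configuration file.
#' @export
writeDemoConfig <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- genToyCompoundClasses(seed)
  compoundsCsv <- file.path(dir, "compounds.csv")
  writeCompounds(cs, compoundsCsv)
  spec <- syntheticPlateSpec(seed = seed, nPerCluster = 4, nInactive = 2)
  gen <- genPlate(spec)
  plateCsv <- file.path(dir, "plate.csv")
  writeFeatureTable(gen$plate, plateCsv)
  prof <- zscoreProfiles(gen$plate)
  modelPath <- file.path(dir, "cluster_model.json")
  labels <- gen$truth$cluster_labels[colData(prof)$compound_id]
  topConc <- max(spec$concentrations)
  subs <- lapply(sort(unique(stats::na.omit(labels))), function(cl) {
    sel <- !is.na(labels) & labels == cl &
      colData(prof)$concentration_um == topConc
    extractSubprofile(prof[, sel], name = cl)
  })
  writeClusterModel(clusterModel(subs), modelPath)
  cfg <- list(
    seed = seed,
    output_dir = file.path(dir, "results"),
    compounds = compoundsCsv,
    plate = plateCsv,
    cluster_model = modelPath,
    np_likeness = list(np_label = "np_like", syn_label = "drug_like"),
    analysis = list(
      theta_z = 3, activity_threshold = 5,
      similarity_threshold = 75, robust_scale = 1.4826
    )
  )
  cfgPath <- file.path(dir, "run.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA)
  cfgPath
}
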