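#' Read / write an ROI time-series file
#'
#' Tab-separated text with a header row of ROI identifiers and one row per
#' time point. Parsing is strict: ragged rows and non-numeric cells raise
#' errors naming the offending line or column.
#'
#' @param path file path.
#' @return numeric matrix (time points x ROIs) with ROI column names.
#' @export
readTimeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "numeric")
  m <- as.matrix(df)
  if (anyNA(m)) stop("non-numeric or missing cells in ", path)
  m
}

#' @rdname readTimeseries
#' @param ts numeric matrix with ROI column names.
#' @export
writeTimeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read / write an atlas label table
#'
#' Tab-separated table with columns `roi_id` and `network`; ROI order in
#' the file fixes the matrix row/column order.
#'
#' @param path file path.
#' @return A [NetworkPartition-class].
#' @export
readPartition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("roi_id", "network") %in% names(df)))
    stop("partition table must have roi_id and network columns")
  if (anyDuplicated(df$roi_id))
    stop("duplicate roi_id: ",
         paste(unique(df$roi_id[duplicated(df$roi_id)]), collapse = ", "))
  nets <- factor(df$network, levels = unique(df$network))
  new("NetworkPartition", roiIds = as.character(df$roi_id), networks = nets)
}

#' @rdname readPartition
#' @param partition a `NetworkPartition`.
#' @export
writePartition <- function(partition, path) {
  utils::write.table(data.frame(roi_id = roiIds(partition),
                                network = as.character(networkOf(partition))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated table with at least subject_id, group, age and sex columns.
#' Rows missing sex (or age) are rejected with a warning, since they cannot
#' enter the confound model.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotype <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- is.na(df$sex) | is.na(df$age)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing age/sex rejected")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Write a synthetic healthy cohort to disk
#'
#' One TSV per episode, plus the atlas label table, a phenotype stub and a
#' JSON manifest listing (subject, episode, condition, path) and the
#' generating seed.
#'
#' @param cohort output of [genHealthyCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(cohort$episodes, function(e) {
    f <- sprintf("%s_%s.tsv", e$subject, e$episode)
    writeTimeseries(e$ts, file.path(dir, f))
    list(subject = e$subject, episode = e$episode, condition = e$condition,
         path = f)
  })
  writePartition(cohort$partition, file.path(dir, "atlas.tsv"))
  manifest <- list(n_rois = nRois(cohort$partition), atlas = "atlas.tsv",
                   seed = cohort$config$seed, records = recs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' Load a cohort written by [writeCohort()]
#'
#' Validates that every referenced file exists, that (subject, episode) is
#' unique and that the column counts match the manifest's `n_rois`.
#'
#' @param dir directory containing manifest.json.
#' @return list with `episodes` and `partition` in [genHealthyCohort()]
#'   layout.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  partition <- readPartition(file.path(dir, manifest$atlas))
  recs <- manifest$records
  if (anyDuplicated(paste(recs$subject, recs$episode)))
    stop("duplicate (subject, episode) in manifest")
  episodes <- lapply(seq_len(nrow(recs)), function(r) {
    ts <- readTimeseries(file.path(dir, recs$path[r]))
    if (ncol(ts) != manifest$n_rois)
      stop("column count of ", recs$path[r], " does not match n_rois")
    list(subject = recs$subject[r], episode = recs$episode[r],
         condition = recs$condition[r], ts = ts)
  })
  list(episodes = episodes, partition = partition)
}

#' Run the two-stage pipeline end to end on synthetic cohorts
#'
#' Stage 1 (emotion decoding): generate a healthy cohort, compute
#' sliding-window dynamic FC, cluster window vectors into K states, decode
#' the two conditions per state combination with LOSO ReliefF + linear SVM,
#' apply the optimal-model rule, intersect per-fold selections into stable
#' features and derive DEFN network-pair weights. Stage 2 (clinical
#' transfer): generate a clinical cohort whose group effect sits in the
#' generator's designated pairs, run the DEFN-masked nested-CV classifier
#' against the whole-brain baseline with shared folds, compare them by
#' McNemar and map network importance.
#'
#' Stage seeds are derived deterministically from `seed` via [deriveSeed()],
#' so the whole bundle is reproducible from one integer.
#'
#' @param config a [simConfig()] for the healthy cohort.
#' @param nControls,nPatients clinical cohort sizes (default 50/50).
#' @param clinicalEffectSize standardized shift on the planted pairs
#'   (default 1).
#' @param combos state combinations to decode: "all" or a list of integer
#'   vectors (default "all").
#' @param nInit,maxIter clustering settings forwarded to
#'   [clusterStatesTwoStep()].
#' @param nSelected,reliefNeighbors,cost decoder settings.
#' @param outerFolds,innerFolds nested-CV settings.
#' @param useConfounds regress age/sex inside CV folds (default TRUE).
#' @param seed root seed.
#' @param out optional path; when given the bundle (minus large matrices)
#'   is written as JSON.
#' @return list bundle with stage-1 and stage-2 results.
#' @export
runPipeline <- function(config = simConfig(), nControls = 50L,
                        nPatients = 50L, clinicalEffectSize = 1,
                        combos = "all", nInit = 10L, maxIter = 100L,
                        nSelected = 200L, reliefNeighbors = 10L, cost = 1,
                        outerFolds = 10L, innerFolds = 10L,
                        useConfounds = TRUE, seed = 1L, out = NULL) {
  config$seed <- deriveSeed(seed, 1L)
  cohort <- genHealthyCohort(config)
  partition <- cohort$partition

  series <- lapply(cohort$episodes, function(e)
    slidingWindowFC(e$ts, subjectId = e$subject, episodeId = e$episode,
                    condition = e$condition))
  pooled <- poolWindows(series)
  model <- clusterStatesTwoStep(pooled$x, config$K, nInit = nInit,
                                maxIter = maxIter, seed = deriveSeed(seed, 2L),
                                info = pooled$info)
  sfc <- computeStateFC(series, model)

  comboList <- if (identical(combos, "all")) enumerateCombos(config$K) else {
    names(combos) <- vapply(combos, paste, "", collapse = "")
    combos
  }
  decoded <- lapply(comboList, function(cb) {
    tryCatch({
      smp <- buildComboSamples(sfc, cb)
      losoDecode(smp$x, smp$y, smp$subjects, nSelected = nSelected,
                 reliefNeighbors = reliefNeighbors, cost = cost,
                 seed = deriveSeed(seed, 3L))
    }, error = function(e) {
      message(sprintf("combo %s skipped: %s", paste(cb, collapse = ""),
                      conditionMessage(e)))
      NULL
    })
  })
  keep <- !vapply(decoded, is.null, logical(1))
  if (!any(keep)) stop("no state combination could be decoded")
  decoded <- decoded[keep]
  comboList <- comboList[keep]
  means <- vapply(decoded, `[[`, numeric(1), "mean")
  sds <- vapply(decoded, `[[`, numeric(1), "sd")
  opt <- selectOptimalModel(means, sds, tolerance = 0.005)
  optCombo <- comboList[[opt]]
  stable <- stableFeatures(decoded[[opt]]$selected)
  weights <- defnWeights(stable, optCombo, partition)

  effectPairs <- cohort$truth$conditionEffectPairs
  clinical <- genClinicalCohort(nControls, nPatients, partition,
                                effectPairs = effectPairs,
                                effectSize = clinicalEffectSize,
                                seed = deriveSeed(seed, 4L))
  confounds <- if (useConfounds)
    data.frame(age = clinical$phenotype$age, sex = clinical$phenotype$sex)
  masked <- nestedCVClassify(clinical$features, clinical$group, weights,
                             partition, outerFolds = outerFolds,
                             innerFolds = innerFolds, confounds = confounds,
                             cost = cost, seed = deriveSeed(seed, 5L))
  baseline <- baselineClassify(clinical$features, clinical$group,
                               folds = outerFolds, confounds = confounds,
                               cost = cost, seed = deriveSeed(seed, 5L))
  mcn <- mcnemarCompare(masked@predictions$pred, baseline@predictions$pred,
                        clinical$group)
  importance <- networkImportance(masked, partition)

  bundle <- list(
    seed = seed,
    stage1 = list(
      stateFrequencies = stateFrequencies(model),
      comboAccuracy = data.frame(combo = names(comboList), mean = means,
                                 sd = sds, row.names = NULL),
      optimalCombo = names(comboList)[opt],
      nStableFeatures = length(stable),
      weights = weightTable(weights)),
    stage2 = list(
      maskedAccuracy = masked@accuracy, maskedAUC = masked@auc,
      baselineAccuracy = baseline@accuracy, baselineAUC = baseline@auc,
      finalNTop = masked@finalNTop, mcnemar = mcn[c("statistic", "p")],
      leakageTouches = masked@leakageTouches,
      importance = importance),
    objects = list(model = model, weights = weights, masked = masked,
                   baseline = baseline, partition = partition))
  if (!is.null(out)) {
    slim <- bundle[c("seed", "stage1", "stage2")]
    jsonlite::write_json(slim, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  bundle
}
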