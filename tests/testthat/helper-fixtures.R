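# Shared fixtures and independent oracles, built in code at test time.

tinyPartition <- function() genNetworkPartition(c(3L, 2L), c("A", "B"))

sixNetPartition <- function(roisPerNet = 4L, nNet = 6L)
  genNetworkPartition(rep(roisPerNet, nNet), paste0("Net", seq_len(nNet)))

makeStateFCSet <- function(fc, info, p)
  methods::new("StateFCSet", fc = fc, info = info, p = p)

# Paired-condition StateFCSet with a planted happy-minus-sad shift on
# `shiftEdges`: per subject a shared baseline plus independent noise.
pairedStateFCSet <- function(nSubjects, p, shiftEdges = integer(0),
                             shift = 0, noiseSd = 0.1, state = 1L) {
  d <- p * (p - 1L) / 2L
  fc <- NULL; info <- NULL
  for (s in seq_len(nSubjects)) {
    base <- rnorm(d, 0, 0.3)
    happy <- base + rnorm(d, 0, noiseSd)
    happy[shiftEdges] <- happy[shiftEdges] + shift
    sad <- base + rnorm(d, 0, noiseSd)
    fc <- rbind(fc, happy, sad)
    info <- rbind(info,
      data.frame(subject = sprintf("s%02d", s),
                 episode = c("happy_1", "sad_1"),
                 condition = c("happy", "sad"), state = state,
                 nWindows = 10L, stringsAsFactors = FALSE))
  }
  rownames(fc) <- NULL
  makeStateFCSet(fc, info, as.integer(p))
}

# Exhaustive sign-enumeration oracle for the two-sided exact Wilcoxon
# signed-rank p-value (no ties, no zeros), mirroring the two-sided doubling
# convention of the exact distribution.
wilcoxExactOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v > mu) 2 * mean(vs >= v) else 2 * mean(vs <= v)
  min(p, 1)
}

# Brute-force L1 nearest-centroid assignment.
bruteAssign <- function(x, centroids) {
  apply(x, 1L, function(row)
    which.min(apply(centroids, 1L, function(ce) sum(abs(row - ce)))))
}

precisionAtK <- function(ranked, truthPairs) {
  k <- length(truthPairs)
  mean(ranked[seq_len(k)] %in% truthPairs)
}

# Small healthy-cohort configuration used by the recovery tests.
recoveryConfig <- function(seed, ...) {
  simConfig(nSubjects = 8L, episodesPerCondition = 2L, nTimepoints = 150L,
            nRois = 24L, networkSizes = rep(4L, 6L), K = 2L,
            conditionEffect = 0.4, seed = seed, ...)
}

# Stage 1 of the pipeline on a generated cohort: states -> optimal combo ->
# stable features -> DEFN weights.
stageOneWeights <- function(cohort, nInit = 5L, nSelected = 60L, seed = 1L) {
  series <- lapply(cohort$episodes, function(e)
    slidingWindowFC(e$ts, subjectId = e$subject, episodeId = e$episode,
                    condition = e$condition))
  pooled <- poolWindows(series)
  model <- clusterStatesTwoStep(pooled$x, cohort$config$K, nInit = nInit,
                                maxIter = 100L, seed = seed,
                                info = pooled$info)
  sfc <- computeStateFC(series, model)
  combos <- enumerateCombos(cohort$config$K)
  decoded <- lapply(combos, function(cb) {
    smp <- buildComboSamples(sfc, cb)
    losoDecode(smp$x, smp$y, smp$subjects, nSelected = nSelected, seed = seed)
  })
  means <- vapply(decoded, `[[`, numeric(1), "mean")
  sds <- vapply(decoded, `[[`, numeric(1), "sd")
  opt <- selectOptimalModel(means, sds, tolerance = 0.005)
  stable <- stableFeatures(decoded[[opt]]$selected)
  list(model = model, sfc = sfc, series = series,
       weights = defnWeights(stable, combos[[opt]], cohort$partition),
       optimal = names(combos)[opt], decoded = decoded)
}

# DEFN weights whose nonzero pairs are exactly `pairs` (descending), for
# transfer tests that need a known ranking.
syntheticWeights <- function(partition, pairs) {
  epairs <- edgeNetworkPairs(partition)
  stable <- integer(0)
  for (k in seq_along(pairs)) {
    idx <- which(epairs == pairs[k])
    # keep a decreasing fraction of each pair's edges so ranks are strict
    stable <- c(stable, idx[seq_len(max(1L, floor(length(idx) * (1 - (k - 1) / (2 * length(pairs))))))])
  }
  defnWeights(stable, 1L, partition)
}
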