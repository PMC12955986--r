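#' Simulation configuration for the healthy cohort
#'
#' Collects the generator parameters with validated defaults. The defaults
#' are desk-scale (12 subjects, 40 ROIs in 6 networks) so that a full run
#' stays fast; a full-scale configuration (51 subjects, 432 ROIs in 18
#' networks, 600 time points) is reached by overriding the counts. States
#' are encoded as network-block correlation templates; each condition has
#' its own sticky Markov chain over the states with a distinct stationary
#' distribution, so the two conditions differ both in state occupancy and
#' (through `conditionEffect`) in connectivity on designated network-pair
#' edges.
#'
#' @param nSubjects subjects in the cohort (default 12).
#' @param episodesPerCondition episodes per subject per condition (default 3,
#'   i.e. 6 episodes in total).
#' @param nTimepoints time points per episode (default 600).
#' @param nRois number of ROIs (default 40; must equal sum(networkSizes)).
#' @param networkSizes ROIs per network (default 6 networks over 40 ROIs).
#' @param networkLabels network names.
#' @param K number of latent states (default 4).
#' @param conditions the two condition labels (default happy/sad).
#' @param stayProb Markov self-transition stickiness (default 0.97, so the
#'   mean state dwell of ~33 time points exceeds the default 30-point
#'   analysis window and states are recoverable from windowed FC).
#' @param occupancySkew exponent shaping the per-condition stationary
#'   distributions (0 = identical uniform occupancy; default 1).
#' @param withinR,activeR,betweenR correlation template levels: baseline
#'   within-network, elevated within-network for a state's active blocks,
#'   and between-network (defaults 0.3 / 0.7 / 0.05).
#' @param conditionEffect correlation shift between conditions on the
#'   effect edges, split +/- half per condition (default 0.3).
#' @param effectPairs network-pair labels carrying the condition effect;
#'   NULL picks the first `nEffectPairs` between-network pairs in canonical
#'   order.
#' @param nEffectPairs used when `effectPairs` is NULL (default 2).
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return validated list of class `simConfig`.
#' @export
simConfig <- function(nSubjects = 12L, episodesPerCondition = 3L,
                      nTimepoints = 600L, nRois = 40L,
                      networkSizes = c(8L, 8L, 7L, 7L, 5L, 5L),
                      networkLabels = paste0("Net", seq_along(networkSizes)),
                      K = 4L, conditions = c("happy", "sad"),
                      stayProb = 0.97, occupancySkew = 1,
                      withinR = 0.3, activeR = 0.7, betweenR = 0.05,
                      conditionEffect = 0.3, effectPairs = NULL,
                      nEffectPairs = 2L, seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects),
              episodesPerCondition = as.integer(episodesPerCondition),
              nTimepoints = as.integer(nTimepoints), nRois = as.integer(nRois),
              networkSizes = as.integer(networkSizes),
              networkLabels = as.character(networkLabels), K = as.integer(K),
              conditions = as.character(conditions), stayProb = stayProb,
              occupancySkew = occupancySkew, withinR = withinR,
              activeR = activeR, betweenR = betweenR,
              conditionEffect = conditionEffect, effectPairs = effectPairs,
              nEffectPairs = as.integer(nEffectPairs), seed = as.integer(seed))
  if (sum(cfg$networkSizes) != cfg$nRois)
    stop("networkSizes must sum to nRois")
  if (any(c(cfg$nSubjects, cfg$episodesPerCondition, cfg$nTimepoints,
            cfg$nRois, cfg$K) < 1L))
    stop("all counts must be positive")
  if (length(cfg$conditions) != 2L) stop("exactly two conditions required")
  if (cfg$stayProb <= 0 || cfg$stayProb >= 1) stop("stayProb in (0,1) required")
  structure(cfg, class = "simConfig")
}

# stationary state preference of one condition: condition 1 favours
# higher-indexed states, condition 2 the reverse; skew 0 gives uniform
conditionStationary <- function(K, skew) {
  w1 <- seq_len(K)^skew
  w2 <- rev(seq_len(K))^skew
  list(w1 / sum(w1), w2 / sum(w2))
}

# sticky chain with prescribed stationary distribution:
# P = a I + (1-a) 1 pi', whose stationary distribution is pi
stickyChain <- function(pi, stay) {
  K <- length(pi)
  stay * diag(K) + (1 - stay) * matrix(pi, K, K, byrow = TRUE)
}

markovPath <- function(n, P, init) {
  K <- nrow(P)
  s <- integer(n)
  s[1L] <- sample.int(K, 1L, prob = init)
  for (t in 2:n) s[t] <- sample.int(K, 1L, prob = P[s[t - 1L], ])
  s
}

# correlation template of one state: active network blocks at activeR,
# other within-network blocks at withinR, between-network at betweenR
stateTemplate <- function(partition, activeBlocks, withinR, activeR, betweenR) {
  ni <- as.integer(networkOf(partition))
  p <- nRois(partition)
  same <- outer(ni, ni, "==")
  m <- matrix(betweenR, p, p)
  m[same] <- withinR
  act <- ni %in% activeBlocks
  m[same & outer(act, act, "&")] <- activeR
  diag(m) <- 1
  m
}

# guarantee a usable correlation matrix: nearest-PD repair (logged) plus a
# minimal ridge so that the Cholesky factor exists
ensurePD <- function(m, label = "matrix") {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(list(corr = m, chol = ch))
  message(sprintf("repairing non-positive-definite %s via nearest-PD", label))
  m2 <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
  ch <- tryCatch(chol(m2), error = function(e) NULL)
  if (is.null(ch)) {
    m2 <- m2 + diag(1e-8, nrow(m2))
    m2 <- stats::cov2cor(m2)
    ch <- chol(m2)
  }
  list(corr = m2, chol = ch)
}

#' Generate a healthy cohort with latent connectivity states
#'
#' For every subject, episode and condition, draws a latent state path from
#' the condition's sticky Markov chain and samples each time point from a
#' zero-mean multivariate normal whose correlation matrix is the active
#' state's template. The condition effect perturbs the designated
#' network-pair edges' correlations by +/- `conditionEffect`/2 between the
#' two conditions (first condition gets the positive half, so
#' condition-1-minus-condition-2 contrasts come out positive); any template
#' rendered non-positive-definite is repaired by nearest-PD projection (and
#' the repair is logged).
#'
#' @param config a [simConfig()] object.
#' @param partition optional [NetworkPartition-class]; defaults to contiguous
#'   blocks from the config.
#' @return list with `episodes` (each: subject, episode, condition, ts),
#'   `partition`, `config` and `truth` (state paths, per-state/condition
#'   correlation matrices, effect edges, transition matrices and stationary
#'   distributions).
#' @export
genHealthyCohort <- function(config, partition = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(partition))
    partition <- genNetworkPartition(config$networkSizes, config$networkLabels)
  set.seed(config$seed)
  K <- config$K
  p <- nRois(partition)
  nNet <- length(networkLabels(partition))
  conds <- config$conditions

  # designate the condition-effect edges
  pairs <- allNetworkPairs(partition)
  effectPairs <- config$effectPairs
  if (is.null(effectPairs) && config$conditionEffect > 0) {
    between <- pairs$pair[pairs$netA != pairs$netB]
    effectPairs <- between[seq_len(min(config$nEffectPairs, length(between)))]
  }
  epairs <- edgeNetworkPairs(partition)
  effectEdges <- if (length(effectPairs)) which(epairs %in% effectPairs) else integer(0)
  map <- upperIndexMap(p)

  # state x condition correlation matrices and Cholesky factors
  corrs <- vector("list", K)
  chols <- vector("list", K)
  for (k in seq_len(K)) {
    active <- which((seq_len(nNet) - 1L) %% K == (k - 1L))
    base <- stateTemplate(partition, active, config$withinR, config$activeR,
                          config$betweenR)
    corrs[[k]] <- vector("list", 2L)
    chols[[k]] <- vector("list", 2L)
    for (c2 in 1:2) {
      m <- base
      if (length(effectEdges)) {
        delta <- config$conditionEffect / 2 * (if (c2 == 1L) 1 else -1)
        ii <- map$i[effectEdges]; jj <- map$j[effectEdges]
        m[cbind(ii, jj)] <- pmin(pmax(m[cbind(ii, jj)] + delta, -0.95), 0.95)
        m[cbind(jj, ii)] <- m[cbind(ii, jj)]
      }
      fixed <- ensurePD(m, sprintf("state %d / %s template", k, conds[c2]))
      corrs[[k]][[c2]] <- fixed$corr
      chols[[k]][[c2]] <- fixed$chol
    }
  }

  statn <- conditionStationary(K, config$occupancySkew)
  trans <- lapply(statn, stickyChain, stay = config$stayProb)
  names(trans) <- names(statn) <- conds

  episodes <- list()
  statePaths <- list()
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("sub%02d", s)
    for (c2 in 1:2) {
      for (e in seq_len(config$episodesPerCondition)) {
        eid <- sprintf("%s_%d", conds[c2], e)
        path <- markovPath(config$nTimepoints, trans[[c2]], statn[[c2]])
        z <- matrix(stats::rnorm(config$nTimepoints * p), config$nTimepoints, p)
        ts <- matrix(0, config$nTimepoints, p)
        for (k in seq_len(K)) {
          rows <- which(path == k)
          if (length(rows))
            ts[rows, ] <- z[rows, , drop = FALSE] %*% chols[[k]][[c2]]
        }
        colnames(ts) <- roiIds(partition)
        episodes[[length(episodes) + 1L]] <-
          list(subject = sid, episode = eid, condition = conds[c2], ts = ts)
        statePaths[[paste(sid, eid, sep = "|")]] <- path
      }
    }
  }

  truth <- list(statePaths = statePaths, trueCentroidFC = corrs,
                conditionEffectPairs = effectPairs,
                conditionEffectEdges = effectEdges,
                transitionMatrices = trans, stationary = statn)
  list(episodes = episodes, partition = partition, config = config,
       truth = truth)
}

#' Generate a clinical cohort with planted network-pair group effects
#'
#' Produces per-subject vectorized static-FC feature vectors (Fisher-Z
#' scale) in which the patient group's edges inside the designated network
#' pairs are shifted by `effectSize` noise standard deviations, together
#' with a phenotype table (age, sex, group, synthetic severity score).
#' Optional confound coupling adds `confoundCoupling["age"] * centred age +
#' confoundCoupling["sex"] * sex` to every feature; combined with
#' group-specific age means or sex proportions this creates
#' confound-mediated separability that in-fold regression must remove.
#'
#' @param nControls,nPatients group sizes.
#' @param partition a [NetworkPartition-class].
#' @param effectPairs network-pair labels carrying the group effect (must be
#'   non-empty when `effectSize` > 0).
#' @param effectSize standardized mean shift on affected edges (>= 0).
#' @param confoundCoupling named numeric `c(age=, sex=)` slopes (default 0).
#' @param ageMean named numeric `c(control=, patient=)` (default both 35).
#' @param ageSd age SD (default 10).
#' @param sexProb named numeric probability of sex = 1 per group.
#' @param noiseSd edge noise SD on the Z scale (default 0.2).
#' @param seed integer seed.
#' @return list: `features` (subjects x edges), `group` (factor
#'   control/patient), `phenotype` (data.frame), `truth`.
#' @export
genClinicalCohort <- function(nControls, nPatients, partition,
                              effectPairs = character(), effectSize = 0,
                              confoundCoupling = c(age = 0, sex = 0),
                              ageMean = c(control = 35, patient = 35),
                              ageSd = 10,
                              sexProb = c(control = 0.5, patient = 0.5),
                              noiseSd = 0.2, seed = 1L) {
  stopifnot(nControls >= 1L, nPatients >= 1L, effectSize >= 0)
  if (effectSize > 0 && !length(effectPairs))
    stop("nonzero effectSize requires non-empty effectPairs")
  set.seed(as.integer(seed))
  p <- nRois(partition)
  d <- p * (p - 1L) / 2L
  epairs <- edgeNetworkPairs(partition)
  if (length(effectPairs) && !all(effectPairs %in% epairs))
    stop("unknown network pair in effectPairs")
  effectEdges <- which(epairs %in% effectPairs)

  n <- nControls + nPatients
  isPatient <- rep(c(0L, 1L), c(nControls, nPatients))
  group <- factor(ifelse(isPatient == 1L, "patient", "control"),
                  levels = c("control", "patient"))
  age <- stats::rnorm(n, ifelse(isPatient == 1L, ageMean[["patient"]],
                                ageMean[["control"]]), ageSd)
  sex <- stats::rbinom(n, 1L, ifelse(isPatient == 1L, sexProb[["patient"]],
                                     sexProb[["control"]]))
  score <- stats::rnorm(n, 10 + 12 * isPatient, 4)

  mu <- stats::rnorm(d, 0.2, 0.15)
  x <- matrix(stats::rnorm(n * d, 0, noiseSd), n, d) +
    matrix(mu, n, d, byrow = TRUE)
  if (length(effectEdges) && effectSize > 0)
    x[isPatient == 1L, effectEdges] <-
      x[isPatient == 1L, effectEdges] + effectSize * noiseSd
  ageC <- age - mean(ageMean)
  if (confoundCoupling[["age"]] != 0) x <- x + ageC %o% rep(confoundCoupling[["age"]], d)
  if (confoundCoupling[["sex"]] != 0) x <- x + sex %o% rep(confoundCoupling[["sex"]], d)

  phenotype <- data.frame(subject_id = sprintf("clin%03d", seq_len(n)),
                          group = as.character(group), age = age, sex = sex,
                          score = score, stringsAsFactors = FALSE)
  truth <- list(effectPairs = effectPairs, effectEdges = effectEdges,
                effectSize = effectSize, confoundCoupling = confoundCoupling)
  list(features = x, group = group, phenotype = phenotype, truth = truth)
}

#' Derive a stage seed from a root seed
#'
#' Deterministic 31-bit linear-congruential derivation so that one root seed
#' reproducibly yields independent per-stage seeds.
#'
#' @param seed integer root seed.
#' @param offset integer stage offset.
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(offset)) %%
               2147483647)
}
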