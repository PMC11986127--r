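## Synthetic resting-state EEG with planted microstate structure: smooth
## template topographies, a semi-Markov state sequence with gamma-distributed
## dwell times, an oscillation-modulated signal model with spatially
## correlated noise, and three-group cohorts with planted effects plus
## Likert questionnaire scores correlated with one state's occurrence.

#' Simulation specification for one recording
#'
#' Defaults emulate the study conditions: 5-minute eyes-closed recordings at
#' 250 Hz with four recurring quasi-stable topographies of 55-75 ms mean
#' duration, alpha-band (10 Hz) GFP waxing and waning, and moderate
#' signal-to-noise.
#'
#' @param nChannels sensor count (default 64).
#' @param samplingRate Hz (default 250).
#' @param durationS recording length in seconds (default 300).
#' @param K number of planted maps (default 4).
#' @param meanDurationsMs per-state mean dwell time in ms (default
#'   c(55, 65, 75, 60) for K = 4, else 65 each).
#' @param transitionMatrix K x K successor probabilities, zero diagonal,
#'   rows summing to 1 (default uniform over the other states).
#' @param oscillationFreqHz frequency of the rectified-sinusoid amplitude
#'   envelope (default 10).
#' @param snr ratio of map-signal RMS to noise RMS (default 5).
#' @param amplitudeUv peak signal amplitude in microvolts (default 30).
#' @param gammaShape shape of the gamma dwell-time distribution (default 2;
#'   dwell times are not geometric).
#' @param seed RNG seed (optional).
#' @return A validated list of class \code{msSimulationSpec}.
#' @export
simulationSpec <- function(nChannels = 64, samplingRate = 250,
                           durationS = 300, K = 4,
                           meanDurationsMs = NULL, transitionMatrix = NULL,
                           oscillationFreqHz = 10, snr = 5,
                           amplitudeUv = 30, gammaShape = 2, seed = NULL) {
  if (is.null(meanDurationsMs))
    meanDurationsMs <- if (K == 4) c(55, 65, 75, 60) else rep(65, K)
  if (length(meanDurationsMs) != K) stop("one mean duration per state needed")
  if (any(meanDurationsMs <= 0)) stop("mean durations must be positive")
  if (snr <= 0) stop("snr must be positive")
  if (is.null(transitionMatrix)) {
    transitionMatrix <- matrix(1 / max(K - 1, 1), K, K)
    diag(transitionMatrix) <- 0
    if (K == 1) transitionMatrix <- matrix(1, 1, 1)
  }
  if (K > 1) {
    if (any(abs(diag(transitionMatrix)) > 1e-12))
      stop("transition matrix must have a zero diagonal")
    if (any(abs(rowSums(transitionMatrix) - 1) > 1e-9))
      stop("transition rows must sum to 1")
  }
  spec <- list(nChannels = nChannels, samplingRate = samplingRate,
               durationS = durationS, K = K,
               meanDurationsMs = meanDurationsMs,
               transitionMatrix = transitionMatrix,
               oscillationFreqHz = oscillationFreqHz, snr = snr,
               amplitudeUv = amplitudeUv, gammaShape = gammaShape,
               seed = seed)
  class(spec) <- "msSimulationSpec"
  spec
}

#' Smooth template topographies on a montage
#'
#' Draws K average-referenced, unit-norm topographies as random combinations
#' of low-order polynomial (solid-harmonic) fields of the sensor positions,
#' redrawing until every pair satisfies |spatial correlation| <= maxPairCorr.
#'
#' @param montage a \linkS4class{SensorMontage}.
#' @param K number of maps (<= channel count).
#' @param degree maximum polynomial degree of the spatial fields (default 2).
#' @param maxPairCorr pairwise dissimilarity bound (default 0.6).
#' @param maxTries redraw budget per map (default 200).
#' @param seed RNG seed (optional).
#' @return A \linkS4class{MicrostateMapSet} (level "subject").
#' @export
makeTemplateMaps <- function(montage, K, degree = 2, maxPairCorr = 0.6,
                             maxTries = 200, seed = NULL) {
  nC <- length(channelNames(montage))
  if (K > nC) stop("K exceeds the channel count")
  if (!is.null(seed)) set.seed(seed)
  p <- montage@positions
  basis <- cbind(p[, 1], p[, 2], p[, 3])
  if (degree >= 2)
    basis <- cbind(basis, p[, 1] * p[, 2], p[, 1] * p[, 3], p[, 2] * p[, 3],
                   p[, 1]^2 - p[, 2]^2, 3 * p[, 3]^2 - 1)
  if (degree >= 3)
    basis <- cbind(basis, p[, 1]^3, p[, 2]^3, p[, 3]^3,
                   p[, 1] * p[, 2] * p[, 3])
  out <- matrix(0, K, nC)
  i <- 1
  while (i <= K) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      m <- as.vector(basis %*% rnorm(ncol(basis)))
      m <- m - mean(m)
      n <- sqrt(sum(m^2))
      if (n == 0) next
      m <- m / n
      if (i == 1 ||
          all(abs(out[seq_len(i - 1), , drop = FALSE] %*% m) <= maxPairCorr)) {
        out[i, ] <- m; ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not draw %d maps with pairwise |corr| <= ",
                          "%.2f; lower K or raise the bound"), K, maxPairCorr))
    i <- i + 1
  }
  colnames(out) <- channelNames(montage)
  MicrostateMapSet(out, level = "subject")
}

#' Semi-Markov microstate state sequence
#'
#' Dwell times per visit are gamma-distributed (shape \code{gammaShape},
#' mean as specified per state, converted to frames with a 1-frame floor);
#' the successor state is drawn from the transition matrix. K = 1 yields a
#' single segment spanning the whole recording.
#'
#' @param spec an \code{\link{simulationSpec}} object.
#' @param seed RNG seed; overrides the spec's seed when given.
#' @return A fully labeled \linkS4class{MicrostateSegmentation}.
#' @export
simulateStateSequence <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$durationS * spec$samplingRate)
  K <- spec$K
  if (K == 1)
    return(MicrostateSegmentation(rep(1L, n), 1L, spec$samplingRate))
  meanFrames <- spec$meanDurationsMs * spec$samplingRate / 1000
  lab <- integer(n)
  pos <- 1L
  state <- sample.int(K, 1)
  while (pos <= n) {
    d <- rgamma(1, shape = spec$gammaShape,
                scale = meanFrames[state] / spec$gammaShape)
    len <- max(1L, as.integer(round(d)))
    lab[pos:min(n, pos + len - 1L)] <- state
    pos <- pos + len
    state <- sample.int(K, 1, prob = spec$transitionMatrix[state, ])
  }
  MicrostateSegmentation(lab, K, spec$samplingRate)
}

## k-nearest-neighbour spatial smoothing matrix for the noise model
.smoothingMatrix <- function(montage, nNeighbors = 4) {
  pos <- montage@positions
  D <- as.matrix(dist(pos))
  n <- nrow(pos)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(nNeighbors + 1, n))]
    S[i, nb] <- 1 / length(nb)
  }
  S
}

#' Synthesize EEG from maps and a state sequence
#'
#' Signal model: x(t) = A * a(t) * m_{s(t)} + noise, with a(t) a rectified
#' sinusoid at the oscillation frequency (GFP waxing and waning), and noise
#' spatially correlated white noise (neighbor-averaged) scaled so the
#' map-signal RMS over the recording is \code{snr} times the noise RMS.
#' Every frame is average-referenced.
#'
#' @param mapset templates (\linkS4class{MicrostateMapSet}) over the montage
#'   channels.
#' @param sequence a \linkS4class{MicrostateSegmentation} from
#'   \code{\link{simulateStateSequence}}.
#' @param montage the \linkS4class{SensorMontage}.
#' @param spec an \code{\link{simulationSpec}}.
#' @param seed RNG seed for the noise (optional).
#' @return An \linkS4class{EEGRecording}.
#' @export
simulateEEG <- function(mapset, sequence, montage, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- maps(mapset)
  lab <- frameLabels(sequence)
  n <- length(lab)
  tt <- (seq_len(n) - 1) / spec$samplingRate
  a <- abs(sin(2 * pi * spec$oscillationFreqHz * tt))
  X <- t(M)[, lab, drop = FALSE] * rep(spec$amplitudeUv * a, each = nrow(t(M)))
  sigRMS <- sqrt(mean(X^2))
  if (is.finite(spec$snr)) {
    S <- .smoothingMatrix(montage)
    noise <- S %*% matrix(rnorm(nrow(X) * n), nrow(X), n)
    noise <- noise * (sigRMS / spec$snr / sqrt(mean(noise^2)))
    X <- X + noise
  }
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- channelNames(montage)
  EEGRecording(X, spec$samplingRate, montage, history = "simulated")
}

#' Cohort specification for the three-group design
#'
#' Defaults mirror the study design: groups of 30/60/60 subjects (labelled
#' g1/g2/g3 for a patient-like, an older and a younger control group), a
#' decrease of one state's mean duration in the first two groups, an
#' increase of another state's duration in the first group, and one
#' questionnaire domain whose score correlates with the decreased state's
#' occurrence.
#'
#' @param groupSizes subjects per group (default c(30, 60, 60)).
#' @param groupNames group labels (default g1, g2, g3).
#' @param durationMultipliers groups x K matrix of multipliers on the mean
#'   dwell times (default: state 3 x0.85 in groups 1-2, state 1 x1.15 in
#'   group 1, otherwise 1), given K = 4.
#' @param subjectSdLog log-normal between-subject spread of the dwell-time
#'   means (default 0.08).
#' @param corrTarget target correlation between the designated state's true
#'   occurrence and the designated questionnaire domain (default 0.3).
#' @param corrState state whose occurrence drives the questionnaire domain
#'   (default 3).
#' @param corrDomain questionnaire domain index it drives (default 9,
#'   the visual-thoughts slot of the 10-domain inventory).
#' @param seed RNG seed (optional).
#' @return A validated list of class \code{msCohortSpec}.
#' @export
cohortSpec <- function(groupSizes = c(30, 60, 60),
                       groupNames = c("g1", "g2", "g3"),
                       durationMultipliers = NULL, subjectSdLog = 0.08,
                       corrTarget = 0.3, corrState = 3, corrDomain = 9,
                       seed = NULL) {
  if (any(groupSizes <= 0)) stop("group sizes must be positive")
  spec <- list(groupSizes = groupSizes, groupNames = groupNames,
               durationMultipliers = durationMultipliers,
               subjectSdLog = subjectSdLog, corrTarget = corrTarget,
               corrState = corrState, corrDomain = corrDomain, seed = seed)
  class(spec) <- "msCohortSpec"
  spec
}

## Ground-truth temporal parameters from a label vector, computed with
## independent arithmetic (boundary detection by diff, no shared code with
## the metrics module).
.truthFromLabels <- function(lab, rate, K) {
  breaks <- c(0L, which(diff(lab) != 0L), length(lab))
  segState <- lab[breaks[-1]]
  segLen <- diff(breaks)
  keep <- segState != 0L
  segState <- segState[keep]; segLen <- segLen[keep]
  labeledS <- sum(segLen) / rate
  do.call(rbind, lapply(seq_len(K), function(s) {
    lens <- segLen[segState == s]
    data.frame(state = s,
               duration_ms = if (length(lens)) 1000 * sum(lens) /
                 (length(lens) * rate) else NA_real_,
               coverage_pct = 100 * sum(lens) / sum(segLen),
               occurrence_per_s = length(lens) / labeledS)
  }))
}

#' Simulate a three-group cohort with planted effects
#'
#' Draws per-subject dwell-time means (group multiplier times log-normal
#' subject jitter), generates each subject's state sequence (and, unless
#' \code{metricsOnly}, the EEG), computes ground-truth temporal parameters
#' directly from the generated label sequences, and produces a 30-item
#' Likert questionnaire whose designated domain tracks the designated
#' state's true occurrence at the target correlation.
#'
#' @param cohort a \code{\link{cohortSpec}}.
#' @param sim a \code{\link{simulationSpec}} describing each recording.
#' @param montage sensor montage; generated from \code{sim$nChannels} when
#'   NULL.
#' @param templates planted \linkS4class{MicrostateMapSet}; drawn with
#'   \code{\link{makeTemplateMaps}} when NULL.
#' @param metricsOnly skip EEG synthesis, returning sequences and truth
#'   only (fast path for statistical calibration studies).
#' @param seed RNG seed; overrides the cohort spec's seed.
#' @return List with \code{recordings} (or NULL), \code{sequences},
#'   \code{truth} (per subject x state data.frame), \code{questionnaire}
#'   (subjects x 30 items), \code{groups}, \code{templates},
#'   \code{montage}.
#' @export
simulateCohort <- function(cohort, sim, montage = NULL, templates = NULL,
                           metricsOnly = FALSE, seed = NULL) {
  if (is.null(seed)) seed <- cohort$seed
  if (!is.null(seed)) set.seed(seed)
  K <- sim$K
  nG <- length(cohort$groupSizes)
  mult <- cohort$durationMultipliers
  if (is.null(mult)) {
    mult <- matrix(1, nG, K)
    if (K >= 3 && nG >= 2) { mult[1, 3] <- 0.85; mult[2, 3] <- 0.85 }
    if (K >= 1 && nG >= 1) mult[1, 1] <- 1.15
  }
  if (is.null(montage)) montage <- makeSphericalMontage(sim$nChannels)
  if (is.null(templates))
    templates <- makeTemplateMaps(montage, K,
                                  seed = sample.int(2^31 - 1, 1))
  groups <- rep(cohort$groupNames, cohort$groupSizes)
  nSub <- length(groups)
  ids <- sprintf("S%03d", seq_len(nSub))
  recs <- if (metricsOnly) NULL else vector("list", nSub)
  seqs <- vector("list", nSub)
  truth <- list()
  for (i in seq_len(nSub)) {
    g <- match(groups[i], cohort$groupNames)
    subjMeans <- sim$meanDurationsMs * mult[g, ] *
      exp(rnorm(K, 0, cohort$subjectSdLog))
    subSpec <- sim
    subSpec$meanDurationsMs <- subjMeans
    subSpec$seed <- NULL
    sq <- simulateStateSequence(subSpec)
    seqs[[i]] <- sq
    if (!metricsOnly)
      recs[[i]] <- simulateEEG(templates, sq, montage, subSpec)
    tr <- .truthFromLabels(frameLabels(sq), sim$samplingRate, K)
    tr <- cbind(subject_id = ids[i], group = groups[i], tr)
    truth[[i]] <- tr
  }
  truth <- do.call(rbind, truth)
  if (!metricsOnly) names(recs) <- ids
  names(seqs) <- ids
  ## questionnaire: 10 domains x 3 items on a 1-5 Likert scale
  occ <- truth$occurrence_per_s[truth$state == cohort$corrState]
  zOcc <- (occ - mean(occ)) / max(sd(occ), 1e-12)
  items <- matrix(0L, nSub, 30)
  for (d in seq_len(10)) {
    latentZ <- if (d == cohort$corrDomain)
      cohort$corrTarget * zOcc + sqrt(1 - cohort$corrTarget^2) * rnorm(nSub)
    else rnorm(nSub)
    latentItem <- 3 + 0.8 * latentZ        # per-item latent mean on 1-5
    for (j in seq_len(3)) {
      v <- round(latentItem + rnorm(nSub, 0, 0.5))
      items[, (d - 1) * 3 + j] <- pmin(pmax(v, 1L), 5L)
    }
  }
  colnames(items) <- sprintf("item%02d", 1:30)
  questionnaire <- data.frame(subject_id = ids, group = groups, items,
                              stringsAsFactors = FALSE)
  list(recordings = recs, sequences = seqs, truth = truth,
       questionnaire = questionnaire, groups = groups,
       templates = templates, montage = montage)
}
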