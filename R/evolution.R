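#' @include predictor.R
NULL

.checkFitnessInputs <- function(pred) {
  if (pred$K < 2L || length(unique(pred$fam)) < 2L)
    stop("fitness needs >= 2 profiled kinases from >= 2 families")
  if (all(pred$noDonor))
    stop("no profiled kinase has an eligible donor")
  if (any(pred$noDonor))
    warning("skipping kinase(s) with no eligible donor: ",
            paste(pred$profIds[pred$noDonor], collapse = ", "))
  invisible(pred)
}

#' Fitness of one specificity mask
#'
#' For every profiled kinase, its PSSM is predicted leave-family-out under the
#' mask and compared to the observed PSSM by Frobenius distance; the fitness is
#' the median of these distances over kinases. Lower is fitter: the search
#' evolves by minimisation. Kinases with no eligible donor are skipped with a
#' warning.
#'
#' @param mask a [SpecificityMask-class].
#' @param aln a [DomainAlignment-class].
#' @param profiles named list of [SpecificityProfile-class].
#' @param cfg a [PredictionConfig-class].
#' @param sm substitution matrix.
#' @return non-negative scalar median prediction error.
#' @export
maskFitness <- function(mask, aln, profiles, cfg = predictionConfig(),
                        sm = blosum62()) {
  pred <- .checkFitnessInputs(.makePredictor(aln, profiles, cfg, sm))
  stats::median(pred$kinaseErrors(maskScores(mask)), na.rm = TRUE)
}

#' Random initial mask population
#'
#' `populationSize` masks with entries i.i.d. uniform on \[0, 1\],
#' reproducible from `cfg@seed`.
#'
#' @param L alignment length.
#' @param cfg an [EvolutionConfig-class].
#' @return list of [SpecificityMask-class].
#' @export
initPopulation <- function(L, cfg) {
  stopifnot(L >= 1L)
  set.seed(cfg@seed)
  lapply(seq_len(cfg@populationSize),
         function(i) SpecificityMask(stats::runif(L)))
}

## stable elite indices: lowest fitness first, ties by earlier index
.eliteIndices <- function(fitnesses, eliteFraction) {
  nElite <- max(1L, ceiling(eliteFraction * length(fitnesses)))
  order(fitnesses, seq_along(fitnesses))[seq_len(nElite)]
}

.singlePointCrossover <- function(a, b, cut) c(a[seq_len(cut)], b[-seq_len(cut)])

#' Produce the next GA generation
#'
#' The lowest-fitness `ceiling(eliteFraction * n)` masks are copied unchanged
#' (elitism; fitness ties broken by earlier population index). The remaining
#' slots are filled by single-point cross-over of two distinct elite parents
#' (a `crossoverRate` share) and by mutated elite copies, where each position
#' independently with probability `mutationRate` is resampled uniformly on
#' \[0, 1\]. Consumes the current RNG stream; seed management belongs to
#' [evolve()].
#'
#' @param pop list of [SpecificityMask-class].
#' @param fitnesses numeric vector aligned with `pop`.
#' @param cfg an [EvolutionConfig-class].
#' @return list of [SpecificityMask-class] of the same size.
#' @export
nextGeneration <- function(pop, fitnesses, cfg) {
  n <- length(pop)
  if (length(fitnesses) != n) stop("pop and fitnesses lengths differ")
  M <- vapply(pop, maskScores, numeric(length(maskScores(pop[[1]]))))
  M <- matrix(M, ncol = n)  # L x n
  L <- nrow(M)
  eliteIdx <- .eliteIndices(fitnesses, cfg@eliteFraction)
  elite <- M[, eliteIdx, drop = FALSE]
  nElite <- ncol(elite)
  nRest <- n - nElite
  out <- matrix(0, L, n)
  out[, seq_len(nElite)] <- elite
  if (nRest > 0L) {
    nCross <- round(cfg@crossoverRate * nRest)
    if (nElite < 2L) nCross <- 0L  # cross-over needs two distinct parents
    slot <- nElite
    for (k in seq_len(nCross)) {
      par <- sample.int(nElite, 2L)
      cut <- if (L > 1L) sample.int(L - 1L, 1L) else 1L
      slot <- slot + 1L
      out[, slot] <- .singlePointCrossover(elite[, par[1]], elite[, par[2]], cut)
    }
    for (k in seq_len(nRest - nCross)) {
      src <- elite[, sample.int(nElite, 1L)]
      hit <- stats::runif(L) < cfg@mutationRate
      if (any(hit)) src[hit] <- stats::runif(sum(hit))
      slot <- slot + 1L
      out[, slot] <- src
    }
  }
  lapply(seq_len(n), function(k) SpecificityMask(out[, k]))
}

#' Evolve specificity masks by a learning classifier system
#'
#' Runs the full loop — leave-family-out PSSM prediction, median-Frobenius
#' fitness, elite selection, mutation and cross-over — until `maxGenerations`
#' or until the best fitness has not improved by more than 1e-9 for
#' `convergenceWindow` generations. Fully reproducible from `cfg@seed`.
#' Mask fitnesses are memoised within the run (elites are never re-evaluated),
#' which changes nothing but speed.
#'
#' @param aln a [DomainAlignment-class].
#' @param profiles named list of [SpecificityProfile-class]; the training set.
#' @param cfg an [EvolutionConfig-class].
#' @param pcfg optional [PredictionConfig-class]; defaults to
#'   `predictionConfig(alpha = cfg@alpha)`.
#' @param sm substitution matrix.
#' @param verbose log best fitness every 50 generations to stderr.
#' @return an [EvolutionResult-class].
#' @export
evolve <- function(aln, profiles, cfg = evolutionConfig(), pcfg = NULL,
                   sm = blosum62(), verbose = FALSE) {
  if (is.null(pcfg)) pcfg <- predictionConfig(alpha = cfg@alpha)
  pred <- .checkFitnessInputs(.makePredictor(aln, profiles, pcfg, sm))
  L <- pred$L

  cache <- new.env(parent = emptyenv())
  evalPop <- function(pop) {
    keys <- vapply(pop, function(m)
      paste(sprintf("%.17g", maskScores(m)), collapse = ","), "")
    fit <- numeric(length(pop))
    todo <- !vapply(keys, exists, NA, envir = cache)
    if (any(todo)) {
      M <- vapply(pop[todo], maskScores, numeric(L))
      newFit <- pred$fitnessOfMasks(matrix(M, nrow = L))
      for (k in seq_along(newFit))
        assign(keys[todo][k], newFit[k], envir = cache)
    }
    for (k in seq_along(pop)) fit[k] <- get(keys[k], envir = cache)
    fit
  }

  pop <- initPopulation(L, cfg)  # sets the seed; stream continues below
  traj <- numeric(cfg@maxGenerations)
  bestTraj <- matrix(0, cfg@maxGenerations, L)
  bestFit <- Inf
  stall <- 0L
  gen <- 0L
  fit <- suppressWarnings(evalPop(pop))
  repeat {
    gen <- gen + 1L
    genBestIdx <- order(fit, seq_along(fit))[1]
    traj[gen] <- fit[genBestIdx]
    bestTraj[gen, ] <- maskScores(pop[[genBestIdx]])
    if (traj[gen] < bestFit - 1e-9) {
      bestFit <- traj[gen]
      stall <- 0L
    } else stall <- stall + 1L
    if (verbose && gen %% 50L == 0L)
      message("generation ", gen, ": best fitness ", format(traj[gen], digits = 6))
    if (gen >= cfg@maxGenerations || stall >= cfg@convergenceWindow) break
    pop <- nextGeneration(pop, fit, cfg)
    fit <- suppressWarnings(evalPop(pop))
  }

  bestIdx <- order(fit, seq_along(fit))[1]
  new("EvolutionResult",
      bestFitnessTrajectory = traj[seq_len(gen)],
      bestMaskTrajectory = bestTraj[seq_len(gen), , drop = FALSE],
      finalPopulation = pop, finalFitness = fit,
      bestMask = pop[[bestIdx]], generationsRun = gen, seed = cfg@seed)
}

#' Run several independent deployments
#'
#' Runs [evolve()] `cfg@nRuns` times with seeds `cfg@seed + 0:(nRuns-1)`.
#'
#' @inheritParams evolve
#' @return list of [EvolutionResult-class].
#' @export
evolveRuns <- function(aln, profiles, cfg = evolutionConfig(), pcfg = NULL,
                       sm = blosum62(), verbose = FALSE) {
  lapply(seq_len(cfg@nRuns) - 1L, function(off) {
    cfgRun <- cfg
    cfgRun@seed <- cfg@seed + off
    evolve(aln, profiles, cfgRun, pcfg, sm, verbose = verbose)
  })
}

#' Scan the alpha sharpening exponent
#'
#' Runs a (typically short-budget) [evolve()] per candidate alpha and returns
#' the alpha whose converged best fitness is lowest (ties: smallest alpha) —
#' the procedure by which alpha = 3 was selected for the kinase domain.
#'
#' @param aln,profiles,cfg,sm as in [evolve()].
#' @param alphas non-empty numeric vector of candidate exponents.
#' @return list with `alpha` (the winner) and `fitness` (named per-alpha
#'   converged best fitness).
#' @export
selectAlpha <- function(aln, profiles, alphas, cfg = evolutionConfig(),
                        sm = blosum62()) {
  if (length(alphas) == 0L) stop("alphas must be non-empty")
  fitness <- vapply(alphas, function(a) {
    cfgA <- cfg
    cfgA@alpha <- as.numeric(a)
    res <- evolve(aln, profiles, cfgA, predictionConfig(alpha = a), sm)
    min(res@bestFitnessTrajectory)
  }, 0)
  names(fitness) <- as.character(alphas)
  ord <- order(fitness, alphas)  # ties -> smallest alpha
  list(alpha = alphas[ord[1]], fitness = fitness)
}

#' Aggregate independent runs into per-column DoS scores
#'
#' The aggregated score of a column is the mean of that column across the
#' runs' final best masks. The diagnostic dissimilarity trajectory is the
#' per-generation mean pairwise Frobenius distance between the runs' best
#' masks (runs that converged early are padded with their final best mask),
#' which should fall as independent deployments converge on similar solutions.
#'
#' @param results list of [EvolutionResult-class] over the same alignment.
#' @return list with `scores` (a [DoSScoreVector-class]) and `dissimilarity`
#'   (numeric per-generation trajectory; all zeros for a single run).
#' @export
aggregateRuns <- function(results) {
  if (length(results) == 0L) stop("no results to aggregate")
  Ls <- vapply(results, function(r) length(maskScores(r@bestMask)), 0L)
  if (length(unique(Ls)) != 1L) stop("runs have mixed alignment lengths")
  L <- Ls[1]
  nR <- length(results)
  best <- t(vapply(results, function(r) maskScores(r@bestMask), numeric(L)))
  scores <- new("DoSScoreVector", scores = colMeans(best),
                nRuns = as.integer(nR), perRunBest = best)

  gens <- max(vapply(results, function(r) r@generationsRun, 0L))
  padded <- lapply(results, function(r) {
    tr <- r@bestMaskTrajectory
    if (nrow(tr) < gens)
      tr <- rbind(tr, matrix(tr[nrow(tr), ], gens - nrow(tr), L, byrow = TRUE))
    tr
  })
  dissim <- vapply(seq_len(gens), function(g) {
    if (nR < 2L) return(0)
    d <- 0; npair <- 0L
    for (i in seq_len(nR - 1L)) for (j in seq(i + 1L, nR)) {
      d <- d + frobeniusDistance(padded[[i]][g, ], padded[[j]][g, ])
      npair <- npair + 1L
    }
    d / npair
  }, 0)
  list(scores = scores, dissimilarity = dissim)
}

#' Model-count accounting for a search campaign
#'
#' With `populationSize` masks per generation and `generations` generations to
#' convergence, one deployment explores `populationSize * generations`
#' candidate models; `nRuns` independent deployments explore `nRuns` times
#' that. With the human-kinome settings (100 masks, ~2,500 generations, 10
#' deployments) this is 250,000 models per deployment and 2,500,000 in total.
#'
#' @param populationSize masks per generation.
#' @param generations generations to convergence.
#' @param nRuns independent deployments.
#' @return list with `modelsPerDeployment` and `modelsTotal`.
#' @export
generationAccounting <- function(populationSize = 100, generations = 2500,
                                 nRuns = 10) {
  per <- populationSize * generations
  list(modelsPerDeployment = per, modelsTotal = per * nRuns)
}
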