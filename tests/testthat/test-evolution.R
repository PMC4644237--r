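test_that("initial populations are seeded, bounded and uniform", {
  cfg <- evolutionConfig(populationSize = 100, seed = 1)
  p1 <- initPopulation(10, cfg)
  p2 <- initPopulation(10, cfg)
  expect_identical(lapply(p1, maskScores), lapply(p2, maskScores))
  all <- unlist(lapply(p1, maskScores))
  expect_true(all(all >= 0 & all <= 1))
  # mean of 10^4 uniform draws within 3 standard errors of 0.5
  se <- sqrt(1 / 12) / sqrt(length(all))
  expect_lt(abs(mean(all) - 0.5), 3 * se)
})

test_that("mask fitness equals a longhand evaluation on a 4-kinase toy set", {
  aln <- toyAlignment()
  profs <- toyProfiles()
  mask <- SpecificityMask(replace(rep(0, 5), 3, 1))  # one-hot at column 3
  cfg <- predictionConfig(alpha = 3)

  # longhand: per query, weights from per-column similarity at column 3 only,
  # prediction as the explicit weighted mean over cross-family donors
  sm <- blosum62()
  seqm <- sequenceMatrix(aln)
  rescale <- function(a, b) (sm[a, b] - min(sm)) / (max(sm) - min(sm))
  fam <- families(aln)
  errs <- vapply(names(profs), function(q) {
    donors <- setdiff(names(profs), q)
    donors <- donors[fam[donors] != fam[q]]
    w <- vapply(donors, function(j) rescale(seqm[q, 3], seqm[j, 3]), 0)
    wa <- w^3
    if (sum(wa) == 0) wa <- rep(1, length(wa))
    wa <- wa / sum(wa)
    pred <- Reduce(`+`, Map(function(wk, j) wk * profileValues(profs[[j]]),
                            as.list(wa), donors))
    bruteFrobenius(pred, profileValues(profs[[q]]))
  }, 0)
  expect_equal(maskFitness(mask, aln, profs, cfg), median(errs))
})

test_that("identical observed profiles give zero fitness for any mask", {
  aln <- toyAlignment()
  same <- lapply(toyProfiles(), function(p)
    SpecificityProfile(domainId(p), matrix(2.5, 3, 20)))
  for (rep in 1:3) {
    mask <- SpecificityMask(runif(5))
    expect_equal(maskFitness(mask, aln, same, predictionConfig()), 0)
  }
})

test_that("next generation preserves elites and implements the operators", {
  set.seed(1)
  pop <- lapply(1:10, function(i) SpecificityMask(runif(6)))
  fit <- c(5, 1, 3, 2, 4, 6, 7, 8, 9, 10)
  cfgDegenerate <- evolutionConfig(populationSize = 10, eliteFraction = 0.2,
                                   mutationRate = 0, crossoverRate = 0)
  nxt <- nextGeneration(pop, fit, cfgDegenerate)
  expect_length(nxt, 10)
  eliteScores <- lapply(pop[c(2, 4)], maskScores)  # two lowest fitnesses
  expect_identical(lapply(nxt[1:2], maskScores), eliteScores)
  # with no mutation and no cross-over every child is a copy of an elite
  for (m in nxt[3:10])
    expect_true(any(vapply(eliteScores, identical, NA, maskScores(m))))

  # single-point cross-over of all-0 and all-1 parents: prefix then suffix
  cfgCross <- evolutionConfig(populationSize = 4, eliteFraction = 0.5,
                              mutationRate = 0, crossoverRate = 1)
  popC <- list(SpecificityMask(rep(0, 6)), SpecificityMask(rep(1, 6)),
               SpecificityMask(runif(6)), SpecificityMask(runif(6)))
  nxtC <- nextGeneration(popC, c(1, 2, 3, 4), cfgCross)
  for (m in nxtC[3:4]) {
    s <- maskScores(m)
    expect_true(all(s %in% c(0, 1)))
    expect_true(all(diff(s) %in% c(-1, 0, 1)) && sum(diff(s) != 0) <= 1)
  }
})

test_that("evolution is elitist, convergent and seed-reproducible", {
  synth <- smallSynth()
  cfg <- evolutionConfig(populationSize = 16, maxGenerations = 60,
                         convergenceWindow = 60, alpha = 3, seed = 9)
  r1 <- evolve(synth$alignment, synth$profiles, cfg)
  r2 <- evolve(synth$alignment, synth$profiles, cfg)
  expect_identical(fitnessTrajectory(r1), fitnessTrajectory(r2))
  expect_identical(maskScores(bestMask(r1)), maskScores(bestMask(r2)))
  tr <- fitnessTrajectory(r1)
  expect_true(all(diff(tr) <= 1e-12))        # elitism: never worse
  expect_lt(tr[length(tr)], tr[1])           # selection pressure acted
})

test_that("early stopping triggers after a stalled convergence window", {
  aln <- toyAlignment()
  same <- lapply(toyProfiles(), function(p)
    SpecificityProfile(domainId(p), matrix(1, 3, 20)))
  cfg <- evolutionConfig(populationSize = 8, maxGenerations = 500,
                         convergenceWindow = 5, seed = 2)
  res <- evolve(aln, same, cfg)  # fitness pinned at 0: stalls immediately
  expect_lte(res@generationsRun, 10)
  expect_true(all(fitnessTrajectory(res) == 0))
})

test_that("alpha selection prefers sharp weighting when only the nearest donor informs", {
  # four singleton families; each query's most similar donor carries an
  # identical profile while distant donors disagree
  aln <- DomainAlignment(
    c("n1", "n2", "f1", "f2"),
    c("WWWWWWWWWW", "WWWWWWWWWV", "AAAAAAAAAA", "AAAAAAAAAV"),
    family = c("fa", "fb", "fc", "fd"))
  mk <- function(id, v) SpecificityProfile(id, matrix(v, 2, 20))
  profs <- list(n1 = mk("n1", 1), n2 = mk("n2", 1),
                f1 = mk("f1", 9), f2 = mk("f2", 9))
  mask <- SpecificityMask(rep(1, 10))
  fitSharp <- maskFitness(mask, aln, profs, predictionConfig(alpha = 8))
  fitFlat <- maskFitness(mask, aln, profs, predictionConfig(alpha = 0))
  expect_lt(fitSharp, fitFlat)

  cfg <- evolutionConfig(populationSize = 8, maxGenerations = 10,
                         convergenceWindow = 10, seed = 4)
  sel <- selectAlpha(aln, profs, c(0, 8), cfg)
  expect_equal(sel$alpha, 8)
  expect_length(sel$fitness, 2)
  expect_true(all(sel$fitness >= 0))
  expect_equal(selectAlpha(aln, profs, 3, cfg)$alpha, 3)
})

test_that("aggregation averages best masks and tracks inter-run dissimilarity", {
  synth <- smallSynth()
  cfg <- evolutionConfig(populationSize = 12, maxGenerations = 30,
                         convergenceWindow = 30, alpha = 3, seed = 5, nRuns = 2)
  runs <- evolveRuns(synth$alignment, synth$profiles, cfg)
  agg <- aggregateRuns(runs)
  expect_s4_class(agg$scores, "DoSScoreVector")
  expect_equal(dosScores(agg$scores),
               colMeans(rbind(maskScores(bestMask(runs[[1]])),
                              maskScores(bestMask(runs[[2]])))))

  single <- aggregateRuns(runs[1])
  expect_equal(dosScores(single$scores), maskScores(bestMask(runs[[1]])))
  expect_true(all(single$dissimilarity == 0))

  twin <- aggregateRuns(list(runs[[1]], runs[[1]]))
  expect_true(all(twin$dissimilarity == 0))

  short <- evolve(toyAlignment(),
                  lapply(toyProfiles(), function(p)
                    SpecificityProfile(domainId(p), matrix(1, 3, 20))),
                  evolutionConfig(populationSize = 8, maxGenerations = 5,
                                  convergenceWindow = 5, seed = 1))
  expect_error(aggregateRuns(list(runs[[1]], short)), "mixed")
})
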