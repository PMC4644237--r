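test_that("DoS calling is a strict threshold with monotone nesting", {
  expect_equal(callDoS(c(0.95, 0.2, 0.91), 0.9), c(1L, 3L))
  expect_equal(callDoS(c(0.95, 0.2, 0.91), 1.0), integer(0))
  set.seed(3)
  s <- runif(50)
  for (pair in list(c(0.2, 0.5), c(0.5, 0.8), c(0.1, 0.9))) {
    lo <- callDoS(s, pair[1]); hi <- callDoS(s, pair[2])
    expect_true(all(hi %in% lo))
  }
  expect_error(callDoS(s, 1.5), "threshold")
})

test_that("subset correlation matches a rank-then-Pearson brute force", {
  synth <- smallSynth()
  aln <- synth$alignment
  profs <- synth$profiles[1:5]
  subset <- c(2L, 4L, 9L, 11L)

  rep <- seqSpecCorrelation(aln, profs, subset)
  expect_equal(rep@nPairs, 10L)
  expect_equal(rep@nColumns, 4L)
  expect_equal(rep@fractionOfAlignment, 4 / 20)

  # independent oracle: explicit pair loops + Pearson on average ranks
  sm <- blosum62()
  seqm <- sequenceMatrix(aln)
  ids <- names(profs)
  x <- c(); y <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- 0
    for (p in subset) {
      a <- seqm[ids[i], p]; b <- seqm[ids[j], p]
      xi <- xi + if (a == "-" || b == "-") min(sm) else sm[a, b]
    }
    x <- c(x, xi)
    y <- c(y, -bruteFrobenius(profileValues(profs[[ids[i]]]),
                              profileValues(profs[[ids[j]]])))
  }
  expect_equal(rep@rho, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("subset correlation hits the exact endpoints on engineered data", {
  # sequences whose subset similarity ranks exactly match specificity ranks
  aln <- DomainAlignment(c("k1", "k2", "k3"), c("WW", "WA", "AA"),
                         family = c("f1", "f2", "f3"))
  mk <- function(id, v) SpecificityProfile(id, matrix(v, 1, 20))
  profsUp <- list(k1 = mk("k1", 0), k2 = mk("k2", 1), k3 = mk("k3", 3))
  # x ranks: (k1,k2) > (k2,k3) > (k1,k3); y built to rank identically
  r <- seqSpecCorrelation(aln, profsUp, 1:2)
  expect_equal(r@rho, 1.0)
  # and values |v1-v2| > |v2-v3| > |v1-v3| reverse every rank
  profsDown <- list(k1 = mk("k1", 0), k2 = mk("k2", 10), k3 = mk("k3", 4))
  r2 <- seqSpecCorrelation(aln, profsDown, 1:2)
  expect_equal(r2@rho, -1.0)

  # constant similarity vector -> rho undefined with a warning
  alnConst <- DomainAlignment(c("k1", "k2", "k3"), c("AA", "AA", "AA"),
                              family = c("f1", "f2", "f3"))
  expect_warning(rc <- seqSpecCorrelation(alnConst, profsUp, 1:2), "constant")
  expect_true(is.na(rc@rho))
})

test_that("enrichment equals the exhaustive hypergeometric enumeration", {
  r <- enrichmentTest(1:5, 1:5, 10)
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(enrichmentTest(integer(0), 1:5, 10)$p, 1.0)

  # exhaustive oracle for L <= 12: over all called-sets of the same size,
  # the one-sided p is the fraction with overlap >= observed
  set.seed(8)
  for (rep in 1:4) {
    L <- sample(8:12, 1)
    called <- sort(sample(L, sample(2:5, 1)))
    golden <- sort(sample(L, sample(2:5, 1)))
    a <- length(intersect(called, golden))
    draws <- combn(L, length(called))
    pEnum <- mean(apply(draws, 2, function(d)
      length(intersect(d, golden)) >= a))
    expect_equal(enrichmentTest(called, golden, L)$p, pEnum,
                 tolerance = 1e-12)
  }
  expect_error(enrichmentTest(1:7, 8:12, 10), "smaller")
})

test_that("column conservation is negative entropy over non-gap residues", {
  aln <- DomainAlignment(
    ids = paste0("k", 1:10),
    sequences = vapply(1:10, function(i)
      paste0("A", AA20[i], if (i <= 5) "A" else "-", "-"), ""),
    family = rep("f", 10))
  cc <- columnConservation(aln)
  expect_equal(cc$conservation[1], 0)                       # all 'A'
  expect_equal(cc$gapFraction[1], 0)
  expect_equal(cc$conservation[2], -log2(10))               # 10 distinct AAs
  expect_equal(cc$conservation[3], 0)                       # half A, half gap
  expect_equal(cc$gapFraction[3], 0.5)
  expect_true(is.na(cc$conservation[4]))                    # all gap
  expect_equal(cc$gapFraction[4], 1)

  # uniform over all 20 amino acids
  aln20 <- DomainAlignment(paste0("k", 1:20), AA20, family = rep("f", 20))
  expect_equal(columnConservation(aln20)$conservation, -log2(20))
})

test_that("conservation comparison has the exact two-sided rank-sum null", {
  cons <- c(1, 2, 3, 4, 5, 6)
  # most extreme 3-vs-3 split: exact two-sided p = 2/20
  r <- compareConservation(1:3, 4:6, cons)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  expect_equal(r$medianDifference, 2 - 5)

  # identical sets: every assignment equally extreme -> p = 1
  same <- compareConservation(1:3, 1:3, cons)
  expect_equal(same$p, 1.0)

  # tie-free exact path agrees with the independent wilcox.test exact null
  set.seed(10)
  a <- rnorm(8); b <- rnorm(9)
  mine <- compareConservation(1:8, 9:17, c(a, b))
  ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # normal approximation stays within 0.02 of the exact answer
  a2 <- rnorm(15); b2 <- rnorm(15)
  approx <- compareConservation(1:15, 16:30, c(a2, b2))
  expect_equal(approx$method, "normal approximation")
  refExact <- wilcox.test(a2, b2, exact = TRUE)$p.value
  expect_lt(abs(approx$p - refExact), 0.02)

  expect_error(compareConservation(integer(0), 1:3, cons), "empty")
  expect_error(compareConservation(1:2, 3, c(NA, NA, 1)), "empty")
})

test_that("BLOSUM distances are symmetric max-complement sums", {
  alnW <- DomainAlignment(c("w1", "w2", "w3"), c("WWW", "WWW", "WWW"),
                          family = c("f1", "f2", "f3"))
  dW <- blosumDistanceMatrix(alnW, 1:3)
  expect_true(all(dW == 0))  # W/W attains the matrix maximum

  synth <- smallSynth()
  d <- blosumDistanceMatrix(synth$alignment, c(1L, 5L, 9L))
  expect_equal(d, t(d))
  expect_true(all(d >= 0))
  # identical sequences: d = sum over subset of (max - diagonal score)
  sm <- blosum62()
  aln2 <- DomainAlignment(c("x", "y"), c("AR", "AR"), family = c("f1", "f2"))
  d2 <- blosumDistanceMatrix(aln2, 1:2)
  expect_equal(d2["x", "y"],
               (max(sm) - sm["A", "A"]) + (max(sm) - sm["R", "R"]))
  # gap pairs are scored at the matrix minimum
  aln3 <- DomainAlignment(c("x", "y"), c("A-", "AR"), family = c("f1", "f2"))
  expect_equal(blosumDistanceMatrix(aln3, 1:2)["x", "y"],
               (max(sm) - sm["A", "A"]) + (max(sm) - min(sm)))
})

test_that("neighbor joining recovers generating trees on additive distances", {
  # 4-taxon tree with known branch lengths -> additive matrix -> exact recovery
  set.seed(21)
  for (n in c(4, 5)) {
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.5, 2)
    dm <- cophenetic(true)
    rec <- buildDendrogram(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(as.vector(cophenetic(rec)[rownames(dm), colnames(dm)])),
                 sort(as.vector(dm)), tolerance = 1e-9)
  }

  # 3 taxa: unique topology, branch lengths solve the three-point equations
  d12 <- 3; d13 <- 5; d23 <- 6
  dm3 <- matrix(c(0, d12, d13, d12, 0, d23, d13, d23, 0), 3,
                dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tr3 <- buildDendrogram(dm3)
  a <- (d12 + d13 - d23) / 2
  b <- (d12 + d23 - d13) / 2
  cc <- (d13 + d23 - d12) / 2
  tip <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                  tr3$tip.label)
  expect_equal(unname(tip[c("t1", "t2", "t3")]), c(a, b, cc))

  # Newick round trip preserves topology
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr3, f)
  expect_equal(ape::dist.topo(ape::read.tree(f), tr3), 0, ignore_attr = TRUE)

  expect_error(buildDendrogram(matrix(0, 2, 2)), ">= 3 taxa")
})

test_that("NJ agrees with a least-squares scan over all 5-taxon topologies", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  true <- ape::rtree(5)
  true$edge.length <- runif(nrow(true$edge), 0.5, 2)
  dm <- cophenetic(true)
  rec <- buildDendrogram(dm)
  # brute-force oracle: score every unrooted 5-taxon topology by its
  # least-squares fit to the distances; the best must match NJ's topology
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = rownames(dm))
  ss <- vapply(all5, function(tp) {
    fit <- phangorn::nnls.tree(dm, tp, method = "unrooted")
    sum((cophenetic(fit)[rownames(dm), colnames(dm)] - dm)^2)
  }, 0)
  bestTopo <- all5[[which.min(ss)]]
  expect_equal(ape::dist.topo(bestTopo, rec), 0, ignore_attr = TRUE)
})
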