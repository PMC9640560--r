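featureTable <- function() readReport(tpmtExample("relative_score_features"))

test_that("distances to amyloid regions follow boundary arithmetic", {
  expect_equal(nearestRegionDistance(150), 1L)   # one past 147-149
  expect_equal(nearestRegionDistance(c(89, 182)), c(0L, 0L))  # inside
  expect_equal(nearestRegionDistance(33), 31L)   # to the 64-69 interval
  expect_equal(nearestRegionDistance(64), 0L)    # interval start
  expect_equal(nearestRegionDistance(63), 1L)
  regions <- IRanges::IRanges(start = 10, end = 20)
  expect_equal(nearestRegionDistance(c(5, 10, 15, 20, 25), regions),
               c(5L, 0L, 0L, 0L, 5L))
  expect_error(nearestRegionDistance(5, IRanges::IRanges()), "non-empty")
})

test_that("binding energies re-baseline against the wild type", {
  be <- readReport(tpmtExample("binding_energy"))
  wt <- be$binding_energy[be$system == "WT-SAH"]
  mut <- setNames(be$binding_energy[be$system != "WT-SAH"],
                  be$system[be$system != "WT-SAH"])
  delta <- bindingEnergyScore(mut, wt)
  expect_equal(delta[["W33G"]], 154.58)
  expect_equal(delta[["L182P"]], 36.53)
  expect_true(all(delta > 0))  # every mutant binds worse than wild type
  expect_equal(bindingEnergyScore(c(X = wt), wt)[["X"]], 0)
  expect_error(bindingEnergyScore(mut), "wild-type reference")
  expect_error(bindingEnergyScore(mut, NA_real_), "wild-type reference")
})

test_that("cumulative oncogenic scores sum the two coding p-scores", {
  onc <- cumulativeOncogenicScore(readReport(tpmtExample("oncogenic_scores")))
  expect_equal(onc[["W33G"]], 0.898663 + 0.907987)
  expect_equal(which.max(onc), c(W33G = 1L))
})

test_that("the oncogenic category reproduces the worked relative score", {
  onc <- cumulativeOncogenicScore(readReport(tpmtExample("oncogenic_scores")))
  feats <- data.frame(mutation = names(onc), category = "ONCOGENIC",
                      value = unname(onc), direction = "HIGHER_WORSE")
  rel <- relativeCategoryScores(feats)
  expect_equal(rel["W33G", "ONCOGENIC"], 100)
  expect_equal(rel["W78R", "ONCOGENIC"], 83.942, tolerance = 0.001)
})

test_that("proximity categories invert the normalised distance", {
  feats <- data.frame(mutation = c("V89E", "W150G", "W33G"),
                      category = "AFR_DIST",
                      value = c(0, 1, 31), direction = "PROXIMITY")
  rel <- relativeCategoryScores(feats)[, "AFR_DIST"]
  expect_equal(unname(rel), c(100, 100 - 100 / 31, 0), tolerance = 1e-12)
  expect_equal(unname(round(rel, 2)), c(100, 96.77, 0))
})

test_that("relative scores are scale and permutation invariant", {
  feats <- featureTable()
  base <- relativeCategoryScores(feats)
  scaled <- feats
  hw <- scaled$direction == "HIGHER_WORSE"
  scaled$value[hw] <- as.numeric(scaled$value[hw]) * 7.5
  expect_equal(relativeCategoryScores(scaled)[, colnames(base)], base)
  set.seed(5)
  shuffled <- feats[sample(nrow(feats)), ]
  perm <- relativeCategoryScores(shuffled)
  expect_equal(perm[rownames(base), colnames(base)], base)
  expect_equal(totalScore(perm)[rownames(base), "Total"],
               totalScore(base)[, "Total"])
})

test_that("raising a non-maximal raw value never lowers its scores", {
  feats <- featureTable()
  base <- totalScore(relativeCategoryScores(feats))
  bumped <- feats
  i <- which(bumped$mutation == "W78R" & bumped$category == "MDS")
  bumped$value[i] <- as.numeric(bumped$value[i]) + 5  # still below the max
  res <- totalScore(relativeCategoryScores(bumped))
  expect_gte(res["W78R", "MDS"], base["W78R", "MDS"])
  expect_gte(res["W78R", "Total"], base["W78R", "Total"])
})

test_that("degenerate categories are handled as contracts promise", {
  neg <- data.frame(mutation = c("A", "B"), category = "MDS",
                    value = c(-1, 3), direction = "HIGHER_WORSE")
  expect_error(relativeCategoryScores(neg), "re-baseline")
  zero <- data.frame(mutation = c("A", "B"), category = "BPI",
                     value = c(0, 0), direction = "HIGHER_WORSE")
  expect_warning(rel <- relativeCategoryScores(zero), "all values zero")
  expect_equal(unname(rel[, "BPI"]), c(0, 0))
  allInside <- data.frame(mutation = c("A", "B"), category = "AFR_DIST",
                          value = c(0, 0), direction = "PROXIMITY")
  expect_equal(unname(relativeCategoryScores(allInside)[, "AFR_DIST"]),
               c(100, 100))
  partial <- data.frame(mutation = c("A", "B", "A"),
                        category = c("SQBT", "SQBT", "MDS"),
                        value = c(1, 2, 3),
                        direction = "HIGHER_WORSE")
  expect_message(rel <- relativeCategoryScores(partial), "skipping")
  expect_equal(colnames(rel), "SQBT")
})

test_that("each category tops out at exactly 100 and Total is unique", {
  feats <- featureTable()
  m <- relativeScoreMatrix(feats)
  expect_true(all(m >= 0 & m <= 100))
  # worth-normalised categories reach 100 exactly at their maximum; a
  # proximity category reaches 100 exactly when some mutation sits at
  # distance zero
  hw <- unique(feats$category[feats$direction == "HIGHER_WORSE"])
  expect_true(all(apply(m[, c(hw, "Total"), drop = FALSE], 2, max) == 100))
  expect_equal(max(m[, "AFR_DIST"]), 100)  # V89E and L182P at distance 0
  prox <- unique(feats$category[feats$direction == "PROXIMITY"])
  for (cat in prox) {
    vals <- feats[feats$category == cat, ]
    nearest <- vals$mutation[which.min(as.numeric(vals$value))]
    expect_equal(unname(m[nearest, cat]), max(m[, cat]))
  }
  expect_equal(sum(m[, "Total"] == 100), 1L)
})

test_that("the feature table orders the five candidates as published", {
  m <- relativeScoreMatrix(featureTable())
  expect_equal(rownames(m), c("W33G", "W150G", "V89E", "L182P", "W78R"))
  expect_equal(m["W33G", "Total"], 100)
})

test_that("ties at the maximum all score 100", {
  feats <- data.frame(mutation = rep(c("A", "B"), 2),
                      category = rep(c("SQBT", "MDS"), each = 2),
                      value = c(4, 4, 2, 2), direction = "HIGHER_WORSE")
  m <- totalScore(relativeCategoryScores(feats))
  expect_equal(unname(m[, "Total"]), c(100, 100))
  single <- data.frame(mutation = "A", category = "SQBT", value = 3,
                       direction = "HIGHER_WORSE")
  expect_equal(unname(totalScore(relativeCategoryScores(single))[, "Total"]),
               100)
})

test_that("fixture feature values agree with their upstream sources", {
  feats <- featureTable()
  val <- function(mut, cat) {
    as.numeric(feats$value[feats$mutation == mut & feats$category == cat])
  }
  # stage votes (discovery mode) feed SQBT / SRBT
  res <- runScreening(candidateSeqMatrix(), candidateStructMatrix())
  for (mut in c("W33G", "W78R", "V89E", "W150G", "L182P")) {
    expect_equal(val(mut, "SQBT"), res[mut, "seqVote"])
    expect_equal(val(mut, "SRBT"), res[mut, "structVote"])
  }
  # oncogenic sums feed ONCOGENIC
  onc <- cumulativeOncogenicScore(readReport(tpmtExample("oncogenic_scores")))
  for (mut in names(onc)) {
    expect_equal(val(mut, "ONCOGENIC"), unname(onc[mut]), tolerance = 1e-6)
  }
  # re-baselined binding energies feed MDS
  be <- readReport(tpmtExample("binding_energy"))
  wt <- be$binding_energy[be$system == "WT-SAH"]
  for (mut in c("W33G", "L182P")) {
    expect_equal(val(mut, "MDS"),
                 bindingEnergyScore(
                   be$binding_energy[be$system == mut], wt))
  }
  # amyloid distances feed AFR_DIST
  pos <- variantPosition(parseSubstitution(c("W33G", "W78R", "V89E",
                                             "W150G", "L182P")))
  expect_equal(vapply(c("W33G", "W78R", "V89E", "W150G", "L182P"),
                      val, 0, cat = "AFR_DIST"),
               setNames(as.numeric(nearestRegionDistance(pos)),
                        c("W33G", "W78R", "V89E", "W150G", "L182P")))
  # conservation components sum to the CONSERVATION raw values
  cons <- readReport(tpmtExample("conservation_components"))
  for (i in seq_len(nrow(cons))) {
    expect_equal(val(cons$variant[i], "CONSERVATION"),
                 cons$consurf_color[i] + cons$msa_count[i] +
                   cons$cdd_count[i])
  }
})
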