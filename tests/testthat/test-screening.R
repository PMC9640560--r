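test_that("stage-1 votes count damaging-family calls out of the panel", {
  pm <- candidateSeqMatrix()
  s1 <- stage1Vote(pm)
  expect_equal(s1["W33G", "vote"], 12L)
  expect_true(s1["W33G", "pass"])
  # nine of twelve printed damaging-family labels
  expect_equal(s1["F66I", "vote"], 9L)
  expect_true(s1["F66I", "pass"])
})

test_that("an all-neutral or non-evaluable sequence row cannot pass", {
  raw <- matrix("Neutral", 1, 12,
                dimnames = list("L49S",
                                defaultToolRegistry()$name[1:12]))
  s1 <- stage1Vote(matrixFromRaw(raw, "SEQUENCE"))
  expect_equal(s1$vote, 0L)
  expect_false(s1$pass)
  raw[] <- NA_character_
  s1 <- stage1Vote(matrixFromRaw(raw, "SEQUENCE"))
  expect_false(s1$evaluable)
  expect_false(s1$pass)
})

test_that("strict mode demands strong calls from the MuSiC trio", {
  tools <- defaultToolRegistry()
  structTools <- tools$name[tools$category == "STRUCTURE"]
  raw <- matrix(c(rep("Destabilizing", 4), "Decrease",
                  "Decrease", "Decrease", "Decrease"), 1, 8,
                dimnames = list("L49S", structTools))
  pm <- matrixFromRaw(raw, "STRUCTURE")
  strict <- stage2Vote(pm, screeningConfig(musicMode = "strict"))
  lenient <- stage2Vote(pm, screeningConfig(musicMode = "lenient"))
  expect_equal(strict$vote, 5L)
  expect_false(strict$pass)
  expect_equal(lenient$vote, 8L)
  expect_true(lenient$pass)
})

test_that("strict stage-2 votes on the candidate table match the encoding", {
  s2 <- stage2Vote(candidateStructMatrix(),
                   screeningConfig(musicMode = "strict"))
  expect_equal(s2["W33G", "vote"], 8L)
  expect_true(all(s2$pass))
  votes <- setNames(s2$vote, s2$variant)
  expect_equal(votes[c("W78R", "V89E", "W150G", "L182P", "Y240S")],
               c(W78R = 6L, V89E = 7L, W150G = 8L, Y240S = 6L,
                 L182P = 7L)[c("W78R", "V89E", "W150G", "L182P", "Y240S")])
})

test_that("an all-UNKNOWN structural panel is non-evaluable", {
  s2 <- stage2Vote(goldStructMatrix(), screeningConfig())
  expect_false(s2["M1V", "evaluable"])
  expect_false(s2["M1V", "pass"])
})

test_that("the discovery screen finds six passers and five novel variants", {
  res <- runScreening(candidateSeqMatrix(), candidateStructMatrix())
  expect_equal(sum(res$stage1Pass), 53L)
  expect_equal(sum(res$stage2Pass), 6L)
  expect_equal(res$variant[res$stage2Pass],
               c("W33G", "W78R", "V89E", "W150G", "L182P", "Y240S"))
  expect_equal(res$variant[res$novel],
               c("W33G", "W78R", "V89E", "W150G", "L182P"))
  # deterministic ordering by position
  expect_false(is.unsorted(res$position))
})

test_that("the novelty filter is driven by the known-deleterious set", {
  res <- runScreening(candidateSeqMatrix(), candidateStructMatrix(),
                      screeningConfig(knownDeleterious = character()))
  expect_equal(sum(res$novel), 6L)
})

test_that("a vote threshold above the panel size empties the pass set", {
  res <- runScreening(candidateSeqMatrix(), candidateStructMatrix(),
                      screeningConfig(kSeq = 13L))
  expect_equal(sum(res$stage1Pass), 0L)
  expect_equal(sum(res$stage2Pass), 0L)
})

test_that("structural-only variants trigger a warning and fail stage 1", {
  seqPm <- candidateSeqMatrix()[1:10, ]
  expect_warning(res <- runScreening(seqPm, candidateStructMatrix()),
                 "structural matrix but not")
  expect_false("Y240S" %in% res$variant[res$stage2Pass])
})

test_that("stage votes agree with the brute-force oracle", {
  registry <- defaultToolRegistry()
  strongTools <- registry$name[registry$strongCallSupported]
  set.seed(42)
  for (rep in 1:5) {
    raw <- randomCallMatrix(20, "STRUCTURE")
    pm <- matrixFromRaw(raw, "STRUCTURE")
    calls <- callMatrix(pm)
    for (mode in c("strict", "lenient")) {
      got <- stage2Vote(pm, screeningConfig(musicMode = mode))
      want <- vapply(rownames(calls), function(v) {
        oracleVote(as.list(setNames(calls[v, ], colnames(calls))),
                   strongTools, strict = mode == "strict")
      }, integer(1))
      expect_equal(setNames(got$vote, got$variant), want)
    }
    rawSeq <- randomCallMatrix(20, "SEQUENCE")
    pmSeq <- matrixFromRaw(rawSeq, "SEQUENCE")
    callsSeq <- callMatrix(pmSeq)
    got <- stage1Vote(pmSeq)
    want <- vapply(rownames(callsSeq), function(v) {
      oracleVote(as.list(setNames(callsSeq[v, ], colnames(callsSeq))))
    }, integer(1))
    expect_equal(setNames(got$vote, got$variant), want)
  }
})

test_that("upgrading a single call never decreases a vote", {
  set.seed(7)
  for (rep in 1:5) {
    raw <- randomCallMatrix(10, "STRUCTURE")
    pm <- matrixFromRaw(raw, "STRUCTURE")
    i <- sample(nrow(raw), 1)
    j <- sample(ncol(raw), 1)
    sev <- match(raw[i, j], severityLabel)
    if (sev == 3L) next
    upgraded <- raw
    upgraded[i, j] <- severityLabel[sev + 1L]
    pmUp <- matrixFromRaw(upgraded, "STRUCTURE")
    for (mode in c("strict", "lenient")) {
      cfg <- screeningConfig(musicMode = mode)
      expect_true(all(stage2Vote(pmUp, cfg)$vote >=
                        stage2Vote(pm, cfg)$vote))
    }
  }
})

test_that("raising the vote threshold never enlarges the pass set", {
  set.seed(13)
  raw <- randomCallMatrix(30, "STRUCTURE")
  pm <- matrixFromRaw(raw, "STRUCTURE")
  prev <- rownames(raw)
  for (k in 1:8) {
    s2 <- stage2Vote(pm, screeningConfig(kStruct = k))
    cur <- s2$variant[s2$pass]
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the strict pass set is contained in the lenient pass set", {
  set.seed(99)
  for (rep in 1:5) {
    raw <- randomCallMatrix(25, "STRUCTURE")
    pm <- matrixFromRaw(raw, "STRUCTURE")
    s2s <- stage2Vote(pm, screeningConfig(musicMode = "strict"))
    s2l <- stage2Vote(pm, screeningConfig(musicMode = "lenient"))
    strictPass <- s2s$variant[s2s$pass]
    lenientPass <- s2l$variant[s2l$pass]
    expect_true(all(strictPass %in% lenientPass))
  }
})
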