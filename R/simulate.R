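## Synthetic predictor panels: conditionally independent tool errors around
## a latent deleterious/benign truth label, with Gaussian score emission for
## the score-valued MuSiC tools. Together with the exact Poisson-binomial
## vote-tail oracle this makes every screening stage testable without any
## real predictor output.

#' Default truth-conditional score models
#'
#' Two-component Gaussian emission models for the score-valued MuSiC tools:
#' per truth state a mean and standard deviation on the tool's native scale
#' (ddG in kcal/mol for PoPMuSiC, dTm in degC for HoTMuSiC, the SNPMuSiC
#' deleteriousness index). Defaults place truly deleterious variants well
#' into the destabilising tail (roughly 95% destabilising calls, with a
#' 16-60% strong-call rate depending on the tool) and benign variants near
#' but mostly on the stable side of the call cutoff (roughly 10% false
#' destabilising calls), mimicking the accuracy usually reported for
#' stability predictors.
#'
#' @return Named list with per-tool `del = c(mean, sd)` and
#'   `ben = c(mean, sd)`.
#' @export
defaultScoreModels <- function() {
  list(
    "PoPMuSiC" = list(del = c(mean = 2.5, sd = 1.5),
                      ben = c(mean = -1.3, sd = 1.0)),
    "HoTMuSiC" = list(del = c(mean = -8, sd = 4),
                      ben = c(mean = 2.5, sd = 2.0)),
    "SNPMuSiC" = list(del = c(mean = 1.2, sd = 0.8),
                      ben = c(mean = -0.8, sd = 0.6)))
}

#' Configure a synthetic predictor panel
#'
#' Study conditions for [simulatePredictions()]: panel composition from the
#' registry, prevalence of truly deleterious variants, per-tool sensitivity
#' and specificity for label-valued tools, Gaussian emission models for
#' score-valued tools, a per-cell missingness rate, and an optional
#' common-latent-factor correlation between label tools (0 = conditional
#' independence, the assumption behind the consensus rationale).
#'
#' @param nVariants Number of variants to simulate.
#' @param prevalence Proportion of truly deleterious variants in (0, 1);
#'   the degenerate values 0 and 1 are allowed with a warning.
#' @param sensitivity,specificity Scalar or per-tool named vector of label
#'   call probabilities given the truth state.
#' @param scoreModels See [defaultScoreModels()].
#' @param missingRate Per-cell probability of a missing prediction.
#' @param correlation Latent-factor correlation in \[0, 1) between label
#'   tools given truth.
#' @param seed Optional integer seed; a fixed seed makes
#'   [simulatePredictions()] fully reproducible.
#' @param registry Tool registry, see [defaultToolRegistry()].
#' @return A list of class `"SyntheticConfig"`.
#' @examples
#' syntheticConfig(nVariants = 100, prevalence = 0.3, seed = 1)
#' @export
syntheticConfig <- function(nVariants = 1000L, prevalence = 0.3,
                            sensitivity = 0.9, specificity = 0.9,
                            scoreModels = defaultScoreModels(),
                            missingRate = 0, correlation = 0, seed = NULL,
                            registry = defaultToolRegistry()) {
  .checkRegistry(registry)
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (prevalence %in% c(0, 1)) {
    warning("degenerate prevalence ", prevalence,
            ": one truth class is empty", call. = FALSE)
  }
  labelTools <- registry$name[!registry$name %in% names(scoreModels)]
  se <- if (length(sensitivity) == 1L) {
    stats::setNames(rep(sensitivity, length(labelTools)), labelTools)
  } else sensitivity[labelTools]
  sp <- if (length(specificity) == 1L) {
    stats::setNames(rep(specificity, length(labelTools)), labelTools)
  } else specificity[labelTools]
  if (anyNA(se) || anyNA(sp) || any(se <= 0 | se > 1 | sp <= 0 | sp > 1)) {
    stop("sensitivities and specificities must be in (0, 1] for every ",
         "label tool")
  }
  if (missingRate < 0 || missingRate >= 1) {
    stop("missingRate must be in [0, 1)")
  }
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must be in [0, 1)")
  }
  structure(list(nVariants = as.integer(nVariants),
                 prevalence = prevalence, sensitivity = se,
                 specificity = sp, scoreModels = scoreModels,
                 missingRate = missingRate, correlation = correlation,
                 seed = seed, registry = registry),
            class = "SyntheticConfig")
}

## Unique, parseable substitution labels: decode sampled indices over the
## (position, ref, alt) grid of the TPMT sequence.
.syntheticVariants <- function(n) {
  total <- tpmtLength() * 20L * 19L
  if (n > total) {
    stop("at most ", total, " distinct substitutions are available")
  }
  k <- sample.int(total, n) - 1L
  pos <- (k %% tpmtLength()) + 1L
  rest <- k %/% tpmtLength()
  refI <- (rest %% 20L) + 1L
  altI <- (rest %/% 20L) + 1L
  alt <- vapply(seq_len(n), function(i) .AA1[-refI[i]][altI[i]], "")
  paste0(.AA1[refI], pos, alt)
}

#' Simulate a predictor panel with known truth
#'
#' Draws a latent deleterious/benign label per variant, then emits per-tool
#' predictions conditionally on the truth: label tools call `"Deleterious"`
#' with probability `sensitivity` (truth deleterious) or `1 - specificity`
#' (truth benign), score tools draw from their truth-conditional Gaussian
#' and are left raw for [harmonizeScore()], and cells go missing at the
#' configured rate. With a fixed `seed` the output is fully reproducible.
#'
#' @param config A `SyntheticConfig`, see [syntheticConfig()].
#' @return A list with `truth` (`data.frame` of `variant`, `deleterious`)
#'   and long-form prediction tables `seq` and `struct` ready for
#'   [buildPredictionMatrix()].
#' @examples
#' sim <- simulatePredictions(syntheticConfig(nVariants = 50, seed = 1))
#' head(sim$truth)
#' @export
simulatePredictions <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$nVariants
  variants <- .syntheticVariants(n)
  truth <- stats::rbinom(n, 1L, config$prevalence)
  u <- stats::rnorm(n)  # common latent factor
  rho <- config$correlation
  registry <- config$registry
  emit <- function(tools) {
    cells <- lapply(tools, function(tl) {
      if (tl %in% names(config$scoreModels)) {
        mdl <- config$scoreModels[[tl]]
        pars <- rbind(mdl$ben, mdl$del)[truth + 1L, , drop = FALSE]
        raw <- as.character(signif(stats::rnorm(n, pars[, 1L], pars[, 2L]),
                                   6L))
      } else {
        p <- ifelse(truth == 1L, config$sensitivity[tl],
                    1 - config$specificity[tl])
        x <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
        raw <- ifelse(x <= stats::qnorm(p), "Deleterious", "Neutral")
      }
      missing <- stats::runif(n) < config$missingRate
      raw[missing] <- NA_character_
      data.frame(rsid = NA_character_, variant = variants, tool = tl,
                 raw = raw, missing = missing, stringsAsFactors = FALSE)
    })
    do.call(rbind, cells)
  }
  seqTools <- registry$name[registry$category == "SEQUENCE"]
  structTools <- registry$name[registry$category == "STRUCTURE"]
  list(truth = data.frame(variant = variants,
                          deleterious = truth == 1L,
                          stringsAsFactors = FALSE),
       seq = emit(seqTools), struct = emit(structTools))
}

#' Exact k-of-n vote probability (Poisson-binomial tail)
#'
#' Probability that at least `k` of `n` independent, non-identical
#' Bernoulli trials succeed, computed exactly by dynamic-programming
#' convolution over the per-tool success probabilities. Reduces to the
#' binomial tail when all probabilities are equal.
#'
#' @param p Numeric vector of per-tool success probabilities in \[0, 1\].
#' @param k Vote threshold.
#' @return The tail probability `P(successes >= k)`.
#' @examples
#' consensusOperatingPoint(rep(0.5, 12), 9)  # 299/4096
#' @export
consensusOperatingPoint <- function(p, k) {
  if (any(p < 0 | p > 1) || anyNA(p)) stop("probabilities must be in [0, 1]")
  n <- length(p)
  if (k > n) stop("vote threshold k = ", k, " exceeds panel size n = ", n)
  if (k <= 0L) return(1)
  f <- 1  # distribution of the running success count
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  sum(f[(k + 1L):(n + 1L)])
}

## Per-tool probability of contributing a stage vote, given the truth state.
.voteProbabilities <- function(config, screenCfg, category, truth) {
  registry <- config$registry
  tools <- registry$name[registry$category == category]
  strict <- category == "STRUCTURE" && screenCfg@musicMode == "strict"
  rules <- defaultScoreRules()
  p <- vapply(tools, function(tl) {
    if (tl %in% names(config$scoreModels)) {
      mdl <- config$scoreModels[[tl]]
      pars <- if (truth) mdl$del else mdl$ben
      rule <- rules[[tl]]
      strong <- strict && registry$strongCallSupported[registry$name == tl]
      cutoff <- if (strong) rule$strongCutoff else rule$delCutoff
      if (rule$direction == "HIGHER_WORSE") {
        stats::pnorm(cutoff, pars["mean"], pars["sd"], lower.tail = FALSE)
      } else {
        stats::pnorm(cutoff, pars["mean"], pars["sd"])
      }
    } else if (truth) {
      config$sensitivity[[tl]]
    } else {
      1 - config$specificity[[tl]]
    }
  }, numeric(1))
  p * (1 - config$missingRate)
}

#' Analytic operating characteristics of the consensus screen
#'
#' Exact per-stage and two-stage pass probabilities of the screen under a
#' synthetic panel configuration, conditional on the truth state: each
#' tool's vote probability is derived from its sensitivity/specificity (or
#' its Gaussian score model and threshold rule, honouring strict-mode
#' strong calls), and the k-of-n tail is evaluated with the exact
#' Poisson-binomial convolution. Conditional independence of tools given
#' truth makes the two-stage probability the product of the stage
#' probabilities; a non-zero `correlation` in the config breaks this and
#' triggers a warning.
#'
#' @param config A `SyntheticConfig`.
#' @param screenCfg A [ScreeningConfig-class].
#' @return A list with `stage1`, `stage2`, `overall`, each a named vector
#'   `c(sensitivity =, fpr =)`.
#' @examples
#' operatingCharacteristics(syntheticConfig(nVariants = 10))$overall
#' @export
operatingCharacteristics <- function(config,
                                     screenCfg = screeningConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$correlation > 0) {
    warning("analytic operating points assume conditionally independent ",
            "tools; config has correlation > 0", call. = FALSE)
  }
  point <- function(category, k, truth) {
    consensusOperatingPoint(
      .voteProbabilities(config, screenCfg, category, truth), k)
  }
  s1 <- c(sensitivity = point("SEQUENCE", screenCfg@kSeq, TRUE),
          fpr = point("SEQUENCE", screenCfg@kSeq, FALSE))
  s2 <- c(sensitivity = point("STRUCTURE", screenCfg@kStruct, TRUE),
          fpr = point("STRUCTURE", screenCfg@kStruct, FALSE))
  list(stage1 = s1, stage2 = s2, overall = s1 * s2)
}
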