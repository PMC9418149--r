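# Tajima's D, Fu's Fs, and the neutral infinite-sites coalescent simulator
# used to calibrate their significance.

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard constants
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1*n) + a2/a1^2`,
#' `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n sample size (>= 4).
#' @param S number of segregating sites.
#' @param meanPairwiseDiff mean number of pairwise differences per locus
#'   (`k`, not per site).
#' @return list `D` (NA when `S == 0`), `computable` (logical), plus the
#'   inputs. With no segregating sites the statistic is undefined and is
#'   returned flagged rather than as 0.
#' @export
tajimasD <- function(n, S, meanPairwiseDiff) {
  stopifnot(n >= 4)
  if (S == 0)
    return(list(D = NA_real_, computable = FALSE, n = n, S = S,
                meanPairwiseDiff = meanPairwiseDiff))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (meanPairwiseDiff - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, computable = TRUE, n = n, S = S,
       meanPairwiseDiff = meanPairwiseDiff)
}

.stirlingCache <- new.env(parent = emptyenv())

# log unsigned Stirling numbers of the first kind, |s(n, k)| for k = 1..n,
# by the recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| carried in log space
# (log-sum-exp), stable for n in the hundreds. Cached per n: the neutrality
# p-value simulation evaluates Fs thousands of times at one n.
logStirlingFirst <- function(n) {
  key <- as.character(n)
  hit <- .stirlingCache[[key]]
  if (!is.null(hit)) return(hit)
  cur <- 0                            # n = 1: |s(1,1)| = 1
  if (n == 1L) return(cur)
  for (m in 1L:(n - 1L)) {
    prev <- c(cur, -Inf)            # k = 1..m+1, |s(m, m+1)| = 0
    shifted <- c(-Inf, cur)         # |s(m, k-1)|
    a <- log(m) + prev
    big <- pmax(a, shifted)
    cur <- big + log1p(exp(pmin(a, shifted) - big))
    cur[is.nan(cur)] <- -Inf
    cur[1L] <- log(m) + prev[1L]    # no k-1 term for k = 1
    cur[m + 1L] <- 0                # |s(n, n)| = 1
  }
  .stirlingCache[[key]] <- cur
  cur
}

# Vectorized Tajima's D over replicate (S, meanPairwiseDiff) vectors at
# fixed n; NA where S = 0.
.tajimaDvec <- function(n, S, k) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  out <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  out[S == 0] <- NA_real_
  out
}

#' Ewens distribution of the number of haplotypes
#'
#' `P(K = k | n, theta) = |s(n,k)| theta^k / theta_(n)` with `theta_(n)` the
#' rising factorial, computed in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (per locus).
#' @return numeric vector of probabilities for `k = 1..n`.
#' @export
ewensK <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- logStirlingFirst(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp - max(logp)) / sum(exp(logp - max(logp)))
}

#' Fu's Fs
#'
#' `S' = P(K >= k_obs | theta = theta_pi)` under the Ewens sampling
#' distribution, and `Fs = ln(S' / (1 - S'))`. `theta_pi` is the pairwise
#' difference estimate of theta (mean pairwise differences per locus), Fu's
#' prescription for this statistic.
#'
#' @param n sample size (>= 2).
#' @param thetaPi per-locus theta estimate (> 0).
#' @param kObs observed number of distinct haplotypes (1..n).
#' @return list `Fs`, `Sprime`, `computable`; `Fs` is `+Inf` when
#'   `k_obs = 1` (the event `K >= 1` is certain) and `-Inf` when `S'`
#'   underflows, both flagged via `computable = FALSE`.
#' @export
fusFs <- function(n, thetaPi, kObs) {
  stopifnot(n >= 2, kObs >= 1, kObs <= n)
  if (thetaPi <= 0)
    return(list(Fs = NA_real_, Sprime = NA_real_, computable = FALSE))
  if (kObs == 1L) {
    # K >= 1 is certain: the logit diverges
    return(list(Fs = Inf, Sprime = 1, computable = FALSE))
  }
  p <- ewensK(n, thetaPi)
  Sp <- sum(p[kObs:n])
  if (Sp >= 1) {
    # K >= 1 is certain (or the complement underflows): logit diverges
    return(list(Fs = Inf, Sprime = 1, computable = FALSE))
  }
  if (Sp <= 0)
    return(list(Fs = -Inf, Sprime = 0, computable = FALSE))
  list(Fs = log(Sp / (1 - Sp)), Sprime = Sp, computable = TRUE)
}

#' Simulate one sample under the neutral infinite-sites coalescent
#'
#' Standard n-coalescent: while `k` lineages remain, an exponential waiting
#' time with rate `k(k-1)/2` (coalescent units) elapses and a uniformly
#' chosen pair merges. Mutations fall on each branch as Poisson(theta/2 x
#' branch length), each hitting a fresh site (infinite sites). Sites are
#' reported as distinct integer positions 1..S in order of appearance.
#'
#' @param n sample size (>= 2).
#' @param theta per-locus scaled mutation rate (>= 0).
#' @param seed optional integer seed (private RNG stream).
#' @return list with `genotypes` (n x S 0/1 matrix; 1 = derived),
#'   `S`, `meanPairwiseDiff`, `k` (number of distinct haplotypes),
#'   `tmrca` (coalescent units), `totalTime` (total branch length),
#'   `mutations` (list of tip index vectors carrying each mutation).
#' @export
simulateNeutralSample <- function(n, theta, seed = NULL) {
  stopifnot(n >= 2, theta >= 0)
  withSeed(seed, {
    lineages <- as.list(seq_len(n))   # descendant tip sets
    muts <- list()
    tmrca <- 0
    ttot <- 0
    k <- n
    while (k > 1L) {
      t <- rexp(1L, rate = k * (k - 1) / 2)
      tmrca <- tmrca + t
      ttot <- ttot + k * t
      nm <- rpois(k, theta / 2 * t)
      for (j in which(nm > 0L))
        for (r in seq_len(nm[j]))
          muts[[length(muts) + 1L]] <- lineages[[j]]
      pair <- sample.int(k, 2L)
      lineages[[pair[1L]]] <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
      lineages[[pair[2L]]] <- NULL
      k <- k - 1L
    }
    S <- length(muts)
    geno <- matrix(0L, n, S)
    if (S > 0)
      for (s in seq_len(S)) geno[muts[[s]], s] <- 1L
    counts <- colSums(geno)
    kpair <- if (S > 0) sum(counts * (n - counts)) / (n * (n - 1) / 2) else 0
    khap <- if (S > 0) nrow(unique(geno)) else 1L
    list(genotypes = geno, S = S, meanPairwiseDiff = kpair, k = khap,
         tmrca = tmrca, totalTime = ttot, mutations = muts)
  })
}

#' Batch coalescent summary statistics
#'
#' Fast path for significance calibration: simulates `reps` independent
#' neutral infinite-sites samples and returns per-replicate `S`, mean
#' pairwise differences and haplotype count (compiled implementation; the
#' pure-R [simulateNeutralSample()] is retained as the reference
#' implementation and cross-checked in the test suite).
#'
#' @inheritParams simulateNeutralSample
#' @param reps number of replicates.
#' @return data.frame with columns `S`, `meanPairwiseDiff`, `k`.
#' @export
simulateNeutralStats <- function(n, theta, reps, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, reps >= 1)
  m <- withSeed(seed, coal_stats(as.integer(n), as.numeric(theta),
                                 as.integer(reps)))
  data.frame(S = as.integer(m[, 1L]), meanPairwiseDiff = m[, 2L],
             k = as.integer(m[, 3L]))
}

#' Coalescent-calibrated p-values for Tajima's D and Fu's Fs
#'
#' Simulates `nReps` neutral infinite-sites samples at the estimated theta
#' (by default the pairwise estimate `theta_pi` of the observed data, the
#' same estimate Fu's Fs conditions on) and reports one-tailed p-values per
#' sign: for a negative observed statistic, the fraction of replicates at
#' least as negative; for a positive one, at least as positive. Replicates
#' with `S = 0` (where D is undefined) are dropped from the D comparison and
#' counted in `nDroppedD`.
#'
#' @param n sample size.
#' @param S observed segregating sites.
#' @param meanPairwiseDiff observed mean pairwise differences per locus.
#' @param kObs observed haplotype count.
#' @param nReps simulation replicates (>= 1000 recommended).
#' @param seed integer seed; recorded in the result.
#' @param thetaEstimator `"pi"` (default) or `"watterson"` for the null
#'   theta.
#' @return list `D`, `pD`, `Fs`, `pFs`, `theta0`, `nReps`, `seed`,
#'   `nDroppedD`, plus both tails (`pD_low`, `pD_high`, `pFs_low`,
#'   `pFs_high`: fractions of replicates `<=` and `>=` the observed value).
#' @export
neutralityPvalues <- function(n, S, meanPairwiseDiff, kObs, nReps = 1000L,
                              seed = NULL,
                              thetaEstimator = c("pi", "watterson")) {
  thetaEstimator <- match.arg(thetaEstimator)
  a1 <- sum(1 / seq_len(n - 1))
  theta0 <- if (thetaEstimator == "pi") meanPairwiseDiff else S / a1
  Dobs <- tajimasD(n, S, meanPairwiseDiff)
  Fobs <- fusFs(n, meanPairwiseDiff, kObs)
  if (theta0 <= 0)
    return(list(D = Dobs$D, pD = NA_real_, Fs = Fobs$Fs, pFs = NA_real_,
                theta0 = theta0, nReps = 0L, seed = seed, nDroppedD = 0L,
                pD_low = NA_real_, pD_high = NA_real_, pFs_low = NA_real_,
                pFs_high = NA_real_))
  sim <- simulateNeutralStats(n, theta0, nReps, seed = seed)
  ok <- sim$S > 0
  Dsim <- .tajimaDvec(n, sim$S[ok], sim$meanPairwiseDiff[ok])
  Fsim <- vapply(seq_len(nReps), function(i) {
    f <- fusFs(n, max(sim$meanPairwiseDiff[i], .Machine$double.eps),
               sim$k[i])
    f$Fs
  }, 0)
  pD_low <- if (length(Dsim)) mean(Dsim <= Dobs$D) else NA_real_
  pD_high <- if (length(Dsim)) mean(Dsim >= Dobs$D) else NA_real_
  pFs_low <- mean(Fsim <= Fobs$Fs)
  pFs_high <- mean(Fsim >= Fobs$Fs)
  pD <- if (!Dobs$computable) NA_real_
        else if (Dobs$D <= 0) pD_low else pD_high
  pFs <- if (Fobs$Fs <= 0) pFs_low else pFs_high
  list(D = Dobs$D, pD = pD, Fs = Fobs$Fs, pFs = pFs, theta0 = theta0,
       nReps = nReps, seed = seed, nDroppedD = sum(!ok),
       pD_low = pD_low, pD_high = pD_high, pFs_low = pFs_low,
       pFs_high = pFs_high)
}

#' Neutrality tests per population
#'
#' Convenience wrapper: computes observed D and Fs per group of an aligned
#' data set and calibrates both with the internal coalescent simulator.
#'
#' @param aln a [DloopAlignment-class].
#' @param by grouping column of `sampleData(aln)`.
#' @param pooled optional named list of group levels to pool (see
#'   [diversityTable()]).
#' @param nReps simulation replicates per group.
#' @param seed master seed; per-group seeds are derived from it and recorded.
#' @return data.frame `group`, `N`, `S`, `D`, `p_D`, `Fs`, `p_Fs`,
#'   `theta0`, `n_reps`, `seed`.
#' @export
neutralityTest <- function(aln, by = "population", pooled = NULL,
                           nReps = 1000L, seed = NULL) {
  sd0 <- sampleData(aln)
  groups <- split(sd0$sample_id, sd0[[by]])
  if (!is.null(pooled))
    for (nm in names(pooled))
      groups[[nm]] <- sd0$sample_id[sd0[[by]] %in% pooled[[nm]]]
  rows <- lapply(seq_along(groups), function(gi) {
    g <- names(groups)[gi]
    ids <- groups[[gi]]
    if (length(ids) < 4L)
      return(data.frame(group = g, N = length(ids), S = NA_integer_,
                        D = NA_real_, p_D = NA_real_, Fs = NA_real_,
                        p_Fs = NA_real_, theta0 = NA_real_, n_reps = 0L,
                        seed = NA_integer_))
    sub <- aln[ids]
    sc <- classifySites(sub)
    nd <- nucleotideDiversity(sub)
    part <- collapseHaplotypes(sub)
    sg <- childSeed(seed, gi)
    np <- neutralityPvalues(length(ids), sc$S, nd$meanPairwiseDiff,
                            nHaplotypes(part), nReps = nReps, seed = sg)
    data.frame(group = g, N = length(ids), S = sc$S, D = np$D, p_D = np$pD,
               Fs = np$Fs, p_Fs = np$pFs, theta0 = np$theta0,
               n_reps = nReps, seed = if (is.null(sg)) NA_integer_ else sg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
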