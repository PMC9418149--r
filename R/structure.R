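# Distance-based population structure: pairwise Phi-ST with permutation
# tests, hierarchical AMOVA, and PCoA of the fixation-index matrix.

# Sum of pairwise distances within an index set, divided by its size
# (the AMOVA "SSD" for one stratum; d plays the role of squared distance).
.ssd <- function(d, idx) {
  if (length(idx) < 2L) return(0)
  sum(d[idx, idx]) / 2 / length(idx)
}

# Two-level variance decomposition (among populations / within populations)
# from a pairwise-difference matrix and a population factor.
.amova2 <- function(d, pop) {
  N <- length(pop)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  sstot <- sum(d) / 2 / N
  sswp <- sum(vapply(pops, function(ix) .ssd(d, ix), 0))
  ssap <- sstot - sswp
  np <- lengths(pops)
  dfap <- P - 1L
  dfwp <- N - P
  s2w <- sswp / dfwp
  nc <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (ssap / dfap - s2w) / nc
  list(SSa = ssap, SSw = sswp, dfa = dfap, dfw = dfwp,
       sigma2a = s2a, sigma2w = s2w,
       phiST = s2a / (s2a + s2w))
}

#' Pairwise Phi-ST between populations
#'
#' For each population pair, the fixation index is the among-population
#' variance fraction of a two-population AMOVA on the pairwise
#' sequence-difference matrix. Significance comes from permuting individuals
#' between the two populations; the p-value is the fraction of permutations
#' (plus the observed arrangement) with a Phi-ST at least as large. Negative
#' Phi-ST estimates are reported as computed, not truncated.
#'
#' @param aln a [DloopAlignment-class] (or a precomputed list with elements
#'   `d` and population vector via `dist`/`pop` arguments).
#' @param by grouping column of `sampleData(aln)` used as population label.
#' @param nPerm permutations per pair (published convention: 10000).
#' @param seed integer seed for reproducible permutations.
#' @param sitePolicy passed to [seqDistances()].
#' @return list of class `FstResult`: `fst` (symmetric matrix, zero
#'   diagonal), `p` (permutation p-values, `NA` diagonal), `nPerm`, `seed`,
#'   `excluded` (populations with < 2 sequences, dropped with a warning).
#' @export
pairwiseFst <- function(aln, by = "population", nPerm = 10000L, seed = NULL,
                        sitePolicy = "complete") {
  d <- seqDistances(aln, sitePolicy)$d
  pop <- sampleData(aln)[[by]]
  sizes <- table(pop)
  excl <- names(sizes)[sizes < 2L]
  if (length(excl))
    warning("population(s) with < 2 sequences excluded: ",
            paste(excl, collapse = ", "))
  keep <- !(pop %in% excl)
  d <- d[keep, keep, drop = FALSE]
  pop <- pop[keep]
  pops <- sort(unique(pop))
  P <- length(pops)
  if (P < 2L) stop("need at least two populations with >= 2 sequences")
  fst <- matrix(0, P, P, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  withSeed(seed, {
    for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
      ix <- which(pop %in% c(pops[i], pops[j]))
      dp <- d[ix, ix, drop = FALSE]
      pp <- factor(pop[ix])
      obs <- .amova2(dp, pp)
      fst[i, j] <- fst[j, i] <- obs$phiST
      n1 <- sum(pp == pops[i]); npair <- length(ix)
      # Phi-ST is a decreasing function of the within-group SS at fixed
      # sizes, so permutations only need SS within; done in chunks through
      # BLAS for speed.
      sstot <- sum(dp) / 2 / npair
      nc <- (npair - (n1^2 + (npair - n1)^2) / npair)
      ge <- 0L
      left <- nPerm
      while (left > 0L) {
        m <- min(left, 500L)
        Z <- vapply(seq_len(m), function(q) {
          z <- numeric(npair); z[sample.int(npair, n1)] <- 1; z
        }, numeric(npair))
        DZ <- dp %*% Z
        ssw1 <- colSums(Z * DZ) / 2 / n1
        ssw2 <- colSums((1 - Z) * (rowSums(dp) - DZ)) / 2 / (npair - n1)
        sswp <- ssw1 + ssw2
        s2w <- sswp / (npair - 2)
        s2a <- ((sstot - sswp) - s2w) / nc
        phi <- s2a / (s2a + s2w)
        ge <- ge + sum(phi >= obs$phiST - 1e-12)
        left <- left - m
      }
      pmat[i, j] <- pmat[j, i] <- permPvalue(ge, nPerm)
    }
  })
  structure(list(fst = fst, p = pmat, nPerm = nPerm, seed = seed,
                 excluded = excl), class = "FstResult")
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance from the pairwise sequence-difference
#' matrix into among-group, among-population-within-group, and
#' within-population components (sums of squares of the
#' Excoffier-Smouse-Quattro decomposition; mean squares equated to their
#' expectations). With a single group (or `layout = NULL`) the two-level
#' decomposition (among/within populations) is returned. Negative variance
#' components are reported as computed, so percentages can fall outside
#' [0, 100].
#'
#' Permutation schemes follow the level being tested: `Phi_ST` permutes
#' sequences among populations irrespective of groups, `Phi_SC` permutes
#' sequences among populations within their group, and `Phi_CT` permutes
#' whole populations among groups.
#'
#' @param aln a [DloopAlignment-class].
#' @param layout named list: group name -> character vector of population
#'   labels, or `NULL` for no grouping.
#' @param by grouping column of `sampleData(aln)` holding population labels.
#' @param nPerm number of permutations (published convention: 1000).
#' @param seed integer seed.
#' @param sitePolicy passed to [seqDistances()].
#' @return list of class `AmovaResult` with `components` (data.frame:
#'   source, df, SS, sigma2, percent), `phi` (named vector), `p` (named
#'   vector of permutation p-values), `nPerm`, `seed`, `layout`.
#' @export
amova <- function(aln, layout = NULL, by = "population", nPerm = 1000L,
                  seed = NULL, sitePolicy = "complete") {
  d <- seqDistances(aln, sitePolicy)$d
  pop <- as.character(sampleData(aln)[[by]])
  if (length(unique(pop)) < 2L) stop("AMOVA needs at least two populations")
  if (is.null(layout)) layout <- list(all = unique(pop))
  grpOf <- setNames(rep(names(layout), lengths(layout)),
                    unlist(layout, use.names = FALSE))
  if (!all(pop %in% names(grpOf)))
    stop("population(s) missing from layout: ",
         paste(setdiff(pop, names(grpOf)), collapse = ", "))
  grp <- unname(grpOf[pop])
  N <- length(pop)

  if (length(layout) < 2L) {
    obs <- .amova2(d, factor(pop))
    comp <- data.frame(
      source = c("Among populations", "Within populations"),
      df = c(obs$dfa, obs$dfw), SS = c(obs$SSa, obs$SSw),
      sigma2 = c(obs$sigma2a, obs$sigma2w), stringsAsFactors = FALSE)
    comp$percent <- 100 * comp$sigma2 / sum(comp$sigma2)
    phi <- c(Phi_ST = obs$phiST)
    pST <- withSeed(seed, {
      ge <- 0L
      for (q in seq_len(nPerm)) {
        phiP <- .amova2(d, factor(sample(pop)))$phiST
        if (phiP >= obs$phiST - 1e-12) ge <- ge + 1L
      }
      permPvalue(ge, nPerm)
    })
    return(structure(list(components = comp, phi = phi,
                          p = c(Phi_ST = pST), nPerm = nPerm, seed = seed,
                          layout = layout), class = "AmovaResult"))
  }

  fit3 <- function(pop, grp) {
    pops <- split(seq_len(N), pop)
    grps <- split(seq_len(N), grp)
    P <- length(pops); G <- length(grps)
    sstot <- sum(d) / 2 / N
    sswp <- sum(vapply(pops, function(ix) .ssd(d, ix), 0))
    ssg <- sum(vapply(grps, function(ix) .ssd(d, ix), 0))
    ssag <- sstot - ssg                  # among groups
    ssapg <- ssg - sswp                  # among populations within groups
    dfag <- G - 1L; dfapg <- P - G; dfwp <- N - P
    np <- lengths(pops)
    Ng <- lengths(grps)
    popGrp <- vapply(names(pops), function(p) grp[pops[[p]][1L]], "")
    sumNp2overNg <- sum(vapply(names(grps), function(g) {
      sum(np[popGrp == g]^2) / Ng[g]
    }, 0))
    n1 <- (N - sumNp2overNg) / dfapg
    n2 <- (sumNp2overNg - sum(np^2) / N) / dfag
    n3 <- (N - sum(Ng^2) / N) / dfag
    s2c <- sswp / dfwp
    s2b <- (ssapg / dfapg - s2c) / n1
    s2a <- (ssag / dfag - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    list(SS = c(ssag, ssapg, sswp), df = c(dfag, dfapg, dfwp),
         sigma2 = c(s2a, s2b, s2c),
         phi = c(Phi_CT = s2a / tot,
                 Phi_SC = s2b / (s2b + s2c),
                 Phi_ST = (s2a + s2b) / tot))
  }
  obs <- fit3(pop, grp)
  comp <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = obs$df, SS = obs$SS, sigma2 = obs$sigma2, stringsAsFactors = FALSE)
  comp$percent <- 100 * comp$sigma2 / sum(comp$sigma2)

  p <- withSeed(seed, {
    geST <- geSC <- geCT <- 0L
    popLevels <- unique(pop)
    popGrpMap <- grpOf[popLevels]
    for (q in seq_len(nPerm)) {
      # Phi_ST: sequences among populations irrespective of groups
      permPop <- sample(pop)
      permGrp <- unname(grpOf[permPop])
      if (fit3(permPop, permGrp)$phi["Phi_ST"] >=
          obs$phi["Phi_ST"] - 1e-12) geST <- geST + 1L
      # Phi_SC: sequences among populations within groups
      permPop2 <- pop
      for (g in unique(grp)) {
        ing <- which(grp == g)
        permPop2[ing] <- sample(pop[ing])
      }
      if (fit3(permPop2, grp)$phi["Phi_SC"] >=
          obs$phi["Phi_SC"] - 1e-12) geSC <- geSC + 1L
      # Phi_CT: whole populations among groups
      permMap <- setNames(sample(unname(popGrpMap)), popLevels)
      permGrp3 <- unname(permMap[pop])
      if (fit3(pop, permGrp3)$phi["Phi_CT"] >=
          obs$phi["Phi_CT"] - 1e-12) geCT <- geCT + 1L
    }
    c(Phi_CT = permPvalue(geCT, nPerm), Phi_SC = permPvalue(geSC, nPerm),
      Phi_ST = permPvalue(geST, nPerm))
  })
  structure(list(components = comp, phi = obs$phi, p = p, nPerm = nPerm,
                 seed = seed, layout = layout), class = "AmovaResult")
}

#' @export
print.AmovaResult <- function(x, ...) {
  cat("AMOVA (", x$nPerm, "permutations )\n")
  print(transform(x$components, percent = round(percent, 2)))
  cat("Phi statistics:\n")
  print(round(x$phi, 5))
  cat("Permutation p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' @export
print.FstResult <- function(x, ...) {
  cat("Pairwise Phi-ST (", x$nPerm,
      "permutations; upper triangle: p-values )\n")
  m <- x$fst
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 5))
  invisible(x)
}

#' Principal coordinates analysis of a fixation-index matrix
#'
#' Classical (Gower) PCoA: the distance matrix is squared, double-centred,
#' and eigendecomposed; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues, and the percent variation of each axis is its
#' eigenvalue over the sum of positive eigenvalues.
#'
#' @param fst an `FstResult` from [pairwiseFst()], or a symmetric distance
#'   matrix.
#' @return list of class `PcoaResult`: `coordinates` (populations x axes),
#'   `eigenvalues`, `percent`, `cumulative12` (percent variation of axes
#'   1-2), `degenerate` (TRUE when the input matrix is all zero).
#' @export
pcoaFromFst <- function(fst) {
  m <- if (inherits(fst, "FstResult")) fst$fst else as.matrix(fst)
  if (nrow(m) < 3L) stop("PCoA needs at least three populations")
  if (all(abs(m) < 1e-15))
    return(structure(list(coordinates = matrix(0, nrow(m), 1,
                                               dimnames = list(rownames(m),
                                                               "Axis1")),
                          eigenvalues = 0, percent = NA_real_,
                          cumulative12 = NA_real_, degenerate = TRUE),
                     class = "PcoaResult"))
  # negative pairwise estimates are admissible input; centre on their raw
  # values like the source matrix reports them
  n <- nrow(m)
  # k = n - 1 axes are requested and the non-positive tail is filtered
  # afterwards; cmdscale's warning about that tail is expected
  cs <- suppressWarnings(cmdscale(stats::as.dist(m), k = n - 1L,
                                  eig = TRUE))
  ev <- cs$eig
  pos <- ev > 1e-12 * max(abs(ev))
  pct <- ifelse(pos, 100 * ev / sum(ev[pos]), NA_real_)
  coords <- cs$points
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = ev, percent = pct,
                 cumulative12 = sum(pct[1:2], na.rm = TRUE),
                 degenerate = FALSE),
            class = "PcoaResult")
}

#' @export
print.PcoaResult <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("PCoA: degenerate (all-zero distance matrix)\n")
    return(invisible(x))
  }
  cat("PCoA |", nrow(x$coordinates), "populations; axes 1-2 carry",
      sprintf("%.2f%%", x$cumulative12), "of positive-eigenvalue mass\n")
  print(round(x$coordinates[, 1:min(3, ncol(x$coordinates)), drop = FALSE],
              4))
  invisible(x)
}
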