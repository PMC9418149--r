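# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (loops, enumeration, exact
# arithmetic) and share no code with the package implementations.

# ---- global affine-gap aligner (Needleman-Wunsch-Gotoh) -------------------
# match +1, mismatch -1, gap of length g costs 4 + (g - 1) (first position
# 4, each extension 1). Returns the per-reference-position states of one
# optimal alignment (query along reference).
oracleAlign <- function(query, ref) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  open <- 4; ext <- 1
  M <- matrix(NEG, n + 1, m + 1)   # q[i] aligned to r[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in reference (insertion in query)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query (deletion vs reference)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - (i - 1) * ext
  for (j in seq_len(m)) Y[1, j + 1] <- -open - (j - 1) * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (q[i] == r[j]) 1 else -1
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext)
    }
  }
  # traceback from the best of the three end states
  states <- character(m)
  i <- n; j <- m
  lab <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                      Y[n + 1, m + 1]))]
  while (i > 0 || j > 0) {
    if (lab == "M") {
      states[j] <- q[i]
      s <- if (q[i] == r[j]) 1 else -1
      prev <- c(M[i, j], X[i, j], Y[i, j])
      lab <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1; j <- j - 1
    } else if (lab == "X") {        # query base consumed, no ref position
      from <- c(M[i, j + 1] - open, X[i, j + 1] - ext)
      lab <- c("M", "X")[which.max(from)]
      i <- i - 1
    } else {                        # deletion: gap state at this position
      states[j] <- "-"
      from <- c(M[i + 1, j] - open, Y[i + 1, j] - ext)
      lab <- c("M", "Y")[which.max(from)]
      j <- j - 1
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  list(states = states, score = score)
}

# ---- diversity oracles ----------------------------------------------------
# Haplotype diversity by explicit pair counting: probability two distinct
# draws differ, with the n/(n-1) correction applied as (1 - sum p^2) form is
# avoided on purpose.
oracleHd <- function(counts) {
  n <- sum(counts)
  same <- sum(counts * (counts - 1))    # ordered identical pairs
  (1 - same / (n * (n - 1)))
}

# Nucleotide diversity by an explicit double loop over sequence pairs.
oraclePi <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (n * (n - 1) / 2) / L
}

# Tajima's D written straight from the textbook constant definitions,
# independently of the package arrangement.
oracleTajimaD <- function(n, S, khat) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# ---- exact Ewens / Stirling oracle ---------------------------------------
# Unsigned Stirling numbers of the first kind by exact integer recurrence.
# For n <= 12 all values are far below 2^53, so double arithmetic is exact.
oracleStirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1                         # s(0,0) = 1
  for (m in 1:n) {
    for (k in 1:m) {
      s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
    }
  }
  s[n + 1, 2:(n + 1)]                  # |s(n, k)|, k = 1..n
}

oracleEwensTail <- function(n, theta, kObs) {
  st <- oracleStirling(n)
  rising <- prod(theta + 0:(n - 1))
  p <- st * theta^(1:n) / rising
  sum(p[kObs:n])
}

# ---- AMOVA sums-of-squares oracle ----------------------------------------
# Literal translation of the hierarchical decomposition with explicit loops.
oracleAmova <- function(d, pop, grp = NULL) {
  N <- length(pop)
  ssdOf <- function(ids) {
    tot <- 0
    if (length(ids) >= 2)
      for (a in seq_along(ids)) for (b in seq_along(ids))
        if (a < b) tot <- tot + d[ids[a], ids[b]]
    tot / length(ids)
  }
  sstot <- ssdOf(seq_len(N))
  pops <- unique(pop)
  sswp <- 0
  for (p in pops) sswp <- sswp + ssdOf(which(pop == p))
  if (is.null(grp)) {
    P <- length(pops)
    ssap <- sstot - sswp
    s2w <- sswp / (N - P)
    sumn2 <- 0
    for (p in pops) sumn2 <- sumn2 + sum(pop == p)^2
    nc <- (N - sumn2 / N) / (P - 1)
    s2a <- (ssap / (P - 1) - s2w) / nc
    return(list(sigma2 = c(s2a, s2w), phiST = s2a / (s2a + s2w),
                SS = c(ssap, sswp)))
  }
  grps <- unique(grp)
  ssg <- 0
  for (g in grps) ssg <- ssg + ssdOf(which(grp == g))
  ssag <- sstot - ssg
  ssapg <- ssg - sswp
  P <- length(pops); G <- length(grps)
  s2c <- sswp / (N - P)
  term <- 0
  for (g in grps) {
    ing <- which(grp == g)
    for (p in unique(pop[ing])) term <- term + sum(pop == p)^2 / length(ing)
  }
  n1 <- (N - term) / (P - G)
  sumn2 <- 0
  for (p in pops) sumn2 <- sumn2 + sum(pop == p)^2
  n2 <- (term - sumn2 / N) / (G - 1)
  sumNg2 <- 0
  for (g in grps) sumNg2 <- sumNg2 + sum(grp == g)^2
  n3 <- (N - sumNg2 / N) / (G - 1)
  s2b <- (ssapg / (P - G) - s2c) / n1
  s2a <- (ssag / (G - 1) - s2c - n2 * s2b) / n3
  list(sigma2 = c(s2a, s2b, s2c), SS = c(ssag, ssapg, sswp),
       phi = c(CT = s2a / (s2a + s2b + s2c),
               SC = s2b / (s2b + s2c),
               ST = (s2a + s2b) / (s2a + s2b + s2c)))
}

# ---- spanning tree / Steiner oracles -------------------------------------
# Minimum spanning tree length by exhaustive enumeration over all labelled
# spanning trees (Pruefer sequences), practical for <= 6 nodes.
oracleMstLength <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  best <- Inf
  pruefer <- function(seq_) {
    # decode a Pruefer sequence into an edge list
    deg <- rep(1L, n)
    for (x in seq_) deg[x] <- deg[x] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1L
    seq2 <- seq_
    for (x in seq2) {
      leaf <- which(deg == 1L)[1L]
      edges[ptr, ] <- c(leaf, x); ptr <- ptr + 1L
      deg[leaf] <- deg[leaf] - 1L
      deg[x] <- deg[x] - 1L
    }
    last <- which(deg == 1L)
    edges[ptr, ] <- last
    edges
  }
  idx <- rep(1L, n - 2)
  repeat {
    ed <- pruefer(idx)
    tot <- sum(d[ed])
    if (tot < best) best <- tot
    # next index vector in base n
    pos <- 1L
    while (pos <= n - 2) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= n) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > n - 2) break
  }
  best
}

hammingMat <- function(M) {
  H <- nrow(M)
  d <- matrix(0, H, H, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(H)) for (j in seq_len(H))
    d[i, j] <- sum(M[i, ] != M[j, ])
  d
}

# Exhaustive Steiner minimum over candidate grids: minimum MST length over
# the observed haplotypes plus any subset (size <= maxExtra) of candidate
# internal vertices. Candidates: every combination of observed states per
# site. Practical for <= 4-5 observed haplotypes over <= 5-6 binary sites.
oracleSteinerLength <- function(M, maxExtra = 2) {
  perSite <- lapply(seq_len(ncol(M)), function(j) unique(M[, j]))
  grid <- as.matrix(expand.grid(perSite, stringsAsFactors = FALSE))
  keyM <- apply(M, 1, paste, collapse = "")
  keyG <- apply(grid, 1, paste, collapse = "")
  grid <- grid[!(keyG %in% keyM), , drop = FALSE]
  primLen <- function(d) {
    H <- nrow(d)
    inTree <- c(TRUE, rep(FALSE, H - 1))
    best <- unname(d[1, ])
    tot <- 0
    for (k in seq_len(H - 1)) {
      cand <- which(!inTree)
      nxt <- cand[which.min(best[cand])]
      tot <- tot + best[nxt]
      inTree[nxt] <- TRUE
      best <- pmin(best, unname(d[nxt, ]))
    }
    tot
  }
  best <- primLen(hammingMat(M))
  # universal lower bound: every variable site mutates at least once
  lb <- sum(vapply(seq_len(ncol(M)), function(j)
    length(unique(M[, j])) > 1, TRUE))
  ng <- nrow(grid)
  for (k in seq_len(min(maxExtra, ng))) {
    if (best <= lb) break
    combs <- utils::combn(ng, k)
    for (ci in seq_len(ncol(combs))) {
      aug <- rbind(M, grid[combs[, ci], , drop = FALSE])
      len <- primLen(hammingMat(aug))
      if (len < best) best <- len
      if (best <= lb) break
    }
  }
  best
}

# ---- misc -----------------------------------------------------------------
# Build a DloopAlignment from explicit state rows (list of strings) over a
# toy reference.
toyAlignment <- function(rows, refSeq, pops = NULL, regions = NULL) {
  n <- length(rows)
  ids <- sprintf("s%02d", seq_len(n))
  if (is.null(pops)) pops <- rep("P1", n)
  if (is.null(regions)) regions <- rep("R1", n)
  stmat <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  rownames(stmat) <- ids
  meta <- data.frame(sample_id = ids, population = pops, region = regions,
                     stringsAsFactors = FALSE)
  matriline:::alignmentFromStates(stmat, meta, referenceFrame(refSeq))
}

# Random no-gap alignment over a toy reference with iid substitutions.
randomToyAlignment <- function(n, L, subRate = 0.08, pops = NULL) {
  refSeq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  rows <- vapply(seq_len(n), function(i) {
    b <- strsplit(refSeq, "")[[1]]
    hit <- runif(L) < subRate
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }, "")
  toyAlignment(rows, refSeq, pops = pops)
}

writeToyFasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

writeToyPopmap <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
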