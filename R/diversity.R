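# Haplotype collapsing, site classification, and Nei diversity statistics.

# Sites retained under the site policy. Complete deletion: a site enters only
# if every sequence has a called base (A/C/G/T) there — the convention of the
# classical haplotype tools this module mirrors.
.includedSites <- function(st) {
  which(apply(st, 2L, function(col) all(col %in% BASES)))
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences identical over the included sites share a haplotype. Under the
#' default `"complete"` site policy any site with a gap or missing state in
#' any sequence is excluded before comparison; under `"pairwise"` all sites
#' are kept and gap/missing states must match exactly (a conservative,
#' transitive stand-in for pairwise deletion at the collapsing step).
#' Haplotype ids `Hap_1, Hap_2, ...` are assigned in first-occurrence order.
#'
#' @param aln a [DloopAlignment-class].
#' @param sitePolicy `"complete"` (default) or `"pairwise"`.
#' @return a [HaplotypePartition-class].
#' @export
collapseHaplotypes <- function(aln, sitePolicy = c("complete", "pairwise")) {
  sitePolicy <- match.arg(sitePolicy)
  st <- states(aln)
  if (nrow(st) == 0L) stop("empty alignment")
  inc <- if (sitePolicy == "complete") .includedSites(st)
         else seq_len(ncol(st))
  if (!length(inc)) stop("no sites retained under the site policy")
  sub <- st[, inc, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  first <- !duplicated(key)
  hapIds <- setNames(paste0("Hap_", seq_len(sum(first))), key[first])
  memb <- setNames(unname(hapIds[key]), rownames(st))
  hs <- sub[first, , drop = FALSE]
  rownames(hs) <- unname(hapIds)
  colnames(hs) <- as.character(inc)
  new("HaplotypePartition", membership = memb, hapStates = hs,
      includedSites = as.integer(inc), sampleData = sampleData(aln),
      sitePolicy = sitePolicy)
}

#' Classify variable sites
#'
#' Over the included sites (complete deletion), a site is variable
#' (segregating) if at least two called states occur; it is a singleton if
#' every state other than the most frequent occurs exactly once, and
#' parsimony-informative otherwise (so for bi-allelic sites:
#' singletons + informative = segregating).
#'
#' @param aln a [DloopAlignment-class] with at least two sequences.
#' @return list `S`, `singletons`, `parsimonyInformative`, `excludedSites`
#'   (positions dropped for gaps/missing), `variableSites` (positions).
#' @export
classifySites <- function(aln) {
  st <- states(aln)
  if (nrow(st) < 2L) stop("need at least two sequences")
  inc <- .includedSites(st)
  excl <- setdiff(seq_len(ncol(st)), inc)
  vs <- integer(); sing <- 0L; pis <- 0L
  for (j in inc) {
    cnt <- sort(table(st[, j]), decreasing = TRUE)
    if (length(cnt) < 2L) next
    vs <- c(vs, j)
    if (all(cnt[-1L] == 1L)) sing <- sing + 1L else pis <- pis + 1L
  }
  list(S = length(vs), singletons = sing, parsimonyInformative = pis,
       excludedSites = excl, variableSites = vs)
}

#' Nei haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` over haplotype frequencies, with the
#' Nei (1987) sampling variance of gene diversity:
#' `V = 2/(n(n-1)) * {2(n-2)[sum(p^3) - (sum(p^2))^2] + sum(p^2) - (sum(p^2))^2}`.
#'
#' @param x a [HaplotypePartition-class], or an integer vector of haplotype
#'   counts.
#' @return list `Hd`, `se`, `n`, `Ht`.
#' @export
haplotypeDiversity <- function(x) {
  counts <- if (is(x, "HaplotypePartition")) hapCounts(x) else as.integer(x)
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity needs n >= 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  Hd <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, se = sqrt(max(V, 0)), n = n, Ht = length(counts))
}

# Pairwise difference counts over a state matrix whose columns are all
# called bases. Uses one-hot matrix products so the n^2 L work runs in BLAS.
.pairDiffs <- function(sub) {
  n <- nrow(sub); L <- ncol(sub)
  matches <- matrix(0, n, n)
  for (b in BASES) {
    X <- (sub == b) * 1
    matches <- matches + tcrossprod(X)
  }
  d <- L - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(sub), rownames(sub))
  d
}

#' Pairwise sequence difference matrix
#'
#' Counts of differing sites between every pair of sequences. Under the
#' `"complete"` policy all pairs are compared over the same included-site
#' set; under `"pairwise"` each pair is compared over the sites called in
#' both, and the count is rescaled to the full frame is NOT applied (raw
#' counts are returned in both cases).
#'
#' @inheritParams collapseHaplotypes
#' @return list `d` (symmetric integer-valued matrix, zero diagonal),
#'   `Leff` (included-site count; for `"pairwise"` a matrix of per-pair
#'   compared-site counts).
#' @export
seqDistances <- function(aln, sitePolicy = c("complete", "pairwise")) {
  sitePolicy <- match.arg(sitePolicy)
  st <- states(aln)
  if (sitePolicy == "complete") {
    inc <- .includedSites(st)
    if (!length(inc)) stop("no sites retained under complete deletion")
    sub <- st[, inc, drop = FALSE]
    list(d = .pairDiffs(sub), Leff = length(inc))
  } else {
    called <- matrix(st %in% BASES, nrow = nrow(st))
    shared <- tcrossprod(called * 1)
    matches <- matrix(0, nrow(st), nrow(st))
    for (b in BASES) matches <- matches + tcrossprod((st == b) * 1)
    d <- shared - matches
    diag(d) <- 0
    dimnames(d) <- list(rownames(st), rownames(st))
    list(d = d, Leff = shared)
  }
}

#' Nucleotide diversity
#'
#' Mean per-site proportion of differences over all sequence pairs,
#' `pi = sum_{i<j} d_ij / (C(n,2) * L_eff)`, with the Nei (1987) sampling
#' variance `V = (n+1)/(3(n-1)L) * pi + 2(n^2+n+3)/(9n(n-1)) * pi^2`.
#'
#' @inheritParams collapseHaplotypes
#' @return list `pi`, `se`, `n`, `Leff`, `meanPairwiseDiff` (mean number of
#'   differences per sequence pair, the per-locus quantity used by the
#'   neutrality tests).
#' @export
nucleotideDiversity <- function(aln, sitePolicy = c("complete", "pairwise")) {
  sitePolicy <- match.arg(sitePolicy)
  sd_ <- seqDistances(aln, sitePolicy)
  n <- nrow(states(aln))
  if (n < 2L) stop("nucleotide diversity needs n >= 2")
  npair <- n * (n - 1) / 2
  if (sitePolicy == "complete") {
    k <- sum(sd_$d[upper.tri(sd_$d)]) / npair
    L <- sd_$Leff
    pi <- k / L
  } else {
    ut <- upper.tri(sd_$d)
    prop <- sd_$d[ut] / pmax(sd_$Leff[ut], 1)
    pi <- mean(prop)
    L <- mean(sd_$Leff[ut])
    k <- pi * L
  }
  V <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, se = sqrt(max(V, 0)), n = n, Leff = L, meanPairwiseDiff = k)
}

#' Per-population diversity table
#'
#' Computes, for each level of a grouping column (and optionally for pooled
#' super-groups), the molecular diversity indices: N, number of haplotypes,
#' haplotype diversity and nucleotide diversity with their standard errors,
#' plus the segregating-site count. Each group is analysed on its own subset
#' with its own complete-deletion site set. Pooled rows (e.g. regional
#' "overall" rows) pool sequences, they do not average indices.
#'
#' @param aln a [DloopAlignment-class].
#' @param by grouping column of `sampleData(aln)` (default `"population"`).
#' @param pooled optional named list of character vectors of group levels to
#'   pool into extra rows, e.g. `list(MSEA = c("Cambodia", "Laos"))`.
#' @return data.frame with one row per group: `group`, `N`, `Ht`, `S`, `Hd`,
#'   `Hd_se`, `pi`, `pi_se`.
#' @export
diversityTable <- function(aln, by = "population", pooled = NULL) {
  sd0 <- sampleData(aln)
  groups <- split(sd0$sample_id, sd0[[by]])
  if (!is.null(pooled)) {
    for (nm in names(pooled)) {
      groups[[nm]] <- sd0$sample_id[sd0[[by]] %in% pooled[[nm]]]
    }
  }
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    sub <- aln[ids]
    if (length(ids) < 2L)
      return(data.frame(group = g, N = length(ids), Ht = NA_integer_,
                        S = NA_integer_, Hd = NA_real_, Hd_se = NA_real_,
                        pi = NA_real_, pi_se = NA_real_))
    part <- collapseHaplotypes(sub)
    hd <- haplotypeDiversity(part)
    pv <- nucleotideDiversity(sub)
    sc <- classifySites(sub)
    data.frame(group = g, N = length(ids), Ht = hd$Ht, S = sc$S,
               Hd = hd$Hd, Hd_se = hd$se, pi = pv$pi, pi_se = pv$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
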