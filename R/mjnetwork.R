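# Median-joining haplotype networks: epsilon-relaxed minimum spanning
# network, quasi-median (Steiner point) insertion, mutation-labelled edges,
# and the rho-statistic TMRCA utility.

# Hamming distance matrix between rows of a character state matrix.
.hamming <- function(M) {
  H <- nrow(M)
  d <- matrix(0L, H, H, dimnames = list(rownames(M), rownames(M)))
  if (H < 2L) return(d)
  for (i in seq_len(H - 1L)) for (j in (i + 1L):H) {
    d[i, j] <- d[j, i] <- sum(M[i, ] != M[j, ])
  }
  d
}

# Hamming distances from one state vector to every row of M.
.hammingTo <- function(M, v) {
  colSums(t(M) != v)
}

# Minimum spanning tree by Prim on a dense distance matrix; returns the
# edge list (i, j, w) and total length.
.mstEdges <- function(d) {
  H <- nrow(d)
  if (H < 2L) return(list(edges = matrix(0, 0, 3), length = 0))
  inTree <- c(TRUE, rep(FALSE, H - 1L))
  best <- d[1L, ]
  parent <- rep(1L, H)
  edges <- matrix(0, H - 1L, 3L)
  tot <- 0
  for (k in seq_len(H - 1L)) {
    cand <- which(!inTree)
    nxt <- cand[which.min(best[cand])]
    edges[k, ] <- c(parent[nxt], nxt, best[nxt])
    tot <- tot + best[nxt]
    inTree[nxt] <- TRUE
    upd <- !inTree & d[nxt, ] < best
    best[upd] <- d[nxt, upd]
    parent[upd] <- nxt
  }
  list(edges = edges, length = tot)
}

.mstLength <- function(d) .mstEdges(d)$length

# MST length after adding one vertex with distance vector dm to all current
# vertices: the new MST lives inside (old MST edges) + (edges to the new
# vertex), so Kruskal on those 2H-1 edges suffices.
.mstAugLength <- function(mstEdges, dm) {
  H <- length(dm)
  ei <- c(mstEdges[, 1L], seq_len(H))
  ej <- c(mstEdges[, 2L], rep(H + 1L, H))
  ew <- c(mstEdges[, 3L], dm)
  o <- order(ew)
  parent <- seq_len(H + 1L)
  tot <- 0; used <- 0L
  for (e in o) {
    a <- ei[e]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- ej[e]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) {
      parent[a] <- b
      tot <- tot + ew[e]
      used <- used + 1L
      if (used == H) break
    }
  }
  tot
}

# Minimax (bottleneck) distances: the maximal edge on the MST path between
# every pair. An edge (u,v) belongs to some MST iff d(u,v) equals the
# minimax distance; the epsilon relaxation admits d <= minimax + epsilon.
.minimax <- function(d) {
  H <- nrow(d)
  mst <- .mstEdges(d)$edges
  adj <- vector("list", H)
  w <- vector("list", H)
  for (r in seq_len(nrow(mst))) {
    a <- mst[r, 1L]; b <- mst[r, 2L]
    adj[[a]] <- c(adj[[a]], b); w[[a]] <- c(w[[a]], mst[r, 3L])
    adj[[b]] <- c(adj[[b]], a); w[[b]] <- c(w[[b]], mst[r, 3L])
  }
  mm <- matrix(0, H, H, dimnames = dimnames(d))
  for (s in seq_len(H)) {
    seen <- rep(FALSE, H); seen[s] <- TRUE
    queue <- s
    dmax <- numeric(H)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (qi in seq_along(adj[[v]])) {
        u <- adj[[v]][qi]
        if (!seen[u]) {
          seen[u] <- TRUE
          dmax[u] <- max(dmax[v], w[[v]][qi])
          queue <- c(queue, u)
        }
      }
    }
    mm[s, ] <- dmax
  }
  mm
}

# The epsilon-relaxed minimum spanning network over a distance matrix:
# edge (u,v) admitted iff d(u,v) <= minimax(u,v) + epsilon. At epsilon = 0
# this is the union of all minimum spanning trees.
.msnFromD <- function(d, epsilon = 0) {
  H <- nrow(d)
  if (H == 1L) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    return(igraph::set_vertex_attr(g, "name", value = rownames(d)))
  }
  mm <- .minimax(d)
  keep <- d <= mm + epsilon & upper.tri(d) & d > 0
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(H, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(d))
  g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]))
  igraph::E(g)$weight <- d[idx]
  g
}

#' Build the epsilon-relaxed minimum spanning network
#'
#' Computes the union of all minimum spanning trees over the Hamming
#' distances between haplotype state vectors, relaxed so that a link is
#' admitted whenever its length is within `epsilon` of the minimal cost
#' connecting its two endpoints (the bottleneck distance).
#'
#' @param x a [HaplotypePartition-class], or a character state matrix
#'   (haplotypes x sites, rownames = haplotype ids; invariant columns are
#'   dropped).
#' @param epsilon non-negative integer relaxation (default 0, the usual
#'   software default).
#' @return an [igraph::igraph] with edge attribute `weight` (Hamming
#'   length).
#' @export
buildMSN <- function(x, epsilon = 0) {
  M <- .networkStates(x)
  if (nrow(M) < 2L) stop("need at least two haplotypes")
  .msnFromD(.hamming(M), epsilon)
}

# Extract the variable-site state matrix used for network construction.
.networkStates <- function(x) {
  M <- if (is(x, "HaplotypePartition")) hapStates(x) else x
  varying <- vapply(seq_len(ncol(M)), function(j)
    length(unique(M[, j])) > 1L, TRUE)
  M[, varying, drop = FALSE]
}

# Quasi-medians of a state triplet: per-site majority state; sites where all
# three states differ spawn one variant per state (capped).
.quasiMedians <- function(M3, cap = 64L) {
  s1 <- M3[1L, ]; s2 <- M3[2L, ]; s3 <- M3[3L, ]
  maj <- ifelse(s1 == s2 | s1 == s3, s1, ifelse(s2 == s3, s2, NA))
  tie <- which(is.na(maj))
  if (!length(tie)) {
    out <- matrix(maj, 1L)
    colnames(out) <- colnames(M3)
    return(out)
  }
  if (3^length(tie) > cap)
    stop("quasi-median variant explosion (", 3^length(tie), " > ", cap,
         ") for one triplet; increase the cap or reduce epsilon")
  perSite <- lapply(tie, function(j) unique(M3[, j]))
  grid <- as.matrix(expand.grid(perSite, stringsAsFactors = FALSE))
  out <- matrix(rep(maj, nrow(grid)), nrow = nrow(grid), byrow = TRUE)
  out[, tie] <- grid
  colnames(out) <- colnames(M3)
  out
}

#' Median-joining network (quasi-median insertion)
#'
#' Starting from the epsilon-relaxed minimum spanning network over the
#' observed haplotypes, iteratively scans connected triplets (a vertex with
#' two network neighbours), proposes their quasi-medians (per-site majority
#' state; three-way ties spawn one variant per state), and greedily adds the
#' median that most reduces the total network cost (the minimum spanning
#' tree length over the augmented node set), rebuilding after each addition
#' until no median improves the cost. Median vectors not lying on any
#' shortest path between observed haplotypes, and any of degree <= 1, are
#' pruned. The cost is non-increasing across insertions by construction.
#'
#' @inheritParams buildMSN
#' @param maxRounds safety cap on insertion rounds (error if exceeded).
#' @param popCounts optional matrix of per-population sample counts per
#'   observed haplotype (rows = haplotype ids) for pie-chart style exports.
#' @param sizes named vector of sample counts per observed haplotype;
#'   derived automatically from a `HaplotypePartition`.
#' @return an [MJNetwork-class].
#' @export
medianJoiningNetwork <- function(x, epsilon = 0, maxRounds = 200L,
                                 sizes = NULL, popCounts = NULL) {
  M <- .networkStates(x)
  if (nrow(M) < 2L) stop("need at least two haplotypes")
  if (is.null(sizes)) {
    sizes <- if (is(x, "HaplotypePartition")) hapCounts(x)
             else setNames(rep(1L, nrow(M)), rownames(M))
  }
  if (is.null(popCounts) && is(x, "HaplotypePartition")) {
    popCounts <- table(membership(x)[x@sampleData$sample_id],
                       x@sampleData$population)
    popCounts <- matrix(as.integer(popCounts), nrow = nrow(popCounts),
                        dimnames = dimnames(popCounts))
  }
  observed <- rownames(M)
  cur <- M
  d <- .hamming(cur)
  mst <- .mstEdges(d)
  cost <- mst$length
  medCount <- 0L
  for (round in seq_len(maxRounds + 1L)) {
    if (round > maxRounds)
      stop("median insertion did not converge within ", maxRounds,
           " rounds at epsilon = ", epsilon)
    g <- .msnFromD(d, epsilon)
    nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
    cand <- list()
    for (v in seq_along(nbrs)) {
      nb <- as.integer(nbrs[[v]])
      if (length(nb) < 2L) next
      prs <- combn(nb, 2L)
      for (q in seq_len(ncol(prs)))
        cand[[length(cand) + 1L]] <- c(prs[1L, q], v, prs[2L, q])
    }
    added <- FALSE
    if (length(cand)) {
      # dedupe triplets before expanding quasi-medians
      trip <- unique(t(vapply(cand, function(tr) sort(tr), integer(3L))))
      meds <- do.call(rbind, lapply(seq_len(nrow(trip)), function(r)
        .quasiMedians(cur[trip[r, ], , drop = FALSE])))
      keyCur <- apply(cur, 1L, paste, collapse = "")
      keyMed <- apply(meds, 1L, paste, collapse = "")
      keep <- !(keyMed %in% keyCur) & !duplicated(keyMed)
      meds <- meds[keep, , drop = FALSE]
      if (nrow(meds)) {
        tcur <- t(cur)
        gains <- vapply(seq_len(nrow(meds)), function(mi) {
          cost - .mstAugLength(mst$edges, colSums(tcur != meds[mi, ]))
        }, 0)
        # accept in gain order with ties broken on the state key, so the
        # result is independent of haplotype input order
        medKey <- apply(meds, 1L, paste, collapse = "")
        for (mi in order(-gains, medKey)) {
          if (gains[mi] <= 1e-9) break
          dm <- .hammingTo(cur, meds[mi, ])
          gain <- cost - .mstAugLength(mst$edges, dm)
          if (gain <= 1e-9) next
          medCount <- medCount + 1L
          nm <- paste0("mv", medCount)
          cur <- rbind(cur, meds[mi, , drop = FALSE])
          rownames(cur)[nrow(cur)] <- nm
          d <- rbind(cbind(d, dm), c(dm, 0L))
          rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- nm
          mst <- .mstEdges(d)
          cost <- mst$length
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  # prune medians not on any observed-to-observed shortest path, then any
  # left with degree <= 1; repeat to stability
  repeat {
    g <- .msnFromD(d, epsilon)
    D <- igraph::distances(g, weights = igraph::E(g)$weight)
    med <- setdiff(rownames(cur), observed)
    if (!length(med)) break
    Dobs <- D[observed, observed, drop = FALSE]
    onPath <- vapply(med, function(m) {
      via <- outer(D[observed, m], D[m, observed], "+")
      any(via <= Dobs + 1e-9 & Dobs > 0)
    }, TRUE)
    deg <- igraph::degree(g)[med]
    drop <- med[!onPath | deg <= 1L]
    if (!length(drop)) break
    keep <- !(rownames(cur) %in% drop)
    cur <- cur[keep, , drop = FALSE]
    d <- d[keep, keep, drop = FALSE]
  }
  g <- .msnFromD(d, epsilon)
  el <- igraph::as_data_frame(g, what = "edges")
  positions <- vapply(seq_len(nrow(el)), function(r) {
    diffs <- which(cur[el$from[r], ] != cur[el$to[r], ])
    paste(colnames(cur)[diffs], collapse = ",")
  }, "")
  igraph::E(g)$positions <- positions
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% observed,
                              "observed", "median")
  igraph::V(g)$size <- ifelse(igraph::V(g)$kind == "observed",
                              as.integer(sizes[igraph::V(g)$name]), 0L)
  if (is.null(popCounts))
    popCounts <- matrix(integer(), 0, 0)
  new("MJNetwork", graph = g, nodeStates = cur, epsilon = epsilon,
      popCounts = popCounts)
}

#' Minimum mutational steps between network nodes
#'
#' Shortest-path length (sum of edge Hamming lengths) between two nodes, or
#' the minimum over two node sets (e.g. the haplotypes of two haplogroups).
#'
#' @param net an [MJNetwork-class].
#' @param a,b node names (vectors allowed; the minimum over pairs is
#'   returned).
#' @return number of mutational steps.
#' @export
mutationSteps <- function(net, a, b) {
  g <- networkGraph(net)
  miss <- setdiff(c(a, b), igraph::V(g)$name)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  D <- igraph::distances(g, v = a, to = b, weights = igraph::E(g)$weight)
  min(D)
}

#' Rho-statistic TMRCA approximation
#'
#' The rho statistic is the sample-size-weighted mean mutational distance
#' from a designated root node to every observed haplotype; dividing by the
#' per-site clock rate times the sequence length converts it to years. This
#' is a fast founder-age approximation, not a Bayesian node-age estimate;
#' treat the result as indicative only.
#'
#' @param net an [MJNetwork-class].
#' @param root root node name.
#' @param rate substitutions/site/year (default `3.13e-7`, a published
#'   chicken control-region clock rate).
#' @param L sites used for the clock (default 1232).
#' @return list `rho`, `tmrcaYears`, `rate`, `L`, `root`.
#' @export
estimateTmrcaRho <- function(net, root, rate = 3.13e-7, L = 1232L) {
  g <- networkGraph(net)
  if (!root %in% igraph::V(g)$name) stop("unknown root node: ", root)
  v <- igraph::V(g)
  obs <- v$name[v$kind == "observed"]
  sizes <- setNames(v$size, v$name)[obs]
  if (sum(sizes) == 0) stop("total sample size is zero")
  D <- igraph::distances(g, v = root, to = obs,
                         weights = igraph::E(g)$weight)
  rho <- sum(sizes * D[1L, ]) / sum(sizes)
  list(rho = rho, tmrcaYears = rho / (rate * L), rate = rate, L = L,
       root = root)
}

#' Export a network
#'
#' `writeNetworkGraphml()` writes GraphML with node attributes (`kind`,
#' `size`, per-population counts) and the `positions` edge attribute;
#' `writeNetworkNexus()` writes a NEXUS file with a Network block listing
#' vertices and mutation-labelled edges; `writeNetworkEdges()` writes a TSV
#' edge list.
#'
#' @param net an [MJNetwork-class].
#' @param path output file.
#' @export
writeNetworkGraphml <- function(net, path) {
  g <- networkGraph(net)
  if (nrow(net@popCounts)) {
    for (p in colnames(net@popCounts)) {
      cnt <- setNames(net@popCounts[, p], rownames(net@popCounts))
      vals <- ifelse(igraph::V(g)$name %in% names(cnt),
                     as.integer(cnt[igraph::V(g)$name]), 0L)
      g <- igraph::set_vertex_attr(g, paste0("n_", p), value = vals)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkGraphml
#' @export
writeNetworkNexus <- function(net, path) {
  g <- networkGraph(net)
  v <- igraph::V(g)
  el <- networkEdges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("", con)
  writeLines("BEGIN NETWORK;", con)
  writeLines(sprintf("  DIMENSIONS NVERTICES=%d NEDGES=%d;",
                     length(v), nrow(el)), con)
  writeLines("  VERTICES", con)
  for (i in seq_along(v))
    writeLines(sprintf("    %d %s kind=%s size=%d%s", i, v$name[i],
                       v$kind[i], v$size[i],
                       if (i == length(v)) ";" else ","), con)
  writeLines("  EDGES", con)
  idx <- setNames(seq_along(v), v$name)
  for (r in seq_len(nrow(el)))
    writeLines(sprintf("    %d %d %d steps=%d positions=%s%s", r,
                       idx[[el$from[r]]], idx[[el$to[r]]],
                       as.integer(el$steps[r]),
                       gsub(",", "|", el$positions[r]),
                       if (r == nrow(el)) ";" else ","), con)
  writeLines("END;", con)
  invisible(path)
}

#' @rdname writeNetworkGraphml
#' @export
writeNetworkEdges <- function(net, path) {
  write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
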