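# Median-joining networks: spanning networks, quasi-median insertion,
# mutation steps, rho TMRCA, exports.

mkStates <- function(..., sites = NULL) {
  rows <- list(...)
  M <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  rownames(M) <- paste0("H", seq_along(rows))
  colnames(M) <- if (is.null(sites)) as.character(seq_len(ncol(M)))
                 else sites
  M
}

test_that("two haplotypes yield a single edge of their Hamming length", {
  M <- mkStates("AAAA", "AGGA")
  net <- medianJoiningNetwork(M)
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_equal(e$steps, 2)
  expect_identical(e$positions, "2,3")
})

test_that("pairwise-equidistant triplet forms a triangle (all MSTs union)", {
  M <- mkStates("AAA", "GGA", "GAG")   # all pairwise distances 2
  g <- buildMSN(M, epsilon = 0)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 2))
})

test_that("unique-MST toys match the exhaustive spanning-tree oracle", {
  set.seed(428)
  for (rep in 1:10) {
    M <- matrix(sample(c("A", "G"), 4 * 7, TRUE, prob = c(0.7, 0.3)), 4, 7)
    rownames(M) <- paste0("H", 1:4)
    colnames(M) <- as.character(1:7)
    if (anyDuplicated(apply(M, 1, paste, collapse = ""))) next
    d <- hammingMat(M)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    mstLen <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(oracleMstLength(d), mstLen)
    msn <- buildMSN(M, epsilon = 0)
    # the MSN contains a spanning tree of minimal weight and every MSN edge
    # is the bottleneck length for its endpoints
    expect_gte(igraph::ecount(msn), 3L)
    sub <- igraph::mst(msn, weights = igraph::E(msn)$weight)
    expect_equal(sum(igraph::E(sub)$weight), mstLen)
  }
})

test_that("a perfect star gains exactly one consensus median", {
  M <- mkStates("GAAA", "AGAA", "AAGA")  # consensus AAAA is the Steiner point
  net <- medianJoiningNetwork(M)
  v <- igraph::V(networkGraph(net))
  med <- v$name[v$kind == "median"]
  expect_length(med, 1L)
  expect_equal(unname(igraph::degree(networkGraph(net), med)), 3)
  # node states span the three variable sites; the median is the consensus
  expect_identical(paste(nodeStates(net)[med, ], collapse = ""), "AAA")
  # total length drops from 4 (any MST) to 3 (star through the median)
  expect_equal(sum(networkEdges(net)$steps), 3)
})

test_that("collinear haplotypes gain no median", {
  M <- mkStates("AAAA", "GAAA", "GGGA")  # A - B - C on a line
  net <- medianJoiningNetwork(M)
  v <- igraph::V(networkGraph(net))
  expect_identical(sum(v$kind == "median"), 0L)
  expect_equal(sum(networkEdges(net)$steps), 3)
})

test_that("median insertion never increases total network length", {
  set.seed(429)
  for (rep in 1:40) {
    H <- sample(3:6, 1)
    S <- sample(4:8, 1)
    M <- matrix(sample(c("A", "G"), H * S, TRUE), H, S)
    rownames(M) <- paste0("H", seq_len(H))
    colnames(M) <- as.character(seq_len(S))
    keys <- apply(M, 1, paste, collapse = "")
    if (anyDuplicated(keys)) next
    before <- sum(igraph::E(igraph::mst(
      igraph::graph_from_adjacency_matrix(hammingMat(M),
                                          mode = "undirected",
                                          weighted = TRUE)))$weight)
    net <- medianJoiningNetwork(M)
    after <- sum(igraph::E(igraph::mst(
      networkGraph(net), weights = igraph::E(networkGraph(net))$weight)
      )$weight)
    expect_lte(after, before + 1e-9)
  }
})

test_that("tree-like (infinite-sites) data reach the parsimony bound", {
  # data simulated without homoplasy: every variable site mutates once, so
  # the Steiner minimum equals the number of variable sites; the network
  # must attain it
  set.seed(430)
  for (rep in 1:10) {
    sim <- simulateNeutralSample(5, 3)
    if (sim$S < 2 || sim$S > 8) next
    M <- matrix(c("A", "G")[sim$genotypes + 1L], nrow(sim$genotypes))
    keys <- apply(M, 1, paste, collapse = "")
    M <- M[!duplicated(keys), , drop = FALSE]
    if (nrow(M) < 3) next
    rownames(M) <- paste0("H", seq_len(nrow(M)))
    colnames(M) <- as.character(seq_len(ncol(M)))
    varying <- apply(M, 2, function(cl) length(unique(cl)) > 1)
    net <- medianJoiningNetwork(M)
    totalLen <- sum(igraph::E(igraph::mst(
      networkGraph(net), weights = igraph::E(networkGraph(net))$weight)
      )$weight)
    expect_equal(totalLen, sum(varying))
  }
})

test_that("networks equal exhaustive Steiner search on tiny instances", {
  set.seed(431)
  done <- 0
  while (done < 6) {
    H <- sample(3:4, 1)
    S <- sample(3:5, 1)
    M <- matrix(sample(c("A", "G"), H * S, TRUE), H, S)
    rownames(M) <- paste0("H", seq_len(H))
    colnames(M) <- as.character(seq_len(S))
    keys <- apply(M, 1, paste, collapse = "")
    if (anyDuplicated(keys)) next
    net <- medianJoiningNetwork(M)
    got <- sum(igraph::E(igraph::mst(
      networkGraph(net), weights = igraph::E(networkGraph(net))$weight)
      )$weight)
    best <- oracleSteinerLength(M, maxExtra = 2)
    expect_gte(got, best)        # can never beat the optimum
    expect_lte(got, best + 1)    # and stays within one step of it
    done <- done + 1
  }
})

test_that("network structure is invariant to haplotype input order", {
  set.seed(432)
  for (rep in 1:10) {
    M <- matrix(sample(c("A", "G"), 5 * 6, TRUE), 5, 6)
    rownames(M) <- paste0("H", 1:5)
    colnames(M) <- as.character(1:6)
    if (anyDuplicated(apply(M, 1, paste, collapse = ""))) next
    canonical <- function(net) {
      st <- nodeStates(net)
      key <- apply(st, 1, paste, collapse = "")
      e <- networkEdges(net)
      sort(paste(pmin(key[e$from], key[e$to]),
                 pmax(key[e$from], key[e$to]), e$steps))
    }
    n1 <- medianJoiningNetwork(M)
    n2 <- medianJoiningNetwork(M[sample(5), ])
    expect_identical(canonical(n1), canonical(n2))
  }
})

test_that("mutation steps are shortest-path sums over edge lengths", {
  # path H1 -2- H2 -3- H3 -4- H4
  M <- mkStates("AAAAAAAAA", "GGAAAAAAA", "GGGGGAAAA", "GGGGGGGGG")
  net <- medianJoiningNetwork(M)
  expect_equal(mutationSteps(net, "H1", "H2"), 2)
  expect_equal(mutationSteps(net, "H1", "H4"), 9)
  # minimum over node sets
  expect_equal(mutationSteps(net, c("H1", "H2"), c("H3", "H4")), 3)
  expect_error(mutationSteps(net, "H1", "nope"), "unknown")
})

test_that("rho TMRCA matches closed-form arithmetic", {
  M <- mkStates("AAAA", "GAAA", "AGAA", "AAGA", "AAAG")
  net <- medianJoiningNetwork(M, sizes = c(H1 = 0L, H2 = 1L, H3 = 1L,
                                           H4 = 1L, H5 = 1L))
  est <- estimateTmrcaRho(net, "H1")
  expect_equal(est$rho, 1)
  expect_equal(est$tmrcaYears, 1 / (3.13e-7 * 1232), tolerance = 1e-9)
  # all samples on the root haplotype: rho = 0
  net2 <- medianJoiningNetwork(mkStates("AA", "GG"),
                               sizes = c(H1 = 10L, H2 = 0L))
  expect_warning(est2 <- estimateTmrcaRho(net2, "H1"), NA)
  expect_equal(est2$rho, 0)
  expect_equal(est2$tmrcaYears, 0)
  # rho via network paths equals direct Hamming distance on tree-like data
  M3 <- mkStates("AAAA", "GAAA", "GGAA", "GGGA")
  net3 <- medianJoiningNetwork(M3)
  direct <- mean(c(0, 1, 2, 3))
  expect_equal(estimateTmrcaRho(net3, "H1")$rho, direct)
})

test_that("network exports write parseable files", {
  M <- mkStates("GAAA", "AGAA", "AAGA")
  net <- medianJoiningNetwork(M)
  gml <- tempfile(fileext = ".graphml")
  writeNetworkGraphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(back),
                   igraph::vcount(networkGraph(net)))
  nex <- tempfile(fileext = ".nex")
  writeNetworkNexus(net, nex)
  txt <- readLines(nex)
  expect_identical(txt[1], "#NEXUS")
  expect_true(any(grepl("NVERTICES=4", txt)))
  tsv <- tempfile(fileext = ".tsv")
  writeNetworkEdges(net, tsv)
  expect_identical(nrow(read.delim(tsv)), 3L)
})
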