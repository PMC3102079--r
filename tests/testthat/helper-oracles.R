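# Independent brute-force oracles, written as naive loops over nodes, dyads
# and triples. They share no code with the package internals (which use
# matrix algebra, igraph and compiled incremental updates).

randomNetwork <- function(n, p, nodeData = NULL) {
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(up)) < p
  brainNetwork(n, up[keep, , drop = FALSE], nodeData = nodeData)
}

pathNetwork <- function(n) {
  brainNetwork(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

completeNetwork <- function(n) {
  brainNetwork(n, t(utils::combn(n, 2)))
}

# ring lattice: each node tied to its k nearest neighbours on each side
ringLattice <- function(n, k) {
  e <- NULL
  for (i in seq_len(n))
    for (d in seq_len(k))
      e <- rbind(e, c(i, ((i - 1 + d) %% n) + 1))
  brainNetwork(n, e)
}

bruteAdj <- function(net) {
  n <- nNodes(net)
  A <- matrix(0L, n, n)
  e <- edgeMatrix(net)
  for (r in seq_len(nrow(e))) {
    A[e[r, 1], e[r, 2]] <- 1L
    A[e[r, 2], e[r, 1]] <- 1L
  }
  A
}

bruteSharedPartners <- function(net) {
  A <- bruteAdj(net)
  n <- nrow(A)
  esp <- nsp <- numeric(n - 1)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- 0
    for (k in seq_len(n)) if (k != i && k != j && A[i, k] && A[j, k])
      sp <- sp + 1
    if (A[i, j]) esp[sp + 1] <- esp[sp + 1] + 1
    else nsp[sp + 1] <- nsp[sp + 1] + 1
  }
  list(esp = esp, nsp = nsp, dsp = esp + nsp)
}

bruteTriadCensus <- function(net) {
  A <- bruteAdj(net)
  n <- nrow(A)
  out <- numeric(4)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    m <- A[i, j] + A[i, k] + A[j, k]
    out[m + 1] <- out[m + 1] + 1
  }
  out
}

bruteGeodesic <- function(net) {
  # Floyd-Warshall
  A <- bruteAdj(net)
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  du <- d[upper.tri(d)]
  counts <- numeric(n - 1)
  for (v in du[is.finite(du)]) counts[v] <- counts[v] + 1
  list(counts = counts, unreachable = sum(!is.finite(du)))
}

bruteGw <- function(counts, tau) {
  s <- 0
  for (k in seq_along(counts) - 1)
    if (k >= 1) s <- s + exp(tau) * (1 - (1 - exp(-tau))^k) * counts[k + 1]
  s
}

# naive statistic vector from first principles (loops, no shared code)
bruteStatVector <- function(net, model) {
  A <- bruteAdj(net)
  n <- nrow(A)
  deg <- rowSums(A)
  spd <- bruteSharedPartners(net)
  degCounts <- numeric(n)
  for (v in deg) degCounts[v + 1] <- degCounts[v + 1] + 1
  sapply(model@terms, function(tm) {
    switch(tm$kind,
      edges = sum(A) / 2,
      two_path = sum(deg * (deg - 1) / 2),
      gwd = bruteGw(degCounts, tm$tau),
      gwesp = bruteGw(spd$esp, tm$tau),
      gwnsp = bruteGw(spd$nsp, tm$tau),
      gwdsp = bruteGw(spd$dsp, tm$tau),
      nodematch = {
        val <- as.character(nodeData(net)[[tm$attribute]])
        cnt <- 0
        for (i in 1:(n - 1)) for (j in (i + 1):n)
          if (A[i, j] && val[i] == val[j]) cnt <- cnt + 1
        cnt
      })
  })
}

# naive enumeration of all graphs on n nodes: log partition and moments
bruteEnumeration <- function(model, theta, n, nodeData = NULL) {
  dyads <- t(utils::combn(n, 2))
  M <- nrow(dyads)
  vals <- numeric(2^M)
  G <- matrix(0, 2^M, nTerms(model))
  for (s in 0:(2^M - 1)) {
    bits <- as.integer(intToBits(s))[1:M]
    net <- brainNetwork(n, dyads[bits == 1L, , drop = FALSE],
                        nodeData = nodeData)
    g <- bruteStatVector(net, model)
    G[s + 1, ] <- g
    vals[s + 1] <- sum(theta * g)
  }
  mx <- max(vals)
  w <- exp(vals - mx)
  list(log_kappa = mx + log(sum(w)),
       mean = colSums(G * w) / sum(w))
}

# draw random graphs until the observed statistics are strictly inside the
# attainable range (the exact MLE then exists)
interiorNetwork <- function(n, p, model) {
  repeat {
    net <- randomNetwork(n, p)
    g <- statisticVector(net, model)
    if (all(g > 0) && edgeCount(net) < choose(n, 2) &&
        !inherits(tryCatch(exactMLE(net, model), error = identity),
                  "error"))
      return(net)
  }
}

allSevenTermModel <- function() {
  ergmModel("edges", "two_path", ergmTerm("gwd", tau = 0.5),
            ergmTerm("gwesp", tau = 0.75), ergmTerm("gwnsp", tau = 0.75),
            ergmTerm("gwdsp", tau = 0.25),
            ergmTerm("nodematch", attribute = "lobe"))
}

lobeData <- function(n) data.frame(lobe = rep(c("F", "P", "T", "O"),
                                              length.out = n))
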