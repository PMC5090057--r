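# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Felsenstein pruning by direct recursion over the edge matrix, same child
# order as the implementation so signs are comparable.
naive_pic <- function(tree, x) {
  n <- length(tree$tip.label)
  stopifnot(!is.null(names(x)))
  tipval <- x[tree$tip.label]
  env <- new.env()
  env$bl <- numeric(n + tree$Nnode)
  env$bl[tree$edge[, 2L]] <- tree$edge.length
  env$contrast <- setNames(rep(NA_real_, tree$Nnode),
                           seq.int(n + 1L, n + tree$Nnode))
  value <- function(node) {
    if (node <= n) return(tipval[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    stopifnot(length(kids) == 2L)
    x1 <- value(kids[1L]); x2 <- value(kids[2L])
    v1 <- env$bl[kids[1L]]; v2 <- env$bl[kids[2L]]
    env$contrast[as.character(node)] <- (x1 - x2) / sqrt(v1 + v2)
    env$bl[node] <- env$bl[node] + v1 * v2 / (v1 + v2)
    (x1 / v1 + x2 / v2) / (1 / v1 + 1 / v2)
  }
  value(n + 1L)
  env$contrast
}

# Step-up BH by the textbook loop.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# All permutations of 1..n (small n), for exhaustive permutation nulls.
enumerate_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (s in enumerate_perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[s])
  }
  out
}

# Small random bifurcating tree with positive branch lengths.
random_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips)
  tree$edge.length <- runif(length(tree$edge.length), 0.1, 2)
  tree
}

tiny_gfs <- function(n_fam = 3L, n_sp = 4L, seed = 5L) {
  set.seed(seed)
  m <- matrix(rpois(n_fam * n_sp, 5) + 1L, n_fam, n_sp,
              dimnames = list(paste0("F", seq_len(n_fam)),
                              paste0("sp", seq_len(n_sp))))
  m
}
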