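# Independent brute-force oracles used across the test files. These are
# deliberately written as direct transcriptions of the definitions (nested
# loops, no shared code with the package internals).

# Support sets by exhaustive enumeration over all (i, j, m, n).
# Returns a list keyed "i,j" -> matrix with columns m, n.
oracle_support_sets <- function(x, y, stds, tol_units, self) {
  n_in <- nrow(x); n_rt <- nrow(y); k <- ncol(x)
  tol <- tol_units * stds
  out <- list()
  for (i in seq_len(n_in)) for (j in seq_len(n_rt)) {
    if (self && i == j) next
    mem <- NULL
    for (m in seq_len(n_in)) for (n in seq_len(n_rt)) {
      if (m == i && n == j) next
      if (self && m == n) next
      delta <- (x[i, ] - x[m, ]) - (y[j, ] - y[n, ])
      if (all(abs(delta) <= tol)) mem <- rbind(mem, c(m, n))
    }
    if (!is.null(mem)) out[[paste(i, j, sep = ",")]] <- mem
  }
  out
}

# Robustness by direct summation given oracle support sets; each support set
# is compared together with its defining mapping pair.
oracle_robustness <- function(ss, i, j, x, y, stds, std_factor) {
  key <- paste(i, j, sep = ",")
  mem <- ss[[key]]
  if (is.null(mem)) return(0)
  enc <- function(p) paste(p[, 1], p[, 2], sep = ",")
  set_ij <- c(key, enc(mem))
  total <- 0
  for (r in seq_len(nrow(mem))) {
    m <- mem[r, 1]; n <- mem[r, 2]
    key_mn <- paste(m, n, sep = ",")
    set_mn <- c(key_mn,
                if (is.null(ss[[key_mn]])) character(0) else enc(ss[[key_mn]]))
    inter <- length(intersect(set_ij, set_mn))
    uni <- length(union(set_ij, set_mn))
    jac <- if (uni == 0) 0 else inter / uni
    delta <- (x[i, ] - x[m, ]) - (y[j, ] - y[n, ])
    stat <- sum((delta / (stds * std_factor))^2)
    total <- total + jac * pchisq(stat, df = ncol(x), lower.tail = FALSE)
  }
  total
}

# Brute-force DBSCAN: core points from neighborhood counts (including self),
# clusters as connected components of the core-core adjacency, border points
# attachable to any cluster owning a core neighbor.
oracle_dbscan <- function(z, cutoff, min_points) {
  n <- nrow(z)
  d <- as.matrix(dist(z))
  adj <- d <= cutoff
  core <- rowSums(adj) >= min_points
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (p in which(core)) {
    if (!is.na(comp[p])) next
    cid <- cid + 1L
    stack <- p
    while (length(stack) > 0) {
      q <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[q])) next
      comp[q] <- cid
      nb <- which(adj[q, ] & core & is.na(comp))
      stack <- c(stack, nb)
    }
  }
  border_opts <- lapply(seq_len(n), function(p) {
    if (core[p]) return(integer(0))
    unique(comp[which(adj[p, ] & core)])
  })
  list(core = core, core_cluster = comp, border_options = border_opts)
}

# random small peak list for property tests
random_peaklist <- function(n, k = 2, spread = 1) {
  peak_list(matrix(runif(n * k, 0, spread), n, k))
}
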