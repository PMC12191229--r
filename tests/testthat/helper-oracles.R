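# Independent oracles and small fixtures used across the suite.

# Minimal 4-marker panel: one DNA, one nuclear, two membrane.
tiny_panel <- function() {
  marker_panel(c("DNA1", "Ki67", "CD44", "F4/80"),
               c("191Ir", "168Er", "171Yb", "146Nd"),
               c("dna", "nuclear", "membrane", "membrane"))
}

# Two well-separated phenotypes on the tiny panel.
tiny_phenotypes <- function(sep = 40) {
  base <- c(DNA1 = 30, Ki67 = 0.5, CD44 = 0.5, `F4/80` = 0.5)
  a <- base; a["CD44"] <- sep
  b <- base; b["F4/80"] <- sep
  list(list(name = "tumor cells", means = a, proportion = 0.5),
       list(name = "macrophages", means = b, proportion = 0.5))
}

# Exhaustive nearest-neighbor scan (the O(n^2) oracle).
nn_exhaustive <- function(qx, qy, rx, ry, exclude = NULL) {
  vapply(seq_along(qx), function(i) {
    d <- sqrt((rx - qx[i])^2 + (ry - qy[i])^2)
    if (!is.null(exclude) && !is.na(exclude[i])) d <- d[-exclude[i]]
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))
}

# Benjamini-Hochberg by the step-up definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Total within-cluster sum of squares of an assignment.
wss_objective <- function(x, cl) {
  sum(vapply(unique(cl), function(c) {
    sub <- x[cl == c, , drop = FALSE]
    sum(scale(sub, scale = FALSE)^2)
  }, numeric(1)))
}

# Exhaustive minimum 2-means objective over all bipartitions (n <= 15).
wss_exhaustive_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    cl <- as.integer(intToBits(code))[1:n]
    if (all(cl == cl[1])) next
    best <- min(best, wss_objective(x, cl))
  }
  best
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(choose(v, 2))
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
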