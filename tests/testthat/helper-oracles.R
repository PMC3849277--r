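# Independent oracles.  These re-derive expected values from first
# principles (raw OBO text, naive summations, explicit enumeration) and are
# deliberately kept free of the package's own graph machinery.

# edge list straight from OBO text (child -> parent over is_a/part_of)
oracle_edges <- function(obo_text) {
  lines <- trimws(strsplit(obo_text, "\n", fixed = TRUE)[[1L]])
  child <- NA_character_
  from <- character(0L)
  to <- character(0L)
  for (ln in lines) {
    if (grepl("^id:", ln)) child <- trimws(sub("^id:", "", ln))
    else if (grepl("^is_a:", ln)) {
      p <- sub("\\s*!.*$", "", trimws(sub("^is_a:", "", ln)))
      from <- c(from, child); to <- c(to, p)
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      p <- sub("\\s*!.*$", "", trimws(sub("^relationship:\\s*part_of", "", ln)))
      from <- c(from, child); to <- c(to, p)
    }
  }
  data.frame(child = from, parent = to, stringsAsFactors = FALSE)
}

# transitive closure by repeated edge expansion
oracle_ancestors <- function(edges, term, inclusive = FALSE) {
  anc <- character(0L)
  frontier <- term
  repeat {
    nxt <- setdiff(edges$parent[edges$child %in% frontier], anc)
    if (!length(nxt)) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(if (inclusive) unique(c(term, anc)) else unique(anc))
}

# naive Eq-1 (average best matches) and Eq-2 (best-match average)
oracle_abm <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  s <- 0
  for (i in seq_len(n)) s <- s + max(mat[i, ])
  for (j in seq_len(m)) s <- s + max(mat[, j])
  s / (n + m)
}

oracle_bma <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  a <- 0; b <- 0
  for (i in seq_len(n)) a <- a + max(mat[i, ])
  for (j in seq_len(m)) b <- b + max(mat[, j])
  (a / n + b / m) / 2
}

# naive Eq-3 (Dice) and Eq-4 (universal) direct measures
oracle_simdic <- function(icv, cp, cq) {
  inter <- intersect(cp, cq)
  2 * sum(icv[inter]) / (sum(icv[cp]) + sum(icv[cq]))
}

oracle_simuic <- function(icv, cp, cq) {
  inter <- intersect(cp, cq)
  sum(icv[inter]) / max(sum(icv[cp]), sum(icv[cq]))
}

# hypergeometric upper tail by direct term-wise summation (exact until
# double rounding; error << 1e-12 for N <= 60)
oracle_hyper_tail <- function(N, m, n, l) {
  ks <- l:min(n, m)
  if (l > min(n, m)) return(0)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# brute-force UPGMA agglomeration on a distance matrix: returns the sorted
# merge heights (average of ALL inter-point distances between clusters)
oracle_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0L)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# adjusted Rand index
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# naive MICA-family term similarity from explicit common-ancestor
# enumeration over the raw edge list
oracle_term_sim <- function(edges, icv, ic_max, t1, t2, approach) {
  ca <- intersect(oracle_ancestors(edges, t1, inclusive = TRUE),
                  oracle_ancestors(edges, t2, inclusive = TRUE))
  vals <- icv[ca]
  vals <- vals[!is.na(vals)]
  icm <- max(vals)
  lin <- function(x) if (icv[[t1]] + icv[[t2]] <= 0) 0 else
    2 * x / (icv[[t1]] + icv[[t2]])
  if (t1 == t2) return(1)
  out <- switch(approach,
    resnik = icm / ic_max,
    lin = lin(icm),
    relevance = lin(icm) * (1 - exp(-icm)),
    li = lin(icm) * (1 - 1 / (1 + icm)),
    xgrasm_resnik = {
      ica <- vals[vals > 0]
      if (t1 == t2) 1 else if (!length(ica)) 0 else mean(ica) / ic_max
    },
    xgrasm = {
      ica <- vals[vals > 0]
      if (t1 == t2) 1 else if (!length(ica)) 0 else lin(mean(ica))
    }
  )
  min(max(out, 0), 1)
}
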