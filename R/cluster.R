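# Protein functional clustering: agglomerative clustering on the distance
# d = 1 - similarity (with Newick export), and spectral k-means on the
# similarity graph.

#' Pairwise protein similarity matrix
#'
#' Scores every pair of the given proteins under one measure.  Proteins
#' without annotation in the namespace are dropped with a warning; fewer
#' than two surviving proteins is an error.
#'
#' @param graph a `go_ontology`.
#' @param corpus a `go_corpus`.
#' @param proteins protein accessions or gene symbols.
#' @param measure registry label or list (see [protein_similarity()]).
#' @param ic IC table where the measure needs one.
#' @param namespace GO namespace.
#' @return a symmetric numeric matrix with unit diagonal and the protein ids
#'   as dimnames.
#' @export
protein_sim_matrix <- function(graph, corpus, proteins, measure, ic = NULL,
                               namespace = "biological_process") {
  proteins <- unique(vapply(proteins, function(x) resolve_protein(corpus, x),
                            character(1L)))
  annotated <- proteins %in% names(corpus$direct[[namespace]])
  if (any(!annotated)) {
    warning("dropping ", sum(!annotated),
            " protein(s) without annotation in ", namespace, ": ",
            paste(proteins[!annotated], collapse = ", "))
    proteins <- proteins[annotated]
  }
  if (length(proteins) < 2L) {
    gf_error("fewer than two annotated proteins; nothing to cluster",
             "gf_parameter_error")
  }
  n <- length(proteins)
  m <- diag(1, n)
  dimnames(m) <- list(proteins, proteins)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- protein_similarity(graph, corpus, proteins[i], proteins[j],
                              measure, ic, namespace)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Drop proteins until a similarity matrix is NA-free
#'
#' Iteratively removes the protein with the most missing entries; imputation
#' would invent similarity.
#'
#' @param sim a square similarity matrix.
#' @return the largest NA-free principal submatrix under the greedy policy.
#' @export
drop_na_proteins <- function(sim) {
  while (anyNA(sim) && nrow(sim) > 0L) {
    na_count <- rowSums(is.na(sim))
    worst <- which.max(na_count)
    sim <- sim[-worst, -worst, drop = FALSE]
  }
  sim
}

#' Hierarchical clustering of a protein similarity matrix
#'
#' Agglomerative clustering on the distance `1 - similarity`.  Merge order
#' is deterministic given the input order.
#'
#' @param sim a symmetric similarity matrix in `[0, 1]` (no `NA`; see
#'   [drop_na_proteins()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an object of class `go_dendrogram`: a list with the `hclust`
#'   tree, the `linkage`, and the `newick` serialization (branch lengths on
#'   the `1 - s` distance scale).
#' @export
cluster_hierarchical <- function(sim, linkage = c("average", "complete",
                                                  "single")) {
  linkage <- match.arg(linkage)
  if (anyNA(sim)) {
    gf_error("similarity matrix contains NA; drop or complete it first",
             "gf_parameter_error")
  }
  if (nrow(sim) < 2L) {
    gf_error("need at least two proteins to cluster", "gf_parameter_error")
  }
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, linkage = linkage,
                 newick = ape::write.tree(phy)),
            class = "go_dendrogram")
}

#' @export
print.go_dendrogram <- function(x, ...) {
  cat("go_dendrogram (", x$linkage, " linkage, ",
      length(x$hclust$labels), " leaves)\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

# k-means++ seeding on an embedding matrix, driven by a local RNG stream
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

#' Spectral k-means clustering of a protein similarity matrix
#'
#' Embeds the similarity graph through the normalized Laplacian
#' (`L = I - D^{-1/2} S D^{-1/2}`) into the k leading eigenvectors,
#' row-normalizes, and runs k-means with k-means++ initialization at the
#' given seed; deterministic for a fixed seed.
#'
#' @param sim a symmetric similarity matrix (no `NA`).
#' @param k expected number of clusters, `2 <= k < nrow(sim)`.
#' @param seed integer RNG seed.
#' @return a named integer vector protein -> cluster id in `1..k`.
#' @export
cluster_spectral <- function(sim, k, seed = 1L) {
  if (anyNA(sim)) {
    gf_error("similarity matrix contains NA; drop or complete it first",
             "gf_parameter_error")
  }
  n <- nrow(sim)
  if (k < 2L || k >= n) {
    gf_error(sprintf("k = %d out of range (need 2 <= k < %d)", k, n),
             "gf_parameter_error")
  }
  S <- (sim + t(sim)) / 2
  deg <- rowSums(S)
  deg[deg <= 0] <- .Machine$double.eps
  Dm <- 1 / sqrt(deg)
  L <- diag(n) - (Dm %o% Dm) * S
  ev <- eigen(L, symmetric = TRUE)
  # k smallest eigenvalues of L
  X <- ev$vectors[, n:(n - k + 1L), drop = FALSE]
  rn <- sqrt(rowSums(X^2))
  rn[rn == 0] <- 1
  X <- X / rn

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  centers <- .kmeanspp_centers(X, k)
  if (anyDuplicated(centers)) {
    # degenerate embedding with coincident points: break ties minutely
    centers <- centers + matrix(stats::runif(length(centers), -1e-9, 1e-9),
                                nrow(centers))
  }
  km <- stats::kmeans(X, centers = centers, iter.max = 100L)
  stats::setNames(km$cluster, rownames(sim))
}
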