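# Fuzzy k-means clustering of gene expression profiles.
#
# Genes are the clustered observations: each gene's vector is its
# (per-gene standardized) expression across samples, so Euclidean distance
# reflects profile shape rather than magnitude. Membership degrees follow
#   u_ij = 1 / sum_k (||x_i - v_j|| / ||x_i - v_k||)^(2/(m-1))
# and centroids are the membership-weighted means
#   v_j = sum_i u_ij^m x_i / sum_i u_ij^m.

.COINCIDENT_EPS <- 1e-12

.sqDistToCentroids <- function(X, V) {
  # points x centroids matrix of squared Euclidean distances
  d2 <- outer(rowSums(X^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
  pmax(d2, 0)
}

#' Fuzzy k-means membership degrees
#'
#' Computes the membership matrix for fixed centroids:
#' \deqn{u_{ij} = 1 / \sum_k (\|x_i - v_j\| / \|x_i - v_k\|)^{2/(m-1)}.}
#' Rows sum to one. A point coincident with one or more centroids gets its
#' full membership split equally among the coincident centroids (the
#' documented tie rule); a point equidistant from all centroids gets
#' uniform membership.
#'
#' @param X points x dims numeric matrix.
#' @param V centroids x dims numeric matrix (pairwise distinct).
#' @param mFuzz fuzziness exponent, > 1.
#' @return points x centroids membership matrix.
#' @export
fuzzyMembership <- function(X, V, mFuzz = 2) {
  X <- as.matrix(X); V <- as.matrix(V)
  stopifnot(mFuzz > 1, ncol(X) == ncol(V))
  d2 <- .sqDistToCentroids(X, V)
  expo <- 1 / (mFuzz - 1)              # applied to squared distances
  inv <- (1 / pmax(d2, .Machine$double.xmin))^expo
  U <- inv / rowSums(inv)
  hit <- d2 <= .COINCIDENT_EPS
  coincident <- rowSums(hit) > 0
  if (any(coincident)) {
    U[coincident, ] <- 0
    U[coincident, ] <- hit[coincident, , drop = FALSE] /
      rowSums(hit[coincident, , drop = FALSE])
  }
  dimnames(U) <- list(rownames(X), rownames(V))
  U
}

#' Fuzzy k-means centroid update
#'
#' Membership-weighted mean of the data points:
#' \deqn{v_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m.}
#' A cluster whose weights all vanish is re-seeded from a random data
#' point (seeded externally via the caller's RNG state) with a message.
#'
#' @param X points x dims matrix.
#' @param U points x clusters membership matrix (rows sum to 1).
#' @param mFuzz fuzziness exponent.
#' @return clusters x dims centroid matrix.
#' @export
updateCentroids <- function(X, U, mFuzz = 2) {
  X <- as.matrix(X)
  W <- U^mFuzz
  tot <- colSums(W)
  dead <- tot <= .Machine$double.xmin
  V <- matrix(NA_real_, ncol(U), ncol(X))
  if (any(!dead))
    V[!dead, ] <- t(W[, !dead, drop = FALSE]) %*% X / tot[!dead]
  if (any(dead)) {
    message(sprintf("re-seeding %d empty cluster(s) from random points",
                    sum(dead)))
    V[dead, ] <- X[sample.int(nrow(X), sum(dead)), , drop = FALSE]
  }
  rownames(V) <- colnames(U)
  V
}

.fuzzyObjective <- function(X, V, U, mFuzz) {
  sum(U^mFuzz * .sqDistToCentroids(as.matrix(X), V))
}

#' Fit fuzzy k-means
#'
#' Alternates [fuzzyMembership()] and [updateCentroids()] from a seeded
#' random-distinct-points initialization until the maximum centroid
#' displacement falls below \code{tol} or \code{maxIter} is reached. The
#' objective \eqn{J = \sum_{ij} u_{ij}^m \|x_i - v_j\|^2} is recorded per
#' iteration and is non-increasing.
#'
#' @param X points x dims matrix (for gene clustering: genes in rows,
#'   samples in columns; see [standardizeGenes()]).
#' @param c number of clusters (>= 1; fewer points than clusters is an
#'   error). Cohort-scale gene clustering is typically scanned over
#'   c = 6..12.
#' @param mFuzz fuzziness exponent, default 2 (the field-standard value).
#' @param tol convergence tolerance on max centroid displacement.
#' @param maxIter iteration cap.
#' @param seed integer seed for the initialization.
#' @return A [FuzzyClustering-class].
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
#' fit <- fitFuzzyKmeans(X, c = 2, seed = 1)
#' table(apply(membership(fit), 1, which.max))
#' @export
fitFuzzyKmeans <- function(X, c, mFuzz = 2, tol = 1e-5, maxIter = 300,
                           seed = 1) {
  X <- as.matrix(X)
  if (c < 1) stop("c must be >= 1")
  if (nrow(X) < c)
    stop(sprintf("fewer points (%d) than clusters (%d)", nrow(X), c))
  if (is.null(rownames(X))) rownames(X) <- paste0("p", seq_len(nrow(X)))
  seed <- as.integer(seed)
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
  # initialize from distinct points (distinct rows, to keep centroids apart)
  uniq <- which(!duplicated(X))
  if (length(uniq) < c)
    stop("not enough distinct points to seed centroids")
  V <- X[uniq[sample.int(length(uniq), c)], , drop = FALSE]
  rownames(V) <- paste0("cluster", seq_len(c))

  objective <- numeric(0)
  converged <- FALSE
  U <- fuzzyMembership(X, V, mFuzz)
  for (it in seq_len(maxIter)) {
    Vnew <- updateCentroids(X, U, mFuzz)
    rownames(Vnew) <- rownames(V)
    U <- fuzzyMembership(X, Vnew, mFuzz)
    objective <- c(objective, .fuzzyObjective(X, Vnew, U, mFuzz))
    disp <- max(sqrt(rowSums((Vnew - V)^2)))
    V <- Vnew
    if (disp < tol) { converged <- TRUE; break }
  }
  new("FuzzyClustering", c = as.integer(c), mFuzz = mFuzz, centroids = V,
      membership = U, objective = objective, converged = converged,
      seed = seed)
}

#' Standardize gene expression profiles for clustering
#'
#' Transposes an expression [OmicsBlock-class] to genes x samples and
#' standardizes each gene to zero mean and unit variance across samples
#' (constant genes are centred only), so Euclidean distance between gene
#' profiles reflects shape rather than magnitude.
#'
#' @param block expression [OmicsBlock-class] (samples x genes).
#' @return genes x samples standardized matrix.
#' @export
standardizeGenes <- function(block) {
  G <- t(blockValues(block))
  mu <- rowMeans(G)
  sdv <- apply(G, 1, sd)
  sdv[sdv == 0] <- 1
  (G - mu) / sdv
}

#' Rank genes by their maximal cluster membership
#'
#' Assigns each gene to its argmax-membership cluster and scores it by
#' that maximal membership degree (its centrality in the cluster). Genes
#' are ordered by cluster, then score descending, with a deterministic
#' lexicographic tie-break on gene identifier.
#'
#' @param clustering a fitted [FuzzyClustering-class].
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{score}, sorted as described.
#' @export
rankGenesByMembership <- function(clustering) {
  U <- membership(clustering)
  genes <- rownames(U)
  cl <- apply(U, 1, which.max)
  score <- U[cbind(seq_len(nrow(U)), cl)]
  out <- data.frame(gene = genes, cluster = as.integer(cl), score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
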