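# Expression-profile processing: detection filter, deregulation calls,
# standardization, fuzzy c-means soft clustering with membership cores,
# cluster-number selection, set overlap and target enrichment.

#' Gene-expression time-course matrix
#'
#' @param values genes x timepoints matrix (intensities or fold changes),
#'   gene ids as rownames.
#' @param timepoints numeric timepoint labels (min), increasing; the first
#'   is the t = 0 reference.
#' @param detection_p optional matrix of detection p-values, same shape.
#' @return an object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, timepoints, detection_p = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values needs gene ids as rownames")
  if (length(timepoints) != ncol(values))
    stop("timepoints must match the number of columns")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (!is.null(detection_p) && !all(dim(detection_p) == dim(values)))
    stop("detection_p must have the same shape as values")
  structure(list(values = values, timepoints = timepoints,
                 detection_p = detection_p), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d timepoints (%g-%g min)%s\n",
              nrow(x$values), ncol(x$values), min(x$timepoints),
              max(x$timepoints),
              if (is.null(x$detection_p)) "" else ", with detection p-values"))
  invisible(x)
}

#' Detection filter
#'
#' Keeps genes detected (p below threshold) in at least one condition.
#'
#' @param em an [expression_matrix()] with detection p-values.
#' @param p_threshold detection p-value threshold (default 0.05).
#' @return filtered \code{expression_matrix}.
#' @export
filter_detected <- function(em, p_threshold = 0.05) {
  if (is.null(em$detection_p))
    stop("no detection p-values present; skip this filter explicitly if intended")
  keep <- apply(em$detection_p, 1, min) < p_threshold
  expression_matrix(em$values[keep, , drop = FALSE], em$timepoints,
                    em$detection_p[keep, , drop = FALSE])
}

#' Deregulation calls
#'
#' Flags a gene as deregulated when the absolute log2 fold change relative
#' to the t = 0 timepoint exceeds 1 at any timepoint (strict inequality);
#' the direction is the sign of the most extreme log2 fold change.
#'
#' @param em an [expression_matrix()] of positive values whose first
#'   timepoint is the reference.
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @return data frame with \code{gene}, \code{max_abs_log2fc},
#'   \code{direction} ("up"/"down"/"none").
#' @export
call_deregulated <- function(em, lfc_threshold = 1) {
  v <- em$values
  if (any(v <= 0)) stop("values must be positive for log fold changes")
  if (em$timepoints[1] != 0) stop("first timepoint must be the t = 0 reference")
  lfc <- log2(v / v[, 1])
  idx <- apply(abs(lfc), 1, which.max)
  extreme <- lfc[cbind(seq_len(nrow(lfc)), idx)]
  data.frame(
    gene = rownames(v),
    max_abs_log2fc = abs(extreme),
    direction = ifelse(abs(extreme) > lfc_threshold,
                       ifelse(extreme > 0, "up", "down"), "none"),
    stringsAsFactors = FALSE)
}

#' Standardize expression profiles
#'
#' Per-gene z-scoring of the log2 profile (population standard deviation),
#' so clustering sees only the \emph{shape} of each time course. Genes with
#' zero variance are excluded (their shape is undefined).
#'
#' @param em an [expression_matrix()] of positive values.
#' @return list with \code{z} (standardized matrix), \code{excluded}
#'   (zero-variance gene ids).
#' @export
standardize_profiles <- function(em) {
  v <- em$values
  if (any(v <= 0)) stop("values must be positive for the log transform")
  lg <- log2(v)
  mu <- rowMeans(lg)
  sdp <- sqrt(rowMeans((lg - mu)^2))  # population sd
  excluded <- rownames(v)[sdp == 0]
  keep <- sdp > 0
  z <- (lg[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
  if (length(excluded)) warning(length(excluded), " zero-variance gene(s) excluded")
  list(z = z, excluded = excluded)
}

# Farthest-point (k-means++-style) centroid initialization.
init_centroids <- function(x, c) {
  n <- nrow(x)
  first <- sample.int(n, 1)
  idx <- first
  d2 <- rowSums((x - matrix(x[first, ], n, ncol(x), byrow = TRUE))^2)
  while (length(idx) < c) {
    nxt <- which.max(d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums((x - matrix(x[nxt, ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' Fuzzy c-means soft clustering
#'
#' Standard fuzzy c-means on Euclidean distance: membership
#' \code{u_ij = (1/d_ij^2)^(1/(m-1))} normalized over clusters, centroids
#' the \code{u^m}-weighted means, iterated until the membership change
#' falls below \code{tol}. A gene exactly on a centroid gets membership 1
#' there. The c-means objective \code{sum(u^m d^2)} is checked to be
#' non-increasing across iterations.
#'
#' @param x standardized profiles (genes x timepoints).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1; default 1.5).
#' @param seed integer seed for the centroid initialization.
#' @param tol convergence tolerance on max membership change.
#' @param max_iter iteration cap.
#' @param n_start number of seeded initializations (the first uses
#'   farthest-point seeding, the rest random gene rows); the run with the
#'   lowest final objective is returned (default 10).
#' @return an object of class \code{cluster_result}: \code{centroids},
#'   \code{memberships} (rows sum to 1), \code{m}, \code{iterations},
#'   \code{objective} (trace), \code{min_intercentroid} (smallest pairwise
#'   centroid distance).
#' @export
fuzzy_cmeans <- function(x, c, m = 1.5, seed, tol = 1e-6, max_iter = 500,
                         n_start = 10) {
  if (missing(seed)) stop("fuzzy_cmeans requires an explicit seed")
  best <- NULL
  for (s in seq_len(n_start)) {
    res <- fuzzy_cmeans_once(x, c, m, seed + s - 1, tol, max_iter,
                             random_init = s > 1)
    if (is.null(best) ||
        res$objective[length(res$objective)] <
          best$objective[length(best$objective)])
      best <- res
  }
  best
}

fuzzy_cmeans_once <- function(x, c, m, seed, tol, max_iter,
                              random_init = FALSE) {
  x <- as.matrix(x)
  if (c < 2) stop("c must be >= 2")
  if (nrow(x) < c) stop("need at least c genes")
  if (m <= 1) stop("fuzzifier m must be > 1")
  set.seed(seed)
  cen <- if (random_init) x[sample.int(nrow(x), c), , drop = FALSE]
         else init_centroids(x, c)
  n <- nrow(x)
  u_old <- matrix(0, n, c)
  obj <- numeric(0)
  expn <- 1 / (m - 1)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(cen) +
      outer(rep(1, n), rowSums(cen^2))
    d2[d2 < 0] <- 0
    u <- matrix(0, n, c)
    zero <- d2 <= .Machine$double.eps
    onzero <- rowSums(zero) > 0
    if (any(onzero))
      u[onzero, ] <- zero[onzero, , drop = FALSE] /
        rowSums(zero[onzero, , drop = FALSE])
    if (any(!onzero)) {
      w <- (1 / d2[!onzero, , drop = FALSE])^expn
      u[!onzero, ] <- w / rowSums(w)
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    if (length(obj) > 1 && obj[length(obj)] > obj[length(obj) - 1] + 1e-8 *
        max(1, obj[length(obj) - 1]))
      warning("c-means objective increased; check inputs")
    cen <- (t(um) %*% x) / colSums(um)
    if (max(abs(u - u_old)) < tol) { u_old <- u; break }
    u_old <- u
  }
  dimnames(u_old) <- list(rownames(x), paste0("cluster_", seq_len(c)))
  dc <- stats::dist(cen)
  structure(list(centroids = cen, memberships = u_old, m = m,
                 iterations = it, objective = obj,
                 min_intercentroid = min(dc)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, %d genes, m = %g, %d iterations, min inter-centroid %.3f\n",
              ncol(x$memberships), nrow(x$memberships), x$m, x$iterations,
              x$min_intercentroid))
  invisible(x)
}

#' Cluster-number selection curve
#'
#' Runs the soft clustering for each candidate cluster count and records
#' the minimum inter-centroid distance; a pronounced drop after c* suggests
#' c* clusters. The helper flags the c with the largest relative drop from
#' its predecessor.
#'
#' @param x standardized profiles.
#' @param c_range candidate cluster counts.
#' @param m fuzzifier.
#' @param seed integer seed (each c uses \code{seed}).
#' @return data frame with \code{c}, \code{min_intercentroid},
#'   \code{relative_drop}, \code{elbow} flag.
#' @export
select_cluster_count <- function(x, c_range, m = 1.5, seed) {
  if (missing(seed)) stop("select_cluster_count requires an explicit seed")
  md <- vapply(c_range, function(cc)
    fuzzy_cmeans(x, cc, m = m, seed = seed)$min_intercentroid, numeric(1))
  drop <- c(NA, 1 - md[-1] / md[-length(md)])
  elbow <- rep(FALSE, length(c_range))
  if (length(c_range) > 1) elbow[which.max(drop)] <- TRUE
  data.frame(c = c_range, min_intercentroid = md,
             relative_drop = drop, elbow = elbow)
}

#' Extract cluster cores
#'
#' @param memberships genes x clusters membership matrix.
#' @param threshold minimum membership (default 0.5); genes meeting it in
#'   several clusters (possible only at exactly 0.5) belong to each.
#' @return named list of gene-id vectors, one per cluster.
#' @export
extract_cores <- function(memberships, threshold = 0.5) {
  lapply(seq_len(ncol(memberships)), function(j)
    rownames(memberships)[memberships[, j] >= threshold])
}

#' Overlap (Szymkiewicz-Simpson) coefficient
#'
#' \code{|X intersect Y| / min(|X|, |Y|)} between two gene sets.
#'
#' @param X,Y non-empty character vectors.
#' @return value in [0, 1].
#' @export
overlap_coefficient <- function(X, Y) {
  X <- unique(X); Y <- unique(Y)
  if (!length(X) || !length(Y)) stop("sets must be non-empty")
  length(intersect(X, Y)) / min(length(X), length(Y))
}

#' Target-set enrichment of a cluster
#'
#' One-sided Fisher's exact test of the association between cluster
#' membership and target-set membership within a gene universe.
#'
#' @param cluster_genes genes in the cluster (subset of universe).
#' @param target_genes target set (subset of universe).
#' @param universe all genes considered.
#' @return list with \code{odds_ratio}, \code{p_value},
#'   \code{neg_log10_p}, \code{table} (the 2x2 contingency table).
#' @export
enrichment_test <- function(cluster_genes, target_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  cluster_genes <- unique(cluster_genes); target_genes <- unique(target_genes)
  if (!all(cluster_genes %in% universe) || !all(target_genes %in% universe))
    stop("cluster and target sets must be subsets of the universe")
  a <- length(intersect(cluster_genes, target_genes))
  b <- length(setdiff(cluster_genes, target_genes))
  cc <- length(setdiff(target_genes, cluster_genes))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(cluster = c("in", "out"),
                                target = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       neg_log10_p = -log10(ft$p.value), table = tab)
}
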