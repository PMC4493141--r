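# Comparing unfolding pathways: Manhattan distances between residue-wise
# percolation profiles, k-medoids clustering, per-variant cluster
# distributions and their pairwise correlations. A low correlation between
# two variants' distributions flags low confidence in their relative
# thermostability prediction.

#' Bundle percolation profiles from several variants
#'
#' @param profiles numeric matrix, one row per network topology, one column
#'   per residue (values in K), or a list of equal-length profile vectors.
#' @param labels variant label per profile.
#' @return object of class `cna_profile_set`.
#' @export
profile_set <- function(profiles, labels) {
  if (is.list(profiles) && !is.matrix(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  labels <- as.character(labels)
  if (length(labels) != nrow(profiles))
    stop("one label per profile required")
  if (any(!nzchar(labels))) stop("labels must be non-empty")
  if (any(!is.finite(profiles))) stop("profiles contain non-finite values")
  structure(list(profiles = profiles, labels = labels),
            class = "cna_profile_set")
}

#' Manhattan distance between two percolation profiles
#'
#' @param a,b numeric profiles of equal length (K).
#' @return sum of absolute residue-wise differences (K).
#' @examples
#' manhattan_distance(c(1, 2), c(2, 4))
#' @export
manhattan_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles have different lengths")
  sum(abs(a - b))
}

#' Partition profiles around medoids
#'
#' k-medoids clustering of the profiles under Manhattan distance
#' (Partitioning Around Medoids with deterministic BUILD initialization and
#' swap phase to convergence); the objective is the mean dissimilarity of
#' all profiles to their nearest medoid. `seed` is accepted for interface
#' stability but unused: PAM on a fixed profile set is deterministic.
#'
#' @param ps a [profile_set()].
#' @param k number of clusters (default 10).
#' @param seed unused; PAM is deterministic.
#' @return list with `medoids` (profile row indices), `assignment`,
#'   `objective`, `k`.
#' @export
pam_cluster <- function(ps, k = 10, seed = NULL) {
  stopifnot(inherits(ps, "cna_profile_set"))
  n <- nrow(ps$profiles)
  if (k > n) stop("k must not exceed the number of profiles")
  if (k == n) {
    return(list(medoids = seq_len(n), assignment = seq_len(n),
                objective = 0, k = as.integer(k)))
  }
  d <- dist(ps$profiles, method = "manhattan")
  fit <- cluster::pam(d, k = k, diss = TRUE)
  list(medoids = as.integer(fit$id.med),
       assignment = as.integer(fit$clustering),
       objective = unname(fit$objective["swap"]),
       k = as.integer(k))
}

#' Clustering objective as a function of k
#'
#' Used to choose the number of clusters: the mean dissimilarity to the
#' nearest medoid is monitored while `k` grows and the elbow is read off.
#'
#' @param ps a [profile_set()].
#' @param k_range integer vector of cluster counts.
#' @param seed unused; see [pam_cluster()].
#' @return data frame with `k` and `objective`.
#' @export
objective_vs_k <- function(ps, k_range, seed = NULL) {
  data.frame(k = as.integer(k_range),
             objective = vapply(k_range, function(k) pam_cluster(ps, k)$objective,
                                numeric(1)))
}

#' Per-variant cluster distributions
#'
#' Counts how many of each variant's network topologies fall into each
#' pathway cluster.
#'
#' @param assignment cluster assignment per profile (from [pam_cluster()]).
#' @param labels variant label per profile.
#' @param k number of clusters.
#' @return integer matrix, variants x clusters.
#' @export
cluster_distribution <- function(assignment, labels, k) {
  stopifnot(length(assignment) == length(labels))
  if (any(assignment < 1 | assignment > k)) stop("assignment outside 1..k")
  tab <- table(factor(labels, levels = unique(labels)),
               factor(assignment, levels = seq_len(k)))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  mat
}

#' Pairwise correlations of cluster distributions
#'
#' Pearson correlation between the cluster-count vectors of every pair of
#' variants. A high correlation means the two variants unfold through
#' similar pathway distributions; a low one flags that their relative
#' thermostability prediction should be treated with caution. Zero-variance
#' distributions yield `NA` (recorded as missing) with a warning.
#'
#' @param counts variants x clusters count matrix (from
#'   [cluster_distribution()]).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
distribution_correlation_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least two variants")
  degenerate <- apply(counts, 1, function(x) stats::var(x) == 0)
  if (any(degenerate))
    warning("zero-variance distribution(s): ",
            paste(rownames(counts)[degenerate], collapse = ", "),
            "; correlations recorded as missing")
  r <- suppressWarnings(cor(t(counts)))
  diag(r) <- 1
  r
}

#' Mean pathway correlation per variant
#'
#' The average off-diagonal correlation of each variant against all others;
#' variants below `threshold` are flagged as pathway outliers whose
#' thermostability ranking is less reliable.
#'
#' @param r correlation matrix from [distribution_correlation_matrix()].
#' @param threshold flag threshold on the mean correlation (default 0.16).
#' @return data frame with `variant`, `mean_r`, `low_confidence`.
#' @export
pathway_reliability <- function(r, threshold = 0.16) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  mean_r <- vapply(seq_len(nrow(r)), function(i)
    mean(r[i, -i], na.rm = TRUE), numeric(1))
  data.frame(variant = rownames(r) %||% as.character(seq_len(nrow(r))),
             mean_r = mean_r, low_confidence = mean_r < threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
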