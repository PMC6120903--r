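condition_key <- function(conditions) {
  paste(conditions$strain, conditions$medium, conditions$stresses, sep = " | ")
}

#' Merged condition-by-site binary profile matrix
#'
#' Evolution runs sharing the same strain, medium and stress set are merged
#' into one binary mutation profile (one row per unique combination); the
#' columns are all tracked genome sites. Mutations hitting different
#' positions or with different types within a site are not distinguished.
#'
#' @param compendium a `compendium`.
#' @return object of class `condition_profiles`: list with `matrix` (0/1,
#'   rows = merged conditions, columns = sites), `keys` (data.frame with
#'   strain/medium/stresses/generations and member condition ids).
#' @export
build_condition_profiles <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  cond <- compendium$conditions
  key <- condition_key(cond)
  groups <- split(cond$condition_id, key)
  sites <- compendium_sites(compendium)
  mat <- matrix(0L, nrow = length(groups), ncol = length(sites),
                dimnames = list(names(groups), sites))
  reps <- compendium$replicates
  for (i in seq_along(groups)) {
    ids <- reps$replicate_id[reps$condition_id %in% groups[[i]]]
    mat[i, ] <- replicate_set_profile(compendium, ids)
  }
  first <- match(names(groups), key)
  keys <- data.frame(key = names(groups),
                     strain = cond$strain[first], medium = cond$medium[first],
                     stresses = cond$stresses[first],
                     generations = vapply(groups, function(ids)
                       max(cond$generations[cond$condition_id %in% ids]), numeric(1)),
                     n_conditions = lengths(groups),
                     stringsAsFactors = FALSE)
  keys$condition_ids <- unname(groups)
  rownames(keys) <- NULL
  structure(list(matrix = mat, keys = keys), class = "condition_profiles")
}

## plug-in entropy of a Bernoulli(p) in bits
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

#' Pairwise mutual-information matrix of mutation profiles
#'
#' Plug-in (empirical) mutual information, in bits, between every pair of
#' genome sites across merged condition profiles. Sites mutated under fewer
#' than two conditions are excluded before the computation, following the
#' filtering used for co-occurrence analysis. The diagonal holds the marginal
#' entropy of each site.
#'
#' @param profiles a [build_condition_profiles()] result, or a plain binary
#'   matrix (rows = conditions, columns = sites).
#' @param min_conditions minimum number of conditions a site must be mutated
#'   in to be kept (default 2).
#' @return object of class `mi_matrix`: list with `sites`, `values`
#'   (symmetric matrix, bits) and `n_conditions`.
#' @export
mi_matrix <- function(profiles, min_conditions = 2L) {
  X <- if (inherits(profiles, "condition_profiles")) profiles$matrix else as.matrix(profiles)
  if (is.null(colnames(X))) colnames(X) <- paste0("site", seq_len(ncol(X)))
  keep <- colSums(X) >= min_conditions
  X <- X[, keep, drop = FALSE]
  R <- nrow(X)
  if (R < 2L) stopf("need at least 2 condition profiles for mutual information")
  if (!ncol(X)) stopf("no sites mutated in >= %d conditions", min_conditions)
  n11 <- crossprod(X)
  c1 <- colSums(X)
  n10 <- outer(c1, rep(1, length(c1))) - n11   # x=1, y=0
  n01 <- t(n10)
  n00 <- R - n11 - n10 - n01
  term <- function(nxy, rx, ry) {
    # nxy * log2(nxy * R / (rx * ry)) / R, with 0 log 0 = 0
    out <- matrix(0, nrow(nxy), ncol(nxy))
    ok <- nxy > 0
    denom <- outer(rx, ry)
    out[ok] <- (nxy[ok] / R) * log2(nxy[ok] * R / denom[ok])
    out
  }
  mi <- term(n11, c1, c1) + term(n10, c1, R - c1) +
    term(n01, R - c1, c1) + term(n00, R - c1, R - c1)
  mi[mi < 0] <- 0  # clip tiny negative rounding noise
  dimnames(mi) <- list(colnames(X), colnames(X))
  diag(mi) <- binary_entropy(c1 / R)
  structure(list(sites = colnames(X), values = mi, n_conditions = R),
            class = "mi_matrix")
}

#' Spectral clustering of the mutual-information matrix
#'
#' Treats the MI matrix as a similarity graph: the symmetric normalized
#' adjacency `D^{-1/2} A D^{-1/2}` (diagonal removed) is eigendecomposed, the
#' `k` leading eigenvectors are row-normalized and clustered with seeded
#' k-means. Clusters are relabelled in decreasing order of mean
#' within-cluster pairwise MI, so cluster 1 is the most strongly
#' co-occurring.
#'
#' @param mi a [mi_matrix()].
#' @param k number of clusters (the co-occurrence analyses in the source
#'   compendium used 19).
#' @param seed RNG seed for the k-means initialization.
#' @param nstart k-means restarts.
#' @return data.frame with columns `site`, `cluster`; attribute
#'   `cluster_summary` holds per-cluster size and mean within-cluster MI.
#' @export
spectral_cluster <- function(mi, k = 19, seed = 1, nstart = 25) {
  stopifnot(inherits(mi, "mi_matrix"))
  A <- mi$values
  if (any(!is.finite(A))) stopf("MI matrix contains non-finite values")
  n <- nrow(A)
  if (k < 2 || k > n) stopf("k must be between 2 and the number of sites (%d)", n)
  diag(A) <- 0
  if (k == n) {  # every site its own cluster; no embedding needed
    out <- data.frame(site = mi$sites, cluster = seq_len(n), stringsAsFactors = FALSE)
    attr(out, "cluster_summary") <- data.frame(cluster = seq_len(n), size = 1L,
                                               mean_within_mi = NA_real_)
    return(out)
  }
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  M <- A * outer(dinv, dinv)
  eig <- eigen(M, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(V^2))
  V <- V / ifelse(rn > 0, rn, 1)
  km <- local_seed(seed, kmeans(V, centers = k, nstart = nstart, iter.max = 100))
  raw <- km$cluster
  within_mi <- vapply(seq_len(k), function(cl) {
    ix <- which(raw == cl)
    if (length(ix) < 2) return(-Inf)
    sub <- A[ix, ix]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  relabel <- order(within_mi, decreasing = TRUE)
  new_lab <- match(raw, relabel)
  out <- data.frame(site = mi$sites, cluster = new_lab, stringsAsFactors = FALSE)
  attr(out, "cluster_summary") <- data.frame(
    cluster = seq_len(k),
    size = as.integer(table(factor(new_lab, levels = seq_len(k)))),
    mean_within_mi = ifelse(is.finite(within_mi[relabel]), within_mi[relabel], NA_real_))
  out
}

#' Top co-occurring site pairs
#'
#' Ranks site pairs by mutual information, with lexicographic tie-breaking on
#' the site names for reproducibility.
#'
#' @param mi a [mi_matrix()].
#' @param top_n number of pairs to return (default all).
#' @return data.frame with `site_a`, `site_b`, `mi` sorted descending.
#' @export
rank_pairs <- function(mi, top_n = NULL) {
  stopifnot(inherits(mi, "mi_matrix"))
  v <- mi$values
  ut <- which(upper.tri(v), arr.ind = TRUE)
  out <- data.frame(site_a = mi$sites[ut[, 1]], site_b = mi$sites[ut[, 2]],
                    mi = v[ut], stringsAsFactors = FALSE)
  swap <- out$site_a > out$site_b
  tmp <- out$site_a[swap]; out$site_a[swap] <- out$site_b[swap]; out$site_b[swap] <- tmp
  out <- out[order(-out$mi, out$site_a, out$site_b), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Hierarchical clustering of stresses by mutation profile
#'
#' Within each group of evolution runs sharing strain and medium, every
#' individual stress gets a binary mutation profile (all replicates of
#' conditions containing that stress, merged); stresses are then clustered
#' by Euclidean distance between profiles with Ward's criterion (`ward.D2`).
#' Groups with fewer than two stresses are skipped.
#'
#' @param compendium a `compendium`.
#' @return named list (one entry per strain|medium group) of lists with
#'   `stresses`, `hclust`, and `newick` (the dendrogram serialized with
#'   branch lengths).
#' @export
cluster_stresses <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  cond <- compendium$conditions
  reps <- compendium$replicates
  groups <- split(seq_len(nrow(cond)), paste(cond$strain, cond$medium, sep = " | "))
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    stress_sets <- split_stresses(cond$stresses[rows])
    stresses <- sort(unique(unlist(stress_sets)))
    if (length(stresses) < 2L) next
    prof_list <- lapply(stresses, function(s) {
      cids <- cond$condition_id[rows][vapply(stress_sets, function(x) s %in% x, logical(1))]
      ids <- reps$replicate_id[reps$condition_id %in% cids]
      replicate_set_profile(compendium, ids)
    })
    prof <- do.call(rbind, prof_list)
    rownames(prof) <- stresses
    hc <- hclust(dist(prof, method = "euclidean"), method = "ward.D2")
    out[[g]] <- list(stresses = stresses, hclust = hc,
                     newick = ape::write.tree(ape::as.phylo(hc)))
  }
  if (!length(out)) stopf("no strain+medium group has two or more stresses")
  out
}
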