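#' Pearson-correlation distance between two profiles
#'
#' `d = 1 - r(a, b)`, in `[0, 2]`. Correlation emphasises profile shape over
#' intensity: the distance is invariant under positive affine transforms of
#' either argument. A constant vector has undefined correlation, which is
#' defined as 0 here (distance 1).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return distance in `[0, 2]`.
#' @export
pearson_distance <- function(a, b) {
  1 - safe_cor(a, b)
}

# One k-means pass from a random initial assignment: iterate
# (centroid = arithmetic mean of members, reassign by minimum 1 - r),
# repairing empty clusters by seizing the point farthest from its centroid.
# With correlation distance the mean-update step is not guaranteed to lower
# the total within-cluster distance, so the pass keeps the best partition
# visited rather than only the converged one. Returns
# list(assign, centers, objective).
kmeans_pearson_pass <- function(X, k, max_iter = 200L) {
  n <- nrow(X)
  repeat {   # uniform random assignment, conditioned on no empty cluster
    assign <- sample.int(k, n, replace = TRUE)
    if (all(tabulate(assign, k) > 0L)) break
  }
  best_obj <- Inf
  best_assign <- assign
  for (iter in seq_len(max_iter)) {
    centers <- rowsum(X, assign) / as.vector(table(assign))
    D <- 1 - cor_rows(X, centers)
    obj <- sum(D[cbind(seq_len(n), assign)])
    if (obj < best_obj) {
      best_obj <- obj
      best_assign <- assign
    }
    new_assign <- max.col(-D, ties.method = "first")
    # repair empty clusters: seize the point farthest from its own centroid
    repeat {
      sizes <- tabulate(new_assign, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      own <- D[cbind(seq_len(n), new_assign)]
      own[sizes[new_assign] <= 1L] <- -Inf   # don't empty another cluster
      new_assign[which.max(own)] <- empty[1L]
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  centers <- rowsum(X, best_assign) / as.vector(table(best_assign))
  D <- 1 - cor_rows(X, centers)
  list(assign = best_assign, centers = centers,
       objective = sum(D[cbind(seq_len(n), best_assign)]))
}

# Hartigan-style polish: first-improvement single-point moves on the
# partition objective, applied once to the best-of-npass solution. Lloyd
# iterations with correlation distance can stall short of partitions that
# single-point moves still improve.
refine_partition <- function(X, assign, k, max_sweeps = 25L) {
  n <- nrow(X)
  cluster_cost <- function(idx) {
    if (!length(idx)) return(0)
    sub <- X[idx, , drop = FALSE]
    ctr <- matrix(colMeans(sub), nrow = 1L)
    sum(1 - cor_rows(sub, ctr))
  }
  cost <- vapply(seq_len(k), function(c) cluster_cost(which(assign == c)),
                 numeric(1))
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- assign[i]
      ia <- which(assign == a)
      if (length(ia) <= 1L) next
      cost_a_minus <- cluster_cost(setdiff(ia, i))
      for (b in setdiff(seq_len(k), a)) {
        cost_b_plus <- cluster_cost(c(which(assign == b), i))
        if (cost_a_minus + cost_b_plus < cost[a] + cost[b] - 1e-12) {
          assign[i] <- b
          cost[a] <- cost_a_minus
          cost[b] <- cost_b_plus
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  assign
}

# best-of-npass k-means with Pearson-correlation distance
kmeans_pearson <- function(X, k, npass, seed = NULL, max_iter = 200L) {
  if (nrow(X) < k) stop("fewer profiles (", nrow(X), ") than clusters (", k, ")")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (p in seq_len(npass)) {
    fit <- kmeans_pearson_pass(X, k, max_iter = max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  assign <- refine_partition(X, best$assign, k)
  centers <- rowsum(X, assign) / as.vector(table(assign))
  D <- 1 - cor_rows(X, centers)
  list(assign = assign, centers = centers,
       objective = sum(D[cbind(seq_len(nrow(X)), assign)]))
}

#' Cluster smoothed chromatin profiles of one mark into k subprofiles
#'
#' k-means with Pearson-correlation distance: each pass starts from a random
#' assignment and iterates (centroid = arithmetic mean of member profiles;
#' reassignment by minimum `1 - r`) to convergence; the best of `npass` passes
#' by total within-cluster distance is kept. Centroids are plain means, not
#' re-normalised.
#'
#' @param profiles numeric matrix of smoothed profiles (rows RTSSs, named).
#' @param k number of clusters (default 5).
#' @param npass number of random restarts (default 200).
#' @param seed optional integer seed.
#' @param mark mark name recorded in the result.
#' @return a `subprofile_set`: list with `mark`, `k`, `subprofiles` (k x bins
#'   matrix of mean shapes), `assignments` (named integer vector), `sizes`,
#'   `objective`.
#' @export
kmeans_shapes <- function(profiles, k = 5L, npass = 200L, seed = NULL,
                          mark = "mark") {
  fit <- kmeans_pearson(profiles, k, npass, seed = seed)
  assignments <- setNames(fit$assign, rownames(profiles))
  structure(
    list(mark = mark, k = k, subprofiles = fit$centers,
         assignments = assignments,
         sizes = tabulate(fit$assign, nbins = k), objective = fit$objective),
    class = "subprofile_set"
  )
}

#' @export
print.subprofile_set <- function(x, ...) {
  cat("Subprofile set for mark", x$mark, "\n")
  cat("  k =", x$k, "| profiles clustered:", length(x$assignments),
      "| objective:", format(x$objective, digits = 6), "\n")
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation features of one profile against a mark's subprofiles
#'
#' Pearson r between the (smoothed) profile and each of the k subprofiles.
#' When the raw total chromatin signal is below `min_signal`, all k features
#' are masked to 0; a constant profile likewise yields 0s.
#'
#' @param profile numeric smoothed profile.
#' @param subprofile_set a `subprofile_set` for the same mark.
#' @param raw_total total raw read count of the profile (pre-smoothing).
#' @param min_signal masking threshold (default 100).
#' @return numeric vector of k correlation features.
#' @export
subprofile_correlations <- function(profile, subprofile_set, raw_total,
                                    min_signal = 100) {
  k <- subprofile_set$k
  if (raw_total < min_signal) return(numeric(k))
  vapply(seq_len(k),
         function(c) safe_cor(profile, subprofile_set$subprofiles[c, ]),
         numeric(1))
}

#' Assemble the meta-feature matrix of expressed RTSSs
#'
#' One row per expressed RTSS, one column per (mark, subprofile) pair in the
#' configured mark order: 60 features for a 12-mark panel at k = 5, 55 when a
#' mark is dropped. RTSSs without a profile for a mark — or below the signal
#' threshold — get zeros for that mark's columns.
#'
#' @param mark_data named list (one element per mark, in panel order), each a
#'   list with `smoothed` (profile matrix, rows named by RTSS id), `totals`
#'   (named raw totals) and `subprofiles` (a `subprofile_set`).
#' @param expressed_ids character vector of expressed RTSS ids (row order).
#' @param min_signal masking threshold applied per mark (default 100).
#' @return numeric matrix, rows `expressed_ids`, columns `mark.subprofile`.
#' @export
build_meta_matrix <- function(mark_data, expressed_ids, min_signal = 100) {
  stopifnot(length(mark_data) >= 1L)
  blocks <- lapply(names(mark_data), function(mark) {
    md <- mark_data[[mark]]
    k <- md$subprofiles$k
    block <- matrix(0, nrow = length(expressed_ids), ncol = k,
                    dimnames = list(expressed_ids,
                                    paste(mark, seq_len(k), sep = ".")))
    present <- intersect(expressed_ids, rownames(md$smoothed))
    present <- present[md$totals[present] >= min_signal]
    if (length(present)) {
      block[present, ] <- cor_rows(md$smoothed[present, , drop = FALSE],
                                   md$subprofiles$subprofiles)
    }
    block
  })
  do.call(cbind, blocks)
}

#' Meta-cluster RTSSs on their correlation-coefficient features
#'
#' Applies the same Pearson-distance k-means to the rows of the meta-feature
#' matrix (default k = 10, 1000 passes), grouping RTSSs by their combinatorial
#' chromatin configuration across marks.
#'
#' @param meta_matrix matrix from [build_meta_matrix()].
#' @param k number of metaclusters (default 10).
#' @param npass number of random restarts (default 1000).
#' @param seed optional integer seed.
#' @return a `metacluster_result`: list with `k`, `assignments` (named),
#'   `centers`, `sizes`, `objective`.
#' @export
metacluster <- function(meta_matrix, k = 10L, npass = 1000L, seed = NULL) {
  fit <- kmeans_pearson(meta_matrix, k, npass, seed = seed)
  structure(
    list(k = k, assignments = setNames(fit$assign, rownames(meta_matrix)),
         centers = fit$centers, sizes = tabulate(fit$assign, nbins = k),
         objective = fit$objective),
    class = "metacluster_result"
  )
}

#' @export
print.metacluster_result <- function(x, ...) {
  cat("Metaclustering of", length(x$assignments), "RTSSs into", x$k,
      "clusters\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  objective:", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Per-metacluster, per-mark average subprofiles for heatmap export
#'
#' @param result a `metacluster_result`.
#' @param mark_data as in [build_meta_matrix()].
#' @return long-format data.frame (metacluster, mark, bin, mean_value).
#' @export
metacluster_mark_averages <- function(result, mark_data) {
  rows <- list()
  for (c in seq_len(result$k)) {
    members <- names(result$assignments)[result$assignments == c]
    for (mark in names(mark_data)) {
      sm <- mark_data[[mark]]$smoothed
      present <- intersect(members, rownames(sm))
      if (!length(present)) next
      avg <- colMeans(sm[present, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        metacluster = c, mark = mark, bin = seq_along(avg), mean_value = avg
      )
    }
  }
  do.call(rbind, rows)
}
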