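# K-means clustering of error trajectories within an age group, with a
# scree (elbow) table and an explicit, testable elbow rule.
#
# Participants are represented by their error trajectory binned to 10 s
# means (68 features for the default 689.92 s session): coarse enough to
# keep distances meaningful, fine enough to preserve the temporal patterns
# (uniformly poor, good-then-bad, alternating) that distinguish the
# behavioral archetypes. Features share units (meters), so no per-feature
# normalization is applied.

#' Binned error feature matrix for an age group
#'
#' @param cohort A `cohort`.
#' @param age Age in years.
#' @param bin_width Bin width, seconds. Column `j` is the mean absolute
#'   error over time bin `j`; a trailing partial bin is dropped.
#' @return An object of class `feature_matrix`: `participant_ids`, matrix
#'   `X` (participants x bins) and `bin_width`.
#' @export
feature_matrix <- function(cohort, age, bin_width = 10) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is_scalar_number(bin_width) || bin_width <= 0)
    stop_param("bin_width must be > 0")
  ids <- cohort$manifest$participant_id[cohort$manifest$age == age]
  if (!length(ids)) stop_empty_group("no participants of age %s in cohort", age)
  rows <- lapply(ids, function(id) {
    s <- cohort$sessions[[id]]
    e <- abs(s$samples$position)
    per_bin <- bin_width * s$sample_rate
    n_bins <- floor(length(e) / per_bin)
    if (n_bins < 1)
      stop_param("bin_width %g s exceeds the session length", bin_width)
    bin <- rep(seq_len(n_bins), each = per_bin)
    as.numeric(tapply(e[seq_len(n_bins * per_bin)], bin, mean))
  })
  if (length(unique(lengths(rows))) != 1)
    stop_format("sessions of age %s differ in length; cannot build features", age)
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  structure(list(participant_ids = ids, X = X, bin_width = bin_width),
            class = "feature_matrix")
}

as_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

total_wss <- function(X, cluster) {
  sum(vapply(unique(cluster), function(cl) {
    Y <- X[cluster == cl, , drop = FALSE]
    sum(sweep(Y, 2, colMeans(Y))^2)
  }, 0))
}

# k-means++ seeding: first center uniform, each next center drawn with
# probability proportional to the squared distance to the nearest chosen
# center. Returns a k x p matrix of initial centers.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

lloyd <- function(X, centers) {
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) return(NULL)
  list(cluster = km$cluster, centers = km$centers, inertia = km$tot.withinss)
}

# Deduplicate rows so initial centers are distinct (stats::kmeans requires
# it); falls back to jittering never — callers handle k > #distinct.
distinct_rows <- function(X) X[!duplicated(X), , drop = FALSE]

#' Fit k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations (via [stats::kmeans()]) from `restarts` k-means++
#' seedings, keeping the lowest within-cluster sum of squares (inertia).
#' Deterministic given `seed`. `init_centers`, when supplied, is tried as an
#' additional initialisation (used by [scree()] for nested, monotone fits).
#'
#' @param X A `feature_matrix` or numeric matrix (rows = participants).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts.
#' @param init_centers Optional extra initial center matrix.
#' @return A list: integer `assignments` (named by participant when `X` is a
#'   `feature_matrix`), `inertia`, and the fitted `centers`.
#' @export
kmeans_fit <- function(X, k, seed = 0L, restarts = 10L, init_centers = NULL) {
  ids <- if (inherits(X, "feature_matrix")) X$participant_ids
  X <- as_matrix(X)
  n <- nrow(X)
  if (!is_scalar_count(k) || k < 1 || k > n)
    stop_param("k must be between 1 and the number of rows (%d)", n)
  k <- as.integer(k)
  if (k == 1) {
    out <- list(assignments = rep(1L, n),
                inertia = total_wss(X, rep(1L, n)),
                centers = matrix(colMeans(X), 1))
  } else {
    Xd <- distinct_rows(X)
    if (nrow(Xd) <= k) {
      # every distinct row its own center: inertia 0
      assign_to <- apply(X, 1, function(r) which.min(colSums((t(Xd) - r)^2)))
      out <- list(assignments = as.integer(assign_to), inertia = 0,
                  centers = Xd)
    } else {
      out <- with_seed(seed, {
        best <- NULL
        inits <- c(lapply(seq_len(restarts), function(r) kmeanspp_centers(X, k)),
                   if (!is.null(init_centers)) list(init_centers))
        for (ini in inits) {
          ini <- distinct_rows(ini)
          if (nrow(ini) < k) next
          fit <- lloyd(X, ini)
          if (!is.null(fit) && (is.null(best) || fit$inertia < best$inertia))
            best <- fit
        }
        if (is.null(best)) stop_param("k-means failed to converge for k = %d", k)
        list(assignments = as.integer(best$cluster), inertia = best$inertia,
             centers = best$centers)
      })
    }
  }
  if (!is.null(ids)) names(out$assignments) <- ids
  out
}

#' Scree table: inertia versus number of clusters
#'
#' Fits k = 1..`k_max` with [kmeans_fit()]. Each fit k > 1 is additionally
#' initialised from the (k-1) solution's centers plus the point farthest
#' from its assigned center, so the inertia sequence is non-increasing in k.
#'
#' @param X A `feature_matrix` or matrix.
#' @param k_max Largest k (at most the number of rows).
#' @param seed Integer seed.
#' @param restarts Restarts per k.
#' @return A data frame `(k, inertia)` with the per-k fits attached as
#'   attribute `"fits"`.
#' @export
scree <- function(X, k_max = 6L, seed = 0L, restarts = 10L) {
  Xm <- as_matrix(X)
  k_max <- min(k_max, nrow(Xm))
  fits <- vector("list", k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    init <- if (!is.null(prev)) {
      d2 <- rowSums((Xm - prev$centers[prev$assignments, , drop = FALSE])^2)
      rbind(prev$centers, Xm[which.max(d2), ])
    }
    fits[[k]] <- kmeans_fit(X, k, seed = child_seed(seed, k),
                            restarts = restarts, init_centers = init)
    prev <- fits[[k]]
  }
  out <- data.frame(k = seq_len(k_max),
                    inertia = vapply(fits, `[[`, 0, "inertia"))
  attr(out, "fits") <- fits
  out
}

#' Elbow selection of the number of clusters
#'
#' Picks the interior k maximizing the second difference of the inertia
#' curve, `(W(k-1) - W(k)) - (W(k) - W(k+1))` — the sharpest bend of the
#' scree plot, the parsimony point between few clusters and small
#' within-cluster variance. Ties break toward smaller k.
#'
#' @param inertias A data frame `(k, inertia)` (from [scree()]) with at
#'   least three rows, or a numeric inertia vector for k = 1, 2, ...
#' @return The selected k.
#' @export
#' @examples
#' select_k(data.frame(k = 1:4, inertia = c(100, 20, 18, 17)))  # 2
select_k <- function(inertias) {
  if (is.data.frame(inertias)) {
    inertias <- inertias[order(inertias$k), ]
    w <- inertias$inertia
    ks <- inertias$k
  } else {
    w <- as.numeric(inertias)
    ks <- seq_along(w)
  }
  if (length(w) < 3) stop_param("select_k needs at least three (k, inertia) points")
  interior <- 2:(length(w) - 1)
  score <- (w[interior - 1] - w[interior]) - (w[interior] - w[interior + 1])
  ks[interior[which.max(score)]]
}

#' Cluster one age group end to end
#'
#' [feature_matrix()] -> [scree()] -> [select_k()] -> assignments at the
#' selected k. Singleton clusters — single participants isolated from the
#' rest of their age group — are reported by id.
#'
#' @param cohort A `cohort`.
#' @param age Age in years (needs at least two participants).
#' @param k_max Largest k scanned (capped at the group size).
#' @param seed Integer seed.
#' @param bin_width Feature bin width, seconds.
#' @return An object of class `cluster_result`: `k_values`, `inertias`,
#'   `selected_k`, named `assignments`, `singletons` (ids), `no_structure`
#'   flag (inertia already ~0 at k = 1) and `seed`.
#' @export
cluster_age_group <- function(cohort, age, k_max = 6L, seed = 0L,
                              bin_width = 10) {
  fm <- feature_matrix(cohort, age, bin_width = bin_width)
  n <- nrow(fm$X)
  if (n < 2)
    stop_param("age %s has %d participant(s); clustering needs at least 2", age, n)
  sc <- scree(fm, k_max = min(k_max, n), seed = seed)
  selected_k <- if (nrow(sc) >= 3) select_k(sc) else nrow(sc)
  fit <- attr(sc, "fits")[[selected_k]]
  sizes <- table(fit$assignments)
  singles <- names(fit$assignments)[fit$assignments %in%
                                      as.integer(names(sizes)[sizes == 1])]
  structure(list(k_values = sc$k, inertias = sc$inertia,
                 selected_k = selected_k,
                 assignments = fit$assignments,
                 singletons = singles,
                 no_structure = sc$inertia[1] < 1e-10,
                 seed = as.integer(seed),
                 bin_width = bin_width,
                 age = age),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> age %s: k = %d selected from scree over k = %d..%d%s\n",
              x$age, x$selected_k, min(x$k_values), max(x$k_values),
              if (x$no_structure) " (no structure: zero inertia at k = 1)" else ""))
  for (cl in sort(unique(x$assignments)))
    cat(sprintf("  cluster %d: %s\n", cl,
                paste(names(x$assignments)[x$assignments == cl], collapse = ", ")))
  invisible(x)
}
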