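#' Clustering configuration for trajectory vectors
#'
#' Clustering uses only 6 of the 7 DTV entries: for each domain group one
#' age step contains a single milestone, which makes that entry noisy, so it
#' is dropped from the distance computation — step 5 (12-18 months) for the
#' motor group, step 3 (6-9 months) for the language-social group. Cluster
#' centroids are nonetheless reported over all 7 entries.
#'
#' @param k Number of clusters (default 4); must be at least 2.
#' @param method `"kmeans"` (default) or `"gmm"` (full-covariance Gaussian
#'   mixture).
#' @param dropped_step Which step (1..7) to exclude from the clustering
#'   features; `NULL` picks the domain-group default above.
#' @param seed Integer master seed for initialization.
#' @param n_init Number of k-means++ restarts (best of `n_init` kept).
#' @param theta_low,theta_high Pattern-labelling thresholds, see
#'   [label_patterns()].
#' @return A list of class `devsurv_cluster_config`.
#' @export
cluster_config <- function(k = 4, method = c("kmeans", "gmm"),
                           dropped_step = NULL, seed = 1L, n_init = 10L,
                           theta_low = 0.15, theta_high = 0.5) {
  method <- match.arg(method)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (!is.null(dropped_step) && !dropped_step %in% 1:7) {
    stop("dropped_step must be in 1..7", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), method = method, dropped_step = dropped_step,
         seed = as.integer(seed), n_init = as.integer(n_init),
         theta_low = theta_low, theta_high = theta_high),
    class = "devsurv_cluster_config"
  )
}

default_dropped_step <- function(domain_group) {
  switch(domain_group, motor = 5L, language_social = 3L,
         stop("unknown domain group: ", domain_group, call. = FALSE))
}

# k-means++ seeding (Arthur & Vassilvitskii): centers drawn with probability
# proportional to squared distance to the nearest already-chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[idx, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Cluster trajectory vectors into developmental patterns
#'
#' Partitions complete DTVs with k-means (Lloyd iterations from k-means++
#' starts, best of `n_init` restarts by within-cluster sum of squares) or a
#' full-covariance Gaussian mixture. Distances use the 6 retained entries
#' (see [cluster_config()]); centroids are recomputed over all 7 entries as
#' the per-entry mean of member vectors. Cluster validity is the
#' Calinski-Harabasz index on the clustered features, and each centroid is
#' labelled with a developmental pattern. Results are deterministic given
#' `seed` and `n_init`.
#'
#' @param dtvs Complete trajectory vectors ([build_dtvs()] +
#'   [filter_complete()]).
#' @param config A [cluster_config()].
#' @return A list of class `devsurv_clusters` with elements `assignments`
#'   (tibble `child_id`, `cluster`), `centroids` (k x 7 matrix), `sizes`,
#'   `fractions`, `validity`, `labels`, `dropped_step`, `config`, and
#'   `features` (the n x 6 matrix that was clustered).
#' @export
cluster_dtvs <- function(dtvs, config = cluster_config()) {
  if (!all(dtvs$complete)) {
    stop("clustering requires complete trajectory vectors; run filter_complete()",
         call. = FALSE)
  }
  if (nrow(dtvs) <= config$k) {
    stop("need more vectors (", nrow(dtvs), ") than clusters (", config$k, ")",
         call. = FALSE)
  }
  dropped <- config$dropped_step %||% default_dropped_step(dtvs$domain_group[1])
  full <- dtv_matrix(dtvs)
  x <- full[, -dropped, drop = FALSE]

  n_distinct <- nrow(unique(x))
  cl <- if (n_distinct == 1) {
    # all vectors identical: any split is degenerate; spread children evenly
    # so every centroid equals the common vector
    rep_len(seq_len(config$k), nrow(x))
  } else if (n_distinct <= config$k) {
    stop("only ", n_distinct, " distinct trajectory vectors for k = ",
         config$k, call. = FALSE)
  } else withr::with_seed(config$seed, {
    if (config$method == "kmeans") {
      best <- NULL
      for (r in seq_len(config$n_init)) {
        fit <- suppressWarnings(stats::kmeans(
          x, centers = kmeanspp_centers(x, config$k),
          iter.max = 100, algorithm = "Lloyd"
        ))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      best$cluster
    } else {
      # Mclust resolves mclustBIC in the caller's frame, so bind it locally.
      # The conjugate prior regularizes the component covariances: many
      # children have identical all-zero vectors, which makes an
      # unregularized full-covariance fit singular.
      mclustBIC <- mclust::mclustBIC
      fit <- mclust::Mclust(x, G = config$k, modelNames = "VVV",
                            prior = mclust::priorControl(),
                            verbose = FALSE)
      if (is.null(fit)) stop("Gaussian mixture fit failed", call. = FALSE)
      fit$classification
    }
  })

  # order clusters by size (largest first) for stable reporting
  sizes <- table(cl)
  ord <- order(-as.integer(sizes))
  relabel <- integer(config$k)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(config$k)
  cl <- relabel[cl]

  centroids <- t(vapply(seq_len(config$k),
                        function(j) colMeans(full[cl == j, , drop = FALSE]),
                        numeric(7)))
  colnames(centroids) <- paste0("step", 1:7)
  sizes <- as.integer(table(factor(cl, levels = seq_len(config$k))))
  labels <- label_patterns(centroids, theta_low = config$theta_low,
                           theta_high = config$theta_high)
  structure(
    list(
      assignments = tibble::tibble(child_id = dtvs$child_id, cluster = cl),
      centroids = centroids,
      sizes = sizes,
      fractions = sizes / nrow(dtvs),
      validity = calinski_harabasz(x, cl),
      labels = labels,
      dropped_step = dropped,
      features = x,
      config = config
    ),
    class = "devsurv_clusters"
  )
}

#' @export
print.devsurv_clusters <- function(x, ...) {
  cat("Trajectory clustering (", x$config$method, ", k = ", x$config$k,
      ", dropped step ", x$dropped_step, ")\n", sep = "")
  cat("Calinski-Harabasz:", format(x$validity, digits = 6), "\n\n")
  df <- data.frame(cluster = seq_along(x$sizes), n = x$sizes,
                   fraction = round(x$fractions, 3), label = x$labels,
                   round(x$centroids, 3), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Calinski-Harabasz cluster validity index
#'
#' Ratio of between-cluster to within-cluster dispersion, each normalized by
#' its degrees of freedom:
#' `[B / (k - 1)] / [W / (n - k)]`, where `B` is the sum of squared
#' distances of cluster means to the grand mean weighted by cluster size and
#' `W` the sum of squared distances of points to their cluster mean. Larger
#' is better. Zero within-cluster dispersion yields `Inf`.
#'
#' @param x Numeric matrix, one row per observation.
#' @param assignments Integer/factor cluster labels, one per row; every
#'   cluster must be nonempty and `2 <= k < n`.
#' @return A positive number (possibly `Inf`).
#' @export
calinski_harabasz <- function(x, assignments) {
  x <- as.matrix(x)
  f <- factor(assignments)
  k <- nlevels(f)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)
  if (any(table(f) == 0)) stop("empty cluster", call. = FALSE)
  if (n <= k) stop("need more observations than clusters", call. = FALSE)
  grand <- colMeans(x)
  between <- 0
  within <- 0
  for (lev in levels(f)) {
    xi <- x[f == lev, , drop = FALSE]
    mu <- colMeans(xi)
    between <- between + nrow(xi) * sum((mu - grand)^2)
    within <- within + sum(sweep(xi, 2, mu)^2)
  }
  if (within == 0) return(Inf)
  (between / (k - 1)) / (within / (n - k))
}

#' Label cluster centroids with developmental patterns
#'
#' Quantifies the qualitative trajectory patterns seen in clustered
#' surveillance data: *adequate* — near-zero scores at every age step;
#' *catching up* — high initial score that resolves, i.e. first entry at
#' least `theta_high` and the last two entries below `theta_low`;
#' *worsening* — last entry at least `theta_high` and above the first
#' entry; anything else (including centroids satisfying both directional
#' rules at once) is *other*, e.g. a mid-trajectory bump that resolves.
#'
#' @param centroids Numeric matrix with 7 columns (or a length-7 vector).
#' @param theta_low Threshold under which an entry counts as near zero
#'   (default 0.15).
#' @param theta_high Threshold above which an entry counts as elevated
#'   (default 0.5).
#' @return Character vector of labels, one per centroid row.
#' @examples
#' label_patterns(rbind(
#'   c(0.01, 0.03, 0.06, 0.07, 0.03, 0.03, 0.04),
#'   c(0.66, 0.16, 0.16, 0.14, 0.05, 0.05, 0.06),
#'   c(0.15, 0.14, 0.26, 0.38, 0.69, 1.20, 1.24)
#' ))
#' @export
label_patterns <- function(centroids, theta_low = 0.15, theta_high = 0.5) {
  if (is.null(dim(centroids))) centroids <- matrix(centroids, nrow = 1)
  if (ncol(centroids) != 7) stop("centroids must have 7 entries", call. = FALSE)
  apply(centroids, 1, function(ct) {
    adequate <- all(ct < theta_low)
    catching <- ct[1] >= theta_high && ct[6] < theta_low && ct[7] < theta_low
    worsening <- ct[7] >= theta_high && ct[7] > ct[1]
    if (adequate) return("adequate")
    if (catching && worsening) return("other")
    if (catching) return("catching_up")
    if (worsening) return("worsening")
    "other"
  })
}

#' Covariate distribution per cluster
#'
#' Tabulates child and maternal characteristics within each cluster: counts
#' and percentages per category, with missing values excluded from the
#' tallies of that characteristic only.
#'
#' @param clusters A `devsurv_clusters` result.
#' @param children Child covariate records (see [generate_cohort()] /
#'   [read_children()]); must cover the clustered child ids.
#' @param characteristics Named list mapping a characteristic name to either
#'   a column name (categorical) or a list `list(var =, breaks =)` for a
#'   binned numeric column. The default mirrors the standard surveillance
#'   report: tracking, sex, postpartum depression, maternal age band, birth
#'   weight bins, birth order, maternal education.
#' @return A tibble `characteristic`, `category`, `cluster`, `label`, `n`,
#'   `pct` (percentage within cluster among non-missing).
#' @export
cluster_covariate_table <- function(clusters, children,
                                    characteristics = default_characteristics()) {
  joined <- dplyr::inner_join(clusters$assignments, children, by = "child_id")
  if (nrow(joined) < nrow(clusters$assignments)) {
    stop("children table does not cover all clustered child ids", call. = FALSE)
  }
  lab <- clusters$labels
  out <- lapply(names(characteristics), function(name) {
    spec <- characteristics[[name]]
    if (is.list(spec)) {
      vals <- cut(joined[[spec$var]], breaks = spec$breaks,
                  right = FALSE, include.lowest = TRUE)
    } else {
      vals <- as.character(joined[[spec]])
    }
    df <- tibble::tibble(cluster = joined$cluster, category = as.character(vals))
    df <- df[!is.na(df$category), ]
    tab <- dplyr::summarise(
      dplyr::group_by(df, .data$cluster, .data$category),
      n = dplyr::n(), .groups = "drop_last"
    )
    tab <- dplyr::mutate(tab, pct = 100 * .data$n / sum(.data$n))
    tab <- dplyr::ungroup(tab)
    tab$characteristic <- name
    tab
  })
  res <- dplyr::bind_rows(out)
  res$label <- lab[res$cluster]
  res[c("characteristic", "category", "cluster", "label", "n", "pct")]
}

default_characteristics <- function() {
  list(
    dev_tracking = "dev_tracking",
    sex = "sex",
    ppd = "ppd",
    maternal_age = list(var = "maternal_age", breaks = c(18, 40, 51)),
    birth_weight = list(var = "birth_weight",
                        breaks = c(1, 2.5, 3, 3.5, 4, 4.5, 6)),
    birth_order = "birth_order",
    maternal_education = "maternal_education"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
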