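make_dtvs <- function(m) {
  d <- tibble::as_tibble(as.data.frame(m))
  names(d) <- paste0("step", 1:7)
  d$child_id <- sprintf("c%04d", seq_len(nrow(m)))
  d$domain_group <- "motor"
  d$complete <- TRUE
  d[c("child_id", "domain_group", paste0("step", 1:7), "complete")]
}

test_that("two tight separated groups are recovered exactly", {
  withr::with_seed(5, {
    g1 <- matrix(rnorm(40 * 7, 0, 0.02), 40, 7)
    g2 <- matrix(rnorm(30 * 7, 2, 0.02), 30, 7)
  })
  d <- make_dtvs(rbind(g1, g2))
  rep <- cluster_dtvs(d, cluster_config(k = 2, seed = 1))
  planted <- rep(1:2, c(40, 30))
  expect_equal(length(unique(paste(rep$assignments$cluster, planted))), 2)
  # centroid entries equal the member means (all 7 entries)
  for (j in 1:2) {
    members <- dtv_members <- d[rep$assignments$cluster == j, paste0("step", 1:7)]
    expect_equal(unname(rep$centroids[j, ]), unname(colMeans(as.matrix(members))),
                 tolerance = 1e-9)
  }
  expect_equal(sum(rep$sizes), 70)
})

test_that("identical vectors yield a degenerate split with equal centroids", {
  d <- make_dtvs(matrix(0.2, 20, 7))
  rep <- cluster_dtvs(d, cluster_config(k = 2, seed = 1))
  expect_equal(sum(rep$sizes), 20)
  expect_equal(unname(rep$centroids[1, ]), rep(0.2, 7))
  expect_equal(unname(rep$centroids[2, ]), rep(0.2, 7))
})

test_that("invalid clustering configurations are rejected", {
  expect_error(cluster_config(k = 1), "at least 2")
  expect_error(cluster_config(dropped_step = 9), "dropped_step")
  d <- make_dtvs(matrix(rnorm(21), 3, 7))
  expect_error(cluster_dtvs(d, cluster_config(k = 4)), "more vectors")
  d$complete[1] <- FALSE
  expect_error(cluster_dtvs(d, cluster_config(k = 2)), "complete")
})

test_that("the validity index matches the hand-computed example", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  # W = 1, B = 200, CH = (200/1)/(1/2) = 400
  expect_equal(calinski_harabasz(x, c(1, 1, 2, 2)), 400)
  # duplicated points per cluster: zero within-dispersion
  expect_identical(calinski_harabasz(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                                     c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(x, c(1, 1, 1, 1)), "at least 2")
})

test_that("the validity index agrees with a total-dispersion oracle", {
  # oracle via the decomposition B = T - W (different computation path)
  oracle_ch <- function(x, lab) {
    x <- as.matrix(x)
    tot <- sum(sweep(x, 2, colMeans(x))^2)
    w <- 0
    for (l in unique(lab)) {
      xi <- x[lab == l, , drop = FALSE]
      w <- w + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    k <- length(unique(lab)); n <- nrow(x)
    ((tot - w) / (k - 1)) / (w / (n - k))
  }
  withr::with_seed(8, {
    for (rep in 1:50) {
      n <- sample(8:30, 1)
      p <- sample(2:7, 1)
      k <- sample(2:4, 1)
      x <- matrix(rnorm(n * p), n, p)
      lab <- sample(rep_len(seq_len(k), n))
      got <- calinski_harabasz(x, lab)
      want <- oracle_ch(x, lab)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("planted labels score higher validity than random labels", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(50 * 3, 0, 0.5), 50, 3),
               matrix(rnorm(50 * 3, 5, 0.5), 50, 3))
    planted <- rep(1:2, each = 50)
    random <- sample(planted)
  })
  expect_gt(calinski_harabasz(x, planted), calinski_harabasz(x, random))
})

test_that("centroid pattern labelling matches the canonical trajectory shapes", {
  expect_equal(label_patterns(c(0.01, 0.03, 0.06, 0.07, 0.03, 0.03, 0.04)),
               "adequate")
  expect_equal(label_patterns(c(0.66, 0.16, 0.16, 0.14, 0.05, 0.05, 0.06)),
               "catching_up")
  expect_equal(label_patterns(c(0.15, 0.14, 0.26, 0.38, 0.69, 1.20, 1.24)),
               "worsening")
  expect_equal(label_patterns(c(0.21, 0.27, 0.42, 0.63, 0.71, 1.07, 0.93)),
               "worsening")
  # a mid-trajectory bump that resolves conforms to none of the three
  expect_equal(label_patterns(c(0.03, 0.27, 0.48, 0.35, 0.22, 0.08, 0.09)),
               "other")
  # a high last entry rules out catching-up, so the trajectory is worsening
  expect_equal(label_patterns(c(1.0, 0.1, 0.1, 0.1, 0.1, 0.1, 1.2)),
               "worsening")
  # under custom thresholds both directional rules can fire: resolves to other
  expect_equal(label_patterns(c(0.52, 0.7, 0.1, 0.1, 0.1, 0.1, 0.58),
                              theta_low = 0.6, theta_high = 0.5), "other")
  m <- rbind(c(0, 0, 0, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1, 1))
  expect_equal(label_patterns(m), c("adequate", "other"))
})

test_that("clustering is deterministic under a fixed seed", {
  d <- archetype_dtv_fixture()
  r1 <- cluster_dtvs(d, cluster_config(k = 4, seed = 17))
  r2 <- cluster_dtvs(d, cluster_config(k = 4, seed = 17))
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$centroids, r2$centroids)
})

test_that("pattern labels are stable across methods and cluster counts", {
  d <- archetype_dtv_fixture()
  sets <- list()
  for (k in 3:5) for (m in c("kmeans", "gmm")) {
    rep <- cluster_dtvs(d, cluster_config(k = k, method = m, seed = 11))
    sets[[paste(k, m)]] <- sort(unique(rep$labels))
  }
  for (s in sets) {
    expect_equal(s, c("adequate", "catching_up", "worsening"))
  }
})

test_that("clusters are computed on 6 retained entries with full centroids", {
  d <- archetype_dtv_fixture()
  rep <- cluster_dtvs(d, cluster_config(k = 3, seed = 2))
  expect_equal(ncol(rep$features), 6)
  expect_equal(rep$dropped_step, 5)   # motor default
  expect_equal(ncol(rep$centroids), 7)
  d$domain_group <- "language_social"
  rep2 <- cluster_dtvs(d, cluster_config(k = 3, seed = 2))
  expect_equal(rep2$dropped_step, 3)
  # the dropped entry's values cannot influence the partition
  d3 <- d
  d3$domain_group <- "motor"
  d3$step5 <- rev(d3$step5)
  rep3 <- cluster_dtvs(d3, cluster_config(k = 3, seed = 2))
  base <- cluster_dtvs(d, cluster_config(k = 3, dropped_step = 5, seed = 2))
  expect_identical(rep3$assignments$cluster, base$assignments$cluster)
})

test_that("cluster covariate tables recover a planted male excess", {
  d <- archetype_dtv_fixture()
  rep <- cluster_dtvs(d, cluster_config(k = 3, seed = 4))
  worsening_cl <- which(rep$labels == "worsening")
  adequate_cl <- which(rep$labels == "adequate")
  withr::with_seed(6, {
    in_w <- rep$assignments$cluster == worsening_cl
    children <- tibble::tibble(
      child_id = rep$assignments$child_id,
      sex = ifelse(runif(nrow(rep$assignments)) < ifelse(in_w, 0.7, 0.5),
                   "male", "female"),
      dev_tracking = FALSE
    )
  })
  tab <- cluster_covariate_table(rep, children,
                                 characteristics = list(sex = "sex"))
  male_pct <- function(cl) tab$pct[tab$cluster == cl & tab$category == "male"]
  expect_gt(male_pct(worsening_cl), male_pct(adequate_cl))
  # single characteristic, percentages sum to 100 within cluster
  sums <- tapply(tab$pct, tab$cluster, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})
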