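# Shared fixtures, all built in code.

# the worked-example milestone used throughout: brackets
# [2,6], (6,9], (9,12], (12,18]
demo_milestone <- function() {
  list(milestone_id = "demo", domain = "gross_motor",
       t0 = 2, t75 = 6, t90 = 9, t95 = 12, t100 = 18)
}

tiny_scale <- function() {
  dev_scale(tibble::tibble(
    milestone_id = c("gm01", "fm01", "lg01", "ps01"),
    domain = c("gross_motor", "fine_motor", "language", "personal_social"),
    t0 = c(2, 1, 3, 2),
    t75 = c(6, 4, 8, 5),
    t90 = c(9, 6, 11, 7),
    t95 = c(12, 8, 13, 9),
    t100 = c(18, 12, 20, 14)
  ))
}

make_attempts <- function(child_id, milestone_id, age_months, attained,
                          source = "observed") {
  tibble::tibble(child_id = child_id, milestone_id = milestone_id,
                 age_months = age_months, attained = attained,
                 source = source)
}

# random but valid milestone definitions; occasionally ties thresholds to
# produce degenerate brackets
random_milestone <- function(allow_degenerate = TRUE) {
  if (allow_degenerate) {
    thr <- sort(runif(5, 0, 30))
    if (runif(1) < 0.3) {
      i <- sample(2:4, 1)
      thr[i + 1] <- thr[i]
      thr <- sort(thr)
    }
  } else {
    # month-scale brackets with nonvanishing width
    thr <- cumsum(c(runif(1, 0, 6), runif(4, 0.1, 7)))
  }
  list(milestone_id = "rnd", domain = "language",
       t0 = thr[1], t75 = thr[2], t90 = thr[3], t95 = thr[4], t100 = thr[5])
}

# well-separated DTV blobs around the three archetype shapes
archetype_dtv_fixture <- function(n = c(adequate = 600, catching_up = 150,
                                        worsening = 80),
                                  sd = 0.05, seed = 3) {
  templates <- list(
    adequate    = c(0.03, 0.05, 0.04, 0.06, 0.03, 0.04, 0.03),
    catching_up = c(1.30, 0.70, 0.35, 0.12, 0.06, 0.05, 0.04),
    worsening   = c(0.05, 0.08, 0.12, 0.25, 0.55, 0.90, 1.30)
  )
  withr::with_seed(seed, {
    rows <- lapply(names(templates), function(arch) {
      k <- n[[arch]]
      m <- matrix(rep(templates[[arch]], each = k), k, 7) +
        matrix(rnorm(k * 7, 0, sd), k, 7)
      m <- pmax(m, 0)
      d <- tibble::as_tibble(as.data.frame(m))
      names(d) <- paste0("step", 1:7)
      d$archetype <- arch
      d
    })
    out <- dplyr::bind_rows(rows)
    out$child_id <- sprintf("c%05d", seq_len(nrow(out)))
    out$domain_group <- "motor"
    out$complete <- TRUE
    out[c("child_id", "domain_group", paste0("step", 1:7), "complete",
          "archetype")]
  })
}

# cached simulated cohorts so several test files can share one generation
.cohorts <- new.env(parent = emptyenv())

cohort_fixture <- function(n_children, seed, ...) {
  key <- paste(n_children, seed, deparse(list(...)), collapse = "|")
  if (is.null(.cohorts[[key]])) {
    cfg <- sim_config(n_children = n_children, seed = seed, ...)
    sc <- generate_scale(cfg)
    co <- generate_cohort(sc, cfg)
    .cohorts[[key]] <- list(config = cfg, scale = sc$scale,
                            curves = sc$curves, children = co$children,
                            attempts = co$attempts, truth = co$truth)
  }
  .cohorts[[key]]
}
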