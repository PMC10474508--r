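#' Run configuration for the end-to-end pipeline
#'
#' A single master seed deterministically derives the per-stage seeds, so
#' one integer reproduces an entire run.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param sim A [sim_config()]; its seed is overridden by the derived
#'   simulate-stage seed.
#' @param cluster_k,cluster_method,theta_low,theta_high Clustering settings
#'   (see [cluster_config()]).
#' @param method Score variant, `"lmas"` (default) or `"dmas"`.
#' @param stratifiers Named list of stratifier specs for the compare stage;
#'   each entry is a list with `var` and optionally `breaks`.
#' @return A list of class `devsurv_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = NULL,
                       cluster_k = 4, cluster_method = "kmeans",
                       theta_low = 0.15, theta_high = 0.5,
                       method = "lmas",
                       stratifiers = list(
                         sex = list(var = "sex"),
                         maternal_education = list(var = "maternal_education"),
                         birth_weight = list(var = "birth_weight",
                                             breaks = c(1, 2.5, 3, 3.5, 4, 4.5, 6))
                       )) {
  seed <- as.integer(seed)
  sim <- sim %||% sim_config()
  sim$seed <- derive_seed(seed, 1L)
  structure(
    list(out_dir = out_dir, seed = seed, sim = sim,
         cluster_k = cluster_k, cluster_method = cluster_method,
         theta_low = theta_low, theta_high = theta_high,
         method = method, stratifiers = stratifiers),
    class = "devsurv_run_config"
  )
}

# small deterministic seed derivation, kept well below 2^31
derive_seed <- function(master, stage) {
  (as.integer(master) * 1009L + stage * 9973L) %% 2000000011L
}

#' Run the full surveillance-score pipeline
#'
#' Executes the five stages in order — simulate, score, trajectories,
#' cluster, compare — writing each stage's outputs as plain CSV/JSON under
#' `config$out_dir` and returning a manifest of inputs, seeds and output
#' file hashes. Any stage failure aborts with an error naming the stage.
#' The compare stage runs on the on-term subset of the cohort (children
#' born before 37 gestational weeks are excluded), except the
#' gestational-age stratification which uses the full cohort.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1 simulate
  sim_out <- stage("simulate", {
    sc <- generate_scale(config$sim)
    co <- generate_cohort(sc, config$sim)
    write_scale(sc$scale, out("scale.csv"))
    readr::write_csv(sc$curves, out("curves.csv"))
    write_attempts(co$attempts, out("attempts.csv"))
    write_children(co$children, out("children.csv"))
    write_truth(co$truth, out("truth.csv"))
    list(scale = sc, cohort = co)
  })
  scale <- sim_out$scale$scale
  attempts <- sim_out$cohort$attempts
  children <- sim_out$cohort$children

  # 2 score
  scores <- stage("score", {
    s <- score_table(attempts, scale, method = config$method)
    readr::write_csv(s, out("scores.csv"), na = "")
    s
  })

  # 3 trajectories
  dtvs <- stage("trajectories", {
    res <- lapply(c("motor", "language_social"), function(g) {
      d <- build_dtvs(attempts, scale, domain_group = g, method = config$method)
      write_dtvs(d, out(paste0("dtvs_", g, ".csv")))
      filter_complete(d)
    })
    names(res) <- c("motor", "language_social")
    res
  })

  # 4 cluster
  reports <- stage("cluster", {
    res <- lapply(names(dtvs), function(g) {
      d <- dtvs[[g]]
      if (!all(d$complete)) {
        stop("incomplete trajectory vectors reached clustering; ",
             "filter_complete() must run first")
      }
      cfg <- cluster_config(k = config$cluster_k, method = config$cluster_method,
                            seed = derive_seed(config$seed, 4L),
                            theta_low = config$theta_low,
                            theta_high = config$theta_high)
      rep <- cluster_dtvs(d, cfg)
      readr::write_csv(rep$assignments, out(paste0("assignments_", g, ".csv")))
      jsonlite::write_json(
        list(centroids = unname(apply(rep$centroids, 1, as.numeric,
                                      simplify = FALSE)),
             sizes = rep$sizes, fractions = rep$fractions,
             validity = rep$validity, labels = rep$labels,
             dropped_step = rep$dropped_step,
             assignments_path = paste0("assignments_", g, ".csv")),
        out(paste0("clusters_", g, ".json")), auto_unbox = TRUE, digits = NA)
      rep
    })
    names(res) <- names(dtvs)
    res
  })

  # 5 compare
  stage("compare", {
    onterm <- exclude_preterm(children)
    stopifnot(all(onterm$gestational_age >= 37))
    scores_onterm <- scores[scores$child_id %in% onterm$child_id, ]
    for (nm in names(config$stratifiers)) {
      sp <- config$stratifiers[[nm]]
      st <- stratified_means(scores_onterm, onterm, var = sp$var,
                             breaks = sp$breaks)
      readr::write_csv(st$means, out(paste0("strata_", nm, "_means.csv")))
      if (nrow(st$comparisons) > 0) {
        readr::write_csv(st$comparisons, out(paste0("strata_", nm, "_tests.csv")))
      }
    }
    # gestational age is the one analysis kept on the full cohort
    ga <- children
    ga$ga_category <- as.character(preterm_category(ga$gestational_age))
    st <- stratified_means(scores, ga, var = "ga_category",
                           levels = c("extremely_preterm", "very_preterm",
                                      "late_preterm", "early_term", "full_term"))
    readr::write_csv(st$means, out("strata_gestational_age_means.csv"))
    readr::write_csv(st$comparisons, out("strata_gestational_age_tests.csv"))
    NULL
  })

  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("devsurv")),
    seed = config$seed,
    stage_seeds = list(simulate = config$sim$seed,
                       cluster = derive_seed(config$seed, 4L)),
    n_children = config$sim$n_children,
    outputs = as.list(tools::md5sum(file.path(config$out_dir, files)) |>
                        setNames(files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
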