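# Orchestration: simulate -> activity budgets -> breakpoints -> boosted
# classifier -> trend contrasts -> multi-event CMR, as one seeded,
# logged, reproducible run.

#' Build a pipeline configuration
#'
#' @param seed Global seed, expanded deterministically into per-stage
#'   child seeds.
#' @param outdir Output directory (created if needed).
#' @param stages Named logical list toggling each stage.
#' @param sim A [sim_config()] (its own seed is overridden by the
#'   pipeline's simulate-stage child seed).
#' @param activity List: `thresholds` for [classify_block()].
#' @param breakpoints List: `max_k`, `n_restarts`.
#' @param boost List: `m_rounds`, `tree_depth`, `k_folds`, `n_perm`
#'   (0 skips the permutation test), `cor_threshold`.
#' @param trends List: `period`, `alpha`.
#' @param mecmr List: `n_starts`, `n_boot`.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("run"),
                            stages = list(),
                            sim = sim_config(),
                            activity = list(),
                            breakpoints = list(),
                            boost = list(),
                            trends = list(),
                            mecmr = list(),
                            log_level = "info") {
  defaults <- list(
    stages = list(simulate = TRUE, activity = TRUE, breakpoints = TRUE,
                  boost = TRUE, trends = TRUE, mecmr = TRUE),
    activity = list(thresholds = c(0.05, 0.95)),
    breakpoints = list(max_k = 2, n_restarts = 5),
    boost = list(m_rounds = 100, tree_depth = 1, k_folds = 10,
                 n_perm = 0, cor_threshold = 0.9),
    trends = list(period = 7, alpha = 0.01),
    mecmr = list(n_starts = 5, n_boot = 500))
  merge <- function(d, u) { d[names(u)] <- u; d }
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    stages = merge(defaults$stages, stages),
    sim = sim,
    activity = merge(defaults$activity, activity),
    breakpoints = merge(defaults$breakpoints, breakpoints),
    boost = merge(defaults$boost, boost),
    trends = merge(defaults$trends, trends),
    mecmr = merge(defaults$mecmr, mecmr),
    log_level = log_level
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `sim` block holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$rp_category_counts)) {
    sim_args$rp_category_counts <- unlist(sim_args$rp_category_counts)
  }
  sim <- do.call(sim_config, sim_args)
  pipeline_config(seed = y$seed %||% 1,
                  outdir = y$outdir %||% tempfile("run"),
                  stages = y$stages %||% list(),
                  sim = sim,
                  activity = y$activity %||% list(),
                  breakpoints = y$breakpoints %||% list(),
                  boost = y$boost %||% list(),
                  trends = y$trends %||% list(),
                  mecmr = y$mecmr %||% list(),
                  log_level = y$log_level %||% "info")
}

#' Run the full carry-over-effects pipeline
#'
#' Executes the enabled stages in dependency order, writes every table
#' under `config$outdir` with a provenance header, and returns (and
#' writes as JSON) a manifest of seeds, counts and headline statistics.
#' A failed stage is recorded in the manifest and downstream stages that
#' depend on it are skipped.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (invisible copy written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level != "quiet") message(...)
  child <- function(stage) stage_seed(config$seed, stage)

  manifest <- list(
    package_version = as.character(utils::packageVersion("shearwaterCOE")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    child_seeds = sapply(c("simulate", "activity", "breakpoints", "boost",
                           "trends", "mecmr"), child),
    stages = list(), outputs = list())
  failed <- character(0)
  run_stage <- function(name, deps, fun) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    if (any(deps %in% failed)) {
      manifest$stages[[name]] <<- list(status = "skipped: failed dependency")
      failed <<- c(failed, name)
      return(NULL)
    }
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = paste("failed:",
                                                      conditionMessage(res)))
      failed <<- c(failed, name)
      NULL
    } else {
      manifest$stages[[name]] <<- res$summary
      manifest$outputs[[name]] <<- res$outputs
      res$value
    }
  }

  sim <- config$sim
  sim$seed <- child("simulate")
  env <- new.env()

  run_stage("simulate", character(0), function() {
    env$phen <- simulate_phenology(sim)
    env$imm <- simulate_immersion(sim, env$phen)
    eh <- simulate_encounter_histories(sim)
    env$hist <- eh$histories
    env$truth <- eh$truth
    p1 <- file.path(config$outdir, "phenology.csv")
    p2 <- file.path(config$outdir, "immersion.csv")
    p3 <- file.path(config$outdir, "encounter_histories.csv")
    write_csv_prov(env$phen, p1, sim$seed, "simulate")
    write_csv_prov(env$imm, p2, sim$seed, "simulate")
    write_csv_prov(histories_to_long(env$hist), p3, sim$seed, "simulate")
    counts <- table(env$phen$label)[RP_STATES]
    list(summary = list(
      logger_bird_seasons = nrow(env$phen),
      rp_counts = as.list(counts),
      history_birds = nrow(env$hist$events),
      immersion_blocks = nrow(env$imm)),
      outputs = c(p1, p2, p3), value = TRUE)
  })

  run_stage("activity", "simulate", function() {
    env$profiles <- daily_profiles(env$imm, config$activity$thresholds)
    p <- file.path(config$outdir, "daily_profiles.csv")
    write_csv_prov(env$profiles, p, child("activity"), "activity")
    list(summary = list(n_profiles = nrow(env$profiles),
                        n_birds = length(unique(env$profiles$bird_id))),
         outputs = p, value = TRUE)
  })

  run_stage("breakpoints", "activity", function() {
    set.seed(child("breakpoints"))
    rows <- list()
    for (b in unique(env$profiles$bird_id)) {
      pr <- env$profiles[env$profiles$bird_id == b, ]
      pr <- pr[order(pr$date), ]
      x <- as.numeric(pr$date - pr$date[1])
      f <- tryCatch(
        select_n_breakpoints(x, pr$p_fly, max_k = config$breakpoints$max_k,
                             n_restarts = config$breakpoints$n_restarts),
        error = function(e) NULL)
      if (is.null(f)) next
      rows[[b]] <- data.frame(
        bird_id = b, k = f$n_breakpoints,
        tau = paste(signif(f$tau, 6), collapse = ";"),
        slopes = paste(signif(f$segment_slopes, 6), collapse = ";"),
        rss = f$rss, converged = f$converged)
    }
    bp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    p <- file.path(config$outdir, "breakpoints.csv")
    write_csv_prov(bp, p, child("breakpoints"), "breakpoints")
    first_taus <- suppressWarnings(as.numeric(vapply(
      strsplit(bp$tau[bp$k > 0], ";"), `[`, character(1), 1L)))
    list(summary = list(
      n_birds = nrow(bp),
      k_distribution = as.list(table(bp$k)),
      median_first_tau = stats::median(first_taus, na.rm = TRUE)),
      outputs = p, value = TRUE)
  })

  run_stage("boost", "simulate", function() {
    bo <- config$boost
    model <- train_samme(env$phen, m_rounds = bo$m_rounds,
                         tree_depth = bo$tree_depth,
                         seed = child("boost"))
    imp <- cumulative_importance_ranking(model)
    cv <- cv_error(env$phen, k_folds = bo$k_folds, m_rounds = bo$m_rounds,
                   tree_depth = bo$tree_depth, seed = child("boost"))
    dropped <- drop_correlated_features(env$phen,
                                        threshold = bo$cor_threshold)
    perm <- NULL
    if (bo$n_perm > 0) {
      perm <- permutation_pvalue(env$phen, n_perm = bo$n_perm,
                                 k_folds = bo$k_folds,
                                 m_rounds = bo$m_rounds,
                                 tree_depth = bo$tree_depth,
                                 seed = child("boost"))
    }
    p1 <- file.path(config$outdir, "feature_importance.csv")
    write_csv_prov(imp, p1, child("boost"), "boost")
    p2 <- file.path(config$outdir, "cv_report.csv")
    write_csv_prov(cv$per_fold, p2, child("boost"), "boost")
    env$cv <- cv
    list(summary = list(
      cv_error_rate_pct = 100 * cv$error_rate,
      cv_success_rate_pct = 100 * cv$success_rate,
      top_features = imp$feature[seq_len(min(3, nrow(imp)))],
      dropped_correlated = dropped$dropped,
      permutation_p = if (!is.null(perm)) perm$p_value else NA),
      outputs = c(p1, p2), value = TRUE)
  })

  run_stage("trends", "activity", function() {
    tr <- config$trends
    labels <- stats::setNames(env$phen$label, env$phen$bird_id)
    sexes <- stats::setNames(env$phen$sex, env$phen$bird_id)
    pooled_rp <- list(); pooled_sex <- list()
    mean_rows <- list()
    for (a in c("FLY", "REST", "FORAGE")) {
      gm <- group_mean_trend(env$profiles, labels, a, period = tr$period)
      mean_rows[[a]] <- cbind(activity = a, gm$mean_trend)
      pooled_rp[[a]] <- lapply(gm$bird_trends, function(m) unlist(m))
      gs <- group_mean_trend(env$profiles, sexes, a, period = tr$period)
      # sex contrast on per-bird winter means: one value per bird, so
      # the day-to-day autocorrelation does not inflate the sample size
      pooled_sex[[a]] <- lapply(gs$bird_trends, function(m)
        vapply(m, mean, numeric(1)))
    }
    env$mean_trends <- do.call(rbind, c(mean_rows,
                                        list(make.row.names = FALSE)))
    cmp_rp <- compare_groups(pooled_rp, alpha = tr$alpha, correct = TRUE)
    cmp_sex <- compare_groups(pooled_sex, alpha = tr$alpha, correct = FALSE)
    cmp_sex$activity <- paste0("sex:", cmp_sex$activity)
    cmp <- rbind(cmp_rp, cmp_sex)

    # ECDF table of pooled trend values
    ecdf_rows <- list()
    for (a in names(pooled_rp)) for (g in names(pooled_rp[[a]])) {
      v <- sort(unique(pooled_rp[[a]][[g]]))
      Fv <- stats::ecdf(pooled_rp[[a]][[g]])(v)
      ecdf_rows[[paste(a, g)]] <- data.frame(activity = a, group = g,
                                             x = v, F = Fv)
    }
    mf <- env$mean_trends
    skip_vs_success <- mean(
      mf$mean[mf$activity == "FORAGE" & mf$group == "SKIP"] >
        mf$mean[mf$activity == "FORAGE" & mf$group == "SUCCESS"])
    p1 <- file.path(config$outdir, "group_trends.csv")
    p2 <- file.path(config$outdir, "comparisons.csv")
    p3 <- file.path(config$outdir, "ecdf.csv")
    write_csv_prov(env$mean_trends, p1, child("trends"), "trends")
    write_csv_prov(cmp, p2, child("trends"), "trends")
    write_csv_prov(do.call(rbind, c(ecdf_rows, list(make.row.names = FALSE))),
                   p3, child("trends"), "trends")
    env$comparisons <- cmp
    list(summary = list(
      n_rp_comparisons = nrow(cmp_rp),
      n_rp_significant = sum(cmp_rp$significant),
      skip_gt_success_forage_share = skip_vs_success,
      sex_p_values = stats::setNames(cmp_sex$p_value, cmp_sex$activity)),
      outputs = c(p1, p2, p3), value = TRUE)
  })

  run_stage("mecmr", "simulate", function() {
    me <- config$mecmr
    specs <- list(
      psi_constant = mecmr_spec(psi_by_state = FALSE),
      psi_state = mecmr_spec(psi_by_state = TRUE),
      psi_state_mixture = mecmr_spec(psi_by_state = TRUE,
                                     n_mixture_classes = 2))
    fits <- list()
    for (nm in names(specs)) {
      fits[[nm]] <- fit_mecmr(env$hist, specs[[nm]],
                              n_starts = me$n_starts,
                              seed = child("mecmr"))
    }
    tab <- model_table(fits)
    best <- fits[[tab$model[1]]]
    lr <- longrun_success(best, mode = "next_year",
                          n_boot = if (is.null(best$vcov)) 0 else me$n_boot,
                          seed = child("mecmr"))
    emp <- empirical_transition_matrix(env$hist)
    p1 <- file.path(config$outdir, "mecmr_models.csv")
    p2 <- file.path(config$outdir, "longrun_success.csv")
    write_csv_prov(tab, p1, child("mecmr"), "mecmr")
    write_csv_prov(lr, p2, child("mecmr"), "mecmr")
    env$mecmr_best <- best
    list(summary = list(
      best_model = tab$model[1],
      aic = stats::setNames(tab$aic, tab$model),
      longrun_success = stats::setNames(lr$estimate, lr$state),
      empirical_gap_pairs = emp$n_gap_pairs),
      outputs = c(p1, p2), value = TRUE)
  })

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
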