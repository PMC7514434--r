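#' Configuration for the repetition experiment
#'
#' Encodes the synthetic-data protocol: a fixed toy ground-truth model, a
#' balanced binary tree of `2^K` leaves with all branches `dt`, per-branch
#' expected mutation counts `mu * L * dt` (presets 3, 5 or `Inf` for the
#' i.i.d. limit), and a number of independent repetitions of the root +
#' tree sampling. The paper-scale protocol is `K = 12`, `dt = 0.3`, 30
#' repetitions.
#'
#' @param preset one of `"paper-mu-l-dt-3"`, `"paper-mu-l-dt-5"`,
#'   `"paper-iid"`, or `NULL` to take all values from the arguments
#' @param K duplications (leaves = `2^K`)
#' @param muLdt expected mutations per branch (`Inf` = i.i.d. sample)
#' @param dt branch length in clock units (default 0.3)
#' @param reps repetitions of the sampling process
#' @param seed master seed; all per-repetition seeds derive from it
#' @param arms which inference arms to run; subset of
#'   `c("uncorrected", "reweighted", "site", "pair", "iid")`
#' @param schedule optimizer schedule for the corrections
#' @param kl_samples Monte-Carlo sample size for the KL metric (0 disables)
#' @param n_wt wild types drawn per sample for mutant scoring (0 disables)
#' @param ppv evaluate contact-prediction PPV?
#' @param toy parameters passed to [generate_toy_model()]
#' @return config list for [run_experiment()]
#' @export
experiment_config <- function(preset = NULL, K = 12, muLdt = 3, dt = 0.3,
                              reps = 30, seed = 1,
                              arms = c("uncorrected", "site", "pair", "iid"),
                              schedule = optimizer_schedule(),
                              kl_samples = 1e4, n_wt = 50, ppv = TRUE,
                              toy = toy_model_params()) {
  if (!is.null(preset)) {
    preset <- match.arg(preset,
                        c("paper-mu-l-dt-3", "paper-mu-l-dt-5", "paper-iid"))
    K <- 12; dt <- 0.3; reps <- 30
    muLdt <- switch(preset, "paper-mu-l-dt-3" = 3, "paper-mu-l-dt-5" = 5,
                    "paper-iid" = Inf)
  }
  arms <- match.arg(arms, c("uncorrected", "reweighted", "site", "pair",
                            "iid"), several.ok = TRUE)
  list(K = K, muLdt = muLdt, dt = dt, reps = reps, seed = seed, arms = arms,
       schedule = schedule, kl_samples = kl_samples, n_wt = n_wt, ppv = ppv,
       toy = toy)
}

#' Run the full correction-and-inference experiment
#'
#' For each repetition: sample a phylogenetically biased MSA down a fresh
#' tree (same ground-truth model across repetitions) plus an i.i.d. sample of
#' the same size; estimate the effective mutation rate from the tree sample;
#' run the requested arms — DCA on the raw tree sample (`uncorrected`),
#' on the 80%-reweighted sample (`reweighted`), on an annealed rebuild using
#' the site correction (`site`), using the pair correction (`pair`), and on
#' the i.i.d. sample (`iid`) — and score every inferred model against the
#' ground truth (statistics recovery, parameter Pearson, symmetrized KL,
#' contact PPV, mutant-effect prediction).
#'
#' @param config an [experiment_config()]
#' @param verbose print per-repetition progress?
#' @return list with `truth` (model + edges), `stats` (per-repetition data
#'   frame), `ppv` (long data frame of PPV curves), `mutants` (long data
#'   frame), and `config`
#' @export
run_experiment <- function(config, verbose = FALSE) {
  toy <- config$toy
  L <- toy$L
  truth <- with_seed(config$seed,
                     do.call(generate_toy_model, toy))
  model0 <- truth$model
  M <- 2L^config$K
  mu_sim <- if (is.finite(config$muLdt)) config$muLdt / (L * config$dt) else Inf
  rows <- list(); ppv_rows <- list(); mut_rows <- list()
  for (rep in seq_len(config$reps)) {
    rep_seed <- config$seed + 7919L * rep
    set.seed(rep_seed)
    tree <- grow_binary_tree(config$K, config$dt)
    tree_msa <- if (is.finite(mu_sim))
      sample_tree_msa(model0, tree, mu_sim)
    else sample_iid(model0, M)
    iid_msa <- sample_iid(model0, M)
    f_tree <- count_frequencies(tree_msa)
    f_iid <- count_frequencies(iid_msa)
    mu_eff <- if (is.finite(mu_sim)) {
      fit <- tryCatch(estimate_mu(tree_msa, tree, max_pairs = 2e5),
                      error = function(e) NULL)
      if (is.null(fit)) mu_sim else fit$mu
    } else Inf
    # corrections
    omega_site <- NULL; omega_pair <- NULL
    if (any(c("site", "pair") %in% config$arms) && is.finite(mu_eff))
      omega_site <- correct_all_sites(tree_msa, tree, mu_eff, config$schedule)
    if ("pair" %in% config$arms && is.finite(mu_eff))
      omega_pair <- correct_all_pairs(tree_msa, tree, mu_eff, omega_site,
                                      config$schedule)
    # inference arms -> models
    models <- list()
    for (arm in config$arms) {
      if (arm %in% c("site", "pair") && is.null(omega_site)) next
      models[[arm]] <- switch(arm,
        uncorrected = plm_infer(tree_msa),
        reweighted = plm_infer(tree_msa,
                               weights = reweighting_weights(tree_msa)),
        site = {
          comb <- combine_site_correction(f_tree, omega_site)
          art <- init_profile_msa(omega_site, M, tree_msa$alphabet)
          art <- anneal_msa(art, target_covariance(comb))
          plm_infer(art)
        },
        pair = {
          art <- init_profile_msa(omega_pair, M, tree_msa$alphabet)
          art <- anneal_msa(art, target_covariance(omega_pair))
          plm_infer(art)
        },
        iid = plm_infer(iid_msa))
    }
    # profile baselines for mutant scoring
    prof_tree <- fit_profile(f_tree)
    prof_site <- if (!is.null(omega_site)) fit_profile(omega_site) else NULL
    # ---- metrics ----
    row <- list(rep = rep, seed = rep_seed, mu_eff = mu_eff)
    # statistics recovery vs the i.i.d. sample
    cmp_site <- function(s) compare_stats(flatten_stats(f_iid$site, "site"),
                                          flatten_stats(s, "site"))
    row$pearson_f_site_tree <- cmp_site(f_tree$site)$pearson
    row$slope_f_site_tree <- cmp_site(f_tree$site)$slope
    if (!is.null(omega_site)) {
      cs <- cmp_site(omega_site$site)
      row$pearson_f_site_inf <- cs$pearson
      row$slope_f_site_inf <- cs$slope
    }
    cc_iid <- connected_correlations(f_iid)
    row$pearson_f_pair_tree <-
      compare_stats(as.vector(f_iid$pairs), as.vector(f_tree$pairs))$pearson
    row$pearson_cc_tree <-
      compare_stats(as.vector(cc_iid),
                    as.vector(connected_correlations(f_tree)))$pearson
    if (!is.null(omega_pair)) {
      row$pearson_f_pair_inf <-
        compare_stats(as.vector(f_iid$pairs), as.vector(omega_pair$pairs))$pearson
      row$pearson_cc_inf <-
        compare_stats(as.vector(cc_iid),
                      as.vector(target_covariance(omega_pair)))$pearson
    }
    # per-arm model metrics
    truth_zs <- zero_sum_gauge(model0)
    wt_tree <- wt_fair <- NULL
    if (config$n_wt > 0) {
      idx <- sample.int(M, min(config$n_wt, M))
      wt_tree <- msa_matrix(tree_msa)[idx, , drop = FALSE]
      wt_fair <- msa_matrix(sample_iid(model0, config$n_wt))
    }
    for (arm in names(models)) {
      mod <- models[[arm]]
      zs <- zero_sum_gauge(mod)
      row[[paste0("pearson_J_", arm)]] <-
        stats::cor(as.vector(truth_zs$J), as.vector(zs$J))
      row[[paste0("pearson_h_", arm)]] <-
        stats::cor(as.vector(truth_zs$h), as.vector(zs$h))
      if (config$kl_samples > 0) {
        kl <- symmetrized_kl(model0, mod, n_samples = config$kl_samples)
        row[[paste0("kl_", arm)]] <- kl$kl
        row[[paste0("kl_se_", arm)]] <- kl$se
      }
      if (config$ppv) {
        pc <- ppv_curve(coupling_scores(mod), truth$edges,
                        n_max = 2L * nrow(truth$edges))
        ppv_rows[[length(ppv_rows) + 1L]] <-
          data.frame(rep = rep, arm = arm, N = pc$N, ppv = pc$ppv)
        row[[paste0("ppv_at_E_", arm)]] <- pc$ppv[nrow(truth$edges)]
      }
      if (config$n_wt > 0) {
        for (wt_kind in c("tree", "fair")) {
          wt <- if (wt_kind == "tree") wt_tree else wt_fair
          ms <- mutant_prediction_score(model0, mod, wt)
          mut_rows[[length(mut_rows) + 1L]] <-
            data.frame(rep = rep, arm = arm, wt_set = wt_kind,
                       mean_pearson = ms$mean_pearson)
        }
      }
    }
    if (config$n_wt > 0) {
      for (wt_kind in c("tree", "fair")) {
        wt <- if (wt_kind == "tree") wt_tree else wt_fair
        mut_rows[[length(mut_rows) + 1L]] <-
          data.frame(rep = rep, arm = "profile_tree", wt_set = wt_kind,
                     mean_pearson =
                       mutant_prediction_score(model0, prof_tree, wt)$mean_pearson)
        if (!is.null(prof_site))
          mut_rows[[length(mut_rows) + 1L]] <-
            data.frame(rep = rep, arm = "profile_site", wt_set = wt_kind,
                       mean_pearson =
                         mutant_prediction_score(model0, prof_site, wt)$mean_pearson)
      }
    }
    rows[[rep]] <- as.data.frame(row)
    if (verbose)
      message("repetition ", rep, "/", config$reps, " done (seed ", rep_seed, ")")
  }
  list(truth = truth,
       stats = do.call(rbind, rows),
       ppv = if (length(ppv_rows)) do.call(rbind, ppv_rows) else NULL,
       mutants = if (length(mut_rows)) do.call(rbind, mut_rows) else NULL,
       config = config)
}

#' Write an experiment report to TSV files
#'
#' @param result a [run_experiment()] result
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_experiment_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$stats, file.path(dir, "stats.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$ppv))
    utils::write.table(result$ppv, file.path(dir, "ppv.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(result$mutants))
    utils::write.table(result$mutants, file.path(dir, "mutants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    reps = result$config$reps, K = result$config$K,
    muLdt = result$config$muLdt, seed = result$config$seed,
    arms = result$config$arms,
    mean = as.list(colMeans(result$stats[vapply(result$stats, is.numeric,
                                                logical(1))], na.rm = TRUE)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
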