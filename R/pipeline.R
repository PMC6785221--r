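# End-to-end orchestration: simulate -> preprocess -> unit statistics ->
# population geometry -> decoding, with machine-readable outputs and a
# content-hash manifest.

#' Run configuration for the full pipeline
#'
#' All analysis defaults (25 ms kernel, soft-normalization constant 5,
#' 8 tangling dimensions, epsilon 10% of variance, 1000 permutations, 100
#' hemisphere shuffles, cycles 2-5) appear explicitly so deviations are
#' visible.
#'
#' @param generator A [generator_config()] (used when no session is
#'   supplied to [run_all()]).
#' @param kernel_sd Smoothing kernel SD in ms.
#' @param dt_ms Analysis resolution in ms.
#' @param soft_c Soft-normalization constant.
#' @param n_perm Permutations for the speed-split test.
#' @param n_shuffles Hemisphere-label shuffles.
#' @param tangling_dims,tangling_epsilon Tangling parameters.
#' @param n_pcs Component count for variance-capture summaries.
#' @param stages Character vector of stages to run (subset of
#'   `c("unit_stats", "population", "decoding")`; preprocessing always
#'   runs).
#' @param seed Root seed for all stochastic analysis steps.
#' @return A `cp_run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       kernel_sd = 25, dt_ms = 10, soft_c = 5,
                       n_perm = 1000, n_shuffles = 100,
                       tangling_dims = 8, tangling_epsilon = 0.1,
                       n_pcs = 5,
                       stages = c("unit_stats", "population", "decoding"),
                       seed = 1L) {
  cfg <- list(generator = generator, kernel_sd = kernel_sd, dt_ms = dt_ms,
              soft_c = soft_c, n_perm = n_perm, n_shuffles = n_shuffles,
              tangling_dims = tangling_dims,
              tangling_epsilon = tangling_epsilon, n_pcs = n_pcs,
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "cp_run_config"
  cfg
}

write_csv_out <- function(x, dir, name, files) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, unit statistics, population geometry and
#' decoding, writing CSV/JSON outputs plus a manifest listing every output
#' file with its MD5 content hash. Reruns with an identical configuration
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @param session Optional pre-built `cp_session`; when omitted, one is
#'   simulated from `config$generator`.
#' @return A report bundle (list) with the in-memory results of every
#'   stage, the output directory, and the manifest.
#' @export
run_all <- function(config = run_config(), outdir = tempfile("cyclepop_"),
                    session = NULL) {
  stopifnot(inherits(config, "cp_run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- "simulate"
  bundle <- list(config = config, outdir = outdir)
  tryCatch({
    if (is.null(session)) {
      gen <- generate_session(config$generator)
      session <- gen$session
      bundle$ground_truth <- gen$ground_truth
    }
    bundle$session <- session

    stage <- "preprocess"
    rates <- preprocess_session(session, kernel_sd = config$kernel_sd,
                                dt_out = config$dt_ms)
    bundle$rates <- rates
    files <- write_csv_out(rate_tensor_long(rates, "neural"), outdir,
                           "rates_neural.csv", files)
    files <- write_csv_out(rate_tensor_long(rates, "emg"), outdir,
                           "rates_emg.csv", files)

    if ("unit_stats" %in% config$stages) {
      stage <- "unit_stats"
      us <- unit_stats_table(rates)
      ms <- muscle_stats_table(rates)
      ss <- speed_split_test(rates, n_perm = config$n_perm,
                             seed = child_seed(config$seed, "speedsplit"))
      us$flagged_fraction <- vapply(seq_len(nrow(us)), function(u) {
        sel <- ss$by_unit$unit == us$unit_id[u]
        if (any(sel)) mean(ss$by_unit$flagged_fraction[sel]) else NA_real_
      }, 0)
      pc <- pairwise_correlation_analysis(rates)
      fano <- fano_factor(session)
      mag <- tryCatch(
        required_magnification(ms$modulation_driven,
                               ms$modulation_non_driven,
                               stats::median(us$api, na.rm = TRUE)),
        error = function(e) NA_real_)
      bundle$unit_stats <- list(units = us, muscles = ms,
                                speed_split = ss, pairwise = pc,
                                fano = fano, required_magnification = mag)
      files <- write_csv_out(us, outdir, "unit_stats.csv", files)
      files <- write_csv_out(ms, outdir, "muscle_stats.csv", files)
      jsonlite::write_json(
        list(meta_correlation = pc$meta_correlation,
             fano_slope = fano$slope,
             speed_split_flagged = ss$flagged_fraction,
             required_magnification = mag),
        file.path(outdir, "unit_stats_summary.json"),
        auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(outdir, "unit_stats_summary.json"))
    }

    if ("population" %in% config$stages) {
      stage <- "population"
      sweep3 <- triplet_sweep(rates, n_pcs = config$n_pcs,
                              soft_c = config$soft_c)
      wl <- subspace_contribution_weights(rates, "left",
                                          n_pcs = config$n_pcs,
                                          soft_c = config$soft_c)
      wr <- subspace_contribution_weights(rates, "right",
                                          n_pcs = config$n_pcs,
                                          soft_c = config$soft_c)
      tang <- tangling_comparison(rates, n_dims = config$tangling_dims,
                                  epsilon_fraction =
                                    config$tangling_epsilon,
                                  soft_c = config$soft_c)
      bundle$population <- list(triplet = sweep3,
                                weights = list(left = wl, right = wr),
                                tangling = tang)
      files <- write_csv_out(sweep3$curves, outdir, "capture_curves.csv",
                             files)
      files <- write_csv_out(sweep3$summary, outdir, "capture_summary.csv",
                             files)
      files <- write_csv_out(tang$summary, outdir, "tangling_summary.csv",
                             files)
    }

    if ("decoding" %in% config$stages) {
      stage <- "decoding"
      chd <- cross_hemisphere_muscle_decode(rates, soft_c = config$soft_c)
      sig <- cross_hemisphere_signal_compare(rates, soft_c = config$soft_c)
      shuf <- hemisphere_shuffle_test(rates,
                                      n_resamples = config$n_shuffles,
                                      seed = child_seed(config$seed,
                                                        "hemishuffle"),
                                      soft_c = config$soft_c)
      wa_perf <- wrong_arm_generalization(rates, "train_performing",
                                          soft_c = config$soft_c)
      wa_both <- wrong_arm_generalization(rates, "train_both",
                                          soft_c = config$soft_c)
      bundle$decoding <- list(muscle_decode = chd, signal_compare = sig,
                              shuffle = shuf,
                              wrong_arm = list(train_performing = wa_perf,
                                               train_both = wa_both))
      files <- write_csv_out(chd, outdir, "decoding_r2.csv", files)
      files <- write_csv_out(sig, outdir, "signal_compare.csv", files)
      files <- write_csv_out(wa_perf$table, outdir,
                             "wrong_arm_train_performing.csv", files)
      files <- write_csv_out(wa_both$table, outdir,
                             "wrong_arm_train_both.csv", files)
      jsonlite::write_json(
        list(shuffle_p = shuf$p, shuffle_observed = shuf$observed),
        file.path(outdir, "hemisphere_shuffle.json"),
        auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(outdir, "hemisphere_shuffle.json"))
    }
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  summary <- summarize_run(bundle)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(outdir, "summary.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  bundle$manifest <- manifest
  bundle$summary <- summary
  class(bundle) <- "cp_bundle"
  bundle
}

# Long-format export of a rate tensor.
rate_tensor_long <- function(rates, what = c("neural", "emg")) {
  what <- match.arg(what)
  ids <- if (what == "neural") rates$units$unit_id else
    rates$muscles$channel_id
  arr <- rates[[what]]$mean
  sem <- rates[[what]]$sem
  d <- dim(arr)
  data.frame(
    time_ms = rep(rates$time_ms, d[2] * d[3]),
    channel = rep(rep(ids, each = d[1]), d[3]),
    condition = rep(rates$conditions$condition_id, each = d[1] * d[2]),
    value = as.vector(arr), sem = as.vector(sem))
}

#' Summarize a report bundle into one document
#'
#' Collects the headline quantities of a pipeline run: median
#' arm-preference indices (units, muscles, decoded EMG), median response
#' correlations, meta-correlation, speed-split flagged fraction, Fano
#' slope, variance capture at the summary PC count, tangling means, and
#' decoder R^2 medians. Missing stages yield `NULL` entries, not errors.
#'
#' @param bundle A `cp_bundle` from [run_all()] (possibly partial).
#' @return A named list suitable for JSON serialization.
#' @export
summarize_run <- function(bundle) {
  us <- bundle$unit_stats
  pop <- bundle$population
  dec <- bundle$decoding
  med <- function(x) if (is.null(x)) NULL else
    stats::median(x, na.rm = TRUE)
  cap <- function(type) {
    if (is.null(pop)) return(NULL)
    s <- pop$triplet$summary
    as.list(s[s$type == type, c("mean_captured", "sd_captured")])
  }
  tang <- function(group) {
    if (is.null(pop)) return(NULL)
    s <- pop$tangling$summary
    as.list(s[s$group == group, c("mean", "sd")])
  }
  list(
    n_units = if (is.null(bundle$rates)) NULL else
      nrow(bundle$rates$units),
    n_trials = if (is.null(bundle$rates)) NULL else
      nrow(bundle$rates$trials),
    median_api_units = med(us$units$api),
    median_api_muscles = med(us$muscles$api),
    median_r_arm = med(us$units$r_arm),
    median_r_startpos = med(us$units$r_startpos),
    meta_correlation = if (is.null(us)) NULL else
      us$pairwise$meta_correlation,
    speed_split_flagged_fraction = if (is.null(us)) NULL else
      us$speed_split$flagged_fraction,
    fano_slope = if (is.null(us)) NULL else us$fano$slope,
    required_magnification = if (is.null(us)) NULL else
      us$required_magnification,
    capture_same_arm = cap("same_arm"),
    capture_opposite_arm = cap("opposite_arm"),
    tangling_driving = tang("driving_cortex"),
    tangling_non_driving = tang("non_driving_cortex"),
    tangling_muscle = tang("muscle"),
    decoder_r2_driving = if (is.null(dec)) NULL else
      med(dec$muscle_decode$r2[dec$muscle_decode$source == "driving"]),
    decoder_r2_non_driving = if (is.null(dec)) NULL else
      med(dec$muscle_decode$r2[dec$muscle_decode$source == "non_driving"]),
    median_api_decoded_train_performing = if (is.null(dec)) NULL else
      med(dec$wrong_arm$train_performing$table$api_decoded),
    median_api_decoded_train_both = if (is.null(dec)) NULL else
      med(dec$wrong_arm$train_both$table$api_decoded),
    hemisphere_shuffle_p = if (is.null(dec)) NULL else dec$shuffle$p)
}
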