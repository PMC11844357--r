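#' Default pipeline configuration
#'
#' Returns the configuration list that drives [run_pipeline()]. The cohort
#' defaults are the two study groups' published best-fit pathway parameters
#' (feedforward: pure gain with delay, gain 0.6, delays 185/245 ms;
#' feedback: leaky integrator with delay, gains 1.3/1.0, delays 123/144 ms,
#' pole 0.5 rad/s for control/ataxia respectively), used as ground truth for
#' synthetic subjects. Preview filters are generated as a pure time advance
#' with a first-order roll-off, stronger in the control group.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested named list; round-trips losslessly through YAML.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stimulus = list(
      base_hz = 0.04, n_freqs = 20L,
      velocity_coeff_ref = 1.3, cap_ref = 2.3,
      velocity_coeff_dist = 0.7, cap_dist = 1.5,
      duration_s = 75, sample_rate_hz = 80, transient_s = 25,
      preview_ms = 500
    ),
    cohort = list(
      n_subjects = 4L, remnant_sd = 0, param_cv = 0,
      groups = list(
        control = list(
          ff = list(structure = "gain_delay", k = 0.6, tau = 0.185),
          fb = list(structure = "leaky_integrator_delay", k = 1.3,
                    tau = 0.123, a = 0.5),
          preview = list(advance_s = 0.15, cutoff_hz = 2.0)
        ),
        ataxia = list(
          ff = list(structure = "gain_delay", k = 0.6, tau = 0.245),
          fb = list(structure = "leaky_integrator_delay", k = 1.0,
                    tau = 0.144, a = 0.5),
          preview = list(advance_s = 0.08, cutoff_hz = 1.2)
        )
      )
    ),
    fitting = list(
      candidates_ff = c("gain_delay", "first_order_delay",
                        "second_order_delay"),
      candidates_fb = c("gain_delay", "leaky_integrator_delay",
                        "first_order_delay"),
      n_restarts = 50L, delta = 0.05
    ),
    analysis = list(
      preview = TRUE, margins = TRUE, gain_swap = TRUE,
      smoothing_window = 3L,
      gain_swap_from = "ataxia", gain_swap_to = "control"
    )
  )
}

# first-order-lag-with-advance preview filter generator
preview_filter_fun <- function(advance_s, cutoff_hz) {
  force(advance_s); force(cutoff_hz)
  function(f) exp(1i * 2 * pi * f * advance_s) / (1 + 1i * f / cutoff_hz)
}

# build the synthetic subjects of one group, with optional parameter jitter
build_group_subjects <- function(gname, gcfg, n_subjects, remnant_sd,
                                 param_cv, grid, with_preview = TRUE) {
  jitter <- function(val) {
    if (param_cv <= 0) val else val * exp(stats::rnorm(1, 0, param_cv))
  }
  lapply(seq_len(n_subjects), function(i) {
    ff <- gcfg$ff
    fb <- gcfg$fb
    pf <- model_from_params(ff$structure, vapply(
      ff[setdiff(names(ff), "structure")], jitter, numeric(1)))
    pb <- model_from_params(fb$structure, vapply(
      fb[setdiff(names(fb), "structure")], jitter, numeric(1)))
    m <- if (with_preview && !is.null(gcfg$preview))
      preview_filter_fun(gcfg$preview$advance_s, gcfg$preview$cutoff_hz)
    else NULL
    synthetic_subject(pf, pb, M_preview = m, remnant_sd = remnant_sd,
                      subject_id = sprintf("%s_%02d", gname, i),
                      check_grid = grid$frequencies)
  })
}

# FNV-1a hash of the serialized config, for provenance stamping
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full identification pipeline on a synthetic cohort
#'
#' Executes simulate -> FRF estimation -> pathway isolation -> model
#' fitting/cross-validation -> preview-filter extraction -> stability
#' margins -> counterfactual gain swap, as toggled in the configuration, and
#' writes every artifact (CSV/JSON/YAML) into `out_dir`. All randomness
#' derives from `config$seed`; a repeated run with the same configuration
#' reproduces every number.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`grid`, `plan`,
#'   `subjects`, `frfs`, `pathways`, `group_fits`, `subject_fits`,
#'   `preview`, `margins`, `gain_swap`, `tracking`) plus `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  st <- config$stimulus

  # -- design -------------------------------------------------------------
  say("stage design")
  grid <- build_frequency_grid(st$base_hz, st$n_freqs)
  groups <- frequency_groups(grid)
  plan <- build_session_plan(grid, rng_seed = config$seed)
  utils::write.csv(as.data.frame(plan),
                   file.path(out_dir, "session_plan.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(freq_hz = grid$frequencies, prime = grid$primes,
               amp_ref_cm = amplitude_profile(grid$frequencies,
                                              st$velocity_coeff_ref,
                                              st$cap_ref),
               amp_dist_cm = amplitude_profile(grid$frequencies,
                                               st$velocity_coeff_dist,
                                               st$cap_dist)),
    file.path(out_dir, "frequency_grid.csv"), row.names = FALSE)

  # -- simulate -----------------------------------------------------------
  say("stage simulate")
  co <- config$cohort
  subjects <- list()
  withr_seed(config$seed + 1000L, {
    for (gname in names(co$groups)) {
      subjects[[gname]] <- build_group_subjects(
        gname, co$groups[[gname]], co$n_subjects, co$remnant_sd,
        co$param_cv, grid, with_preview = isTRUE(config$analysis$preview))
    }
  })
  trials <- list()
  for (gname in names(subjects)) {
    for (subj in subjects[[gname]]) {
      trials[[subj$subject_id]] <- simulate_cohort(
        subj, plan, grid, groups,
        duration = st$duration_s, sample_rate = st$sample_rate_hz,
        ref_profile = c(st$velocity_coeff_ref, st$cap_ref),
        dist_profile = c(st$velocity_coeff_dist, st$cap_dist),
        seed = config$seed + 2000L + length(trials))
    }
  }

  # -- estimate + isolate -------------------------------------------------
  say("stage estimate/isolate")
  frfs <- list()      # frfs[[subject]][[condition]] = estimate_frfs() output
  pathways <- list()  # pathways[[subject]][[axis]] = list(PF, PB)
  frf_rows <- list()
  path_rows <- list()
  for (sid in names(trials)) {
    frfs[[sid]] <- list()
    for (pv in c(0, st$preview_ms)) {
      est <- estimate_frfs(trials[[sid]], grid, preview_ms = pv,
                           transient_s = st$transient_s)
      frfs[[sid]][[as.character(pv)]] <- est
      for (e in est) {
        df <- as.data.frame(e)
        df$preview_ms <- pv
        frf_rows[[length(frf_rows) + 1L]] <- df
      }
    }
    pathways[[sid]] <- list()
    for (ax in c("x", "y")) {
      est0 <- frfs[[sid]][["0"]]
      pf <- isolate_feedforward(est0[[paste0("H_YR_", ax)]],
                                est0[[paste0("H_YD_", ax)]])
      pb <- isolate_feedback(est0[[paste0("H_YD_", ax)]])
      pathways[[sid]][[ax]] <- list(PF = pf, PB = pb)
      path_rows[[length(path_rows) + 1L]] <- as.data.frame(pf)
      path_rows[[length(path_rows) + 1L]] <- as.data.frame(pb)
    }
  }
  utils::write.csv(do.call(rbind, frf_rows),
                   file.path(out_dir, "frf_closed_loop.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, path_rows),
                   file.path(out_dir, "frf_pathways.csv"), row.names = FALSE)

  # -- fit + cross-validate ----------------------------------------------
  say("stage fit")
  fitc <- config$fitting
  group_fits <- list()
  sel_structure <- list()
  for (gname in names(subjects)) {
    sids <- vapply(subjects[[gname]], `[[`, character(1), "subject_id")
    group_fits[[gname]] <- list()
    for (pw in c("PF", "PB")) {
      cands <- if (pw == "PF") fitc$candidates_ff else fitc$candidates_fb
      for (ax in c("x", "y")) {
        set <- lapply(sids, function(sid) pathways[[sid]][[ax]][[pw]])
        reports <- lapply(seq_along(cands), function(ci)
          cross_validate(set, cands[ci], n_restarts = fitc$n_restarts,
                         seed = config$seed + 3000L +
                           100L * ci + match(ax, c("x", "y"))))
        sel <- select_model(reports, delta = fitc$delta)
        group_fits[[gname]][[paste(pw, ax, sep = "_")]] <-
          list(reports = reports, selected = sel)
        sel_structure[[paste(gname, pw, sep = "_")]] <- sel$structure
      }
    }
  }
  jsonlite::write_json(
    lapply(group_fits, function(g) lapply(g, function(cell) {
      list(selected = cell$selected$structure,
           params = as.list(cell$selected$params),
           fd_error = cell$selected$fd_error,
           CVE = cell$selected$CVE,
           candidates = lapply(cell$reports, function(r)
             list(structure = r$structure, params = as.list(r$params),
                  fd_error = r$fd_error, CVE = r$CVE, VE = unname(r$VE))))
    })),
    file.path(out_dir, "fit_group.json"), auto_unbox = TRUE, digits = NA)

  # per-subject fits with each group's selected structure
  subject_rows <- list()
  subject_fits <- list()
  for (gname in names(subjects)) {
    sids <- vapply(subjects[[gname]], `[[`, character(1), "subject_id")
    for (sid in sids) {
      for (pw in c("PF", "PB")) {
        strc <- sel_structure[[paste(gname, pw, sep = "_")]]
        for (ax in c("x", "y")) {
          fit <- fit_model(pathways[[sid]][[ax]][[pw]], strc,
                           n_restarts = fitc$n_restarts,
                           seed = config$seed + 4000L +
                             length(subject_rows))
          subject_fits[[paste(sid, pw, ax, sep = "_")]] <- fit
          row <- data.frame(subject = sid, group = gname, pathway = pw,
                            axis = ax, structure = strc,
                            k = fit$params[["k"]], tau = fit$params[["tau"]],
                            a = if ("a" %in% names(fit$params))
                              fit$params[["a"]] else NA_real_,
                            fd_error = fit$fd_error,
                            stringsAsFactors = FALSE)
          subject_rows[[length(subject_rows) + 1L]] <- row
        }
      }
    }
  }
  subject_df <- do.call(rbind, subject_rows)
  utils::write.csv(subject_df, file.path(out_dir, "fit_subjects.csv"),
                   row.names = FALSE)

  # -- preview ------------------------------------------------------------
  preview <- NULL
  if (isTRUE(config$analysis$preview)) {
    say("stage preview")
    prev_rows <- list()
    preview <- list()
    for (sid in names(frfs)) {
      for (ax in c("x", "y")) {
        np <- frfs[[sid]][["0"]]
        pv <- frfs[[sid]][[as.character(st$preview_ms)]]
        two_np <- reference_controller_frfs(np[[paste0("H_YR_", ax)]],
                                            np[[paste0("H_YD_", ax)]])
        two_pv <- reference_controller_frfs(pv[[paste0("H_YR_", ax)]],
                                            pv[[paste0("H_YD_", ax)]])
        m <- extract_preview_filter(two_np, two_pv)
        preview[[paste(sid, ax, sep = "_")]] <- m
        prev_rows[[length(prev_rows) + 1L]] <- data.frame(
          freq_hz = m$frequencies, re = Re(m$M), im = Im(m$M),
          fb_ratio_re = Re(m$feedback_ratio),
          fb_ratio_im = Im(m$feedback_ratio),
          axis = ax, subject = sid, stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, prev_rows),
                     file.path(out_dir, "preview_filter.csv"),
                     row.names = FALSE)
  }

  # -- margins ------------------------------------------------------------
  margins <- NULL
  if (isTRUE(config$analysis$margins)) {
    say("stage margins")
    marg_rows <- list()
    margins <- list()
    for (sid in names(pathways)) {
      for (ax in c("x", "y")) {
        sm <- smooth_frf(pathways[[sid]][[ax]]$PB,
                         window = config$analysis$smoothing_window)
        m_frf <- stability_margins(sm)
        fit <- subject_fits[[paste(sid, "PB", ax, sep = "_")]]
        m_par <- stability_margins(fit$model)
        margins[[paste(sid, ax, sep = "_")]] <-
          list(frf = m_frf, parametric = m_par)
        for (meth in c("frf", "parametric")) {
          m <- if (meth == "frf") m_frf else m_par
          marg_rows[[length(marg_rows) + 1L]] <- data.frame(
            subject = sid, axis = ax, method = meth,
            gain_margin = m$gain_margin, phase_margin = m$phase_margin,
            gc_hz = m$gain_crossover_hz, pc_hz = m$phase_crossover_hz,
            window = config$analysis$smoothing_window,
            stringsAsFactors = FALSE)
        }
      }
    }
    utils::write.csv(do.call(rbind, marg_rows),
                     file.path(out_dir, "margins.csv"), row.names = FALSE)
  }

  # -- tracking error -----------------------------------------------------
  say("stage tracking error")
  te_rows <- list()
  for (sid in names(trials)) {
    for (pv in c(0, st$preview_ms)) {
      trs <- Filter(function(tr) tr$preview_ms == pv, trials[[sid]])
      mse <- mean(vapply(trs, tracking_error, numeric(1),
                         transient_s = st$transient_s))
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        subject = sid, preview_ms = pv, mse_cm2 = mse,
        n_trials = length(trs), stringsAsFactors = FALSE)
    }
  }
  tracking <- do.call(rbind, te_rows)
  utils::write.csv(tracking, file.path(out_dir, "tracking_error.csv"),
                   row.names = FALSE)

  # -- counterfactual gain swap ------------------------------------------
  gain_swap <- NULL
  if (isTRUE(config$analysis$gain_swap)) {
    say("stage gain swap")
    from <- config$analysis$gain_swap_from
    to <- config$analysis$gain_swap_to
    tmpl <- build_group_subjects(from, co$groups[[from]], 1L, 0, 0, grid,
                                 with_preview = FALSE)[[1]]
    gain_swap <- gain_swap_experiment(
      tmpl, co$groups[[to]]$fb$k, grid, groups, plan,
      duration = st$duration_s, sample_rate = st$sample_rate_hz,
      transient_s = st$transient_s, seed = config$seed + 5000L)
    jsonlite::write_json(
      list(from_group = from, to_group = to,
           original_gain = co$groups[[from]]$fb$k,
           swapped_gain = co$groups[[to]]$fb$k,
           mse_original = gain_swap$mse_original,
           mse_swapped = gain_swap$mse_swapped,
           margins_original = unclass(gain_swap$margins_original),
           margins_swapped = unclass(gain_swap$margins_swapped)),
      file.path(out_dir, "gain_swap.json"), auto_unbox = TRUE, digits = NA)
  }

  say("done")
  invisible(list(out_dir = out_dir, grid = grid, plan = plan,
                 subjects = subjects, frfs = frfs, pathways = pathways,
                 group_fits = group_fits, subject_fits = subject_fits,
                 subject_table = subject_df, preview = preview,
                 margins = margins, tracking = tracking,
                 gain_swap = gain_swap))
}

#' Summary tables from a completed pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and returns
#' the tables that group-level statistics consume: per-subject pathway
#' parameters, the feedforward-minus-feedback delay difference per subject,
#' tracking error by preview condition, and stability margins.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Named list of data frames: `parameters`, `delay_difference`,
#'   `tracking_error`, `margins` (the latter `NULL` when the stage was
#'   disabled).
#' @export
summarize_run <- function(run_dir) {
  need <- c("fit_subjects.csv", "tracking_error.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0L)
    stop("missing artifacts in ", run_dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  fits <- utils::read.csv(file.path(run_dir, "fit_subjects.csv"),
                          stringsAsFactors = FALSE)
  te <- utils::read.csv(file.path(run_dir, "tracking_error.csv"),
                        stringsAsFactors = FALSE)
  # per-subject parameters, axes averaged
  agg <- stats::aggregate(cbind(k, tau) ~ subject + group + pathway +
                            structure, data = fits, FUN = mean)
  if (any(!is.na(fits$a))) {
    agg_a <- stats::aggregate(a ~ subject + group + pathway, data = fits,
                              FUN = mean, na.action = stats::na.omit)
    agg <- merge(agg, agg_a, all.x = TRUE)
  }
  wide <- merge(
    agg[agg$pathway == "PF", c("subject", "group", "tau")],
    agg[agg$pathway == "PB", c("subject", "tau")],
    by = "subject", suffixes = c("_ff", "_fb"))
  wide$delay_diff_s <- wide$tau_ff - wide$tau_fb
  margins <- NULL
  if (file.exists(file.path(run_dir, "margins.csv")))
    margins <- utils::read.csv(file.path(run_dir, "margins.csv"),
                               stringsAsFactors = FALSE)
  list(parameters = agg,
       delay_difference = wide[, c("subject", "group", "tau_ff", "tau_fb",
                                   "delay_diff_s")],
       tracking_error = te,
       margins = margins)
}
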