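#' Per-cohort analysis helpers
#'
#' Apply the single-cell analyses across a simulated (or deserialized)
#' cohort and return one row per cell.
#'
#' @param recs List of `cav_recording` objects, one per cell.
#' @return Data frame with one row per cell.
#' @name cohort_analysis
NULL

cell_meta <- function(rec) {
  data.frame(cell_id = rec$cell_id, construct = rec$construct_label,
             replicate_batch = rec$replicate_batch,
             hours_post_transfection = rec$hours_post_transfection,
             stringsAsFactors = FALSE)
}

#' @rdname cohort_analysis
#' @export
analyze_density <- function(recs) {
  do.call(rbind, lapply(recs, current_density))
}

#' @rdname cohort_analysis
#' @export
analyze_gv <- function(recs) {
  do.call(rbind, lapply(recs, function(rec) {
    fit <- fit_boltzmann(build_gv(rec), "activation")
    cbind(cell_meta(rec),
          data.frame(v05 = fit$v05, slope = fit$slope,
                     converged = fit$converged))
  }))
}

#' @rdname cohort_analysis
#' @export
analyze_ssi <- function(recs) {
  do.call(rbind, lapply(recs, function(rec) {
    fit <- fit_boltzmann(build_availability(rec), "inactivation")
    cbind(cell_meta(rec),
          data.frame(v05 = fit$v05, slope = fit$slope,
                     converged = fit$converged))
  }))
}

#' @rdname cohort_analysis
#' @export
analyze_kinetics <- function(recs) {
  do.call(rbind, lapply(recs, function(rec) {
    fit <- fit_kinetics(rec$sweeps[[1]])
    cbind(cell_meta(rec),
          data.frame(tau_act = fit$tau_act, tau_inact = fit$tau_inact,
                     amplitude_c = fit$amplitude_c,
                     converged = fit$converged))
  }))
}

#' @rdname cohort_analysis
#' @param pairs List of `list(ref =, test =)` pairs from
#'   [generate_ph_pairs()].
#' @export
analyze_ph <- function(pairs) {
  do.call(rbind, lapply(pairs, function(pr) ph_ratios(pr$ref, pr$test)))
}

# Fan a master seed out into per-(construct, protocol) sub-seeds in a fixed
# order so each cohort is independently reproducible.
fan_out_seeds <- function(master_seed, constructs,
                          slots = c("iv", "ssi", "kinetics", "density",
                                    "ph6.5", "ph8.0")) {
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(constructs) * length(slots)),
                  nrow = length(constructs),
                  dimnames = list(constructs, slots))
  seeds
}

#' Default configuration for the end-to-end pipeline
#'
#' @param constructs Construct labels (subset of the fixture panel).
#' @param n_cells Cells per construct and protocol.
#' @param seed Master seed; fanned out into per-cohort sub-seeds.
#' @param noise_sd Recording noise sd, pA.
#' @param variability See [cohort_variability()].
#' @param analyses Which analyses to run.
#' @return Configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(constructs = names(cav33_fixtures()),
                            n_cells = 12, seed = 1, noise_sd = 5,
                            variability = cohort_variability(),
                            analyses = c("density", "gv", "ssi", "kinetics",
                                         "window", "ph")) {
  list(constructs = constructs, n_cells = n_cells, seed = seed,
       noise_sd = noise_sd, variability = variability, analyses = analyses)
}

#' Run the end-to-end simulate / analyze / compare pipeline
#'
#' For every requested construct: simulate cohorts under the relevant
#' protocols, run the per-cell analyses, summarize with replicate-aware
#' cohort statistics, compare each variant against WT with unpaired
#' Student's t-tests, and compute window-current areas and ratios from the
#' cohort-mean Boltzmann parameters. Per-construct failures are isolated
#' and reported in the summary, not fatal. With a fixed master seed the
#' emitted JSON summary is byte-identical across runs.
#'
#' @param config List from [pipeline_config()] or a path to a YAML file
#'   with the same fields.
#' @param out_dir Optional output directory; when given, writes
#'   `density.tsv`, `gv_fits.tsv`, `ssi_fits.tsv`, `kinetics.tsv`,
#'   `window.tsv`, `ph_ratios.tsv`, `ph_tests.tsv` and `summary.json`.
#' @return The summary list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.list(config$variability))
    config$variability <- do.call(cohort_variability, config$variability)

  fixtures <- cav33_fixtures()
  unknown <- setdiff(config$constructs, names(fixtures))
  if (length(unknown) > 0)
    stop("unknown construct(s): ", paste(unknown, collapse = ", "))
  seeds <- fan_out_seeds(config$seed, config$constructs)

  tables <- list(density = NULL, gv = NULL, ssi = NULL, kinetics = NULL,
                 ph = NULL)
  errors <- list()
  for (cs in config$constructs) {
    p <- fixtures[[cs]]
    res <- tryCatch({
      out <- list()
      if ("density" %in% config$analyses)
        out$density <- analyze_density(generate_cohort(
          p, protocol_density(), config$n_cells, config$variability,
          config$noise_sd, seed = seeds[cs, "density"]))
      if (any(c("gv", "window") %in% config$analyses))
        out$gv <- analyze_gv(generate_cohort(
          p, protocol_iv(), config$n_cells, config$variability,
          config$noise_sd, seed = seeds[cs, "iv"]))
      if (any(c("ssi", "window") %in% config$analyses))
        out$ssi <- analyze_ssi(generate_cohort(
          p, protocol_ssi(), config$n_cells, config$variability,
          config$noise_sd, seed = seeds[cs, "ssi"]))
      if ("kinetics" %in% config$analyses)
        out$kinetics <- analyze_kinetics(generate_cohort(
          p, protocol_kinetics(), config$n_cells, config$variability,
          config$noise_sd, seed = seeds[cs, "kinetics"]))
      if ("ph" %in% config$analyses) {
        phs <- setdiff(names(p$ph_conductance_factor), "7.4")
        out$ph <- do.call(rbind, lapply(phs, function(ph) {
          analyze_ph(generate_ph_pairs(
            p, as.numeric(ph), config$n_cells, config$variability,
            config$noise_sd,
            seed = seeds[cs, paste0("ph", ph)]))
        }))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cs]] <- conditionMessage(res)
      next
    }
    for (nm in names(res))
      if (!is.null(res[[nm]])) tables[[nm]] <- rbind(tables[[nm]], res[[nm]])
  }

  summary <- summarize_pipeline(tables, config)
  summary$errors <- errors
  summary$seed <- config$seed

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) if (!is.null(d))
      utils::write.table(d, file.path(out_dir, f), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    wr(tables$density, "density.tsv")
    wr(tables$gv, "gv_fits.tsv")
    wr(tables$ssi, "ssi_fits.tsv")
    wr(tables$kinetics, "kinetics.tsv")
    wr(tables$ph, "ph_ratios.tsv")
    wr(summary$window_table, "window.tsv")
    wr(summary$ph_tests_table, "ph_tests.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(summary))
  }
  summary
}

# Cohort summaries, WT comparisons, window areas from cohort-mean fits,
# and pH paired tests.
summarize_pipeline <- function(tables, config) {
  schema_version <- "1"
  constructs <- config$constructs
  per_construct <- list()

  summarize_param <- function(df, value_col, param_name) {
    out <- lapply(split(df, df$construct), function(d) {
      s <- superplot_summary(d[[value_col]], d$replicate_batch,
                             d$hours_post_transfection,
                             parameter_name = param_name,
                             construct_label = d$construct[1])
      list(mean = s$grand_mean, sem = s$sem, n = s$n_cells)
    })
    out[intersect(constructs, names(out))]  # keep the requested order
  }

  params <- list()
  if (!is.null(tables$density))
    params$density <- summarize_param(tables$density, "density", "density")
  if (!is.null(tables$gv)) {
    params$act_v05 <- summarize_param(tables$gv, "v05", "act_v05")
    params$act_slope <- summarize_param(tables$gv, "slope", "act_slope")
  }
  if (!is.null(tables$ssi)) {
    params$inact_v05 <- summarize_param(tables$ssi, "v05", "inact_v05")
    params$inact_slope <- summarize_param(tables$ssi, "slope", "inact_slope")
  }
  if (!is.null(tables$kinetics)) {
    params$tau_act <- summarize_param(tables$kinetics, "tau_act", "tau_act")
    params$tau_inact <- summarize_param(tables$kinetics, "tau_inact",
                                        "tau_inact")
  }

  # unpaired WT-vs-variant comparisons per parameter
  comparisons <- list()
  src <- list(density = c("density", "density"),
              act_v05 = c("gv", "v05"), act_slope = c("gv", "slope"),
              inact_v05 = c("ssi", "v05"), inact_slope = c("ssi", "slope"),
              tau_act = c("kinetics", "tau_act"),
              tau_inact = c("kinetics", "tau_inact"))
  if ("WT" %in% constructs) {
    for (pn in names(src)) {
      tb <- tables[[src[[pn]][1]]]
      if (is.null(tb)) next
      col <- src[[pn]][2]
      wt <- tb[[col]][tb$construct == "WT"]
      for (cs in setdiff(constructs, "WT")) {
        gv <- tb[[col]][tb$construct == cs]
        if (length(wt) < 2 || length(gv) < 2) next
        cmp <- suppressWarnings(
          unpaired_t(wt, gv, parameter_name = pn,
                     label_a = "WT", label_b = cs))
        comparisons[[paste(pn, cs, sep = ".")]] <-
          list(parameter = pn, variant = cs, t = cmp$t_statistic,
               p = cmp$p_value, tier = cmp$significance_tier)
      }
    }
  }

  # window areas from cohort-mean Boltzmann parameters
  window_table <- NULL
  if ("window" %in% config$analyses && !is.null(tables$gv) &&
      !is.null(tables$ssi)) {
    wins <- lapply(constructs, function(cs) {
      g <- tables$gv[tables$gv$construct == cs & tables$gv$converged, ]
      s <- tables$ssi[tables$ssi$construct == cs & tables$ssi$converged, ]
      if (nrow(g) == 0 || nrow(s) == 0) return(NULL)
      window_area(list(v05 = mean(g$v05), slope = mean(g$slope)),
                  list(v05 = mean(s$v05), slope = mean(s$slope)))
    })
    names(wins) <- constructs
    ok <- !vapply(wins, is.null, logical(1))
    ref <- if ("WT" %in% constructs && ok[["WT"]]) wins[["WT"]] else NULL
    window_table <- do.call(rbind, lapply(constructs[ok], function(cs) {
      w <- wins[[cs]]
      data.frame(construct = cs, area = w$area,
                 ratio_vs_WT = if (!is.null(ref)) window_ratio(w, ref)
                               else NA_real_,
                 v_low = w$v_range[1], v_high = w$v_range[2],
                 grid_step = w$grid_step, v_peak = w$v_peak)
    }))
  }

  # paired pH tests per construct x pH, plus across-construct ANOVA/Tukey
  ph_tests_table <- NULL
  ph_anova <- NULL
  if (!is.null(tables$ph)) {
    ph_tests_table <- do.call(rbind, lapply(
      split(tables$ph, list(tables$ph$construct, tables$ph$ph_test),
            drop = TRUE),
      function(d) {
        pt_peak <- tryCatch(paired_test(d$peak_ratio), error = function(e) NULL)
        pt_tau <- tryCatch(paired_test(d$tau_ratio), error = function(e) NULL)
        data.frame(construct = d$construct[1], ph_test = d$ph_test[1],
                   n = nrow(d),
                   mean_peak_ratio = mean(d$peak_ratio),
                   p_peak = if (is.null(pt_peak)) NA_real_ else pt_peak$p_value,
                   mean_tau_ratio = mean(d$tau_ratio),
                   p_tau = if (is.null(pt_tau)) NA_real_ else pt_tau$p_value)
      }))
    ph_anova <- lapply(split(tables$ph, tables$ph$ph_test), function(d) {
      if (length(unique(d$construct)) < 2) return(NULL)
      at <- tryCatch(across_construct_test(d$peak_ratio, d$construct),
                     error = function(e) NULL)
      if (is.null(at)) return(NULL)
      list(f = at$f, p = at$p_value, pairwise = at$pairwise)
    })
  }

  list(schema_version = schema_version,
       constructs = constructs, n_cells = config$n_cells,
       parameters = params, comparisons = comparisons,
       window_table = window_table, ph_tests_table = ph_tests_table,
       ph_anova = ph_anova)
}
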