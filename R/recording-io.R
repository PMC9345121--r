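#' Serialize recordings to disk
#'
#' A recording is written as two plain-text files in
#' `<dir>/<construct>/`: `<cell_id>.json` with the cell metadata and
#' protocol, and `<cell_id>.csv` with the samples in long form
#' (`time_ms, sweep_index, command_mV, current_pA`).
#'
#' @param rec A `cav_recording`.
#' @param dir Cohort directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_recording <- function(rec, dir) {
  sub <- file.path(dir, rec$construct_label)
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(sub, rec$cell_id)
  header <- list(
    cell_id = rec$cell_id, construct_label = rec$construct_label,
    capacitance = rec$capacitance, ph = as.numeric(rec$ph),
    replicate_batch = rec$replicate_batch,
    hours_post_transfection = rec$hours_post_transfection,
    rng_seed = rec$rng_seed,
    params = rec$params[c("gmax", "erev", "act_v05", "act_slope",
                          "inact_v05", "inact_slope", "tau_act",
                          "tau_inact")],
    protocol = list(name = rec$protocol$name,
                    holding = rec$protocol$holding,
                    segments = rec$protocol$segments,
                    sweep_voltages = rec$protocol$sweep_voltages,
                    test_segment = rec$protocol$test_segment,
                    inter_sweep_interval = rec$protocol$inter_sweep_interval,
                    sample_interval = rec$protocol$sample_interval))
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  tabs <- lapply(seq_along(rec$sweeps), function(i) {
    sw <- rec$sweeps[[i]]
    data.frame(time_ms = sw$time, sweep_index = i, command_mV = sw$command,
               current_pA = sw$current)
  })
  utils::write.csv(do.call(rbind, tabs), paste0(base, ".csv"),
                   row.names = FALSE)
  invisible(c(paste0(base, ".json"), paste0(base, ".csv")))
}

#' Read a serialized recording
#'
#' @param base Path to the recording without extension (the common stem of
#'   the `.json`/`.csv` pair).
#' @return A `cav_recording`.
#' @export
read_recording <- function(base) {
  header <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  samples <- utils::read.csv(paste0(base, ".csv"))
  pr <- header$protocol
  protocol <- new_protocol(pr$name,
                           as.data.frame(pr$segments),
                           pr$sweep_voltages, pr$test_segment,
                           pr$inter_sweep_interval, pr$sample_interval,
                           holding = pr$holding)
  pp <- header$params
  params <- gating_params(header$construct_label, gmax = pp$gmax,
                          erev = pp$erev, act_v05 = pp$act_v05,
                          act_slope = pp$act_slope,
                          inact_v05 = pp$inact_v05,
                          inact_slope = pp$inact_slope,
                          tau_act = pp$tau_act, tau_inact = pp$tau_inact)
  sweeps <- lapply(split(samples, samples$sweep_index), function(d) {
    sw <- data.frame(time = d$time_ms, command = d$command_mV,
                     current = d$current_pA)
    # reconstruct segment boundaries from the command trace
    seg_idx <- cumsum(c(TRUE, diff(d$command_mV) != 0))
    starts <- vapply(split(d$time_ms, seg_idx), min, numeric(1))
    ends <- vapply(split(d$time_ms, seg_idx), max, numeric(1))
    volts <- vapply(split(d$command_mV, seg_idx), function(v) v[1],
                    numeric(1))
    attr(sw, "segments") <- data.frame(
      duration = ends - starts + protocol$sample_interval,
      voltage = volts, start = starts, end = ends)
    attr(sw, "sample_interval") <- protocol$sample_interval
    class(sw) <- c("cav_sweep", "data.frame")
    sw
  })
  structure(list(cell_id = header$cell_id,
                 construct_label = header$construct_label,
                 capacitance = header$capacitance, ph = header$ph,
                 sweeps = sweeps[order(as.integer(names(sweeps)))],
                 replicate_batch = header$replicate_batch,
                 hours_post_transfection = header$hours_post_transfection,
                 protocol = protocol, params = params,
                 rng_seed = header$rng_seed),
            class = "cav_recording")
}

#' @rdname write_recording
#' @param recs List of recordings.
#' @export
write_cohort <- function(recs, dir) {
  invisible(unlist(lapply(recs, write_recording, dir = dir)))
}

#' @rdname read_recording
#' @param dir Cohort directory as written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  jsons <- list.files(dir, pattern = "\\.json$", recursive = TRUE,
                      full.names = TRUE)
  lapply(sub("\\.json$", "", jsons), read_recording)
}
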