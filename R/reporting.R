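#' Resolve a protocol run configuration
#'
#' Fills in the documented defaults for one of the named simulation
#' campaigns.  The campaigns differ only in the fields that define
#' them; e.g. the `fig8` configuration is the `fig7` configuration
#' with the sinusoid flag turned off.
#'
#' @param protocol One of `"fig2"`, `"fig3"`, `"fig6"`, `"fig7"`,
#'   `"fig8"`, `"synth"`.
#' @param seed Master seed. Default 1.
#' @param ... Field overrides (e.g. `n_trials`, `grid_n`, `dt`).
#' @return A fully resolved named list of class `run_config`.
#' @export
resolve_config <- function(protocol, seed = 1, ...) {
  protocol <- match.arg(protocol,
                        c("fig2", "fig3", "fig6", "fig7", "fig8", "synth"))
  cfg <- switch(protocol,
    fig2 = list(protocol = "fig2", seed = seed, n_trials = 4,
                Io = 0.32, sigma_noise = 0.001, dt = 0.1,
                exemplars = data.frame(Js = c(0.17, 0.33, 0.65),
                                       Jo = c(0.01, 0.33, 0.33))),
    fig3 = list(protocol = "fig3", seed = seed, n_trials = 4,
                grid_n = 10, Io = 0.32, sigma_noise = 0.001, dt = 0.1),
    fig6 = list(protocol = "fig6", seed = seed, n_trials = 4,
                grid_n = 10, Io = 0.33, sigma_noise = 0.001,
                sine_amp = 0.05, sine_freq = 2, duration = 5000,
                dt = 0.1),
    fig7 = list(protocol = "fig7", seed = seed, n_trials = 20,
                grid_n = 10, Io = 0.32, sigma_noise = 0.02,
                sine_amp = 0.05, sine_freq = 2, with_sine = TRUE,
                isi = 400, dt = 0.1),
    fig8 = list(protocol = "fig8", seed = seed, n_trials = 20,
                grid_n = 10, Io = 0.32, sigma_noise = 0.02,
                sine_amp = 0.05, sine_freq = 2, with_sine = FALSE,
                isi = 400, dt = 0.1),
    synth = list(protocol = "synth", seed = seed, n_sessions = 20))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("resolve_config: unknown field(s) for protocol ", protocol,
         ": ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

# Full-precision CSV: numbers are formatted with 17 significant digits
# so that write -> read round-trips bit-exactly.
write_table_csv <- function(tab, path) {
  out <- tab
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run a named simulation campaign and write its outputs
#'
#' Executes the campaign described by a [resolve_config()] object and
#' writes (a) the per-cell (or per-session) metric table as a CSV with
#' a header row, and (b) a JSON run manifest holding the fully resolved
#' configuration, seed, and package version, sufficient to reproduce
#' the run.
#'
#' @param config A `run_config` (or the arguments of
#'   [resolve_config()] via `protocol` and `...`).
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with `table` (the result data.frame),
#'   `csv`, and `manifest` paths.
#' @export
run_protocol <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("run_protocol: cannot create output directory ", out_dir)
  probe <- file.path(out_dir, ".write-test")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("run_protocol: output directory not writable: ", out_dir)
  unlink(probe)

  log_line("protocol ", config$protocol, " starting (seed ",
           config$seed, ")")
  tab <- switch(config$protocol,
    fig2 = {
      ex <- config$exemplars
      rows <- lapply(seq_len(nrow(ex)), function(r) {
        res <- run_coincident_protocol(ex$Js[r], ex$Jo[r],
                                       n_trials = config$n_trials,
                                       seed = config$seed,
                                       Io = config$Io,
                                       sigma_noise = config$sigma_noise,
                                       dt = config$dt)
        data.frame(Js = ex$Js[r], Jo = ex$Jo[r], regime = res$regime,
                   delta_s1 = res$delta_s1,
                   crossing = ifelse(is.na(res$crossing), -1L,
                                     res$crossing))
      })
      do.call(rbind, rows)
    },
    fig3 = {
      grid <- full_grid(config$grid_n)
      cells <- expand.grid(i = seq_along(grid$Js_values),
                           j = seq_along(grid$Jo_values))
      rows <- lapply(seq_len(nrow(cells)), function(ci) {
        i <- cells$i[ci]; j <- cells$j[ci]
        res <- run_coincident_protocol(
          grid$Js_values[i], grid$Jo_values[j],
          n_trials = config$n_trials,
          seed = derive_trial_seed(config$seed, i, j, 1),
          Io = config$Io, sigma_noise = config$sigma_noise,
          dt = config$dt)
        data.frame(Js = grid$Js_values[i], Jo = grid$Jo_values[j],
                   delta_s1 = res$delta_s1,
                   crossing = ifelse(is.na(res$crossing), -1L,
                                     res$crossing),
                   regime = res$regime)
      })
      do.call(rbind, rows)
    },
    fig6 = run_slow_osc_sweep(transient_grid(config$grid_n),
                              seed = config$seed, Io = config$Io,
                              sigma_noise = config$sigma_noise,
                              sine_amp = config$sine_amp,
                              sine_freq = config$sine_freq,
                              n_trials = config$n_trials,
                              duration = config$duration,
                              dt = config$dt),
    fig7 = ,
    fig8 = run_sensory_fidelity_sweep(
      transient_grid(config$grid_n), n_trials = config$n_trials,
      seed = config$seed, with_sine = config$with_sine,
      isi = config$isi, Io = config$Io,
      sigma_noise = config$sigma_noise, sine_amp = config$sine_amp,
      sine_freq = config$sine_freq, dt = config$dt)$table,
    synth = {
      rows <- lapply(seq_len(config$n_sessions), function(s) {
        pair <- session_pair(seed = config$seed + 2 * s)
        m_c <- lfp_session_metrics(gen_lfp_session(pair$control))
        m_m <- lfp_session_metrics(gen_lfp_session(pair$modulated))
        data.frame(session = s,
                   as.list(setNames(m_c, paste0("ctl_", names(m_c)))),
                   as.list(setNames(m_m, paste0("mod_", names(m_m)))))
      })
      do.call(rbind, rows)
    })

  csv <- file.path(out_dir, paste0(config$protocol, "_metrics.csv"))
  write_table_csv(tab, csv)
  manifest <- file.path(out_dir, paste0(config$protocol,
                                        "_manifest.json"))
  jsonlite::write_json(
    list(config = unclass(config),
         package_version =
           as.character(utils::packageVersion("mfcircuit"))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("protocol ", config$protocol, " done: ", csv)
  invisible(list(table = tab, csv = csv, manifest = manifest))
}
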