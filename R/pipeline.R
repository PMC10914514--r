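# End-to-end orchestration: simulate the burst-and-coast reference, train the
# interaction network on it, roll it out in closed loop, compute both
# observable reports and the Hellinger comparison, and write a JSON (+ HTML)
# summary. A plain-text config file (INI-style sections of key = value)
# controls every stage; one global seed fans out to fixed per-stage seeds so
# stages can be re-run in isolation.

pipeline_defaults <- function() {
  list(
    preprocess = list(v_min = 3.5, max_step = 5.25, max_gap = 12, target_dt = 0.12),
    abc = list(duration = 1200, dt = 0.12, tau_mean = 0.5, tau_shape = 2,
               l_mean = 7, l_shape = 2, gamma = 0.35,
               wall_amp = 0.45, wall_decay = 7, wall_asym = 0.04,
               att_amp = 0.7, att_dist = 7, ali_amp = 1.0, ali_decay = 20,
               glide = "exponential", tank_radius = 25, body_length = 3.5),
    dli = list(lstm1 = 32, dense1 = 24, dense2 = 16, lstm2 = 16,
               head1 = 16, head2 = 8, history = 5),
    train = list(epochs = 8, batch = 512, lr = 1e-3, lr_decay = 0.95,
                 augment = TRUE),
    rollout = list(steps = 0, rejection = TRUE, cap = 100),
    observables = list(max_lag = 30, policy = "default")
  )
}

#' Read a pipeline run configuration
#'
#' INI-style plain text: `[section]` headers and `key = value` lines; `#`
#' starts a comment. Values are parsed as numbers or logicals where possible.
#' Unknown sections or keys are errors (configs are validated against the
#' schema of [run_pipeline()]'s defaults).
#'
#' @param path config file path; `NULL` returns the defaults.
#' @return nested named list of sections.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(cfg))
        stop(sprintf("unknown config section '[%s]' (line %d)", section, i))
      next
    }
    if (is.null(section)) stop(sprintf("key outside any section at line %d", i))
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop(sprintf("malformed line %d: '%s'", i, lines[i]))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg[[section]]))
      stop(sprintf("unknown key '%s' in section '[%s]' (line %d)", key, section, i))
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <-
      if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  cfg
}

# deterministic per-stage seeds derived from the global seed
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(abc = base * 7L + 1L, train = base * 7L + 2L, rollout = base * 7L + 3L,
       fixtures = base * 7L + 4L)
}

#' Run the full simulate-train-rollout-compare pipeline
#'
#' Stages: (1) burst-and-coast reference simulation; (2) network training on
#' the reference; (3) closed-loop rollout of the trained model for the same
#' number of timesteps; (4) observable reports for both datasets under one
#' binning policy; (5) Hellinger comparison. Artifacts (trajectories, weights
#' sidecar, reports, summary JSON and HTML) are written under `out_dir`; the
#' summary records the config and seed so the run is replayable.
#'
#' @param config a config list from [read_run_config()], or a path.
#' @param seed global seed.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return invisibly, the summary list (reference/model Hellinger report and
#'   stage metadata).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = tempfile("pairswim_run"),
                         verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) pipeline_defaults()
         else config
  seeds <- stage_seeds(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[abc] simulating reference (%g s)", cfg$abc$duration)
  ab <- cfg$abc
  params <- abc_model(tau_mean = ab$tau_mean, tau_shape = ab$tau_shape,
                      l_mean = ab$l_mean, l_shape = ab$l_shape, gamma = ab$gamma,
                      wall_amp = ab$wall_amp, wall_decay = ab$wall_decay,
                      wall_asym = ab$wall_asym, att_amp = ab$att_amp,
                      att_dist = ab$att_dist, ali_amp = ab$ali_amp,
                      ali_decay = ab$ali_decay, glide = ab$glide,
                      tank_radius = ab$tank_radius, body_length = ab$body_length)
  ref <- simulate_abc(params, duration = ab$duration, dt = ab$dt, seed = seeds$abc)
  write_trajectories(ref, file.path(out_dir, "abc_reference.csv"))

  say("[train] fitting the interaction network")
  net <- dli_network_config(lstm1 = cfg$dli$lstm1, dense1 = cfg$dli$dense1,
                            dense2 = cfg$dli$dense2, lstm2 = cfg$dli$lstm2,
                            head1 = cfg$dli$head1, head2 = cfg$dli$head2,
                            history = cfg$dli$history)
  tc <- dli_train_config(epochs = cfg$train$epochs, batch = cfg$train$batch,
                         lr = cfg$train$lr, lr_decay = cfg$train$lr_decay,
                         augment = cfg$train$augment)
  model <- fit_dli(ref, net = net, train = tc, seed = seeds$train)
  save_dli(model, file.path(out_dir, "dli_weights"))

  steps <- if (cfg$rollout$steps > 0) as.integer(cfg$rollout$steps) else length(ref$t)
  say("[rollout] closed-loop rollout (%d steps)", steps)
  roll <- dli_rollout(model, steps = steps, init = ref,
                      rejection = isTRUE(cfg$rollout$rejection) || cfg$rollout$rejection == 1,
                      cap = cfg$rollout$cap, seed = seeds$rollout)
  write_trajectories(roll, file.path(out_dir, "dli_rollout.csv"))

  say("[observables] building reports and Hellinger comparison")
  policy <- binning_policy(cfg$observables$policy, tank_radius = ab$tank_radius)
  rep_ref <- observable_report(ref, policy, max_lag = cfg$observables$max_lag)
  rep_mod <- observable_report(roll, policy, max_lag = cfg$observables$max_lag)
  hd <- compare_observables(rep_ref, rep_mod)
  observables_to_json(rep_ref, file.path(out_dir, "observables_abc.json"))
  observables_to_json(rep_mod, file.path(out_dir, "observables_dli.json"))

  summary <- list(
    seed = seed, stage_seeds = seeds, config = cfg,
    n_steps = list(reference = length(ref$t), rollout = length(roll$t)),
    final_val_nll = utils::tail(model$curves$validation, 1),
    hellinger = as.list(hd$hd)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_summary_html(summary, file.path(out_dir, "summary.html"))
  say("[done] summary written to %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}

# minimal static HTML rendering of the run summary
write_summary_html <- function(summary, path) {
  rows <- paste0(sprintf("<tr><td>%s</td><td>%.4f</td></tr>",
                         names(summary$hellinger),
                         as.numeric(unlist(summary$hellinger))), collapse = "\n")
  html <- paste0(
    "<html><head><title>pairswim run</title></head><body>",
    "<h1>Model-vs-reference comparison</h1>",
    sprintf("<p>seed %s; reference %d steps; rollout %d steps; final validation NLL %.4f</p>",
            summary$seed, summary$n_steps$reference, summary$n_steps$rollout,
            summary$final_val_nll),
    "<table border='1'><tr><th>observable</th><th>Hellinger distance</th></tr>",
    rows, "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Save / load fitted network weights
#'
#' The weights go to a plain-text `.csv.gz`-free representation: one `dput`
#' file per run is avoided in favour of a JSON sidecar with the configs and a
#' flat text matrix dump, so checkpoints survive text-only archiving.
#'
#' @param model a fitted `"dli"`.
#' @param stem output path stem; writes `<stem>.json` (configs, norms) and
#'   `<stem>.txt` (weights).
#' @return `stem`, invisibly.
#' @export
save_dli <- function(model, stem) {
  sidecar <- list(net = unclass(model$net), train = unclass(model$train),
                  norm = model$norm, body_length = model$body_length,
                  target_scale = model$target_scale,
                  n_samples = model$n_samples,
                  curves = model$curves, test_loss = model$test_loss)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  con <- file(paste0(stem, ".txt"), "w")
  on.exit(close(con))
  for (nm in names(model$weights)) {
    w <- model$weights[[nm]]
    writeLines(sprintf("# %s %d %d", nm, nrow(w), ncol(w)), con)
    utils::write.table(w, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(stem)
}

#' @rdname save_dli
#' @export
load_dli <- function(stem) {
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(stem, ".txt"))
  heads <- grep("^# ", lines)
  weights <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^# ", "", lines[heads[i]]), " ")[[1]]
    nr <- as.integer(hd[2]); nc <- as.integer(hd[3])
    block <- lines[(heads[i] + 1L):(heads[i] + nr)]
    weights[[hd[1]]] <- matrix(as.numeric(unlist(strsplit(block, " +"))),
                               nr, nc, byrow = TRUE)
  }
  structure(list(
    weights = weights,
    net = do.call(dli_network_config, sidecar$net[setdiff(names(sidecar$net), "output")]),
    train = do.call(dli_train_config, sidecar$train),
    curves = sidecar$curves, test_loss = sidecar$test_loss,
    target_scale = sidecar$target_scale,
    norm = sidecar$norm, n_samples = sidecar$n_samples,
    body_length = sidecar$body_length, call = quote(load_dli())
  ), class = "dli")
}
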