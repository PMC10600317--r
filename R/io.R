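#' Tabular input/output with schema validation
#'
#' All pipeline artifacts are tab-separated UTF-8 text with a comment
#' header carrying the package version and a hash of the generating
#' configuration, so every artifact is traceable to the run that produced
#' it.
#'
#' @name cli-io
NULL

TAP_LOG_COLUMNS <- c(
  "participant", "rhythm_id", "perf_num", "repetition",
  "start_cue", "t_ms", "velocity"
)

# 32-bit FNV-1a hash of the deparsed object (16-bit split keeps the modular
# multiply exact in doubles); 8 hex digits.
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256 # xor only touches the low byte (b < 256)
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a pipeline table
#'
#' Writes a data.frame as TSV with a `#` header line embedding the package
#' version and a configuration hash.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param config object whose hash is embedded (default `NULL`).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, config = NULL) {
  header <- sprintf(
    "# taprhythm %s config %s",
    as.character(utils::packageVersion("taprhythm")),
    if (is.null(config)) "none" else config_hash(config)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(table, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read and validate a tap log
#'
#' Reads a tap-log TSV and enforces the schema: all columns present, times
#' integer milliseconds within the performance, velocities 7-bit MIDI
#' (1-127). Violations are rejected with a row-level report.
#'
#' @param path TSV path (comment lines starting with `#` are skipped).
#' @param max_t_ms largest admissible tap time (default `30500` ms).
#' @return the validated data.frame.
#' @export
read_tap_log <- function(path, max_t_ms = 30500) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(TAP_LOG_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    stop("tap log missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad_vel <- which(tab$velocity < 1 | tab$velocity > 127)
  bad_t <- which(tab$t_ms < -117 | tab$t_ms > max_t_ms)
  if (length(bad_vel) + length(bad_t) > 0L) {
    stop(
      "rejected tap-log rows - velocity out of 1..127: [",
      paste(utils::head(bad_vel, 10L), collapse = ", "),
      "]; time out of range: [",
      paste(utils::head(bad_t, 10L), collapse = ", "), "]",
      call. = FALSE
    )
  }
  tab
}

#' Run the full analysis pipeline
#'
#' Chains every stage: enumerate the rhythm universe, compute rhythm- and
#' pulse-level features, simulate (or load) a tapping cohort, score
#' performances, join observations to features, fit the tap-probability
#' model, and decompose it. Each stage writes a TSV/JSON artifact into
#' `out_dir`.
#'
#' @param config a list with elements `sim` (a [sim_config()]), `seed`,
#'   optional `taps` (a tap log to use instead of simulating), and optional
#'   `prob_model` (list with `predictors`, `pulse_predictors`).
#' @param out_dir output directory (created if needed).
#' @return named character vector of artifact paths, invisibly; prints one
#'   log line per stage with row counts.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  stopifnot(inherits(cfg, "sim_config"))
  paths <- c()
  log_stage <- function(stage, nrows, path) {
    message(sprintf("[%s] %d rows -> %s", stage, nrows, path))
  }

  catalog <- rhythm_catalog(cfg$rhythms)
  p <- file.path(out_dir, "catalog.tsv")
  write_table(catalog, p, config)
  paths["catalog"] <- p
  log_stage("enumerate", nrow(catalog), p)

  feats <- rhythm_features(cfg$rhythms)
  p <- file.path(out_dir, "features.tsv")
  write_table(feats, p, config)
  paths["features"] <- p
  log_stage("features", nrow(feats), p)

  pfeats <- pulse_features(cfg$rhythms)
  p <- file.path(out_dir, "pulse_features.tsv")
  write_table(pfeats, p, config)
  paths["pulse_features"] <- p
  log_stage("pulse-features", nrow(pfeats), p)

  if (!is.null(config$taps)) {
    taps <- config$taps
    truth <- NULL
  } else {
    sim <- simulate_cohort(cfg, seed = config$seed)
    taps <- sim$taps
    truth <- sim$truth
  }
  p <- file.path(out_dir, "taps.tsv")
  write_table(taps, p, config)
  paths["taps"] <- p
  log_stage("simulate", nrow(taps), p)
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
    paths["truth"] <- p
  }

  scored <- score_performances(taps, cfg$rhythms,
    n_slots = cfg$n_slots, ioi_ms = cfg$ioi_ms
  )
  p <- file.path(out_dir, "scores.tsv")
  write_table(scored$scores, p, config)
  paths["scores"] <- p
  log_stage("score", nrow(scored$scores), p)

  obs <- scored$observations
  # rhythm-level N and K get explicit names: "n_pulses" is reserved for the
  # binomial trial count in the aggregated table
  rf <- feats
  names(rf)[names(rf) == "n_pulses"] <- "rhythm_n"
  names(rf)[names(rf) == "n_cues"] <- "rhythm_k"
  joined <- merge(obs, pfeats, by = c("rhythm_id", "n"), sort = FALSE)
  joined <- merge(joined, rf, by.x = "rhythm_id", by.y = "id", sort = FALSE)
  p <- file.path(out_dir, "joined.tsv")
  write_table(joined, p, config)
  paths["joined"] <- p
  log_stage("join", nrow(joined), p)

  pm <- config$prob_model
  if (is.null(pm)) {
    pm <- list(
      predictors = character(0),
      pulse_predictors = c("proj_cent", "markov2")
    )
  }
  counts <- stats::aggregate(
    cbind(tap_num = tapped, n_pulses = 1) ~
      participant + rhythm_id + perf_num + n,
    data = joined, FUN = sum
  )
  names(counts)[names(counts) == "1"] <- "n_pulses"
  counts <- merge(counts, pfeats, by = c("rhythm_id", "n"), sort = FALSE)
  counts <- merge(counts, rf, by.x = "rhythm_id", by.y = "id", sort = FALSE)
  design <- build_design(counts,
    response = c("tap_num", "n_pulses"),
    predictors = pm$predictors,
    pulse_predictors = pm$pulse_predictors
  )
  fit <- fit_binomial_logit(design)
  dec <- sdt_decompose(fit)
  p <- file.path(out_dir, "fit_prob.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(
        family = fit$family,
        coefficients = as.list(fit$coefficients),
        se = as.list(fit$se),
        odds_ratios = as.list(fit$odds_ratios),
        loglik = fit$loglik,
        decomposition = dec,
        standardization = design$standardization,
        config = config_hash(config),
        version = as.character(utils::packageVersion("taprhythm"))
      ),
      p,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    dput(list(coefficients = fit$coefficients, decomposition = dec), file = p)
  }
  paths["fit_prob"] <- p
  log_stage("fit", nrow(counts), p)

  invisible(paths)
}
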