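# Monte-Carlo evaluation: reconstruction RMSE versus loss count / jitter
# ratio, and heart-rate RMSE/MAE versus loss count per correction method.

#' Root mean squared error
#'
#' @param a,b numeric vectors of equal length (at least 1).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 1L) stop("need at least one element", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Mean absolute error
#'
#' @param a,b numeric vectors of equal length (at least 1).
#' @return `mean(abs(a - b))`.
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 1L) stop("need at least one element", call. = FALSE)
  mean(abs(a - b))
}

#' Monte-Carlo experiment configuration
#'
#' Bundles the simulation conditions shared by the reconstruction and
#' heart-rate experiments: a 30 s analysis window at a nominal 25 Hz (750
#' samples), test signals generated on a 1 kHz lattice with unit power in the
#' 0.8-1.8 Hz resting band, and 1000 trials per condition. Per-trial seeds
#' are derived deterministically from `master_seed` and the condition/trial
#' indices, so every condition is independent and individually re-runnable.
#'
#' @param duration_s analysis window in seconds (default 30).
#' @param nominal_rate_hz nominal sampling rate in Hz (default 25).
#' @param gen_rate_hz dense generation rate in Hz (default 1000).
#' @param band_hz generation/search band in Hz (default `c(0.8, 1.8)`).
#' @param n_trials trials per condition (default 1000).
#' @param loss_grid loss counts to evaluate (default `c(0, 10, 20, 30, 40, 50)`).
#' @param ratio_grid jitter ratios to evaluate (default `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param methods correction methods, a subset of
#'   `c("none", "linear", "cubic", "cic")`.
#' @param cic_cfg a [cic_config()].
#' @param master_seed integer master seed (default 1).
#' @param amplitude test-sinusoid amplitude (default `sqrt(2)`, unit power).
#' @param normalize_rmse if `TRUE`, reconstruction RMSE is divided by
#'   `amplitude`; by default raw signal units are reported.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(duration_s = 30, nominal_rate_hz = 25,
                              gen_rate_hz = 1000, band_hz = c(0.8, 1.8),
                              n_trials = 1000,
                              loss_grid = c(0, 10, 20, 30, 40, 50),
                              ratio_grid = c(0, 0.25, 0.5, 0.75, 1),
                              methods = c("none", "linear", "cubic", "cic"),
                              cic_cfg = cic_config(), master_seed = 1,
                              amplitude = sqrt(2), normalize_rmse = FALSE) {
  stop_if_not_number(duration_s, "duration_s", positive = TRUE)
  stop_if_not_number(nominal_rate_hz, "nominal_rate_hz", positive = TRUE)
  stop_if_not_number(gen_rate_hz, "gen_rate_hz", positive = TRUE)
  stop_if_not_number(n_trials, "n_trials", positive = TRUE)
  stop_if_not_number(master_seed, "master_seed")
  stop_if_not_number(amplitude, "amplitude", positive = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(loss_grid) < 1L || length(ratio_grid) < 1L) {
    stop("condition grids must be non-empty", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, nominal_rate_hz = nominal_rate_hz,
         gen_rate_hz = gen_rate_hz, band_hz = band_hz,
         n_trials = as.integer(n_trials), loss_grid = loss_grid,
         ratio_grid = ratio_grid, methods = methods, cic_cfg = cic_cfg,
         master_seed = as.integer(master_seed), amplitude = amplitude,
         normalize_rmse = isTRUE(normalize_rmse)),
    class = "experiment_config"
  )
}

# Assemble a metric table from a condition x method matrix of trial metrics.
# trial_metrics: list keyed by condition, each an n_trials x n_methods matrix.
make_metric_table <- function(per_trial, conditions, methods, metric,
                              condition_name) {
  rows <- do.call(rbind, lapply(seq_along(conditions), function(ci) {
    m <- per_trial[[ci]]
    data.frame(
      condition = conditions[ci],
      method = methods,
      metric_mean = colMeans(m),
      metric_std = apply(m, 2L, stats::sd),
      row.names = NULL
    )
  }))
  structure(rows, class = c("metric_table", "data.frame"),
            metric = metric, condition = condition_name)
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> metric: %s, condition: %s\n",
              attr(x, "metric") %||% "?", attr(x, "condition") %||% "?"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Reconstruction-error Monte-Carlo experiment
#'
#' Per trial: generate a fresh unit-power random-phase sinusoid, sample it
#' regularly at the nominal rate over the analysis window (the reference),
#' corrupt it (random loss of `k` samples, or timing jitter on a fraction `r`
#' of samples), then measure reconstruction RMSE against the reference for
#' each method. The uncorrected baseline (`"none"`) compares the corrupted
#' value sequence index-aligned against the reference's leading samples —
#' i.e. the lossy stream treated as regular at the nominal rate, which is how
#' uncorrected loss shifts the signal; interpolating methods reconstruct onto
#' the reference grid from the logged timestamps and are compared against the
#' full reference.
#'
#' @param cfg an [experiment_config()].
#' @param mode `"loss"` (condition = loss count, from `cfg$loss_grid`) or
#'   `"jitter"` (condition = irregular-sample ratio, from `cfg$ratio_grid`).
#' @return a `metric_table` with one row per condition x method, holding the
#'   mean and standard deviation of per-trial RMSE.
#' @export
run_reconstruction_experiment <- function(cfg, mode = c("loss", "jitter")) {
  stopifnot(inherits(cfg, "experiment_config"))
  mode <- match.arg(mode)
  conditions <- if (mode == "loss") cfg$loss_grid else cfg$ratio_grid
  grid <- uniform_grid(0, cfg$nominal_rate_hz,
                       round(cfg$duration_s * cfg$nominal_rate_hz))
  methods <- cfg$methods
  interp <- setdiff(methods, "none")
  mode_id <- if (mode == "loss") 1L else 2L
  gt <- grid_times(grid)
  scale <- if (cfg$normalize_rmse) cfg$amplitude else 1
  per_trial <- lapply(seq_along(conditions), function(ci) {
    cond <- conditions[ci]
    out <- matrix(NA_real_, nrow = cfg$n_trials, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (tr in seq_len(cfg$n_trials)) {
      seed_sig <- derive_seed(cfg$master_seed, mode_id, ci, tr, 1L)
      seed_cor <- derive_seed(cfg$master_seed, mode_id, ci, tr, 2L)
      dense <- generate_sinusoid(cfg$duration_s, cfg$band_hz, cfg$amplitude,
                                 seed = seed_sig, rate_hz = cfg$gen_rate_hz)
      ref <- sample_regular(dense, grid)
      if (mode == "loss") {
        cor <- apply_sample_loss(ref, loss_spec(cond, seed = seed_cor))
        none_err <- rmse(cor$values, ref$values[seq_along(cor$values)])
      } else {
        cor <- apply_timing_jitter(dense, grid, jitter_spec(cond, seed = seed_cor))
        none_err <- rmse(cor$values, ref$values)
      }
      if ("none" %in% methods) out[tr, "none"] <- none_err / scale
      for (m in interp) {
        rec <- reconstruct(cor, grid, m, cfg$cic_cfg)
        out[tr, m] <- rmse(rec, ref$values) / scale
      }
    }
    out
  })
  make_metric_table(per_trial, conditions, methods, metric = "rmse",
                    condition_name = if (mode == "loss") "loss_count" else "irregular_ratio")
}

#' Heart-rate error Monte-Carlo experiment
#'
#' Per trial: drop `k` samples (uniformly at random) from each source series,
#' estimate heart rate with every method over the analysis window, and record
#' the error against the reference heart rate. The per-trial metric is the
#' RMSE (and MAE) of the errors across sources, so with a panel of sources
#' the two metrics differ as they do across subjects; with a single source
#' both reduce to the absolute error of one estimate. At loss 0 nothing is
#' random and the across-trial standard deviation is exactly 0.
#'
#' @param sources a [sampled_series()] or a list of them, each covering at
#'   least the analysis window at the nominal rate (a synthetic panel from
#'   [generate_rppg_like()] + [sample_regular()] in the shipped experiments).
#' @param reference_bpm reference heart rate(s): scalar or one per source.
#' @param cfg an [experiment_config()]; conditions are `cfg$loss_grid`.
#' @return a list with `rmse` and `mae` metric tables (condition x method
#'   mean/std across trials).
#' @export
run_hr_experiment <- function(sources, reference_bpm, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (inherits(sources, "sampled_series")) sources <- list(sources)
  if (!length(sources) || !all(vapply(sources, inherits, TRUE, "sampled_series"))) {
    stop("`sources` must be a sampled_series or a list of them", call. = FALSE)
  }
  reference_bpm <- rep_len(as.double(reference_bpm), length(sources))
  count <- round(cfg$duration_s * cfg$nominal_rate_hz)
  windows <- lapply(sources, function(s) {
    if (length(s$values) < count) {
      stop(sprintf("each source must cover the analysis window (%d samples)", count),
           call. = FALSE)
    }
    sampled_series(s$timestamps[seq_len(count)], s$values[seq_len(count)],
                   nominal_rate_hz = cfg$nominal_rate_hz)
  })
  grids <- lapply(windows, function(w) {
    uniform_grid(w$timestamps[1L], cfg$nominal_rate_hz, count)
  })
  band <- spectrum_band(cfg$band_hz[1L], cfg$band_hz[2L])
  methods <- cfg$methods
  conditions <- cfg$loss_grid
  per_trial_sq <- vector("list", length(conditions))
  per_trial_abs <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    k <- conditions[ci]
    msq <- matrix(NA_real_, cfg$n_trials, length(methods),
                  dimnames = list(NULL, methods))
    mab <- msq
    for (tr in seq_len(cfg$n_trials)) {
      errs <- matrix(NA_real_, length(windows), length(methods))
      for (si in seq_along(windows)) {
        seed_cor <- derive_seed(cfg$master_seed, 3L, ci, tr, si)
        lossy <- apply_sample_loss(windows[[si]], loss_spec(k, seed = seed_cor))
        for (mi in seq_along(methods)) {
          hr <- estimate_hr_from_series(lossy, methods[mi], grids[[si]], band,
                                        cfg$cic_cfg)
          errs[si, mi] <- hr$hr_bpm - reference_bpm[si]
        }
      }
      msq[tr, ] <- sqrt(colMeans(errs^2))
      mab[tr, ] <- colMeans(abs(errs))
    }
    per_trial_sq[[ci]] <- msq
    per_trial_abs[[ci]] <- mab
  }
  list(
    rmse = make_metric_table(per_trial_sq, conditions, methods, "rmse", "loss_count"),
    mae = make_metric_table(per_trial_abs, conditions, methods, "mae", "loss_count")
  )
}

#' Write a metric table to CSV
#'
#' Columns `condition, method, metric_mean, metric_std`; numeric columns are
#' written with enough digits to round-trip losslessly well beyond 6
#' significant figures.
#'
#' @param table a `metric_table` (or compatible data frame).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_metric_table <- function(table, path) {
  cols <- c("condition", "method", "metric_mean", "metric_std")
  if (nrow(table) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  df <- as.data.frame(table)[, cols]
  lines <- c(
    paste(cols, collapse = ","),
    sprintf("%.17g,%s,%.17g,%.17g",
            as.double(df$condition), df$method,
            df$metric_mean, df$metric_std)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#'
#' @param path CSV file path.
#' @return a `metric_table` data frame.
#' @export
read_metric_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "method", "metric_mean", "metric_std")
  if (!all(need %in% names(df))) {
    stop("file does not look like a metric table (missing columns)", call. = FALSE)
  }
  structure(df[, need], class = c("metric_table", "data.frame"))
}
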