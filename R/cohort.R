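#' Generate a synthetic fixture cohort
#'
#' Emulates the experimental design at configurable scale: able-bodied and
#' stroke-surrogate subjects, three difficulty conditions
#' (`deep_no_ball`, `deep_ball`, `shallow_ball`), a fixed number of trials
#' per condition. Able subjects get fast smooth minimum-jerk drives; stroke
#' surrogates are tested on both sides, the contralesional side with high
#' impairment severity and the ipsilesional side with mild severity
#' (slower strokes plus randomized corrective submovements, see
#' [impaired_drive()]). Per-subject base parameters are drawn once from
#' group-specific distributions; everything is a deterministic function of
#' `seed`.
#'
#' @param dir Output directory (created if needed); `NULL` keeps the cohort
#'   in memory only.
#' @param n_able,n_stroke Numbers of subjects per group.
#' @param trials_per_condition Trials per subject, side and condition.
#' @param seed Master integer seed.
#' @param noise_sd,pixel_pitch Camera emulation parameters passed to
#'   [generate_synthetic_trial()].
#' @param conditions Conditions to generate.
#' @param severity_contra,severity_ipsi Ranges (length-2) the per-subject
#'   severities are drawn from.
#' @return A list of class `fixture_cohort`: `trials` (list of
#'   [trial_recording()]s), `manifest` (data.frame with one row per trial:
#'   file, subject, hand, condition, seed, severity, drive parameters), and
#'   `dir`. When `dir` is given, each trial is written as CSV+JSON and the
#'   manifest as `manifest.json` + `manifest.csv`.
#' @export
make_fixture_cohort <- function(dir = NULL,
                                n_able = 2, n_stroke = 2,
                                trials_per_condition = 3,
                                seed = 1,
                                noise_sd = 5e-4,
                                pixel_pitch = board_pixel_pitch(),
                                conditions = c("deep_no_ball", "deep_ball",
                                               "shallow_ball"),
                                severity_contra = c(0.5, 0.85),
                                severity_ipsi = c(0.15, 0.4)) {
  stopifnot(n_able >= 0, n_stroke >= 0, trials_per_condition >= 1)
  set.seed(as.integer(seed))
  subjects <- list()
  for (i in seq_len(n_able)) {
    subjects[[length(subjects) + 1L]] <- list(
      id = sprintf("AP%02d", i), hands = "able",
      severity = c(able = 0),
      base_out = stats::runif(1, 0.9, 1.2)
    )
  }
  for (i in seq_len(n_stroke)) {
    subjects[[length(subjects) + 1L]] <- list(
      id = sprintf("PS%02d", i), hands = c("contra", "ipsi"),
      severity = c(
        contra = stats::runif(1, severity_contra[1], severity_contra[2]),
        ipsi = stats::runif(1, severity_ipsi[1], severity_ipsi[2])
      ),
      base_out = stats::runif(1, 1.0, 1.3)
    )
  }

  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }

  trials <- list()
  rows <- list()
  trial_seed <- 0L
  for (sub in subjects) {
    for (hand in sub$hands) {
      sev <- sub$severity[[hand]]
      for (cond in conditions) {
        for (k in seq_len(trials_per_condition)) {
          trial_seed <- trial_seed + 1L
          s <- (as.integer(seed) * 10000L + trial_seed) %% .Machine$integer.max
          drv <- impaired_drive(sev, base_out = sub$base_out,
                                base_back = sub$base_out, seed = s)
          sys <- condition_system(cond)
          rec <- generate_synthetic_trial(
            system = sys, drive = drv, noise_sd = noise_sd,
            pixel_pitch = pixel_pitch, seed = s + 1L,
            condition = cond, subject = sub$id, hand = hand
          )
          fname <- sprintf("%s_%s_%s_%02d.csv", sub$id, hand, cond, k)
          if (!is.null(dir)) write_trial(rec, file.path(dir, fname))
          trials[[length(trials) + 1L]] <- rec
          rows[[length(rows) + 1L]] <- data.frame(
            file = fname, subject = sub$id, hand = hand, condition = cond,
            trial = k, seed = s, severity = sev,
            base_stroke_s = sub$base_out,
            drive_span_s = drive_duration(drv),
            n_submovements = nrow(drv$submovements)
          )
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_able = n_able, n_stroke = n_stroke,
           trials_per_condition = trials_per_condition,
           noise_sd_m = noise_sd, pixel_pitch_m = pixel_pitch,
           trials = manifest),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  structure(list(trials = trials, manifest = manifest, dir = dir),
            class = "fixture_cohort")
}

#' @export
print.fixture_cohort <- function(x, ...) {
  cat(sprintf("<fixture_cohort: %d trials, %d subjects%s>\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              if (is.null(x$dir)) "" else paste0(", dir ", x$dir)))
  invisible(x)
}

#' Compute metrics for a batch of trials
#'
#' Runs [preprocess_trial()] and [compute_metrics()] on every trial of a
#' cohort (in memory, or a directory with a `manifest.csv`) and returns the
#' long trial table consumed by [fit_random_intercept()] / [icc_report()].
#'
#' @param x A `fixture_cohort`, a list of [trial_recording()]s, or a
#'   directory path containing trial CSVs and `manifest.csv`.
#' @param mi_bins Bins for mutual information.
#' @return data.frame with columns `subject`, `group` (hand group),
#'   `difficulty` (condition), `metric`, `value`; risk and MI rows are
#'   omitted (not zero-filled) for no-ball trials.
#' @export
batch_compute <- function(x, mi_bins = 10) {
  recs <- if (inherits(x, "fixture_cohort")) {
    x$trials
  } else if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    man <- utils::read.csv(file.path(x, "manifest.csv"))
    lapply(man$file, function(f) read_trial(file.path(x, f)))
  } else if (is.list(x)) {
    x
  } else {
    stop("batch_compute: unsupported input", call. = FALSE)
  }
  rows <- lapply(recs, function(rec) {
    m <- compute_metrics(preprocess_trial(rec), mi_bins = mi_bins)
    vals <- c(movement_time = m$movement_time, sparc = m$sparc,
              risk = m$risk, mutual_information = m$mutual_information)
    vals <- vals[!is.na(vals)]
    data.frame(subject = rec$subject, group = rec$hand,
               difficulty = rec$condition,
               metric = names(vals), value = unname(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
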