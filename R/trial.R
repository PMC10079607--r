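#' Raw trial recording
#'
#' The unit every pipeline stage consumes: timestamped 2-D cup (and
#' optionally ball) centre positions in the board frame, with the target
#' layout and condition metadata.
#'
#' @param t Sample times (s), strictly increasing, spanning at least 0.5 s.
#' @param cup n x 2 matrix of cup centre positions (m).
#' @param ball n x 2 matrix of ball centre positions (m), or `NULL` for the
#'   no-ball condition.
#' @param start,target Start/target circle centres (m); must differ (they
#'   define the movement axis).
#' @param condition,hand,subject Metadata labels (condition one of
#'   `deep_no_ball`, `deep_ball`, `shallow_ball`; hand one of `contra`,
#'   `ipsi`, `able`).
#' @param system Optional [cup_ball_system()] the recording was made with
#'   (required downstream whenever ball data are present).
#' @param sample_rate Nominal frame rate (Hz), default 80.
#' @param seed Generator seed, if synthetic.
#' @param diameter Target circle diameter (m), default 0.14.
#' @param extra Optional data.frame of additional per-frame columns to carry
#'   through serialization untouched.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(t, cup, ball = NULL, start, target,
                            condition = "deep_ball", hand = "able",
                            subject = "S1", system = NULL,
                            sample_rate = 80, seed = NULL,
                            diameter = 0.14, extra = NULL) {
  cup <- as.matrix(cup)
  stopifnot(is.numeric(t), ncol(cup) == 2, nrow(cup) == length(t))
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    bad <- which(c(FALSE, diff(t) <= 0))[1]
    stop(sprintf("trial_recording: time not strictly increasing at row %d",
                 if (is.na(bad)) which(!is.finite(t))[1] else bad),
         call. = FALSE)
  }
  if (max(t) - min(t) < 0.5) {
    stop("trial_recording: less than 0.5 s of samples", call. = FALSE)
  }
  if (!is.null(ball)) {
    ball <- as.matrix(ball)
    stopifnot(ncol(ball) == 2, nrow(ball) == length(t))
  }
  start <- as.numeric(start); target <- as.numeric(target)
  stopifnot(length(start) == 2, length(target) == 2)
  if (sqrt(sum((target - start)^2)) < 1e-9) {
    stop("trial_recording: start and target centres coincide", call. = FALSE)
  }
  if (!is.null(system)) stopifnot(inherits(system, "cup_ball_system"))
  structure(
    list(t = t, cup = cup, ball = ball, start = start, target = target,
         condition = condition, hand = hand, subject = subject,
         system = system, sample_rate = sample_rate, seed = seed,
         diameter = diameter, extra = extra),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording: %s/%s/%s, %d frames @ %g Hz, %s ball data>\n",
    x$subject, x$hand, x$condition, length(x$t), x$sample_rate,
    if (is.null(x$ball)) "no" else "with"))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a trial recording (CSV + JSON sidecar)
#'
#' One trial per file pair: a CSV with columns `t_s`, `cup_x_m`, `cup_y_m`
#' and, when ball data are present, `ball_x_m`, `ball_y_m` (one row per
#' frame, header mandatory), plus a JSON sidecar holding the metadata and
#' system parameters. Numbers are serialized with 17 significant digits so
#' the round trip is lossless. Unknown CSV columns are preserved.
#'
#' @param rec A [trial_recording()].
#' @param path CSV path.
#' @param meta_path Sidecar path; defaults to `path` with the extension
#'   replaced by `.json`.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   a `trial_recording`.
#' @export
write_trial <- function(rec, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(rec, "trial_recording"))
  df <- data.frame(
    t_s = fmt_num(rec$t),
    cup_x_m = fmt_num(rec$cup[, 1]),
    cup_y_m = fmt_num(rec$cup[, 2]),
    stringsAsFactors = FALSE
  )
  if (!is.null(rec$ball)) {
    df$ball_x_m <- fmt_num(rec$ball[, 1])
    df$ball_y_m <- fmt_num(rec$ball[, 2])
  }
  if (!is.null(rec$extra)) {
    for (nm in names(rec$extra)) df[[nm]] <- rec$extra[[nm]]
  }
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  meta <- list(
    subject = rec$subject, hand = rec$hand, condition = rec$condition,
    sample_rate_hz = rec$sample_rate,
    start_center_m = rec$start, target_center_m = rec$target,
    target_diameter_m = rec$diameter,
    separation_m = sqrt(sum((rec$target - rec$start)^2)),
    seed = rec$seed,
    system = if (!is.null(rec$system)) list(
      ball_mass_kg = rec$system$ball_mass,
      pendulum_length_m = rec$system$pendulum_length,
      escape_angle_rad = rec$system$escape_angle,
      escape_angle_deg = rec$system$escape_angle * 180 / pi,
      cup_mass_kg = rec$system$cup_mass,
      gravity_m_s2 = rec$system$gravity
    )
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

default_meta_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' @rdname write_trial
#' @export
read_trial <- function(path, meta_path = default_meta_path(path)) {
  if (!file.exists(path)) stop("read_trial: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_s", "cup_x_m", "cup_y_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_trial: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  t <- as.numeric(df$t_s)
  if (any(diff(t) <= 0)) {
    stop(sprintf("read_trial: time not strictly increasing at row %d of %s",
                 which(diff(t) <= 0)[1] + 1L, path), call. = FALSE)
  }
  has_ball <- all(c("ball_x_m", "ball_y_m") %in% names(df))
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  system <- NULL
  if (!is.null(meta$system)) {
    system <- cup_ball_system(
      ball_mass = meta$system$ball_mass_kg,
      pendulum_length = meta$system$pendulum_length_m,
      escape_angle = meta$system$escape_angle_rad,
      cup_mass = meta$system$cup_mass_kg,
      gravity = meta$system$gravity_m_s2
    )
  }
  known <- c(need, "ball_x_m", "ball_y_m")
  extra_cols <- setdiff(names(df), known)
  trial_recording(
    t = t,
    cup = cbind(as.numeric(df$cup_x_m), as.numeric(df$cup_y_m)),
    ball = if (has_ball) cbind(as.numeric(df$ball_x_m),
                               as.numeric(df$ball_y_m)) else NULL,
    start = meta$start_center_m %||% c(0, 0),
    target = meta$target_center_m %||% c(0.52, 0),
    condition = meta$condition %||% "deep_ball",
    hand = meta$hand %||% "able",
    subject = meta$subject %||% "S1",
    system = system,
    sample_rate = meta$sample_rate_hz %||% 80,
    seed = meta$seed,
    diameter = meta$target_diameter_m %||% 0.14,
    extra = if (length(extra_cols)) df[extra_cols] else NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
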