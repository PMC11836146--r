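#' Impact kinematics records
#'
#' A kinematics record holds one impact's 6-DOF headform loading: time `t`
#' (ms, uniform step), linear acceleration `ax, ay, az` (g), angular velocity
#' `wx, wy, wz` (rad/s) and, once derived, angular acceleration
#' `aax, aay, aaz` (rad/s^2). It is a tibble subclass (`kin_record`) carrying
#' `helmet_id`, `location` and `coord_note` attributes, so it pipes through
#' dplyr verbs like any data frame.
#'
#' The axis convention is headform-fixed Cartesian: X posterior-to-anterior,
#' Y right-to-left, Z inferior-to-superior, origin at the head centre of
#' gravity. All directional injury-metric constants (BrIC, UBrIC) are keyed
#' to these labels.
#'
#' @param data data frame with columns `t, ax, ay, az, wx, wy, wz` (and
#'   optionally `aax, aay, aaz`).
#' @param helmet_id short helmet identifier (e.g. `"A"`).
#' @param location impact location, one of `"XRot"`, `"YRot"`, `"ZRot"`.
#' @param coord_note free-text statement of the axis convention.
#' @return A `kin_record` tibble.
#' @export
kin_record <- function(data, helmet_id, location,
                       coord_note = kin_coord_note()) {
  rec <- as_tibble(data)
  required <- c("t", "ax", "ay", "az", "wx", "wy", "wz")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0) {
    stop_format(paste0("missing column ", paste(missing, collapse = ", ")))
  }
  attr(rec, "helmet_id") <- as.character(helmet_id)
  attr(rec, "location") <- match.arg(location, c("XRot", "YRot", "ZRot"))
  attr(rec, "coord_note") <- coord_note
  class(rec) <- c("kin_record", class(rec))
  validate_kin_record(rec)
}

#' @rdname kin_record
#' @export
kin_coord_note <- function() {
  paste(
    "Headform-fixed Cartesian frame, origin at head CG:",
    "X posterior->anterior, Y right->left, Z inferior->superior."
  )
}

#' @rdname kin_record
#' @param record a `kin_record`.
#' @export
validate_kin_record <- function(record) {
  t <- record$t
  if (length(t) < 2) stop_data("record needs at least 2 time samples")
  num_cols <- intersect(
    c("t", "ax", "ay", "az", "wx", "wy", "wz", "aax", "aay", "aaz"),
    names(record)
  )
  for (col in num_cols) {
    bad <- which(!is.finite(record[[col]]))
    if (length(bad) > 0) {
      stop_data(sprintf("non-finite value in column %s at row %d", col, bad[1]))
    }
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_data(sprintf("non-monotone time at row %d", which(dt <= 0)[1] + 1))
  }
  if (max(dt) - min(dt) > 1e-9) {
    stop_data("time step not uniform (tolerance 1e-9 ms)")
  }
  record
}

#' @export
print.kin_record <- function(x, ...) {
  cat(sprintf(
    "<kin_record> helmet %s, %s: %d samples, dt = %g ms, span %g ms\n",
    attr(x, "helmet_id"), attr(x, "location"),
    nrow(x), kin_dt(x), max(x$t) - min(x$t)
  ))
  NextMethod()
}

#' Time step of a record in ms
#' @param record a `kin_record`.
#' @return scalar time step (ms).
#' @export
kin_dt <- function(record) {
  mean(diff(record$t))
}

#' Input dialect for kinematics files
#'
#' Declares the units and metadata of a delimited kinematics file. Units are
#' converted on read so stored records are always in ms / g / rad/s.
#'
#' @param time_unit `"ms"` or `"s"`.
#' @param lin_acc_unit `"g"` or `"m/s2"`.
#' @param ang_vel_unit `"rad/s"` or `"deg/s"`.
#' @param helmet_id,location optional metadata overriding filename parsing.
#' @return a named list.
#' @export
kin_dialect <- function(time_unit = "ms", lin_acc_unit = "g",
                        ang_vel_unit = "rad/s",
                        helmet_id = NULL, location = NULL) {
  list(
    time_unit = match.arg(time_unit, c("ms", "s")),
    lin_acc_unit = match.arg(lin_acc_unit, c("g", "m/s2")),
    ang_vel_unit = match.arg(ang_vel_unit, c("rad/s", "deg/s")),
    helmet_id = helmet_id, location = location
  )
}

STANDARD_GRAVITY <- 9.80665

#' Read one kinematics file
#'
#' Reads a delimited text file (comma or tab, autodetected) with a header row
#' naming columns `t, ax, ay, az, wx, wy, wz`. A YAML sidecar `<path>.yaml`,
#' if present, overrides the dialect (units, helmet_id, location). Helmet and
#' location default to being parsed from a `<helmet>_<location>` filename
#' stem.
#'
#' @param path file path.
#' @param dialect a [kin_dialect()].
#' @return a [kin_record()].
#' @export
read_kinematics <- function(path, dialect = kin_dialect()) {
  if (!file.exists(path)) stop_data(paste0("no such file: ", path))
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    keep <- intersect(names(side), names(dialect))
    dialect[keep] <- side[keep]
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  # base strtod parsing is correctly rounded, so 17-significant-digit text
  # round-trips bit-identically
  df <- as_tibble(utils::read.delim(
    path, sep = delim, comment.char = "#", check.names = FALSE
  ))
  required <- c("t", "ax", "ay", "az", "wx", "wy", "wz")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(paste0("missing column ", paste(missing, collapse = ", ")))
  }
  df <- df[required]
  df[] <- lapply(df, as.double)
  if (dialect$time_unit == "s") df$t <- df$t * 1000
  if (dialect$lin_acc_unit == "m/s2") {
    df[c("ax", "ay", "az")] <- df[c("ax", "ay", "az")] / STANDARD_GRAVITY
  }
  if (dialect$ang_vel_unit == "deg/s") {
    df[c("wx", "wy", "wz")] <- df[c("wx", "wy", "wz")] * pi / 180
  }
  meta <- parse_kin_filename(path)
  helmet_id <- dialect$helmet_id %||% meta$helmet_id
  location <- dialect$location %||% meta$location
  if (is.null(helmet_id) || is.null(location)) {
    stop_format(paste0(
      "helmet_id/location not found in filename '", basename(path),
      "' (expected '<helmet>_<XRot|YRot|ZRot>') nor in dialect/sidecar"
    ))
  }
  kin_record(df, helmet_id = helmet_id, location = location)
}

parse_kin_filename <- function(path) {
  stem <- sub("\\.[^.]*$", "", basename(path))
  m <- regmatches(stem, regexec("^(.+)_(XRot|YRot|ZRot)$", stem))[[1]]
  if (length(m) == 3) list(helmet_id = m[2], location = m[3])
  else list(helmet_id = NULL, location = NULL)
}

#' Write a kinematics record to delimited text
#'
#' Values are written with 17 significant digits so that a read/write/read
#' cycle is bit-identical.
#'
#' @param record a `kin_record`.
#' @param path output path.
#' @param sep field separator (`","` or `"\t"`).
#' @param header optional comment lines (without leading `#`) to prepend.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(record, path, sep = ",", header = character()) {
  cols <- c("t", "ax", "ay", "az", "wx", "wy", "wz")
  body <- vapply(
    seq_len(nrow(record)),
    function(i) paste(sprintf("%.17g", unlist(record[i, cols])), collapse = sep),
    character(1)
  )
  lines <- c(
    if (length(header) > 0) paste0("# ", header),
    paste(cols, collapse = sep),
    body
  )
  writeLines(lines, path)
  invisible(path)
}

#' Resample a record onto the canonical analysis grid
#'
#' The canonical grid has `n = 600` samples at `k * 0.05` ms, `k = 0..599`,
#' spanning a 30 ms impact. Off-grid records are linearly interpolated; an
#' already-conforming record is returned unchanged (idempotent).
#'
#' @param record a `kin_record`.
#' @param n number of samples.
#' @param duration total duration in ms; sample `k` sits at `k * duration / n`.
#' @return a `kin_record` on the target grid.
#' @export
resample_to_grid <- function(record, n = 600, duration = 30) {
  target <- (seq_len(n) - 1) * duration / n
  t <- record$t
  if (length(t) == n && max(abs(t - target)) <= 1e-9) {
    return(record)
  }
  if (min(t) > 1e-9 || max(t) < target[n] - 1e-9) {
    stop_data(sprintf(
      "record spans [%g, %g] ms, shorter than required [0, %g] ms",
      min(t), max(t), target[n]
    ))
  }
  cols <- intersect(
    c("ax", "ay", "az", "wx", "wy", "wz", "aax", "aay", "aaz"),
    names(record)
  )
  out <- tibble(t = target)
  for (col in cols) {
    out[[col]] <- approx(t, record[[col]], xout = target, rule = 2)$y
  }
  kin_record(out,
    helmet_id = attr(record, "helmet_id"),
    location = attr(record, "location"),
    coord_note = attr(record, "coord_note")
  )
}

#' Read or write a whole ensemble of kinematics records
#'
#' An ensemble lives in a directory of delimited files plus a tab-separated
#' `manifest.tsv` listing `helmet_id`, `location`, `path` (relative).
#'
#' @param records named list of `kin_record`s.
#' @param dir directory to write into (created if needed).
#' @return `write_kinematics_ensemble()` returns the manifest path;
#'   `read_kinematics_ensemble()` returns a named list of records
#'   (`"<helmet>_<location>"`).
#' @export
write_kinematics_ensemble <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(records, function(rec) {
    fname <- sprintf(
      "%s_%s.csv", attr(rec, "helmet_id"), attr(rec, "location")
    )
    write_kinematics(rec, file.path(dir, fname))
    tibble(
      helmet_id = attr(rec, "helmet_id"),
      location = attr(rec, "location"),
      path = fname
    )
  })
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  invisible(manifest_path)
}

#' @rdname write_kinematics_ensemble
#' @param manifest_path path to `manifest.tsv`.
#' @param dialect a [kin_dialect()] applied to every file.
#' @export
read_kinematics_ensemble <- function(manifest_path, dialect = kin_dialect()) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("helmet_id", "location", "path")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    stop_format(paste0("manifest missing column ", paste(missing, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  records <- purrr::pmap(manifest[need], function(helmet_id, location, path) {
    full <- file.path(base, path)
    if (!file.exists(full)) {
      stop_data(sprintf("missing file for (%s, %s): %s", helmet_id, location, full))
    }
    d <- dialect
    d$helmet_id <- helmet_id
    d$location <- location
    read_kinematics(full, d)
  })
  names(records) <- paste(manifest$helmet_id, manifest$location, sep = "_")
  records
}

`%||%` <- function(x, y) if (is.null(x)) y else x
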