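# AFM force-distance curve containers, TSV I/O and preprocessing.
#
# Native dialect: headered TSV with columns distance_nm, force_nN, direction,
# pair_label, location_id, replicate_id. Multi-curve files hold several
# (pair_label, location_id, replicate_id, direction) groups; a two-column
# dialect (distance_nm, force_nN) is accepted for single curves.

#' Construct an AFM force-distance curve
#'
#' One approach or retract trace: paired distance/force samples plus metadata
#' identifying the interacting pair and the measurement replicate. Distances
#' must be strictly monotone; descending traces are stored ascending.
#'
#' @param distance Distances in nm, strictly monotone, length >= 8.
#' @param force Forces in nN, same length as `distance`.
#' @param direction `"extend"` (approach) or `"retract"`.
#' @param pair_label Label of the probe-substrate pair, e.g. `"CNC-CNC"`.
#' @param location_id,replicate_id Integer measurement indices.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `force_curve`.
#' @examples
#' d <- seq(40, 200, length.out = 50)
#' force_curve(d, 2 * exp(-0.04 * d))
#' @export
force_curve <- function(distance, force, direction = "extend",
                        pair_label = "unknown", location_id = 1L,
                        replicate_id = 1L, metadata = list()) {
  stopifnot(
    "distance and force must be numeric" = is.numeric(distance) && is.numeric(force),
    "distance and force must have equal length" = length(distance) == length(force),
    "curves need at least 8 points" = length(distance) >= 8L,
    "non-finite values are not allowed" = all(is.finite(distance)) && all(is.finite(force))
  )
  direction <- match.arg(direction, c("extend", "retract"))
  dd <- diff(distance)
  if (all(dd < 0)) {           # stored outward-in: normalise to ascending
    distance <- rev(distance)
    force <- rev(force)
  } else if (any(dd <= 0)) {
    stop("distance must be strictly monotone", call. = FALSE)
  }
  structure(
    list(distance = as.numeric(distance), force = as.numeric(force),
         direction = direction, pair_label = as.character(pair_label),
         location_id = as.integer(location_id),
         replicate_id = as.integer(replicate_id), metadata = metadata),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s [%s] loc %d rep %d: %d points, D in [%.4g, %.4g] nm\n",
              x$pair_label, x$direction, x$location_id, x$replicate_id,
              length(x$distance), min(x$distance), max(x$distance)))
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$distance)

#' Construct a set of force curves
#'
#' @param curves A list of [force_curve()] objects.
#' @param metadata Named list of free-form metadata. A `heterogeneous` flag is
#'   added when curves do not share a single pair label.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves, metadata = list()) {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, logical(1), "force_curve")))
  labels <- unique(vapply(curves, `[[`, character(1), "pair_label"))
  metadata$heterogeneous <- length(labels) > 1L
  structure(list(curves = curves, metadata = metadata), class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  labels <- vapply(x$curves, `[[`, character(1), "pair_label")
  cat(sprintf("<curve_set> %d curves, %d pair label(s)\n",
              length(x$curves), length(unique(labels))))
  invisible(x)
}

#' @export
length.curve_set <- function(x) length(x$curves)

curve_to_frame <- function(cv) {
  data.frame(distance_nm = cv$distance, force_nN = cv$force,
             direction = cv$direction, pair_label = cv$pair_label,
             location_id = cv$location_id, replicate_id = cv$replicate_id,
             stringsAsFactors = FALSE)
}

# Normalise one raw group to a valid force_curve; idx only used in messages.
frame_to_curve <- function(df, idx) {
  d <- df$distance_nm
  f <- df$force_nN
  o <- order(d)
  sorted_up <- !is.unsorted(d, strictly = FALSE)
  sorted_down <- !is.unsorted(rev(d), strictly = FALSE)
  if (!sorted_up && !sorted_down) {
    stop(sprintf("curve %d: distances are neither ascending nor descending (shuffled input)", idx),
         call. = FALSE)
  }
  d <- d[o]; f <- f[o]
  if (anyDuplicated(d)) {       # average exact duplicate distances
    f <- as.numeric(tapply(f, d, mean))
    d <- sort(unique(d))
  }
  force_curve(d, f, direction = df$direction[1], pair_label = df$pair_label[1],
              location_id = df$location_id[1], replicate_id = df$replicate_id[1])
}

#' Read force curves from a delimited text file
#'
#' Supports the native multi-curve dialect (full six-column schema, curves
#' keyed by pair label / location / replicate / direction) and a bare
#' two-column dialect holding a single curve. Rows with non-finite entries
#' are dropped and counted in the returned set's metadata. Comma-separated
#' files with the same header are detected automatically.
#'
#' @param path Path to the file.
#' @param dialect `"multi_curve_tsv"` or `"two_column_tsv"`.
#' @return A [curve_set()]; `metadata$n_dropped` counts discarded rows.
#' @export
read_curves <- function(path, dialect = c("multi_curve_tsv", "two_column_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty curve file: %s", path), call. = FALSE)
  if (dialect == "two_column_tsv") {
    names(df)[1:2] <- c("distance_nm", "force_nN")
    df$direction <- "extend"; df$pair_label <- "unknown"
    df$location_id <- 1L; df$replicate_id <- 1L
  } else {
    need <- c("distance_nm", "force_nN", "direction", "pair_label",
              "location_id", "replicate_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("multi_curve_tsv file lacks column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  ok <- is.finite(df$distance_nm) & is.finite(df$force_nN)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  key <- interaction(df$pair_label, df$location_id, df$replicate_id,
                     df$direction, drop = TRUE)
  groups <- split(df, key)
  # preserve file order of first appearance
  first_row <- vapply(groups, function(g) as.integer(rownames(g))[1], integer(1))
  groups <- groups[order(first_row)]
  curves <- lapply(seq_along(groups),
                   function(i) frame_to_curve(groups[[i]], i))
  curve_set(curves, metadata = list(n_dropped = n_dropped, source = path))
}

#' Write force curves to the native TSV dialect
#'
#' Inverse of [read_curves()]: `read_curves(write_curves(x, p))` reproduces
#' `x` to better than 1e-9 relative on both columns. An empty set writes a
#' header-only file.
#'
#' @param curves A [curve_set()] or single [force_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "force_curve")) curves <- curve_set(list(curves))
  stopifnot(inherits(curves, "curve_set"))
  if (length(curves$curves) == 0L) {
    df <- data.frame(distance_nm = numeric(), force_nN = numeric(),
                     direction = character(), pair_label = character(),
                     location_id = integer(), replicate_id = integer())
  } else {
    df <- do.call(rbind, lapply(curves$curves, curve_to_frame))
  }
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only the approach phase of a measurement
#'
#' The approach (extend) half of a force measurement is the part analysed:
#' the retract half carries adhesion hysteresis. For a single curve this is
#' an identity on extend-tagged data and an error on retract-only data; for
#' a set it drops all retract curves.
#'
#' @param x A [force_curve()] or [curve_set()].
#' @return Same class as `x`, extend data only.
#' @export
select_extend <- function(x) {
  if (inherits(x, "force_curve")) {
    if (x$direction != "extend") {
      stop("curve has no approach (extend) phase", call. = FALSE)
    }
    return(x)
  }
  stopifnot(inherits(x, "curve_set"))
  keep <- vapply(x$curves, function(cv) cv$direction == "extend", logical(1))
  if (!any(keep)) stop("curve set has no approach (extend) curves", call. = FALSE)
  curve_set(x$curves[keep], metadata = x$metadata)
}

#' Zero the force baseline of a curve
#'
#' Subtracts the mean force over the farthest `window_fraction` of distances,
#' so the large-separation baseline averages exactly zero. Idempotent.
#'
#' @param curve A [force_curve()].
#' @param window_fraction Fraction (0, 0.5] of the largest distances to use
#'   as baseline window; at least 3 points must fall in it.
#' @return The corrected [force_curve()]; the applied offset is recorded in
#'   `metadata$baseline_offset`.
#' @export
baseline_correct <- function(curve, window_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"),
            window_fraction > 0, window_fraction <= 0.5)
  n <- length(curve$distance)
  n_win <- floor(window_fraction * n)
  if (n_win < 3L) {
    stop(sprintf("baseline window has %d point(s); at least 3 required", n_win),
         call. = FALSE)
  }
  idx <- seq.int(n - n_win + 1L, n)
  offset <- mean(curve$force[idx])
  curve$force <- curve$force - offset
  curve$metadata$baseline_offset <-
    offset + if (is.null(curve$metadata$baseline_offset)) 0 else curve$metadata$baseline_offset
  curve
}

#' Select the large-distance tail of a curve for log-linear fitting
#'
#' Keeps the contiguous run of points starting at the first distance
#' >= `d_min` and ending just before the first force <= `min_force`.
#' Positivity of the retained forces makes the natural-log transform valid;
#' contiguity prevents noise-induced holes in the regression window.
#'
#' @param curve A [force_curve()].
#' @param d_min Smallest distance (nm) admitted to the tail.
#' @param min_force Smallest admissible force (nN); points at or below it,
#'   and everything beyond the first such point, are excluded.
#' @return A [force_curve()] holding the tail (>= 8 points).
#' @export
select_tail <- function(curve, d_min, min_force = 1e-3) {
  stopifnot(inherits(curve, "force_curve"), is.numeric(d_min), is.numeric(min_force))
  if (d_min > max(curve$distance)) {
    stop(sprintf("d_min = %g nm is beyond the curve range [%g, %g] nm",
                 d_min, min(curve$distance), max(curve$distance)), call. = FALSE)
  }
  start <- which(curve$distance >= d_min)[1]
  run <- curve$force[start:length(curve$force)] > min_force
  stop_at <- if (any(!run)) which(!run)[1] - 1L else length(run)
  if (stop_at < 8L) {
    stop(sprintf(
      "tail selection kept %d point(s) (need >= 8): %d before d_min = %g nm, first force <= %g nN at index %d",
      stop_at, start - 1L, d_min, min_force, start + stop_at), call. = FALSE)
  }
  idx <- seq.int(start, start + stop_at - 1L)
  out <- curve
  out$distance <- curve$distance[idx]
  out$force <- curve$force[idx]
  out$metadata$tail_range <- range(out$distance)
  out
}
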