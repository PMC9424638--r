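#' Per-position ROI analysis of a crystal video
#'
#' Runs the positional-variance pipeline on a set of (up to seven, in the
#' original protocol) square ROIs: crop, mean intensity trace, boxcar
#' smoothing, first derivative, transition detection.  ROIs are chosen to
#' represent the crystal while avoiding edges and cracks; that choice is the
#' caller's.
#'
#' @param stack A [frame_stack()].
#' @param rois List of [roi()] objects (at least one).
#' @param window Boxcar window; default 65, the positional-analysis setting.
#' @param ... Passed to [detect_transition()].
#' @return List of class `"position_analysis"`: `events` (data.frame with
#'   one row per ROI: label, t1_s, hwhm_s, peak_height, direction,
#'   shoulders, status) and `summary` (mean/sd of T1 and HWHM over the ROIs
#'   that yielded a transition; sd reported as 0 with an `n=1` flag for a
#'   single success).
#' @export
analyze_positions <- function(stack, rois, window = 65, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(rois)) stop("need at least one ROI")
  if (inherits(rois, "roi")) rois <- list(rois)

  rows <- lapply(rois, function(r) {
    ev <- tryCatch({
      tr <- mean_trace(crop_roi(stack, r), source = r$label)
      detect_transition(first_derivative(boxcar_smooth(tr, window)), ...)
    }, error = function(e) e)
    if (inherits(ev, "error")) {
      data.frame(label = r$label, t1_s = NA_real_, hwhm_s = NA_real_,
                 peak_height = NA_real_, direction = NA_integer_,
                 shoulders = "", status = conditionMessage(ev))
    } else {
      data.frame(label = r$label, t1_s = ev$t1_s, hwhm_s = ev$hwhm_s,
                 peak_height = ev$peak_height, direction = ev$direction,
                 shoulders = paste(signif(ev$shoulder_times_s, 6),
                                   collapse = ";"),
                 status = "ok")
    }
  })
  events <- do.call(rbind, rows)
  ok <- events$status == "ok"
  n <- sum(ok)
  summ <- data.frame(
    n = n,
    mean_t1_s = if (n) mean(events$t1_s[ok]) else NA_real_,
    sd_t1_s = if (n > 1) stats::sd(events$t1_s[ok]) else 0,
    mean_hwhm_s = if (n) mean(events$hwhm_s[ok]) else NA_real_,
    sd_hwhm_s = if (n > 1) stats::sd(events$hwhm_s[ok], na.rm = TRUE) else 0,
    flag = if (n == 1) "n=1" else "")
  structure(list(events = events, summary = summ, window = window),
            class = "position_analysis")
}

#' @export
print.position_analysis <- function(x, ...) {
  cat(sprintf("Positional ROI analysis (boxcar %d): %d/%d ROIs detected\n",
              x$window, sum(x$events$status == "ok"), nrow(x$events)))
  print(x$events[, c("label", "t1_s", "hwhm_s", "status")], row.names = FALSE)
  with(x$summary, cat(sprintf("mean T1 = %.2f +/- %.2f s, mean HWHM = %.2f +/- %.2f s%s\n",
                              mean_t1_s, sd_t1_s, mean_hwhm_s, sd_hwhm_s,
                              if (nzchar(flag)) paste0(" [", flag, "]") else "")))
  invisible(x)
}

#' Concentric ROI-size sweep
#'
#' Transition-uniformity analysis across concentric square ROIs of
#' increasing size (default side lengths 2, 4, 8, 14, 28, 42 px, i.e. about
#' 0.1 to 3 um at 14 px/um).  For each size, per-superpixel traces inside
#' the ROI are smoothed (boxcar, default window 39), differentiated, and
#' their transition events collected; the spread of T1 across superpixels
#' measures transition non-uniformity at that length scale.
#'
#' @param stack A [frame_stack()].
#' @param center Length-2 numeric `(row, col)`, 0-based pixel about which
#'   the ROIs are centered.
#' @param sizes_px Integer vector of ROI side lengths.
#' @param window Boxcar window; default 39, the ROI-size-analysis setting.
#' @param bin_px Superpixel side (1 or 2).
#' @param ... Passed to [detect_transition()].
#' @return List of class `"roi_size_sweep"`: `stats` (data.frame per size:
#'   size_px, size_um, n superpixels detected, mean/sd of T1 and HWHM,
#'   flags) and `events` (data.frame of per-superpixel results).
#' @export
roi_size_sweep <- function(stack, center, sizes_px = c(2, 4, 8, 14, 28, 42),
                           window = 39, bin_px = 1L, ...) {
  stopifnot(inherits(stack, "frame_stack"), length(center) == 2)
  d <- dim(stack$frames)
  h <- d[2]; w <- d[3]
  stats_rows <- list()
  event_rows <- list()
  for (size in as.integer(sizes_px)) {
    top <- as.integer(round(center[1] - size / 2))
    left <- as.integer(round(center[2] - size / 2))
    csize <- size
    if (top < 0 || left < 0 || top + csize > h || left + csize > w) {
      warning(sprintf("ROI of side %d px exceeds the frame; clipping", size))
      top2 <- max(top, 0L); left2 <- max(left, 0L)
      csize <- min(top + csize, h) - top2
      csize <- min(csize, min(left + size, w) - left2)
      top <- top2; left <- left2
      if (csize < bin_px) next
    }
    sub <- crop_roi(stack, roi(top, left, csize, sprintf("size%d", size)))
    traces <- suppressMessages(superpixel_traces(sub, bin_px))
    win <- window
    for (tr in traces) {
      ev <- tryCatch(
        detect_transition(first_derivative(boxcar_smooth(tr, win)), ...),
        error = function(e) NULL)
      event_rows[[length(event_rows) + 1L]] <- data.frame(
        size_px = size,
        superpixel_row = attr(tr, "row"), superpixel_col = attr(tr, "col"),
        t1_s = if (is.null(ev)) NA_real_ else ev$t1_s,
        hwhm_s = if (is.null(ev)) NA_real_ else ev$hwhm_s,
        peak_height = if (is.null(ev)) NA_real_ else ev$peak_height,
        direction = if (is.null(ev)) NA_integer_ else ev$direction,
        detected = !is.null(ev))
    }
    ev_sz <- do.call(rbind, event_rows)
    ev_sz <- ev_sz[ev_sz$size_px == size & ev_sz$detected, , drop = FALSE]
    n <- nrow(ev_sz)
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      size_px = size,
      size_um = size * stack$pixel_size_um,
      n_superpixels = n,
      mean_t1_s = if (n) mean(ev_sz$t1_s) else NA_real_,
      sd_t1_s = if (n > 1) stats::sd(ev_sz$t1_s) else 0,
      mean_hwhm_s = if (n) mean(ev_sz$hwhm_s, na.rm = TRUE) else NA_real_,
      sd_hwhm_s = if (n > 1) stats::sd(ev_sz$hwhm_s, na.rm = TRUE) else 0,
      flag = if (n == 1) "n=1" else "")
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 events = do.call(rbind, event_rows),
                 window = window, bin_px = bin_px),
            class = "roi_size_sweep")
}

#' @export
print.roi_size_sweep <- function(x, ...) {
  cat(sprintf("ROI-size sweep (boxcar %d, bin %d):\n", x$window, x$bin_px))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' k-means classification of transition times
#'
#' Groups T1 values with k-means using k-means++-style seeding and multiple
#' restarts, so the partition is reproducible for a fixed seed and invariant
#' to input order.
#'
#' @param values Numeric vector of T1 values (seconds), `length >= k`.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts (best total within-cluster sum
#'   of squares wins).  Default 10.
#' @return List of class `"cluster_result"`: `labels` (1..k, per input
#'   value), `centroids` (sorted increasing), `k`, `seed`, `tot_withinss`.
#' @export
cluster_t1 <- function(values, k, seed = 1L, restarts = 10L) {
  values <- as.numeric(values)
  n <- length(values)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n < k) stop(sprintf("need at least k = %d values, got %d", k, n))
  if (k == 1L) {
    return(structure(list(labels = rep(1L, n), centroids = mean(values),
                          k = 1L, seed = seed, tot_withinss =
                            sum((values - mean(values))^2)),
                     class = "cluster_result"))
  }
  if (length(unique(values)) < k)
    stop("fewer distinct values than clusters")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_init(values, k)
      km <- suppressWarnings(
        stats::kmeans(values, centers = matrix(centers, ncol = 1),
                      iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  ord <- order(best$centers[, 1])
  relabel <- match(seq_len(k), ord)
  structure(list(labels = relabel[best$cluster],
                 centroids = as.numeric(best$centers[ord, 1]),
                 k = k, seed = seed, tot_withinss = best$tot.withinss),
            class = "cluster_result")
}

# k-means++ seeding: subsequent centers drawn with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_init <- function(values, k) {
  centers <- numeric(k)
  centers[1] <- values[sample.int(length(values), 1L)]
  for (j in 2:k) {
    d2 <- vapply(values, function(v) min((v - centers[1:(j - 1)])^2),
                 numeric(1))
    if (all(d2 == 0)) {
      centers[j] <- values[sample.int(length(values), 1L)]
    } else {
      centers[j] <- values[sample.int(length(values), 1L, prob = d2)]
    }
  }
  centers
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d, centroids %s>\n", x$k,
              paste(signif(x$centroids, 5), collapse = ", ")))
  invisible(x)
}

#' Tabulate transition widths by crystal and ROI size
#'
#' Aggregates HWHM values per (crystal, ROI size) cell, the comparison used
#' to judge which crystal shows the shortest, most uniform transition
#' window.
#'
#' @param events Data frame with columns `crystal`, `size_px` (or
#'   `roi_size`), `hwhm_s`.
#' @return Data frame with one row per (crystal, size): n, mean_hwhm_s,
#'   sd_hwhm_s (sample sd; 0 with flag for n = 1).  Empty input gives an
#'   empty table.
#' @export
hwhm_report <- function(events) {
  if (is.null(events) || !nrow(events)) {
    return(data.frame(crystal = character(), size_px = numeric(),
                      n = integer(), mean_hwhm_s = numeric(),
                      sd_hwhm_s = numeric(), flag = character()))
  }
  if (!"size_px" %in% names(events) && "roi_size" %in% names(events))
    events$size_px <- events$roi_size
  stopifnot(all(c("crystal", "size_px", "hwhm_s") %in% names(events)))
  events <- events[is.finite(events$hwhm_s), , drop = FALSE]
  keys <- unique(events[, c("crystal", "size_px")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- events$crystal == keys$crystal[i] & events$size_px == keys$size_px[i]
    v <- events$hwhm_s[sel]
    data.frame(crystal = keys$crystal[i], size_px = keys$size_px[i],
               n = length(v), mean_hwhm_s = mean(v),
               sd_hwhm_s = if (length(v) > 1) stats::sd(v) else 0,
               flag = if (length(v) == 1) "n=1" else "")
  })
  out <- do.call(rbind, rows)
  out[order(out$crystal, out$size_px), , drop = FALSE]
}

#' Write per-superpixel transition events as CSV
#'
#' Long-format CSV mirroring the analyzer's standard output: one row per
#' trace with source, superpixel coordinates, T1, HWHM, peak height,
#' direction and shoulder times.
#'
#' @param events Data frame of events (e.g. `roi_size_sweep()$events`).
#' @param path Output path.
#' @param source Identifier written in the `source` column.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(events, path, source = "stack") {
  df <- cbind(source = source, events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
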