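# Conformer ensembles (replicate trajectories) and the trajectory-level
# analysis pipeline: replicate concatenation, replicate-averaged
# histograms, intramolecular H-bond fold tallies, folded-event detection,
# representative-frame selection and RMSD cluster extraction.

#' Construct a conformer ensemble
#'
#' @param topology A `nad_topology`.
#' @param coords 3-D array (atoms x 3 x frames) of coordinates, Angstroms.
#' @param time_per_frame Time spacing between frames, ps (default 1).
#' @param replicate Integer replicate id (default 1), or a per-frame
#'   integer vector for concatenated ensembles.
#' @param labels Optional per-frame ground-truth label data.frame.
#' @return An object of class `nad_ensemble`.
#' @export
nad_ensemble <- function(topology, coords, time_per_frame = 1,
                         replicate = 1L, labels = NULL) {
  stopifnot(inherits(topology, "nad_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an atoms x 3 x frames array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coordinate rows (", dim(coords)[1], ") != atom count (",
         nrow(topology$atoms), ")")
  n <- dim(coords)[3]
  rep_id <- if (length(replicate) == 1) rep(as.integer(replicate), n)
            else as.integer(replicate)
  if (length(rep_id) != n) stop("replicate vector length != frame count")
  if (!is.null(labels) && nrow(labels) != n)
    stop("label count (", nrow(labels), ") != frame count (", n, ")")
  dimnames(coords) <- list(topology$atoms$name, c("x", "y", "z"), NULL)
  structure(
    list(topology = topology, coords = coords,
         time_per_frame = time_per_frame, replicate = rep_id,
         labels = labels),
    class = "nad_ensemble"
  )
}

#' Number of frames in an ensemble
#' @param ensemble A `nad_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame as a conformer
#' @param ensemble A `nad_ensemble`.
#' @param i Frame index (1-based).
#' @return A `nad_conformer`.
#' @export
get_frame <- function(ensemble, i) {
  nad_conformer(ensemble$topology, ensemble$coords[, , i])
}

#' @export
print.nad_ensemble <- function(x, ...) {
  cat("nad_ensemble:", x$topology$species, "-", n_frames(x), "frames,",
      length(unique(x$replicate)), "replicate(s),",
      x$time_per_frame, "ps/frame\n")
  invisible(x)
}

#' Frame times in ps
#'
#' Frame i of a single-replicate ensemble is at time i * time_per_frame;
#' concatenated ensembles carry cumulative (time-contiguous) times.
#' @param ensemble A `nad_ensemble`.
#' @return Numeric vector of times, ps.
#' @export
frame_times <- function(ensemble) {
  seq_len(n_frames(ensemble)) * ensemble$time_per_frame
}

#' Concatenate replicate ensembles into one time-contiguous trajectory
#'
#' Frames are ordered replicate-by-replicate in the order given; the
#' global time axis is cumulative and replicate boundaries are retained
#' in the per-frame `replicate` vector.
#'
#' @param ensembles List of `nad_ensemble` objects with identical species
#'   and time-per-frame.
#' @return A single `nad_ensemble`.
#' @export
concatenate_replicates <- function(ensembles) {
  if (inherits(ensembles, "nad_ensemble")) return(ensembles)
  if (!length(ensembles)) stop("no ensembles to concatenate")
  sp <- vapply(ensembles, function(e) e$topology$species, "")
  if (length(unique(sp)) != 1)
    stop("topology mismatch: species ", paste(unique(sp), collapse = " vs "))
  tpf <- vapply(ensembles, function(e) e$time_per_frame, 0)
  if (length(unique(tpf)) != 1)
    stop("time_per_frame mismatch across replicates")
  if (length(ensembles) == 1) return(ensembles[[1]])
  coords <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), dim = c(dim(arrs[[1]])[1], 3,
                                sum(vapply(arrs, function(a) dim(a)[3], 0))))
  }, lapply(ensembles, `[[`, "coords"))
  labels <- lapply(ensembles, `[[`, "labels")
  labels <- if (any(vapply(labels, is.null, TRUE))) NULL
            else do.call(rbind, labels)
  rep_id <- unlist(lapply(ensembles, `[[`, "replicate"))
  nad_ensemble(ensembles[[1]]$topology, coords, tpf[1], rep_id, labels)
}

#' Per-frame metrics table for an ensemble
#'
#' @param ensemble A `nad_ensemble`.
#' @return data.frame with frame index, time (ps), replicate id and every
#'   `compute_metrics()` column.
#' @export
ensemble_metrics <- function(ensemble) {
  n <- n_frames(ensemble)
  rows <- vector("list", n)
  for (i in seq_len(n)) rows[[i]] <- compute_metrics(get_frame(ensemble, i))
  out <- do.call(rbind, rows)
  cbind(data.frame(frame = seq_len(n), time = frame_times(ensemble),
                   replicate = ensemble$replicate), out)
}

#' Replicate-averaged histogram
#'
#' Bins a per-frame metric separately for each replicate and reports the
#' per-bin mean count and sample standard deviation across replicates.
#'
#' @param values Per-frame metric values.
#' @param replicate Per-frame replicate ids (same length).
#' @param bin_width Bin width (default 0.5).
#' @param range Histogram range, default c(0, 20).
#' @return List of class `nad_histogram`: `breaks`, `mid`, per-replicate
#'   `counts` matrix (replicates x bins), `mean`, `sd`.
#' @export
replicate_histogram <- function(values, replicate = rep(1L, length(values)),
                                bin_width = 0.5, range = c(0, 20)) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (length(values) != length(replicate))
    stop("values and replicate lengths differ")
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  reps <- sort(unique(replicate))
  counts <- t(vapply(reps, function(r) {
    v <- values[replicate == r]
    v <- v[v >= range[1] & v < breaks[length(breaks)]]
    tabulate(findInterval(v, breaks), nbins = length(breaks) - 1)
  }, integer(length(breaks) - 1)))
  rownames(counts) <- reps
  structure(
    list(breaks = breaks,
         mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
         counts = counts,
         mean = colMeans(counts),
         sd = if (length(reps) > 1) apply(counts, 2, stats::sd)
              else rep(NA_real_, ncol(counts))),
    class = "nad_histogram"
  )
}

#' @export
print.nad_histogram <- function(x, ...) {
  cat("nad_histogram:", length(x$mid), "bins,", nrow(x$counts),
      "replicate(s),", sum(x$counts), "frames\n")
  invisible(x)
}

#' Tally intramolecular hydrogen-bond fold signatures
#'
#' A frame counts toward one of the four atom-pair bins when any of the
#' bin's pair distances is <= `cutoff` (default 3.3 Angstroms, the
#' potential-hydrogen-bond criterion); a frame with both members of a
#' two-pair bin satisfied still counts once. The bins are
#' [O3'N-O2'A], [O3'A-O1N], [O3'A/O2'A-O4'N], [O3'N/O2'N-O4'A].
#'
#' @param metrics Per-frame metrics (from `ensemble_metrics()`), or a
#'   `nad_ensemble`.
#' @param cutoff Distance cutoff, Angstroms (inclusive).
#' @return List of class `nad_fold_tally`: per-bin `counts`,
#'   `most_prevalent` bin name (ties -> first bin), per-bin `frames`
#'   index lists.
#' @export
track_fold_bins <- function(metrics, cutoff = 3.3) {
  if (inherits(metrics, "nad_ensemble")) metrics <- ensemble_metrics(metrics)
  cols <- c("hb_o3N_o2A", "hb_o3A_o1N", "hb_ribA_o4N", "hb_ribN_o4A")
  miss <- setdiff(cols, names(metrics))
  if (length(miss)) stop("metrics lack H-bond columns: ",
                         paste(miss, collapse = ", "))
  frames <- lapply(cols, function(cl) which(metrics[[cl]] <= cutoff))
  names(frames) <- cols
  counts <- vapply(frames, length, 0L)
  structure(
    list(counts = counts,
         most_prevalent = cols[which.max(counts)],
         frames = frames,
         cutoff = cutoff),
    class = "nad_fold_tally"
  )
}

#' @export
print.nad_fold_tally <- function(x, ...) {
  cat("nad_fold_tally (cutoff", x$cutoff, "A):\n")
  print(x$counts)
  cat("most prevalent:", x$most_prevalent, "\n")
  invisible(x)
}

#' Detect folded events
#'
#' Frames in which the O4'N--C4A distance is <= `cutoff` (default 4.0
#' Angstroms, boundary inclusive), marking the most common folded form.
#'
#' @param metrics Per-frame metrics or a `nad_ensemble`.
#' @param cutoff Distance cutoff, Angstroms.
#' @return Integer vector of frame indices.
#' @export
detect_folded_events <- function(metrics, cutoff = 4.0) {
  if (inherits(metrics, "nad_ensemble")) metrics <- ensemble_metrics(metrics)
  if (!"fold_event_distance" %in% names(metrics))
    stop("metrics lack the fold_event_distance column")
  which(metrics$fold_event_distance <= cutoff)
}

# peak maximum (bin mid) of the mean histogram restricted to a window;
# ties break to the lower-distance bin
histogram_peak <- function(hist, window) {
  sel <- which(hist$mid >= window[1] & hist$mid <= window[2])
  if (!length(sel) || all(hist$mean[sel] == 0)) return(NA_real_)
  hist$mid[sel[which.max(hist$mean[sel])]]
}

#' Select representative frames per foldedness class
#'
#' Folded representatives are the frames of the most prevalent H-bond
#' fold bin. For each folded frame the trajectory is scanned backwards in
#' time (never crossing into the previous replicate) and the first frame
#' whose inter-base distance lies within +- `halfwidth` of the class's
#' histogram peak is taken as that event's semi-extended (and,
#' independently, extended) representative.
#'
#' @param metrics Per-frame metrics table (with `d` and `replicate`).
#' @param tally A `nad_fold_tally` computed on the same frames.
#' @param hist A `nad_histogram` of `d` computed on the same frames.
#' @param windows Classification windows (peak located inside each
#'   class's window).
#' @param halfwidth Acceptance half-width around the peak, Angstroms.
#' @return List with `folded` (frame indices), `semi_extended`,
#'   `extended` (frame indices, deduplicated, NA-free), and the located
#'   `peaks`. Empty classes are reported via attribute `note`.
#' @export
select_representative_frames <- function(metrics, tally, hist,
                                         windows = classification_windows(),
                                         halfwidth = 0.5) {
  folded <- tally$frames[[tally$most_prevalent]]
  peaks <- c(
    semi_extended = histogram_peak(hist, windows$foldedness$semi_extended),
    extended = histogram_peak(hist, windows$foldedness$extended)
  )
  scan_back <- function(i, peak) {
    if (is.na(peak)) return(NA_integer_)
    j <- i - 1L
    while (j >= 1L && metrics$replicate[j] == metrics$replicate[i]) {
      if (abs(metrics$d[j] - peak) <= halfwidth) return(as.integer(j))
      j <- j - 1L
    }
    NA_integer_
  }
  semi <- vapply(folded, scan_back, 0L, peak = peaks[["semi_extended"]])
  ext <- vapply(folded, scan_back, 0L, peak = peaks[["extended"]])
  note <- character(0)
  if (!length(folded)) note <- c(note, "no folded frames in tally")
  if (all(is.na(semi))) note <- c(note, "no semi-extended representative")
  if (all(is.na(ext))) note <- c(note, "no extended representative")
  structure(
    list(folded = folded,
         semi_extended = sort(unique(semi[!is.na(semi)])),
         extended = sort(unique(ext[!is.na(ext)])),
         peaks = peaks),
    note = note
  )
}

#' Extract an RMSD cluster around a reference conformation
#'
#' Candidate frames have superposed heavy-atom RMSD to the reference
#' <= `cutoff` (default 1.0 Angstroms). Frames are then selected greedily
#' from the earliest candidate onwards, requiring each selection to be
#' more than `spacing_ns` (default 5 ns) away in simulation time from
#' every previous selection, stopping after `max_frames` (default 10).
#'
#' @param ensemble A `nad_ensemble`.
#' @param reference A `nad_conformer` (same species).
#' @param cutoff RMSD cutoff, Angstroms (> 0).
#' @param spacing_ns Minimum pairwise time separation, ns (>= 0).
#' @param max_frames Maximum number of selected frames.
#' @return Integer vector of selected frame indices (all candidates if
#'   fewer qualify than requested).
#' @export
cluster_by_rmsd <- function(ensemble, reference, cutoff = 1.0,
                            spacing_ns = 5, max_frames = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (spacing_ns < 0) stop("spacing must be non-negative")
  sel <- heavy_atoms(ensemble$topology)
  rms <- vapply(seq_len(n_frames(ensemble)), function(i) {
    rmsd_superposed(get_frame(ensemble, i), reference, sel)
  }, 0)
  cand <- which(rms <= cutoff)
  times <- frame_times(ensemble)[cand] / 1000  # ps -> ns
  chosen <- integer(0)
  chosen_t <- numeric(0)
  for (k in seq_along(cand)) {
    if (length(chosen) >= max_frames) break
    if (all(abs(times[k] - chosen_t) > spacing_ns)) {
      chosen <- c(chosen, cand[k])
      chosen_t <- c(chosen_t, times[k])
    }
  }
  chosen
}

#' Two-metric scatter table
#'
#' One (x, y) row per frame, unbinned — the data behind plane-angle vs
#' distance and theta vs chi_N scatter panels.
#'
#' @param metrics Per-frame metrics table.
#' @param x,y Metric column names.
#' @return data.frame with columns frame, x, y.
#' @export
scatter_table <- function(metrics, x, y) {
  for (nm in c(x, y))
    if (!nm %in% names(metrics)) stop("unknown metric: ", nm)
  data.frame(frame = seq_len(nrow(metrics)), x = metrics[[x]],
             y = metrics[[y]])
}
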