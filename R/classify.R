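# Conformational-state classification. The underlying populations are
# continuous; the default window boundaries are package defaults placed
# midway between the reported population centers and are fully
# configurable, so categorical tallies are reproducible without
# over-reading density plots.

#' Default classification windows
#'
#' Foldedness windows on the inter-base centroid distance d (folded
#' [0, 6) A, semi-extended [8, 10] A, extended [12, 15] A; anything else
#' is intermediate). Glycosidic windows on chi (anti: [90, 180] u
#' (-180, -90]; syn: [-45, 90); high-anti and high-syn are +-15 degree
#' sub-flag windows around -60 and +110). Pucker threshold on nu2
#' (+-10 degrees around 0 is flat). Amide windows on theta.
#'
#' @return Nested list of windows, editable and accepted by every
#'   classifier.
#' @export
classification_windows <- function() {
  list(
    foldedness = list(
      folded = c(0, 6),
      semi_extended = c(8, 10),
      extended = c(12, 15)
    ),
    glycosidic = list(
      syn = c(-45, 90),
      high_anti = c(-75, -45),
      high_syn = c(95, 125)
    ),
    pucker_flat_halfwidth = 10,
    amide = list(near = 22.5, far = 157.5, offset_max = 90)
  )
}

check_foldedness_windows <- function(w) {
  wins <- w$foldedness
  nm <- names(wins)
  for (i in seq_along(wins)) {
    if (wins[[i]][1] >= wins[[i]][2])
      stop("degenerate foldedness window: ", nm[i])
    for (j in seq_len(i - 1)) {
      if (wins[[i]][1] < wins[[j]][2] && wins[[j]][1] < wins[[i]][2])
        stop("overlapping foldedness windows: ", nm[j], ", ", nm[i])
    }
  }
  invisible(w)
}

#' Classify foldedness from the inter-base distance
#'
#' @param d Inter-base centroid distance(s), Angstroms (>= 0).
#' @param windows Windows list (see `classification_windows()`).
#' @return Character vector: "folded", "semi_extended", "extended" or
#'   "intermediate".
#' @export
classify_foldedness <- function(d, windows = classification_windows()) {
  check_foldedness_windows(windows)
  if (any(d < 0, na.rm = TRUE)) stop("negative inter-base distance")
  w <- windows$foldedness
  out <- rep("intermediate", length(d))
  out[d >= w$folded[1] & d < w$folded[2]] <- "folded"
  out[d >= w$semi_extended[1] & d <= w$semi_extended[2]] <- "semi_extended"
  out[d >= w$extended[1] & d <= w$extended[2]] <- "extended"
  out[is.na(d)] <- NA_character_
  out
}

#' Classify a glycosidic torsion as syn/anti
#'
#' Primary states: anti ([90, 180] u (-180, -90]), syn ([-45, 90)),
#' otherwise "other". The high-anti (~ -60 deg) and high-syn (~ +110 deg)
#' regions are sub-flags, not exclusive states (high-syn in particular is
#' a plausible transition region between the two main rotamers); query
#' them with `glycosidic_subflag()`.
#'
#' @param chi Glycosidic torsion(s), degrees in (-180, 180].
#' @param base "N" (nicotinamide/pyridone) or "A" (adenosine). The same
#'   default windows are used for both bases.
#' @param windows Windows list.
#' @return Character vector: "anti", "syn" or "other".
#' @export
classify_glycosidic <- function(chi, base = c("N", "A"),
                                windows = classification_windows()) {
  base <- match.arg(base)
  chi <- wrap_angle(chi)
  syn <- windows$glycosidic$syn
  out <- rep("other", length(chi))
  out[chi >= syn[1] & chi < syn[2]] <- "syn"
  out[(chi >= 90 & chi <= 180) | (chi > -180 & chi <= -90)] <- "anti"
  out[chi == 180] <- "anti"
  out[is.na(chi)] <- NA_character_
  out
}

#' High-anti / high-syn sub-flag of a glycosidic torsion
#' @inheritParams classify_glycosidic
#' @return Character vector: "high_anti", "high_syn" or "none".
#' @export
glycosidic_subflag <- function(chi, windows = classification_windows()) {
  chi <- wrap_angle(chi)
  ha <- windows$glycosidic$high_anti
  hs <- windows$glycosidic$high_syn
  out <- rep("none", length(chi))
  out[chi >= ha[1] & chi <= ha[2]] <- "high_anti"
  out[chi >= hs[1] & chi <= hs[2]] <- "high_syn"
  out[is.na(chi)] <- NA_character_
  out
}

#' Classify ribose pucker from nu2
#'
#' nu2 <= -10 deg is C2'-endo, nu2 >= +10 deg is C3'-endo, |nu2| < 10 deg
#' is flat (threshold configurable).
#'
#' @param nu2 Endocyclic torsion(s) C1'-C2'-C3'-C4', degrees.
#' @param windows Windows list.
#' @return Character vector: "C2p_endo", "C3p_endo" or "flat".
#' @export
classify_pucker <- function(nu2, windows = classification_windows()) {
  h <- windows$pucker_flat_halfwidth
  out <- rep("flat", length(nu2))
  out[nu2 <= -h] <- "C2p_endo"
  out[nu2 >= h] <- "C3p_endo"
  out[is.na(nu2)] <- NA_character_
  out
}

#' Classify the amide (carboxamide) orientation
#'
#' near_0: |theta| <= 22.5 deg; near_180: |theta| >= 157.5 deg;
#' offset_plus: theta in (22.5, 90]; offset_minus: theta in [-90, -22.5);
#' anything else is "other".
#'
#' @param theta Amide torsion(s) C4N-C3N-C7N-N7N, degrees.
#' @param windows Windows list.
#' @return Character vector.
#' @export
classify_amide <- function(theta, windows = classification_windows()) {
  theta <- wrap_angle(theta)
  a <- windows$amide
  out <- rep("other", length(theta))
  out[abs(theta) <= a$near] <- "near_0"
  out[abs(theta) >= a$far] <- "near_180"
  out[theta > a$near & theta <= a$offset_max] <- "offset_plus"
  out[theta < -a$near & theta >= -a$offset_max] <- "offset_minus"
  out[is.na(theta)] <- NA_character_
  out
}

#' Full categorical state assignment for a metrics table
#'
#' @param metrics Per-frame metrics data.frame (from `compute_metrics()`
#'   or `ensemble_metrics()`).
#' @param windows Windows list.
#' @return data.frame of per-frame states: foldedness, glycosidic_N (+
#'   sub-flag), glycosidic_A, pucker, amide.
#' @export
classify_states <- function(metrics, windows = classification_windows()) {
  data.frame(
    foldedness = classify_foldedness(metrics$d, windows),
    glycosidic_N = classify_glycosidic(metrics$chi_N, "N", windows),
    glycosidic_N_flag = glycosidic_subflag(metrics$chi_N, windows),
    glycosidic_A = classify_glycosidic(metrics$chi_A, "A", windows),
    pucker = classify_pucker(metrics$nu2, windows),
    amide = classify_amide(metrics$theta, windows),
    stringsAsFactors = FALSE
  )
}

#' Fractions of each state over an ensemble
#' @param states Character vector of per-frame states.
#' @return Named numeric vector of fractions (sums to 1).
#' @export
state_fractions <- function(states) {
  tab <- table(states)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Serialize a windows configuration as plain text
#'
#' The exact block is echoed into analysis report headers for provenance.
#' @param windows Windows list.
#' @return Character vector of "key = value" lines.
#' @export
format_windows <- function(windows = classification_windows()) {
  out <- character(0)
  flat <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(v)) flat(key, v)
      else out <<- c(out, paste(key, "=", paste(v, collapse = ", ")))
    }
  }
  flat("", windows)
  out
}
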