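#' Meta-profile container
#'
#' @param anchor one of `"start"`, `"stop"`, `"centile"`, `"mode"`.
#' @param bins ordered bin labels (centiles or nt offsets).
#' @param values normalized density per bin.
#' @param n_features number of features contributing.
#' @param n_skipped positions/windows skipped (outside bounds, zero mean).
#' @return object of class `meta_profile`.
#' @export
meta_profile <- function(anchor, bins, values, n_features, n_skipped = 0L) {
  structure(list(anchor = anchor, bins = bins, values = values,
                 n_features = n_features, n_skipped = n_skipped),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile (", x$anchor, "-anchored): ", length(x$bins), " bins, ",
      x$n_features, " features", sep = "")
  if (x$n_skipped > 0) cat(" (", x$n_skipped, " skipped)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.meta_profile <- function(x, ...) {
  data.frame(bin = x$bins, value = x$values)
}

#' @export
plot.meta_profile <- function(x, ...) {
  plot(x$bins, x$values, type = "l",
       xlab = switch(x$anchor, centile = "ORF centile", "offset (nt)"),
       ylab = "normalized density",
       main = paste0(x$anchor, "-anchored meta-profile"), ...)
  invisible(x)
}

#' ORF-centile meta-profile of site positions
#'
#' Each ORF is compressed into 100 centiles;
#' `centile = floor(100 * (pos - orf_start) / orf_len)` clipped to 99.
#' Per-centile counts are normalized to sum to 1.
#'
#' @param positions data.frame transcript_id, pos (0-based transcript
#'   coordinates, e.g. site mode locations).
#' @param annotation annotation data.frame.
#' @return `meta_profile` with bins 0..99; positions outside their ORF are
#'   skipped and counted in `n_skipped`.
#' @export
centile_profile <- function(positions, annotation) {
  ai <- match(positions$transcript_id, annotation$transcript_id)
  if (anyNA(ai)) stop("position on unknown transcript", call. = FALSE)
  os <- annotation$orf_start[ai]; oe <- annotation$orf_end[ai]
  inside <- positions$pos >= os & positions$pos < oe
  cent <- pmin(floor(100 * (positions$pos[inside] - os[inside]) /
                       (oe[inside] - os[inside])), 99)
  counts <- tabulate(cent + 1L, nbins = 100L)
  total <- sum(counts)
  meta_profile("centile", 0:99,
               if (total > 0) counts / total else rep(0, 100),
               n_features = sum(inside), n_skipped = sum(!inside))
}

#' Start/stop-anchored positional meta-profile
#'
#' Offsets are relative to the first nt of the start codon or the first nt
#' of the stop codon (the last 3 ORF nt). Counts per offset are divided by
#' the number of transcripts contributing at least one position.
#'
#' @param positions data.frame transcript_id, pos.
#' @param annotation annotation data.frame.
#' @param anchor `"start"` or `"stop"`.
#' @param window half-width in nt (> 0); bins run -window..window.
#' @return `meta_profile`.
#' @export
anchored_profile <- function(positions, annotation, anchor = c("start", "stop"),
                             window = 100L) {
  anchor <- match.arg(anchor)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  bins <- seq.int(-window, window)
  if (nrow(positions) == 0L)
    return(meta_profile(anchor, bins, numeric(length(bins)), 0L))
  ai <- match(positions$transcript_id, annotation$transcript_id)
  if (anyNA(ai)) stop("position on unknown transcript", call. = FALSE)
  ref <- if (anchor == "start") annotation$orf_start[ai]
         else annotation$orf_end[ai] - 3L
  off <- positions$pos - ref
  keep <- off >= -window & off <= window
  counts <- tabulate(off[keep] + window + 1L, nbins = length(bins))
  n_tx <- length(unique(positions$transcript_id[keep]))
  meta_profile(anchor, bins,
               if (n_tx > 0) counts / n_tx else numeric(length(bins)),
               n_features = n_tx, n_skipped = sum(!keep))
}

#' Footprint density around binding-site mode locations
#'
#' For each mode, per-nt read density is collected over
#' `[mode - halfwidth, mode + halfwidth]`; windows overhanging transcript
#' ends contribute only their defined offsets. With
#' `normalize = "per_window"` each window is divided by its own mean before
#' aggregation (windows with zero mean are excluded), so deep sites do not
#' dominate; `"global"` averages raw windows and divides by the overall
#' mean. Read-to-position assignment is full-span coverage by default;
#' `"center"` assigns each read to its midpoint and `"end5"` to its 5' end.
#'
#' @param reads footprint read table (pre-filter to one length class with
#'   [filter_footprint_class()] where needed).
#' @param modes data.frame transcript_id, mode (0-based).
#' @param annotation annotation data.frame (for transcript lengths).
#' @param halfwidth window half-width in nt (> 0).
#' @param assign `"coverage"`, `"center"` or `"end5"`.
#' @param normalize `"per_window"` or `"global"`.
#' @return `meta_profile` with bins -halfwidth..halfwidth.
#' @export
mode_centered_density <- function(reads, modes, annotation, halfwidth = 100L,
                                  assign = c("coverage", "center", "end5"),
                                  normalize = c("per_window", "global")) {
  assign <- match.arg(assign); normalize <- match.arg(normalize)
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  bins <- seq.int(-halfwidth, halfwidth)
  nb <- length(bins)
  tlen <- setNames(annotation$total_len, annotation$transcript_id)
  # per-transcript event positions
  ev <- switch(assign,
    coverage = NULL,
    center = (reads$start + reads$end) %/% 2L,
    end5 = reads$start)
  acc <- numeric(nb); nacc <- integer(nb); n_win <- 0L; n_skip <- 0L
  for (i in seq_len(nrow(modes))) {
    tid <- modes$transcript_id[i]; m <- modes$mode[i]
    tl <- tlen[[tid]]
    pos <- m + bins
    def <- pos >= 0L & pos < tl
    if (!any(def)) { n_skip <- n_skip + 1L; next }
    sel <- reads$chrom == tid
    vals <- numeric(nb)
    if (assign == "coverage") {
      rs <- reads$start[sel]; re <- reads$end[sel]
      lo <- m - halfwidth; hi <- m + halfwidth
      for (j in which(rs <= hi & re > lo)) {
        a <- max(rs[j], lo); b <- min(re[j] - 1L, hi)
        idx <- (a - lo + 1L):(b - lo + 1L)
        vals[idx] <- vals[idx] + 1
      }
    } else {
      e <- ev[sel]
      e <- e[e >= m - halfwidth & e <= m + halfwidth]
      if (length(e) > 0L) vals <- vals + tabulate(e - m + halfwidth + 1L, nbins = nb)
    }
    vals[!def] <- NA_real_
    if (normalize == "per_window") {
      mu <- mean(vals[def])
      if (mu == 0) { n_skip <- n_skip + 1L; next }
      vals <- vals / mu
    }
    acc[def] <- acc[def] + vals[def]
    nacc[def] <- nacc[def] + 1L
    n_win <- n_win + 1L
  }
  out <- ifelse(nacc > 0L, acc / nacc, 0)
  if (normalize == "global" && mean(out) > 0) out <- out / mean(out)
  meta_profile("mode", bins, out, n_features = n_win, n_skipped = n_skip)
}

#' Filter footprint reads to one length class
#'
#' Length classes are exact partitions: standard 28-30 nt, short 20-22 nt,
#' disome 57-63 nt.
#' @param reads read table.
#' @param class class name (see [FOOTPRINT_CLASSES]).
#' @return filtered read table.
#' @export
filter_footprint_class <- function(reads, class) {
  if (!class %in% names(FOOTPRINT_CLASSES))
    stop("unknown footprint class: ", class, call. = FALSE)
  out <- reads[(reads$end - reads$start) %in% FOOTPRINT_CLASSES[[class]], ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
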