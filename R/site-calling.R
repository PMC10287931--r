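#' Site-calling parameters
#'
#' Defaults follow a standard PARalyzer-style parameterization for yeast
#' LARP PAR-CLIP: minimum read length 13 nt, minimum 5 reads per group, kernel
#' density estimated only at positions covered by >= 5 reads, clusters kept
#' when they carry >= 2 conversions from >= 2 distinct reads and are
#' 11-100 nt wide (larger clusters are discarded as merged-span or rRNA
#' artifacts). Bandwidth of the Gaussian kernel is 3 nt.
#'
#' @param bandwidth Gaussian kernel SD in nt.
#' @param min_read_len minimum read length retained (nt).
#' @param min_group_reads minimum reads per overlapping read group.
#' @param min_depth minimum read depth for a density estimate at a position.
#' @param min_conversions minimum T-to-C conversions per cluster.
#' @param min_conversion_reads minimum distinct conversion-bearing reads per
#'   cluster.
#' @param min_width,max_width accepted cluster width range (nt).
#' @return a named list of class `site_params`.
#' @export
site_params <- function(bandwidth = 3, min_read_len = 13L, min_group_reads = 5L,
                        min_depth = 5L, min_conversions = 2L,
                        min_conversion_reads = 2L, min_width = 11L,
                        max_width = 100L) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  structure(list(bandwidth = bandwidth, min_read_len = as.integer(min_read_len),
                 min_group_reads = as.integer(min_group_reads),
                 min_depth = as.integer(min_depth),
                 min_conversions = as.integer(min_conversions),
                 min_conversion_reads = as.integer(min_conversion_reads),
                 min_width = as.integer(min_width),
                 max_width = as.integer(max_width)),
            class = "site_params")
}

#' Filter reads by minimum length
#' @param reads conversion-read table.
#' @param min_len minimum length in nt (default 13).
#' @return filtered table; the number of discarded reads is attached as
#'   attribute `n_discarded`.
#' @export
filter_reads <- function(reads, min_len = 13L) {
  keep <- (reads$end - reads$start) >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Group reads into maximal transitively-overlapping sets
#'
#' Reads on the same transcript and strand whose intervals overlap
#' (half-open) transitively form one group; groups with fewer than
#' `min_group_reads` members are discarded.
#'
#' @param reads conversion-read table.
#' @param min_group_reads minimum reads per group (default 5).
#' @return list of read-table subsets, each with attributes `chrom`,
#'   `strand`, `start`, `end`.
#' @export
group_reads <- function(reads, min_group_reads = 5L) {
  if (nrow(reads) == 0L) return(list())
  groups <- list(); gi <- 0L
  for (key in split(seq_len(nrow(reads)),
                    paste(reads$chrom, reads$strand, sep = "\r"))) {
    idx <- key[order(reads$start[key], reads$end[key])]
    cur <- idx[1]; cur_end <- reads$end[idx[1]]
    flush <- function(members) {
      if (length(members) >= min_group_reads) {
        g <- reads[members, , drop = FALSE]
        rownames(g) <- NULL
        attr(g, "chrom") <- g$chrom[1]; attr(g, "strand") <- g$strand[1]
        attr(g, "start") <- min(g$start); attr(g, "end") <- max(g$end)
        gi <<- gi + 1L; groups[[gi]] <<- g
      }
    }
    for (j in idx[-1]) {
      if (reads$start[j] < cur_end) {
        cur <- c(cur, j); cur_end <- max(cur_end, reads$end[j])
      } else {
        flush(cur); cur <- j; cur_end <- reads$end[j]
      }
    }
    flush(cur)
  }
  groups
}

# background event positions for one read: reference-T (plus strand) or
# reference-A (minus strand) covered positions without a conversion; when no
# sequence is available, every covered position is a potential event.
.background_positions <- function(start, end, strand, conv_pos, seq_chars) {
  covered <- seq.int(start, end - 1L)
  if (!is.null(seq_chars)) {
    want <- if (strand == "+") "T" else "A"
    covered <- covered[seq_chars[covered + 1L] == want]
  }
  setdiff(covered, conv_pos)
}

#' Estimate conversion signal and background densities over a read group
#'
#' Signal is the count-normalized Gaussian kernel density of conversion
#' events; background is the same for covered-but-unconverted reference-T
#' positions (one event per read per position; all covered positions are
#' used when `sequence` is `NULL`). Positions covered by fewer than
#' `min_depth` reads are masked (ratio undefined).
#'
#' @param group one read group from [group_reads()].
#' @param bandwidth Gaussian kernel SD in nt.
#' @param min_depth minimum depth for a defined estimate.
#' @param sequence optional transcript sequence (character scalar) for
#'   reference-T background events.
#' @return object of class `density_profile`: list(positions, depth, signal,
#'   background, ratio, defined, conv_pos, conv_read).
#' @export
estimate_densities <- function(group, bandwidth = 3, min_depth = 5L,
                               sequence = NULL) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  gstart <- attr(group, "start"); gend <- attr(group, "end")
  positions <- seq.int(gstart, gend - 1L)
  depth <- integer(length(positions))
  for (i in seq_len(nrow(group))) {
    j <- seq.int(group$start[i] - gstart + 1L, group$end[i] - gstart)
    depth[j] <- depth[j] + 1L
  }
  seq_chars <- if (is.null(sequence)) NULL else strsplit(sequence, "")[[1]]
  conv_list <- conversion_positions(group)
  conv_pos <- unlist(conv_list, use.names = FALSE)
  conv_read <- rep(seq_len(nrow(group)), lengths(conv_list))
  bg_pos <- unlist(lapply(seq_len(nrow(group)), function(i)
    .background_positions(group$start[i], group$end[i], group$strand[i],
                          conv_list[[i]], seq_chars)), use.names = FALSE)
  kde <- function(events) {
    if (length(events) == 0L) return(numeric(length(positions)))
    # mean of Gaussian kernels centered at the events
    colMeans(matrix(dnorm(rep(positions, each = length(events)) - events,
                          sd = bandwidth),
                    nrow = length(events)))
  }
  signal <- kde(conv_pos)
  background <- kde(bg_pos)
  tot <- signal + background
  defined <- depth >= min_depth & tot > 0
  ratio <- ifelse(defined, signal / tot, NA_real_)
  # conversion-capable positions: reference T (+ strand) / A (- strand);
  # unknown sequence leaves every position capable
  capable <- rep(TRUE, length(positions))
  if (!is.null(seq_chars)) {
    want <- if (group$strand[1] == "+") "T" else "A"
    inb <- positions + 1L <= length(seq_chars)
    capable <- inb & seq_chars[pmin(positions + 1L, length(seq_chars))] == want
  }
  structure(list(positions = positions, depth = depth, signal = signal,
                 background = background, ratio = ratio, defined = defined,
                 capable = capable, conv_pos = conv_pos, conv_read = conv_read),
            class = "density_profile")
}

#' Mode location of a density profile
#'
#' The coordinate with the highest signal/(signal + background) value;
#' ties are broken by the leftmost coordinate. When the transcript sequence
#' is known the argmax is taken over conversion-capable positions
#' (reference T), since the ratio is a conversion likelihood and only those
#' positions can host a crosslink; if none is defined, all defined
#' positions are used.
#'
#' @param profile a `density_profile`.
#' @param within optional logical mask (same length as positions)
#'   restricting the argmax, e.g. to one cluster.
#' @return 0-based coordinate.
#' @export
mode_location <- function(profile, within = NULL) {
  ok <- profile$defined
  if (!is.null(within)) ok <- ok & within
  if (!any(ok)) stop("no defined ratio", call. = FALSE)
  if (any(ok & profile$capable)) ok <- ok & profile$capable
  r <- profile$ratio
  r[!ok] <- -Inf
  profile$positions[which.max(r)]
}

#' Call binding sites from conversion reads
#'
#' The full caller: length-filter reads, build overlapping read groups,
#' estimate conversion signal vs background kernel densities per group, take
#' maximal runs of defined positions where signal exceeds background as
#' interaction regions, extend each region to the contiguous read-supported
#' span around it (positions with depth >= `min_depth`) to form the
#' candidate cluster, and keep clusters passing the conversion-count,
#' conversion-read and width thresholds. Each accepted site carries its mode
#' location (argmax of the signal ratio, leftmost on ties).
#'
#' @param reads conversion-read table.
#' @param params a [site_params()] list.
#' @param sequences optional named character vector of transcript sequences
#'   (for reference-T background events).
#' @return binding-site data.frame: chrom, start, end, name, strand,
#'   read_count, conversion_count, conversion_read_count, mode_location.
#' @export
call_sites <- function(reads, params = site_params(), sequences = NULL) {
  reads <- filter_reads(reads, params$min_read_len)
  groups <- group_reads(reads, params$min_group_reads)
  out <- list(); k <- 0L
  for (g in groups) {
    seqc <- if (is.null(sequences)) NULL else sequences[[attr(g, "chrom")]]
    prof <- estimate_densities(g, params$bandwidth, params$min_depth, seqc)
    runs <- .candidate_runs(prof)
    clusters <- .extend_to_clusters(prof, runs, params$min_depth)
    for (r in clusters) {
      a <- prof$positions[r[1]]; b <- prof$positions[r[2]]
      width <- b - a + 1L
      in_run <- prof$conv_pos >= a & prof$conv_pos <= b
      n_conv <- sum(in_run)
      n_conv_reads <- length(unique(prof$conv_read[in_run]))
      if (n_conv < params$min_conversions) next
      if (n_conv_reads < params$min_conversion_reads) next
      if (width < params$min_width || width > params$max_width) next
      within <- seq_along(prof$positions) >= r[1] &
        seq_along(prof$positions) <= r[2]
      mode <- mode_location(prof, within)
      n_reads <- sum(g$start < b + 1L & g$end > a)
      k <- k + 1L
      out[[k]] <- data.frame(chrom = attr(g, "chrom"), start = a,
                             end = b + 1L, name = sprintf("site_%04d", k),
                             strand = attr(g, "strand"),
                             read_count = n_reads, conversion_count = n_conv,
                             conversion_read_count = n_conv_reads,
                             mode_location = mode, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), read_count = integer(0),
                      conversion_count = integer(0),
                      conversion_read_count = integer(0),
                      mode_location = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal runs (index pairs into profile$positions) where the profile is
# defined and signal strictly exceeds background
.candidate_runs <- function(prof) {
  ok <- prof$defined & prof$signal > prof$background
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

# extend each interaction run to the maximal contiguous block of positions
# with depth >= min_depth containing it; runs falling in the same block
# merge into one cluster
.extend_to_clusters <- function(prof, runs, min_depth) {
  if (length(runs) == 0L) return(list())
  ok <- prof$depth >= min_depth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- Map(c, starts[r$values], ends[r$values])
  hit <- unique(vapply(runs, function(rn)
    which(vapply(blocks, function(b) rn[1] >= b[1] && rn[2] <= b[2],
                 logical(1)))[1], integer(1)))
  blocks[sort(hit)]
}
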