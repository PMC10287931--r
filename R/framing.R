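IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = "AG", Y = "CT", S = "GC", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for a degenerate (IUPAC) motif
#'
#' All (possibly overlapping) matches of the pattern are reported, with the
#' coordinate of the pattern's consensus G (`g_position`) for reading-frame
#' attribution. The default YGSU pattern (Y = C/T, S = G/C, U = T on the DNA
#' alphabet) is the consensus enriched in LARP binding sites.
#'
#' @param sequence transcript sequence (character scalar, DNA alphabet).
#' @param pattern IUPAC degenerate pattern; must contain a literal G unless
#'   frame attribution is not needed.
#' @param interval optional 0-based half-open `c(start, end)` restricting
#'   the scan; matches must lie fully inside it.
#' @return data.frame match_start (0-based), g_position.
#' @export
scan_motif <- function(sequence, pattern = "YGSU", interval = NULL) {
  pat <- toupper(pattern)
  if (!all(strsplit(pat, "")[[1]] %in% names(IUPAC_MAP)))
    stop("non-IUPAC symbol in pattern: ", pattern, call. = FALSE)
  pat_dna <- chartr("U", "T", pat)
  g_off <- regexpr("G", pat_dna, fixed = TRUE)[1] - 1L
  sub <- sequence
  shift <- 0L
  if (!is.null(interval)) {
    if (interval[1] < 0 || interval[2] > nchar(sequence) ||
        interval[1] >= interval[2])
      stop("interval outside sequence", call. = FALSE)
    sub <- substr(sequence, interval[1] + 1L, interval[2])
    shift <- as.integer(interval[1])
  }
  if (nchar(sub) < nchar(pat_dna))
    return(data.frame(match_start = integer(0), g_position = integer(0)))
  hits <- Biostrings::matchPattern(pat_dna, Biostrings::DNAString(sub),
                                   fixed = "subject")
  ms <- Biostrings::start(hits) - 1L + shift
  data.frame(match_start = ms,
             g_position = if (g_off >= 0L) ms + g_off else NA_integer_)
}

#' Reading-frame distribution of motif hits within ORFs
#'
#' Frame of each hit is `(g_position - orf_start) mod 3`. Hits outside the
#' ORF are skipped and counted. With `per_site_top = TRUE` each site casts a
#' single vote through its first listed hit — for [site_motif_hits()] output
#' that is the hit nearest the site's mode, matching the per-binding-site
#' framing statistic; the default counts every hit.
#'
#' @param hits data.frame transcript_id, g_position, and optionally
#'   site_name (required for `per_site_top`).
#' @param annotation annotation data.frame.
#' @param per_site_top logical; one hit per site.
#' @return list: `proportions` (frames 0,1,2, summing to 1), `n_hits`,
#'   `n_skipped`.
#' @export
frame_distribution <- function(hits, annotation, per_site_top = FALSE) {
  if (per_site_top) {
    if (!"site_name" %in% names(hits))
      stop("per_site_top requires a site_name column", call. = FALSE)
    hits <- hits[!duplicated(hits$site_name), , drop = FALSE]
  }
  ai <- match(hits$transcript_id, annotation$transcript_id)
  os <- annotation$orf_start[ai]; oe <- annotation$orf_end[ai]
  inside <- !is.na(ai) & hits$g_position >= os & hits$g_position < oe
  if (!any(inside)) stop("no in-ORF motif hits", call. = FALSE)
  fr <- (hits$g_position[inside] - os[inside]) %% 3L
  counts <- tabulate(fr + 1L, nbins = 3L)
  list(proportions = setNames(counts / sum(counts), c("0", "1", "2")),
       n_hits = sum(inside), n_skipped = sum(!inside))
}

#' Reading-frame baseline of a motif across all ORFs
#'
#' Scans every annotated ORF for the pattern and tabulates G frames — the
#' ORFome-wide expectation against which site-restricted framing is judged.
#'
#' @param sequences named character vector of transcript sequences.
#' @param annotation annotation data.frame.
#' @param pattern IUPAC pattern.
#' @return list as in [frame_distribution()].
#' @export
orfome_frame_baseline <- function(sequences, annotation, pattern = "YGSU") {
  hits <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i) {
    tid <- annotation$transcript_id[i]
    h <- scan_motif(sequences[[tid]], pattern,
                    c(annotation$orf_start[i], annotation$orf_end[i]))
    if (nrow(h) == 0L) return(NULL)
    data.frame(transcript_id = tid, g_position = h$g_position,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) stop("no motif hits in any ORF", call. = FALSE)
  frame_distribution(hits, annotation)
}

#' Scan motif hits within binding sites
#'
#' Hits within each site are ordered by distance of the consensus G to the
#' site's mode location (the crosslink summary), nearest first, so the first
#' hit per site is the mode-proximal "top" hit used by the per-site framing
#' statistic.
#'
#' @param sites binding-site data.frame (with `mode_location`).
#' @param sequences named character vector.
#' @param pattern IUPAC pattern.
#' @return data.frame site_name, transcript_id, match_start, g_position,
#'   dist_to_mode.
#' @export
site_motif_hits <- function(sites, sequences, pattern = "YGSU") {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    tid <- sites$chrom[i]
    h <- scan_motif(sequences[[tid]], pattern, c(sites$start[i], sites$end[i]))
    if (nrow(h) == 0L) return(NULL)
    d <- abs(h$g_position - sites$mode_location[i])
    o <- order(d, h$match_start)
    data.frame(site_name = sites$name[i], transcript_id = tid,
               match_start = h$match_start[o], g_position = h$g_position[o],
               dist_to_mode = d[o], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(site_name = character(0), transcript_id = character(0),
                      match_start = integer(0), g_position = integer(0),
                      dist_to_mode = integer(0))
  rownames(out) <- NULL
  out
}

#' Reading frames of binding-site edges
#'
#' Tabulates the codon frame of each site's leading edge (`start`) and
#' trailing edge (`end - 1`) relative to its ORF, overall and stratified by
#' site width.
#'
#' @param sites binding-site data.frame (sites outside ORFs are dropped).
#' @param annotation annotation data.frame.
#' @return list: `leading`, `trailing` (frame proportions), `by_width`
#'   (data.frame width, edge, frame, count).
#' @export
edge_frames <- function(sites, annotation) {
  ai <- match(sites$chrom, annotation$transcript_id)
  os <- annotation$orf_start[ai]; oe <- annotation$orf_end[ai]
  keep <- !is.na(ai) & sites$start >= os & sites$end <= oe
  s <- sites[keep, , drop = FALSE]; os <- os[keep]
  if (nrow(s) == 0L) stop("no sites fully inside ORFs", call. = FALSE)
  lead <- (s$start - os) %% 3L
  trail <- (s$end - 1L - os) %% 3L
  prop <- function(f) setNames(tabulate(f + 1L, nbins = 3L) / length(f),
                               c("0", "1", "2"))
  width <- s$end - s$start
  by_width <- rbind(
    data.frame(width = width, edge = "leading", frame = lead),
    data.frame(width = width, edge = "trailing", frame = trail))
  by_width <- stats::aggregate(list(count = rep(1L, nrow(by_width))),
                               by_width[c("width", "edge", "frame")], sum)
  list(leading = prop(lead), trailing = prop(trail), by_width = by_width)
}

.track_vector <- function(track, transcript_id) {
  tr <- track[track$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(tr) == 0L) return(NULL)
  v <- rep(NA_real_, max(tr$pos) + 1L)
  v[tr$pos + 1L] <- tr$score
  v
}

#' Mean structure score over an interval
#'
#' @param track data.frame transcript_id, pos, score.
#' @param transcript_id transcript.
#' @param start,end 0-based half-open interval.
#' @return mean over defined positions; `NA` if none defined.
#' @export
pars_mean <- function(track, transcript_id, start, end) {
  v <- .track_vector(track, transcript_id)
  if (is.null(v)) return(NA_real_)
  idx <- seq.int(start, end - 1L) + 1L
  idx <- idx[idx >= 1L & idx <= length(v)]
  if (length(idx) == 0L) return(NA_real_)
  mean(v[idx], na.rm = TRUE)
}

#' PARS30: structure-score sum over a 30-nt window
#'
#' 30 nt approximates one ribosome footprint. Windows extending beyond the
#' defined track are flagged `NA`.
#'
#' @param track score track.
#' @param transcript_id transcript.
#' @param window_start 0-based start of the 30-nt window.
#' @return sum, or `NA` for a partially/fully undefined window.
#' @export
pars30 <- function(track, transcript_id, window_start) {
  v <- .track_vector(track, transcript_id)
  if (is.null(v)) return(NA_real_)
  idx <- seq.int(window_start, window_start + 29L) + 1L
  if (any(idx < 1L) || any(idx > length(v))) return(NA_real_)
  s <- v[idx]
  if (anyNA(s)) return(NA_real_)
  sum(s)
}

#' PARS30 sums in the three windows around a site mode
#'
#' Upstream `[-45, -15)`, central `[-15, +15)` and downstream `[+15, +45)`
#' windows relative to the mode (offset 0 belongs to the central window);
#' the three windows tile `[-45, +45)` exactly.
#'
#' @param track score track.
#' @param transcript_id transcript.
#' @param mode 0-based mode location.
#' @return named numeric: upstream, site, downstream.
#' @export
pars30_around_mode <- function(track, transcript_id, mode) {
  c(upstream = pars30(track, transcript_id, mode - 45L),
    site = pars30(track, transcript_id, mode - 15L),
    downstream = pars30(track, transcript_id, mode + 15L))
}
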