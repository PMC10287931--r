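#' Reads per million per kilobase of coding sequence (rpkm)
#'
#' `(count / library_total * 1e6) / cds_len_kb`. Undefined entries (zero
#' library total or length) return `NA`.
#'
#' @param count read count(s).
#' @param library_total total mapped reads in the library.
#' @param cds_len_kb coding-sequence length in kb.
#' @return rpkm value(s).
#' @export
rpkm <- function(count, library_total, cds_len_kb) {
  val <- (count / library_total * 1e6) / cds_len_kb
  bad <- rep_len(!(library_total > 0 & cds_len_kb > 0), length(val))
  val[bad] <- NA_real_
  val
}

#' PAR-CLIP enrichment: CLIP rpkm over total-RNA rpkm
#'
#' Transcripts whose RNA rpkm falls below `floor` are excluded (`NA`) — the
#' ratio is unstable for barely-detected denominators.
#'
#' @param clip_rpkm,rna_rpkm rpkm vectors.
#' @param floor minimum RNA rpkm for a defined ratio.
#' @return enrichment ratio(s), `NA` where excluded.
#' @export
clip_enrichment <- function(clip_rpkm, rna_rpkm, floor = 0.1) {
  val <- clip_rpkm / rna_rpkm
  bad <- rep_len(is.na(rna_rpkm) | rna_rpkm < floor, length(val))
  val[bad] <- NA_real_
  val
}

#' Translation efficiency: footprint rpkm over RNA rpkm
#' @inheritParams clip_enrichment
#' @param rpf_rpkm ribosome-protected-fragment rpkm.
#' @return TE ratio(s).
#' @export
translation_efficiency <- function(rpf_rpkm, rna_rpkm, floor = 0.1) {
  clip_enrichment(rpf_rpkm, rna_rpkm, floor)
}

#' Disome abundance: disome-footprint rpkm over RNA rpkm
#'
#' The disome-class equivalent of translation efficiency.
#' @inheritParams clip_enrichment
#' @param disome_rpkm disome-footprint rpkm.
#' @return ratio(s).
#' @export
disome_abundance <- function(disome_rpkm, rna_rpkm, floor = 0.1) {
  clip_enrichment(disome_rpkm, rna_rpkm, floor)
}

#' Median-of-ratios size factors for a count matrix
#'
#' Reference is the per-transcript geometric mean over libraries (rows with
#' any zero are dropped); each library's factor is the median of its
#' count/reference ratios.
#'
#' @param mat transcripts x libraries count matrix.
#' @return numeric size factors, one per column.
#' @export
size_factors <- function(mat) {
  keep <- apply(mat > 0, 1, all)
  if (!any(keep)) stop("no transcript with nonzero counts in all libraries",
                       call. = FALSE)
  lref <- rowMeans(log(mat[keep, , drop = FALSE]))
  apply(mat[keep, , drop = FALSE], 2, function(col) exp(median(log(col) - lref)))
}

#' Polysome:monosome log2 ratio with size-factor normalization
#'
#' A size-factor-normalized log-ratio (a deliberate simplification of a
#' negative-binomial differential model): counts are scaled by
#' median-of-ratios size factors, a pseudocount keeps zeros finite, and the
#' per-transcript statistic is
#' `log2((poly/sfP + c) / (mono/sfM + c))`.
#'
#' @param poly_counts,mono_counts per-transcript counts (same order).
#' @param pseudocount additive constant `c`.
#' @return numeric log2 ratios.
#' @export
poly_mono_ratio <- function(poly_counts, mono_counts, pseudocount = 0.5) {
  if (sum(poly_counts) == 0 || sum(mono_counts) == 0)
    stop("all-zero library", call. = FALSE)
  sf <- size_factors(cbind(poly = poly_counts, mono = mono_counts))
  log2((poly_counts / sf["poly"] + pseudocount) /
       (mono_counts / sf["mono"] + pseudocount))
}

#' Mann-Whitney rank comparison of two groups
#'
#' The U statistic counts pairs where a group-A value exceeds a group-B
#' value (ties count one half). For `nA + nB <= 12` the two-sided p-value is
#' computed by exhaustive enumeration of all group assignments of the pooled
#' values (exact even under ties); otherwise the normal approximation with
#' tie correction is used.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list(U, p.value, method) of class `rank_compare`.
#' @export
rank_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ustat <- function(idx_a) {
    r <- rank(pooled)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  u <- ustat(seq_len(na))
  mid <- na * nb / 2
  if (na + nb <= 12L) {
    combs <- combn(na + nb, na)
    us <- apply(combs, 2, ustat)
    p <- mean(abs(us - mid) >= abs(u - mid) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    t <- table(pooled)
    tie_term <- sum(t^3 - t) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    z <- (u - mid) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  structure(list(U = u, p.value = p, method = method), class = "rank_compare")
}

#' @export
print.rank_compare <- function(x, ...) {
  cat("Mann-Whitney rank comparison (", x$method, ")\n", sep = "")
  cat("U =", x$U, ", two-sided p =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Build the per-transcript expression table
#'
#' Collects CLIP reads inside accepted clusters, RNA-seq counts and
#' footprint counts per transcript, derives rpkm columns (library totals are
#' the per-assay column sums) and the enrichment / TE / disome-abundance
#' ratios.
#'
#' @param sites accepted binding sites.
#' @param clip_reads conversion-read table.
#' @param annotation annotation data.frame.
#' @param rna_counts data.frame transcript_id, count.
#' @param footprints named list of read tables by class (optional classes).
#' @param floor RNA rpkm floor for ratio denominators.
#' @return data.frame with count, rpkm and ratio columns per transcript.
#' @export
expression_table <- function(sites, clip_reads, annotation, rna_counts,
                             footprints = list(), floor = 0.1) {
  ids <- annotation$transcript_id
  cds_kb <- (annotation$orf_end - annotation$orf_start) / 1000
  # CLIP reads inside accepted clusters only
  clip_n <- setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(sites))) {
    sel <- clip_reads$chrom == sites$chrom[i] &
      clip_reads$start < sites$end[i] & clip_reads$end > sites$start[i]
    clip_n[sites$chrom[i]] <- clip_n[sites$chrom[i]] + sum(sel)
  }
  rna_n <- setNames(rep(0L, length(ids)), ids)
  rna_n[rna_counts$transcript_id] <- rna_counts$count
  df <- data.frame(transcript_id = ids, cds_len_kb = cds_kb,
                   clip_reads = as.integer(clip_n), rna_reads = as.integer(rna_n),
                   stringsAsFactors = FALSE)
  df$clip_rpkm <- rpkm(df$clip_reads, sum(df$clip_reads), df$cds_len_kb)
  df$rna_rpkm <- rpkm(df$rna_reads, sum(df$rna_reads), df$cds_len_kb)
  df$clip_enrichment <- clip_enrichment(df$clip_rpkm, df$rna_rpkm, floor)
  for (cl in names(footprints)) {
    n <- setNames(rep(0L, length(ids)), ids)
    tab <- table(footprints[[cl]]$chrom)
    n[names(tab)] <- as.integer(tab)
    df[[paste0(cl, "_reads")]] <- as.integer(n)
    df[[paste0(cl, "_rpkm")]] <- rpkm(n, sum(n), df$cds_len_kb)
    ratio_col <- if (cl == "disome") "disome_abundance" else paste0(cl, "_te")
    df[[ratio_col]] <- translation_efficiency(df[[paste0(cl, "_rpkm")]],
                                              df$rna_rpkm, floor)
  }
  df
}
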