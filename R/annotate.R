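#' Assign binding sites to transcript regions
#'
#' A site is labeled by the region containing its mode location (the site's
#' point summary), so boundary-spanning sites follow their mode. Transcripts
#' with biotype other than mRNA label as `ncRNA`; sites on transcripts absent
#' from the annotation label as `intergenic`.
#'
#' @param sites binding-site data.frame.
#' @param annotation annotation data.frame (optional `biotype` column).
#' @return `sites` with an added `region_label` column.
#' @export
assign_region <- function(sites, annotation) {
  ai <- match(sites$chrom, annotation$transcript_id)
  lab <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    j <- ai[i]
    if (is.na(j)) { lab[i] <- "intergenic"; next }
    m <- sites$mode_location[i]
    if (m < 0 || m >= annotation$total_len[j])
      stop("mode location ", m, " outside transcript ", sites$chrom[i],
           call. = FALSE)
    bt <- if ("biotype" %in% names(annotation)) annotation$biotype[j] else "mRNA"
    lab[i] <- if (bt != "mRNA") "ncRNA"
      else if (m < annotation$orf_start[j]) "5UTR"
      else if (m < annotation$orf_end[j]) "ORF"
      else "3UTR"
  }
  sites$region_label <- lab
  sites
}

#' Target transcripts: RNAs with at least one accepted binding site
#' @param sites binding-site data.frame.
#' @return character vector of transcript ids.
#' @export
define_targets <- function(sites) {
  sort(unique(sites$chrom))
}

#' Proportion of sites per region label
#' @param sites annotated sites (see [assign_region()]).
#' @return named numeric proportions summing to 1.
#' @export
region_distribution <- function(sites) {
  if (nrow(sites) == 0L) stop("no sites", call. = FALSE)
  tab <- table(sites$region_label)
  prop <- as.numeric(tab) / sum(tab)
  setNames(prop, names(tab))
}

#' Histogram of binding sites per target transcript
#' @param sites binding-site data.frame.
#' @return data.frame n_sites, n_transcripts.
#' @export
sites_per_target <- function(sites) {
  tab <- table(table(sites$chrom))
  data.frame(n_sites = as.integer(names(tab)),
             n_transcripts = as.integer(tab))
}

#' Venn-style exclusive segment counts for named sets
#' @param ... named character vectors (2 or more sets).
#' @return named integer vector; names like `"A"`, `"A&B"` denote the
#'   exclusive segment (members of exactly those sets).
#' @export
overlap_sets <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named", call. = FALSE)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  segs <- unlist(lapply(seq_along(sets), function(k)
    combn(names(sets), k, paste, collapse = "&")))
  out <- setNames(integer(length(segs)), segs)
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Distribution of targets among score quintiles
#'
#' The external score table is ranked into 5 equal-count bins (stable ties;
#' quintile 5 = highest score) and target membership tabulated. Targets
#' absent from the score table are excluded and counted as unscored.
#'
#' @param targets character vector of target transcript ids.
#' @param score_table data.frame with columns transcript_id, score.
#' @return list: `proportions` (per quintile, summing to 1), `counts`,
#'   `n_unscored`.
#' @export
quintile_distribution <- function(targets, score_table) {
  r <- rank(score_table$score, ties.method = "first")
  q <- ceiling(r * 5 / nrow(score_table))
  names(q) <- score_table$transcript_id
  scored <- targets[targets %in% names(q)]
  n_unscored <- length(targets) - length(scored)
  counts <- vapply(1:5, function(k) sum(q[scored] == k), integer(1))
  names(counts) <- paste0("Q", 1:5)
  if (sum(counts) == 0L) stop("no scored targets", call. = FALSE)
  list(proportions = counts / sum(counts), counts = counts,
       n_unscored = n_unscored)
}
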