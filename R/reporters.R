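#' Primer efficiency from a dilution-series slope
#'
#' From the slope of Cq against log10 dilution:
#' `efficiency% = (10^(-1/slope) - 1) * 100`; the amplification factor is
#' `10^(-1/slope)` (2.0 at 100% efficiency, i.e. slope -3.3219).
#'
#' @param slope cycles per log10 dilution (must be negative).
#' @return list(efficiency_pct, factor).
#' @export
primer_efficiency <- function(slope) {
  if (slope >= 0) stop("dilution-series slope must be negative", call. = FALSE)
  f <- 10^(-1 / slope)
  list(efficiency_pct = (f - 1) * 100, factor = f)
}

#' Efficiency-corrected relative amount from Cq values
#'
#' `E_target^(-Cq_target) / E_spike^(-Cq_spike)` — the Pfaffl-corrected
#' delta-delta-Ct quantity against a spiked-in control; with both
#' efficiencies 2 it reduces to `2^(Cq_spike - Cq_target)`.
#'
#' @param cq,spike_cq target and spike-in Cq cycles (vectorized).
#' @param e_target,e_spike amplification factors (> 1).
#' @return unitless relative amount(s).
#' @export
relative_amount <- function(cq, spike_cq, e_target = 2, e_spike = 2) {
  if (is.na(e_target) || is.na(e_spike) || e_target <= 1 || e_spike <= 1)
    stop("amplification factors must be known and > 1", call. = FALSE)
  e_target^(-cq) / e_spike^(-spike_cq)
}

#' Percentage of RNA per gradient fraction
#'
#' @param amounts relative amounts, one per fraction (at least one > 0).
#' @return percentages summing to 100.
#' @export
fraction_distribution <- function(amounts) {
  if (all(amounts == 0)) stop("all amounts are zero", call. = FALSE)
  if (any(amounts < 0)) stop("negative amount", call. = FALSE)
  amounts / sum(amounts) * 100
}

#' Per-fraction RNA distribution from a qPCR Cq table
#'
#' Computes efficiency-corrected relative amounts per fraction and
#' replicate, converts each replicate to percentages across fractions, and
#' summarizes as mean and standard error.
#'
#' @param cq_table data.frame target, fraction, replicate, cq, spike_cq.
#' @param efficiencies named amplification factors `c(target=, spike=)`.
#' @return data.frame fraction, mean_pct, sem_pct, n.
#' @export
qpcr_fraction_distribution <- function(cq_table,
                                       efficiencies = c(target = 2, spike = 2)) {
  cq_table$amount <- relative_amount(cq_table$cq, cq_table$spike_cq,
                                     efficiencies[["target"]],
                                     efficiencies[["spike"]])
  reps <- split(cq_table, cq_table$replicate)
  pcts <- lapply(reps, function(r) {
    r <- r[order(r$fraction), ]
    data.frame(fraction = r$fraction, pct = fraction_distribution(r$amount))
  })
  all <- do.call(rbind, pcts)
  agg <- split(all$pct, all$fraction)
  data.frame(fraction = as.integer(names(agg)),
             mean_pct = vapply(agg, mean, numeric(1)),
             sem_pct = vapply(agg, function(x)
               if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
             n = lengths(agg), row.names = NULL)
}

# shared normalization for readthrough / frameshift percentages:
# 100 * (Fluc/Rluc)_test / (Fluc/Rluc)_control per replicate (within strain
# and condition), then mean +/- sem across replicates
.dlr_percent <- function(dlr, test_reporters, control_reporter, paired = TRUE) {
  if (any(dlr$rluc <= 0)) stop("non-positive Rluc measurement", call. = FALSE)
  dlr$ratio <- dlr$fluc / dlr$rluc
  key <- interaction(dlr$strain, dlr$condition, drop = TRUE)
  out <- list(); k <- 0L
  for (grp in split(dlr, key)) {
    ctrl <- grp[grp$reporter == control_reporter, , drop = FALSE]
    if (nrow(ctrl) == 0L || all(ctrl$ratio == 0))
      stop("missing or zero control reporter '", control_reporter, "'",
           call. = FALSE)
    for (rep_name in intersect(test_reporters, grp$reporter)) {
      test <- grp[grp$reporter == rep_name, , drop = FALSE]
      if (paired) {
        m <- match(test$replicate, ctrl$replicate)
        if (anyNA(m)) stop("unpaired replicate for reporter ", rep_name,
                           call. = FALSE)
        pct <- 100 * test$ratio / ctrl$ratio[m]
      } else {
        pct <- 100 * test$ratio / mean(ctrl$ratio)
      }
      k <- k + 1L
      out[[k]] <- data.frame(strain = test$strain[1], condition = test$condition[1],
                             reporter = rep_name, mean_pct = mean(pct),
                             sem_pct = if (length(pct) > 1)
                               sd(pct) / sqrt(length(pct)) else NA_real_,
                             n = length(pct), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stop-codon readthrough percentage
#'
#' Fluc/Rluc of each stop-codon reporter (UAA, UAG, UGA) normalized to the
#' sense-codon CAA control, per replicate, times 100.
#'
#' @param dlr dual-luciferase table (strain, condition, reporter, replicate,
#'   fluc, rluc).
#' @param test_reporters stop-codon reporters present in the table.
#' @param control_reporter control reporter name.
#' @param paired normalize replicate-by-replicate (default) or against the
#'   pooled mean control ratio.
#' @return data.frame strain, condition, reporter, mean_pct, sem_pct, n.
#' @export
readthrough_percent <- function(dlr, test_reporters = c("UAA", "UAG", "UGA"),
                                control_reporter = "CAA", paired = TRUE) {
  .dlr_percent(dlr, test_reporters, control_reporter, paired)
}

#' Programmed frameshift percentage
#'
#' Fluc/Rluc of the -1 / +1 frameshift reporters normalized to the frame-0
#' control for the same strain and condition.
#'
#' @inheritParams readthrough_percent
#' @export
frameshift_percent <- function(dlr, test_reporters = c("fs_minus1", "fs_plus1"),
                               control_reporter = "frame0", paired = TRUE) {
  .dlr_percent(dlr, test_reporters, control_reporter, paired)
}

#' Two-way ANOVA with Tukey post hoc on per-replicate percentages
#'
#' Convenience wrapper around `stats::aov` + `TukeyHSD` testing strain,
#' condition and their interaction — the standard routine, not re-derived.
#'
#' @param df data.frame with columns pct, strain, condition.
#' @return list(anova = summary table, tukey = TukeyHSD result).
#' @export
dlr_anova <- function(df) {
  fit <- aov(pct ~ strain * condition, data = df)
  list(anova = summary(fit), tukey = TukeyHSD(fit))
}
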