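#' Translation efficiency
#'
#' Translation efficiency (TE) of a transcript: the number of ribosome
#' footprints aligning to its CDS, normalized by the transcript's average
#' RNA-seq density and its CDS length. All arguments recycle, so vectors
#' of transcripts can be scored at once.
#'
#' @param cds_footprints Ribosome footprint count on the CDS (>= 0).
#' @param mean_rna_density Average RNA-seq density of the transcript
#'   (> 0).
#' @param cds_length CDS length in codons (> 0).
#' @return `cds_footprints / (mean_rna_density * cds_length)`.
#' @examples
#' translation_efficiency(100, 2, 50) # 1
#' @export
translation_efficiency <- function(cds_footprints, mean_rna_density,
                                   cds_length) {
  if (any(!is.finite(cds_footprints)) || any(cds_footprints < 0))
    stop("cds_footprints must be non-negative and finite")
  if (any(!is.finite(mean_rna_density)) || any(mean_rna_density <= 0))
    stop("mean_rna_density must be strictly positive")
  if (any(!is.finite(cds_length)) || any(cds_length <= 0))
    stop("cds_length must be strictly positive")
  cds_footprints / (mean_rna_density * cds_length)
}

#' Ribosome pause score of a uORF
#'
#' The highest single-position footprint density in the uORF divided by
#' the mean density over the remaining positions (the peak position —
#' the first one under ties — is excluded from the mean). A flat profile
#' scores 1; a single dominant pause site scores high.
#'
#' @param uorf_densities Non-negative per-position footprint densities,
#'   length >= 2.
#' @return The pause score.
#' @examples
#' pause_score(c(1, 1, 1, 9)) # 9
#' @export
pause_score <- function(uorf_densities) {
  d <- uorf_densities
  if (length(d) < 2)
    stop("pause score needs at least 2 positions")
  if (any(!is.finite(d)) || any(d < 0))
    stop("densities must be non-negative and finite")
  peak <- which.max(d)  # first position under ties
  rest <- mean(d[-peak])
  if (rest <= 0)
    stop("mean density excluding the peak is zero; pause score undefined")
  d[peak] / rest
}

#' Expression-binned Z-scores of translation-efficiency fold changes
#'
#' Sorts transcripts by expression level, partitions them into
#' consecutive bins of `bin_size`, and standardizes the log fold change
#' of translation efficiency within each bin:
#' `Z = (lfc - bin mean) / bin SD`. Binning by expression removes the
#' strong mean-variance dependence of fold-change estimates on coverage,
#' so Z-scores are comparable across expression levels. A final bin
#' smaller than `bin_size / 2` is merged into the previous bin.
#'
#' @param records Data frame with columns `expression` and `lfc` (log
#'   fold change of TE between conditions); other columns pass through.
#' @param bin_size Transcripts per expression bin.
#' @return `records` with added columns `bin` and `zscore`, sorted by
#'   expression; the merge rule used is recorded in
#'   `attr(, "bin_merge")`.
#' @examples
#' r <- data.frame(expression = 1:4, lfc = c(-1, 1, -1, 1))
#' binned_zscores(r, bin_size = 2)$zscore
#' @export
binned_zscores <- function(records, bin_size = 300) {
  stopifnot(is.data.frame(records),
            all(c("expression", "lfc") %in% names(records)))
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to standardize")
  if (any(!is.finite(records$lfc)))
    stop("log fold changes must be finite")
  records <- records[order(records$expression), , drop = FALSE]
  bin <- (seq_len(n) - 1) %/% bin_size + 1
  n_last <- sum(bin == max(bin))
  merged <- FALSE
  if (max(bin) > 1 && n_last < bin_size / 2) {
    bin[bin == max(bin)] <- max(bin) - 1
    merged <- TRUE
  }
  z <- numeric(n)
  for (b in unique(bin)) {
    idx <- bin == b
    s <- stats::sd(records$lfc[idx])
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero log-fold-change variance in expression bin %d", b))
    z[idx] <- (records$lfc[idx] - mean(records$lfc[idx])) / s
  }
  records$bin <- bin
  records$zscore <- z
  attr(records, "bin_merge") <-
    sprintf("bin_size=%d; final bin of %d %s", bin_size, n_last,
            if (merged) "merged into previous bin" else "kept")
  records
}

#' Correlate a uORF feature with stress-response Z-scores
#'
#' Pearson and Spearman correlations with two-sided p-values, plus the
#' ordinary least-squares slope of the Z-scores on the feature — the
#' statistics conventionally reported when relating uORF features
#' (length, TE, pause score) to the translational stress response.
#'
#' @param feature Numeric feature values (e.g. uORF lengths).
#' @param zscores Stress-response Z-scores, same length.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rs`,
#'   `spearman_p`, `slope`, `n`.
#' @examples
#' correlate_features(1:10, 2 * (1:10))$slope # 2
#' @export
correlate_features <- function(feature, zscores) {
  if (length(feature) != length(zscores))
    stop("feature and zscores must have equal length")
  if (length(feature) < 3)
    stop("need at least 3 observations")
  if (any(!is.finite(feature)) || any(!is.finite(zscores)))
    stop("inputs must be finite")
  if (stats::sd(feature) == 0 || stats::sd(zscores) == 0)
    stop("constant input vector: correlation undefined")
  pe <- stats::cor.test(feature, zscores, method = "pearson")
  sp <- stats::cor.test(feature, zscores, method = "spearman",
                        exact = FALSE)
  fit <- stats::lm(zscores ~ feature)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rs = unname(sp$estimate), spearman_p = sp$p.value,
       slope = unname(coef(fit)[2]), n = length(feature))
}

#' Generate a synthetic ribosome-profiling cohort
#'
#' Emulates the data structure of a single-uORF transcript cohort: uORF
#' lengths on a log scale, expression levels spanning several orders of
#' magnitude, per-position uORF footprint densities with one dominant
#' pause peak, and control/stress translation efficiencies whose log fold
#' change carries a planted linear effect of standardized log uORF length
#' plus Gaussian noise. The planted effect is what
#' [correlate_features()] should recover after [binned_zscores()].
#'
#' @param n Number of transcripts (>= 10). The default matches a
#'   typical curated single-uORF cohort size.
#' @param effect_size Coefficient of standardized log uORF length in the
#'   TE log fold change (0 = null cohort).
#' @param noise SD of the Gaussian noise on the log fold change.
#' @param seed Integer seed.
#' @param peak_height Mean fold elevation of the pause peak over the
#'   baseline density.
#' @return List with `profiles` (per-transcript list: `uorf_length`,
#'   `densities`) and `records` (data frame: `transcript_id`,
#'   `uorf_length`, `expression`, `cds_length`, `rna_density`,
#'   `footprints_control`, `footprints_stress`, `te_control`,
#'   `te_stress`, `lfc`, `pause`).
#' @examples
#' cohort <- generate_synthetic_profiles(n = 50, seed = 1)
#' nrow(cohort$records) # 50
#' @export
generate_synthetic_profiles <- function(n = 325, effect_size = 0.5,
                                        noise = 1, seed = 1L,
                                        peak_height = 8) {
  if (n < 10) stop("n must be at least 10")
  set.seed(as.integer(seed))
  uorf_length <- pmax(2L, round(rlnorm(n, meanlog = log(25), sdlog = 0.8)))
  expression <- rlnorm(n, meanlog = 3, sdlog = 1.5)
  cds_length <- pmax(100L, round(rlnorm(n, meanlog = log(450), sdlog = 0.5)))
  rna_density <- expression / cds_length

  profiles <- lapply(seq_len(n), function(i) {
    len <- uorf_length[i]
    base <- rgamma(len, shape = 2, rate = 2 / max(expression[i] / 50, 0.5))
    peak_pos <- sample.int(len, 1)
    base[peak_pos] <- base[peak_pos] +
      peak_height * max(mean(base), 0.1) * (0.5 + runif(1))
    list(transcript_id = sprintf("TX%04d", i), uorf_length = len,
         densities = base)
  })

  len_std <- as.numeric(scale(log(uorf_length)))
  lfc <- -0.5 + effect_size * len_std + rnorm(n, sd = noise)
  te_control <- rlnorm(n, meanlog = 0, sdlog = 0.4)
  te_stress <- te_control * 2^lfc
  footprints_control <- round(te_control * rna_density * cds_length * 50)
  footprints_stress <- round(te_stress * rna_density * cds_length * 50)

  records <- data.frame(
    transcript_id = vapply(profiles, `[[`, character(1), "transcript_id"),
    uorf_length = uorf_length,
    expression = expression,
    cds_length = cds_length,
    rna_density = rna_density,
    footprints_control = footprints_control,
    footprints_stress = footprints_stress,
    te_control = te_control,
    te_stress = te_stress,
    lfc = lfc,
    pause = vapply(profiles, function(p) pause_score(p$densities),
                   numeric(1))
  )
  list(profiles = profiles, records = records)
}

#' Read a per-transcript count table
#'
#' Tab-delimited with a header; required columns are checked and the rest
#' pass through untouched.
#'
#' @param path TSV file path.
#' @param required Column names that must be present.
#' @return Data frame.
#' @export
read_profile_table <- function(path,
                               required = c("transcript_id", "expression")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  tab
}

#' Read a uORF coordinate table
#'
#' BED-like, transcript-relative, 0-based half-open coordinates:
#' tab-delimited columns `transcript_id`, `start`, `end` (no header). The
#' uORF length in codons is derived as `(end - start) / 3`.
#'
#' @param path File path.
#' @return Data frame with `transcript_id`, `start`, `end`,
#'   `uorf_length`.
#' @export
read_uorf_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)[, 1:3]
  names(tab) <- c("transcript_id", "start", "end")
  if (any(tab$end <= tab$start))
    stop("uORF intervals must satisfy end > start (0-based half-open)")
  tab$uorf_length <- (tab$end - tab$start) / 3
  tab
}
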