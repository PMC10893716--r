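#' Kernel smoothing of per-CpG squared statistics
#'
#' Gaussian-kernel smoothing of squared per-CpG t statistics along the
#' genome, the first step of region detection. For CpG i,
#' `S_i = sum_j w_ij t_j^2 / sum_j w_ij` with
#' `w_ij = exp(-(pos_i - pos_j)^2 / (2 sigma^2))`, `sigma = lambda / C`,
#' and weights never crossing chromosome boundaries. Assuming unit-df
#' chi-square inputs, the Satterthwaite effective df of the weighted mean is
#' `nu_i = (sum w)^2 / sum w^2`.
#'
#' @param stats Per-CpG t statistics (finite).
#' @param chrom Chromosome per CpG.
#' @param pos 1-based position per CpG; strictly increasing within each
#'   chromosome (duplicates are an error).
#' @param lambda Bandwidth in bp (default 1000).
#' @param C Bandwidth scaling factor (default 2), so `sigma = lambda / C`.
#' @return A tibble: `chrom`, `pos`, `stat` (input t), `smoothed` (S) and
#'   `eff_df` (nu).
#' @export
kernel_smooth_stats <- function(stats, chrom, pos, lambda = 1000, C = 2) {
  stopifnot(length(stats) == length(pos), length(chrom) == length(pos),
            lambda > 0, C > 0)
  if (any(!is.finite(stats))) stop("Statistics must be finite.", call. = FALSE)
  sigma <- lambda / C
  out_s <- numeric(length(pos))
  out_df <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- pos[i]
    if (is.unsorted(p, strictly = FALSE)) {
      stop("Positions must be sorted within chromosome ", ch, ".", call. = FALSE)
    }
    if (anyDuplicated(p)) {
      stop("Duplicate positions on chromosome ", ch, ".", call. = FALSE)
    }
    dist2 <- outer(p, p, `-`)^2
    w <- exp(-dist2 / (2 * sigma^2))
    t2 <- stats[i]^2
    sw <- rowSums(w)
    out_s[i] <- as.vector(w %*% t2) / sw
    out_df[i] <- sw^2 / rowSums(w^2)
  }
  tibble::tibble(chrom = chrom, pos = pos, stat = stats,
                 smoothed = out_s, eff_df = out_df)
}

#' Scaled chi-square tail probabilities for smoothed statistics
#'
#' Models each smoothed squared statistic as a scaled chi-square: under the
#' null `S ~ chi^2_nu / nu`, so `p = P(chi^2_nu >= nu * S)`. Adds
#' BH-adjusted q-values.
#'
#' @param smoothed Tibble from [kernel_smooth_stats()] (or any table with
#'   `smoothed` and `eff_df` columns).
#' @return The input with `p` and `q` columns appended.
#' @export
satterthwaite_pvals <- function(smoothed) {
  stopifnot(all(smoothed$smoothed >= 0), all(smoothed$eff_df > 0))
  p <- stats::pchisq(smoothed$eff_df * smoothed$smoothed,
                     df = smoothed$eff_df, lower.tail = FALSE)
  smoothed$p <- p
  smoothed$q <- bh_adjust(p)
  smoothed
}

#' Agglomerate significant CpGs into regions
#'
#' Maximal runs of significant CpGs (q at or below `fdr`) in which
#' consecutive genomic gaps never exceed `lambda` form one candidate
#' region; regions with fewer than `min_cpgs` members are dropped.
#' Direction is `Hypo` if all member effects are negative, `Hyper` if all
#' positive, `Mixed` otherwise. Region significance is summarised as the
#' smallest member q.
#'
#' @param scored Tibble with `chrom`, `pos`, `q` (from
#'   [satterthwaite_pvals()]) plus per-CpG effects in `effect`.
#' @param lambda Maximum gap in bp between consecutive member CpGs
#'   (default 1000).
#' @param fdr Significance threshold on q (default 0.05).
#' @param min_cpgs Minimum CpGs per region (default 2).
#' @return A tibble of regions: `chrom`, `start`, `end`, `width`
#'   (`end - start + 1`, 1-based closed), `n_cpgs`, `min_q`, `direction`,
#'   `mean_effect`.
#' @export
group_regions <- function(scored, lambda = 1000, fdr = 0.05, min_cpgs = 2) {
  stopifnot(all(c("chrom", "pos", "q", "effect") %in% names(scored)))
  scored <- scored[order(scored$chrom, scored$pos), ]
  sig <- scored[scored$q <= fdr, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_dmr_table())
  sig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$pos) > lambda))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_cpgs = dplyr::n(),
      min_q = min(.data$q),
      direction = if (all(.data$effect < 0)) "Hypo"
                  else if (all(.data$effect > 0)) "Hyper" else "Mixed",
      mean_effect = mean(.data$effect),
      .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs) |>
    dplyr::mutate(width = .data$end - .data$start + 1L) |>
    dplyr::select("chrom", "start", "end", "width", "n_cpgs", "min_q",
                  "direction", "mean_effect") |>
    dplyr::arrange(.data$chrom, .data$start)
}

empty_dmr_table <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 width = integer(), n_cpgs = integer(), min_q = numeric(),
                 direction = character(), mean_effect = numeric())
}

#' Detect differentially methylated regions
#'
#' End-to-end region detection from a moderated per-CpG fit: squares the
#' moderated t statistics, smooths them along the genome with a Gaussian
#' kernel ([kernel_smooth_stats()]), converts to scaled chi-square tail
#' probabilities with Satterthwaite effective df
#' ([satterthwaite_pvals()]), applies BH adjustment, and agglomerates
#' significant CpGs into regions ([group_regions()]).
#'
#' @param fit A `moderated_fit` (or tibble with `probe_id`, `t`, `logfc_m`).
#' @param annotation Probe annotation providing `chrom` and `pos`.
#' @param lambda Bandwidth and maximum intra-region gap in bp (default 1000).
#' @param C Bandwidth scaling factor (default 2).
#' @param fdr FDR threshold on smoothed q-values (default 0.05).
#' @param min_cpgs Minimum CpGs per region (default 2).
#' @return A tibble of regions as in [group_regions()]; the per-CpG scored
#'   table is attached as attribute `"scored"`.
#' @export
dmr_table <- function(fit, annotation, lambda = 1000, C = 2, fdr = 0.05,
                      min_cpgs = 2) {
  tab <- if (inherits(fit, "probe_fit")) tidy(fit) else fit
  idx <- match(tab$probe_id, annotation$probe_id)
  if (anyNA(idx)) stop("Annotation missing fitted probe(s).", call. = FALSE)
  dat <- tibble::tibble(probe_id = tab$probe_id,
                        chrom = annotation$chrom[idx],
                        pos = annotation$pos[idx],
                        t = tab$t,
                        effect = tab$logfc_m)
  dat <- dat[order(dat$chrom, dat$pos), ]
  sm <- kernel_smooth_stats(dat$t, dat$chrom, dat$pos, lambda = lambda, C = C)
  sm <- satterthwaite_pvals(sm)
  sm$effect <- dat$effect
  sm$probe_id <- dat$probe_id
  out <- group_regions(sm, lambda = lambda, fdr = fdr, min_cpgs = min_cpgs)
  attr(out, "scored") <- sm
  out
}
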