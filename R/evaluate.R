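#' Precision of TE-derived TSS calls against a cap-signal gold standard
#'
#' A call is positive when the gold-standard track carries any mass
#' (> `min_mass`) within the closed window of `radius` bp around the
#' called position.
#'
#' @param calls `data.frame` with `chrom`, `position`, `strand`.
#' @param cap cap-signal container accepted by [coverage_window()].
#' @param radius window half-width in bp (default 100).
#' @param min_mass mass threshold for a positive (default 0).
#' @return list of class `validation_report`: `n_calls`, `n_positive`,
#'   `precision`, `positive` (logical vector), `window_mass`.
#' @export
tss_precision <- function(calls, cap, radius = 100L, min_mass = 0) {
  if (radius <= 0) stop("radius must be > 0")
  mass <- vapply(seq_len(nrow(calls)), function(i)
    sum(coverage_window(cap, calls$chrom[i], calls$position[i] - radius,
                        calls$position[i] + radius + 1L)), numeric(1))
  pos <- mass > min_mass
  structure(list(n_calls = nrow(calls), n_positive = sum(pos),
                 precision = if (nrow(calls)) mean(pos) else NA_real_,
                 positive = pos, window_mass = mass),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d/%d calls supported (precision %.3f)\n",
              x$n_positive, x$n_calls, x$precision))
  invisible(x)
}

#' Signal metaprofile around called positions
#'
#' One row per call, columns covering `-flank` to `+flank` around the
#' position, oriented by strand (`-` strand rows are reversed) and
#' zero-padded outside the chromosome.
#'
#' @param calls `data.frame` with `chrom`, `position`, `strand`.
#' @param signal signal container accepted by [coverage_window()].
#' @param flank half-width in bp (> 0).
#' @return list with `matrix` (`n_calls x (2*flank+1)`) and `mean_profile`
#'   (column means).
#' @export
metaprofile <- function(calls, signal, flank = 500L) {
  if (flank <= 0) stop("flank must be > 0")
  m <- t(vapply(seq_len(nrow(calls)), function(i) {
    v <- coverage_window(signal, calls$chrom[i], calls$position[i] - flank,
                         calls$position[i] + flank + 1L)
    if (calls$strand[i] == "-") rev(v) else v
  }, numeric(2L * flank + 1L)))
  colnames(m) <- as.character(seq(-flank, flank))
  list(matrix = m, mean_profile = colMeans(m))
}

#' Spearman concordance between two activity vectors
#'
#' Rank correlation with average ranks for ties; `NA` (with a warning)
#' when either vector has zero variance.
#'
#' @param a,b paired numeric vectors, length >= 3.
#' @return list with `rho` and `p_value` (both `NA` for degenerate
#'   input).
#' @export
spearman_concordance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must be paired")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
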