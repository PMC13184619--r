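#' Tumour-specific score
#'
#' \deqn{S = \frac{(T_e + 1)/T_t}{(N_e + 1)/N_t}}
#'
#' where \eqn{T_e}/\eqn{N_e} are the numbers of tumour / normal samples
#' expressing the transcript and \eqn{T_t}/\eqn{N_t} the arm totals
#' (testicular normal samples are excluded upstream, see
#' [tumour_specificity()]).  A pseudo-count of 1 on the expressing counts
#' keeps the score finite for transcripts never seen in normals.
#'
#' @param T_e,T_t,N_e,N_t expressing counts and totals (vectorized;
#'   totals must be > 0).
#' @return numeric score(s) `S > 0`.
#' @export
tumour_specific_score <- function(T_e, T_t, N_e, N_t) {
  if (any(T_t <= 0) || any(N_t <= 0)) stop("sample totals must be > 0")
  if (any(T_e < 0) || any(N_e < 0) || any(T_e > T_t) || any(N_e > N_t))
    stop("expressing counts must lie in [0, total]")
  ((T_e + 1) / T_t) / ((N_e + 1) / N_t)
}

#' Tumour-specificity scoring over an expression matrix
#'
#' Computes [tumour_specific_score()] per catalogue transcript from the
#' expressed matrix and cohort labels.  The normal arm pools
#' `adjacent_normal` and `normal` samples and excludes samples whose
#' `tissue` is `"testis"`.  The flag comparator defaults to the strict
#' `S > threshold`; `ge` is available since both conventions appear in
#' practice.
#'
#' @param expression an `expression_matrix` (or a logical matrix,
#'   transcripts x samples).
#' @param cohort cohort `data.frame` (see [read_cohort()]).
#' @param threshold flag threshold (default 8).
#' @param comparator `"gt"` (default) or `"ge"`.
#' @return `data.frame`: `teit_id`, `T_e`, `T_t`, `N_e`, `N_t`, `score`,
#'   `tumour_specific`.
#' @export
tumour_specificity <- function(expression, cohort, threshold = 8,
                               comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  ex <- if (inherits(expression, "expression_matrix")) expression$expressed
        else expression
  cohort <- validate_cohort(cohort)
  tum <- cohort$sample_id[cohort$condition == "tumour"]
  tissue <- if ("tissue" %in% names(cohort)) cohort$tissue else "generic"
  nrm <- cohort$sample_id[cohort$condition %in% c("adjacent_normal", "normal") &
                            tissue != "testis"]
  tum <- intersect(tum, colnames(ex)); nrm <- intersect(nrm, colnames(ex))
  if (length(tum) == 0 || length(nrm) == 0)
    stop("need at least one tumour and one non-testis normal sample")
  T_e <- rowSums(ex[, tum, drop = FALSE])
  N_e <- rowSums(ex[, nrm, drop = FALSE])
  S <- tumour_specific_score(T_e, length(tum), N_e, length(nrm))
  data.frame(teit_id = rownames(ex), T_e = T_e, T_t = length(tum),
             N_e = N_e, N_t = length(nrm), score = S,
             tumour_specific = if (comparator == "gt") S > threshold
                               else S >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag onco-exaptation candidates
#'
#' A catalogue transcript is an onco-exaptation candidate when its
#' assigned gene is on the oncogene list and its structural category ties
#' it to that gene (`annotated` or `chimeric`); intergenic transcripts
#' are never flagged.
#'
#' @param catalogue a `teit_catalogue`.
#' @param classes `data.frame` from [classify_catalogue()] (needs
#'   `teit_id`, `category`).
#' @param oncogenes character vector of gene symbols (ONGene-style list).
#' @return `data.frame`: `teit_id`, `gene_id`, `category`,
#'   `onco_exaptation`.
#' @export
onco_exaptation <- function(catalogue, classes, oncogenes) {
  tab <- catalogue$table
  cat_lab <- classes$category[match(tab$teit_id, classes$teit_id)]
  data.frame(teit_id = tab$teit_id, gene_id = tab$gene_id,
             category = cat_lab,
             onco_exaptation = !is.na(tab$gene_id) &
               tab$gene_id %in% oncogenes &
               cat_lab %in% c("annotated", "chimeric"),
             stringsAsFactors = FALSE)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' P-value from the exact conditional (hypergeometric) distribution with
#' fixed margins, two-tailed by summing all tables as or less probable
#' than the observed one.  The odds ratio is the sample estimate
#' \eqn{ad/bc}, with a Haldane correction of 0.5 added to every cell when
#' any cell is zero.
#'
#' @param a,b,c,d nonnegative integer cell counts (`a`,`b` first row).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("all-zero table")
  p <- fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  if (any(cells == 0)) cells <- cells + 0.5
  list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p_value = min(p, 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure: with p-values sorted ascending,
#' \eqn{q_i = \min_{j \ge i} p_j m / j}, clipped at 1, returned in the
#' original order.
#'
#' @param p p-values in `(0, 1]`.
#' @return FDR values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Tumour-type preferential expression
#'
#' For each transcript and cancer type, a 2x2 Fisher test of expressed /
#' not expressed against this-type / other-types over the tumour arm,
#' BH-adjusted across all transcript-type tests.  A transcript is called
#' preferential for a type when the odds ratio is at least `or_threshold`
#' and the FDR is below `fdr_threshold`.
#'
#' @param expression an `expression_matrix` or logical matrix.
#' @param cohort cohort `data.frame`.
#' @param or_threshold,fdr_threshold call thresholds (defaults 3, 0.05).
#' @return `data.frame` with the contingency cells, `odds_ratio`,
#'   `p_value`, `fdr`, `preferential`.
#' @export
preferential_expression <- function(expression, cohort, or_threshold = 3,
                                    fdr_threshold = 0.05) {
  ex <- if (inherits(expression, "expression_matrix")) expression$expressed
        else expression
  cohort <- validate_cohort(cohort)
  tum <- cohort[cohort$condition == "tumour", , drop = FALSE]
  tum <- tum[tum$sample_id %in% colnames(ex), , drop = FALSE]
  types <- unique(tum$cancer_type)
  if (length(types) < 2) stop("need at least 2 cancer types")
  rows <- list()
  for (id in rownames(ex)) {
    e <- ex[id, tum$sample_id]
    for (ty in types) {
      this <- tum$cancer_type == ty
      a <- sum(e & this); b <- sum(e & !this)
      cc <- sum(!e & this); dd <- sum(!e & !this)
      ft <- fisher_exact_2x2(a, b, cc, dd)
      rows[[paste(id, ty)]] <- data.frame(
        teit_id = id, cancer_type = ty, a = a, b = b, c = cc, d = dd,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$preferential <- out$odds_ratio >= or_threshold & out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

# two-sided Wilcoxon rank-sum; exact permutation for combined n <= 12,
# normal approximation with tie correction otherwise
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n <= 12) {
    splits <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[splits], nrow = n1))
    EW <- n1 * (n + 1) / 2
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    stat <- W - n1 * (n1 + 1) / 2  # U statistic
    return(list(statistic = stat, p_value = p, method = "exact"))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "normal")
}

# log-rank test and hazard ratio for a two-level grouping
logrank_hr <- function(time, event, group) {
  f <- factor(group, levels = c(FALSE, TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ f)
  chisq <- unname(sd$chisq)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  list(chisq = chisq, p_value = p, hazard_ratio = unname(hr))
}

#' Clinical association tests over an expression or activity matrix
#'
#' Per matrix row (transcript or TE family):
#' * `differential` — Wilcoxon rank-sum of the values in tumour vs
#'   normal/adjacent samples (exact permutation when the combined n is at
#'   most 12, normal approximation with tie correction otherwise);
#' * `stage` — Kruskal-Wallis across tumour stages;
#' * `survival` — log-rank test between expressing and non-expressing
#'   tumour samples (`group = "expressed"`: value >= 1) or above/below
#'   the median (`group = "median"`, for continuous family activity),
#'   with the hazard ratio of the expressing/high group.
#'
#' P-values are BH-adjusted within each analysis family separately.
#' Units with a degenerate grouping (fewer than 2 samples per group) are
#' skipped; their ids and reasons are returned in the `skipped`
#' attribute.
#'
#' @param values numeric matrix, units x samples.
#' @param cohort cohort `data.frame`.
#' @param tests subset of `c("differential", "stage", "survival")`.
#' @param group survival grouping rule, `"expressed"` or `"median"`.
#' @return named list of `data.frame`s (one per requested test).
#' @export
clinical_tests <- function(values, cohort,
                           tests = c("differential", "stage", "survival"),
                           group = c("expressed", "median")) {
  group <- match.arg(group)
  cohort <- validate_cohort(cohort)
  cohort <- cohort[cohort$sample_id %in% colnames(values), , drop = FALSE]
  skipped <- list()
  res <- list()
  tum <- cohort$sample_id[cohort$condition == "tumour"]
  nrm <- cohort$sample_id[cohort$condition %in% c("adjacent_normal", "normal")]

  if ("differential" %in% tests) {
    rows <- list()
    for (id in rownames(values)) {
      if (length(tum) < 2 || length(nrm) < 2) {
        skipped[[length(skipped) + 1L]] <- c(id, "differential",
                                             "fewer than 2 samples per arm")
        next
      }
      if (length(unique(values[id, c(tum, nrm)])) == 1L) {
        # constant values carry no rank information
        rows[[id]] <- data.frame(unit = id, statistic = 0, p_value = 1,
                                 effect = 0, stringsAsFactors = FALSE)
        next
      }
      wt <- wilcoxon_rank_sum(values[id, tum], values[id, nrm])
      rows[[id]] <- data.frame(unit = id, statistic = wt$statistic,
                               p_value = wt$p_value,
                               effect = median(values[id, tum]) -
                                 median(values[id, nrm]),
                               stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    if (!is.null(d)) { d$fdr <- bh_adjust(d$p_value); rownames(d) <- NULL }
    res$differential <- d
  }

  if ("stage" %in% tests) {
    st <- cohort[cohort$sample_id %in% tum & !is.na(cohort$stage), , drop = FALSE]
    rows <- list()
    for (id in rownames(values)) {
      tab <- table(st$stage)
      if (length(tab) < 2 || any(tab < 2)) {
        skipped[[length(skipped) + 1L]] <- c(id, "stage", "degenerate stage groups")
        next
      }
      v <- values[id, st$sample_id]
      if (length(unique(v)) == 1L) {
        # all ranks tied: the tie-corrected statistic degenerates to 0
        rows[[id]] <- data.frame(unit = id, statistic = 0, p_value = 1,
                                 effect = NA_real_, stringsAsFactors = FALSE)
        next
      }
      kw <- kruskal.test(v, factor(st$stage))
      rows[[id]] <- data.frame(unit = id, statistic = unname(kw$statistic),
                               p_value = kw$p.value,
                               effect = NA_real_, stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    if (!is.null(d)) { d$fdr <- bh_adjust(d$p_value); rownames(d) <- NULL }
    res$stage <- d
  }

  if ("survival" %in% tests) {
    sv <- cohort[!is.na(cohort$survival_time), , drop = FALSE]
    rows <- list()
    for (id in rownames(values)) {
      v <- values[id, sv$sample_id]
      g <- if (group == "expressed") v >= 1 else v > median(v)
      if (sum(g) < 2 || sum(!g) < 2) {
        skipped[[length(skipped) + 1L]] <- c(id, "survival",
                                             "fewer than 2 samples per group")
        next
      }
      lr <- logrank_hr(sv$survival_time, sv$event, g)
      rows[[id]] <- data.frame(unit = id, statistic = lr$chisq,
                               p_value = lr$p_value,
                               effect = lr$hazard_ratio,
                               stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    if (!is.null(d)) { d$fdr <- bh_adjust(d$p_value); rownames(d) <- NULL }
    res$survival <- d
  }

  attr(res, "skipped") <- if (length(skipped))
    do.call(rbind, lapply(skipped, function(x)
      data.frame(unit = x[1], test = x[2], reason = x[3],
                 stringsAsFactors = FALSE)))
  res
}

#' Tau tissue-specificity index
#'
#' \deqn{\tau = \frac{\sum_i (1 - x_i / x_{max})}{n - 1}}
#'
#' on nonnegative mean expression per tissue: 0 for perfectly uniform
#' expression, 1 for single-tissue expression.
#'
#' @param x nonnegative mean expression per tissue (`n >= 2`, not all
#'   zero).
#' @return tau in `[0, 1]`.
#' @export
tau_index <- function(x) {
  if (length(x) < 2) stop("tau requires at least 2 tissues")
  if (any(x < 0)) stop("expression means must be nonnegative")
  if (all(x == 0)) stop("all-zero expression vector")
  sum(1 - x / max(x)) / (length(x) - 1)
}
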