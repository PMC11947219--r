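# Case-level comparison layer: Shapiro-Wilk-gated two- and three-group tests,
# TAM-ratio comparisons, and the integration data-accounting arithmetic.

shapiro_p <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison of case-level values
#'
#' Shapiro-Wilk is run on each group at \code{alpha_norm}; when both pass, a
#' two-tailed unpaired t-test is used (Welch variant when the variance ratio
#' exceeds \code{welch_ratio}), otherwise a two-tailed Mann-Whitney U test.
#' A constant group has no defined normality and falls to the nonparametric
#' branch (logged in the result).
#'
#' @param a,b numeric vectors of per-case values (>= 3 each).
#' @param alpha_norm normality gate level (default 0.05).
#' @param welch_ratio variance ratio above which Welch's t replaces Student's
#'   t (default 4).
#' @param paired paired comparison (default FALSE).
#' @return object of class \code{comparison_result}: test, statistic, p_value,
#'   shapiro_p, normal (gate outcome), means, n, notes.
#' @export
compare_two_groups <- function(a, b, alpha_norm = 0.05, welch_ratio = 4,
                               paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 cases per group", call. = FALSE)
  sw <- c(shapiro_p(a), shapiro_p(b))
  notes <- character()
  if (any(is.na(sw))) notes <- "constant group: normality undefined, nonparametric branch"
  normal <- !any(is.na(sw)) && all(sw > alpha_norm)
  if (normal) {
    vr <- max(stats::var(a), stats::var(b)) / max(min(stats::var(a), stats::var(b)),
                                                  .Machine$double.eps)
    welch <- vr > welch_ratio
    tt <- stats::t.test(a, b, var.equal = !welch, paired = paired)
    test <- if (welch) "Welch t" else "t"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    tt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
    test <- "Mann-Whitney U"
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 shapiro_p = sw, normal = normal,
                 means = c(mean(a), mean(b)), n = c(length(a), length(b)),
                 notes = notes),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  cat(sprintf("  Shapiro-Wilk p: %s -> %s branch\n",
              paste(signif(x$shapiro_p, 3), collapse = ", "),
              if (x$normal) "parametric" else "nonparametric"))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

# Dunnett's T3 pairwise comparisons: Welch t statistics with Welch df and a
# studentized-maximum-modulus multiplicity adjustment (Sidak form).
dunnett_t3 <- function(values, groups) {
  gl <- unique(groups)
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, df = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_)
  for (k in seq_len(m)) {
    x <- values[groups == pairs[1, k]]; y <- values[groups == pairs[2, k]]
    v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
    se <- sqrt(v1 + v2)
    t <- (mean(x) - mean(y)) / se
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    p <- 2 * stats::pt(-abs(t), df)
    out$statistic[k] <- t; out$df[k] <- df; out$p_raw[k] <- p
    out$p_adj[k] <- min(1, 1 - (1 - p)^m)
  }
  out
}

#' Normality-gated three-group comparison with post-hoc pairwise tests
#'
#' All groups normal (Shapiro-Wilk at \code{alpha_norm}): one-way ANOVA with
#' Tukey's HSD pairwise comparisons. Otherwise: Kruskal-Wallis with Dunnett's
#' T3-style pairwise comparisons (Welch t statistics, studentized-maximum-
#' modulus adjustment).
#'
#' @param values numeric vector of case-level values.
#' @param groups group label per value (exactly 3 groups, >= 3 cases each).
#' @param alpha_norm normality gate level (default 0.05).
#' @return object of class \code{comparison_result} with omnibus test,
#'   p_value, pairwise table, shapiro_p per group.
#' @export
compare_three_groups <- function(values, groups, alpha_norm = 0.05) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 3) stop("need exactly 3 groups", call. = FALSE)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3]
  if (length(small))
    stop(sprintf("group '%s' has fewer than 3 cases", small[1]), call. = FALSE)
  sw <- vapply(gl, function(g) shapiro_p(values[groups == g]), 0)
  normal <- !any(is.na(sw)) && all(sw > alpha_norm)
  if (normal) {
    fit <- stats::aov(values ~ factor(groups))
    an <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)[[1]]
    pairwise <- data.frame(comparison = rownames(tuk),
                           diff = tuk[, "diff"], p_adj = tuk[, "p adj"],
                           row.names = NULL)
    res <- list(test = "ANOVA + Tukey", statistic = an$`F value`[1],
                p_value = an$`Pr(>F)`[1], pairwise = pairwise)
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    t3 <- dunnett_t3(values, groups)
    pairwise <- data.frame(comparison = paste(t3$group1, t3$group2, sep = "-"),
                           diff = t3$statistic, p_adj = t3$p_adj)
    res <- list(test = "Kruskal-Wallis + Dunnett T3",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = pairwise)
  }
  structure(c(res, list(shapiro_p = sw, normal = normal,
                        n = as.integer(sizes[gl]), notes = character(),
                        means = vapply(gl, function(g) mean(values[groups == g]), 0))),
            class = "comparison_result")
}

#' Compare classical versus alternative TAM abundance within a region
#'
#' Case-averaged abundances of the two TAM populations within the stated
#' region are compared via \code{\link{compare_two_groups}}. Cases lacking the
#' region are dropped (logged via message).
#'
#' @param cells cell table with population and region labels.
#' @param classical,alternative the two TAM population labels.
#' @param region region class to restrict to ("AntoniA" or "AntoniB").
#' @param ... passed to \code{\link{compare_two_groups}}.
#' @return a \code{comparison_result}; means are (classical, alternative).
#' @export
tam_ratio_comparison <- function(cells, classical, alternative, region, ...) {
  sub <- cells[cells$region == region, , drop = FALSE]
  dropped <- setdiff(unique(cells$case_id), unique(sub$case_id))
  if (length(dropped))
    message(sprintf("region '%s' absent for case(s) %s: dropped", region,
                    paste(dropped, collapse = ", ")))
  if (nrow(sub) == 0) stop("no cells in the requested region", call. = FALSE)
  ab <- abundance_table(sub, level = "case", exclude_regions = character())
  for (p in c(classical, alternative))
    if (!p %in% colnames(ab)) stop(sprintf("population '%s' absent", p), call. = FALSE)
  compare_two_groups(ab[[classical]], ab[[alternative]], ...)
}

#' Integration data accounting: alignment and matching percentages
#'
#' Given total, aligned and (above a match-score threshold) matched cell
#' counts from a cross-modal integration, reports aligned% of total (2 dp) and
#' matched% of aligned (1 dp).
#'
#' @param n_total,n_aligned,n_matched cell counts with
#'   0 <= n_matched <= n_aligned <= n_total.
#' @param score_threshold the match-score threshold used (default 0.3,
#'   recorded in the report).
#' @return list with aligned_pct, matched_pct, score_threshold and the input
#'   counts.
#' @export
match_accounting <- function(n_total, n_aligned, n_matched,
                             score_threshold = 0.3) {
  if (!(0 <= n_matched && n_matched <= n_aligned && n_aligned <= n_total))
    stop("counts must satisfy 0 <= n_matched <= n_aligned <= n_total",
         call. = FALSE)
  list(aligned_pct = round(100 * n_aligned / n_total, 2),
       matched_pct = round(100 * n_matched / n_aligned, 1),
       score_threshold = score_threshold,
       n_total = n_total, n_aligned = n_aligned, n_matched = n_matched)
}
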