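#' Normality gate for test selection
#'
#' Parametric tests are used only when every group passes a
#' Shapiro-Wilk normality test at `alpha`; one failing group routes the
#' whole comparison to the nonparametric branch (the conservative
#' reading when groups disagree). Zero-variance groups are degenerate
#' for Shapiro-Wilk and are routed nonparametric with a warning.
#'
#' @param samples a numeric vector or list of numeric groups, each with
#'   at least 3 observations.
#' @param alpha significance level of the normality test.
#' @return logical: `TRUE` when the parametric branch applies.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  for (g in samples) {
    if (length(g) < 3L) stop("too few observations")
    if (stats::sd(g) == 0) {
      warning("zero-variance group: routed to the nonparametric branch")
      return(FALSE)
    }
  }
  all(vapply(samples, function(g) stats::shapiro.test(g)$p.value,
             numeric(1)) > alpha)
}

# Dunn's post-hoc test after Kruskal-Wallis: pairwise z statistics on
# mean ranks of the pooled sample, with tie correction and Bonferroni
# adjustment. No pre-installed package provides this test.
dunn_test <- function(groups, p_adjust = "bonferroni") {
  k <- length(groups)
  x <- unlist(groups)
  g <- rep(seq_len(k), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    (rbar[i] - rbar[j]) / se
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  data.frame(comparison = paste(nm[pairs[1, ]], nm[pairs[2, ]], sep = " - "),
             z = as.numeric(z), p = pmin(1, p))
}

# Dunn's post-hoc after Friedman: pairwise z on within-block rank sums.
friedman_dunn_test <- function(mat, p_adjust = "bonferroni") {
  # mat: n blocks (subjects) x k treatments
  n <- nrow(mat); k <- ncol(mat)
  rk <- t(apply(mat, 1, rank))
  rsum <- colSums(rk)
  pairs <- utils::combn(k, 2)
  se <- sqrt(n * k * (k + 1) / 6)
  z <- apply(pairs, 2, function(ij) (rsum[ij[1]] - rsum[ij[2]]) / se)
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  nm <- colnames(mat) %||% paste0("g", seq_len(k))
  data.frame(comparison = paste(nm[pairs[1, ]], nm[pairs[2, ]], sep = " - "),
             z = as.numeric(z), p = pmin(1, p))
}

#' Normality-gated group comparison
#'
#' Implements the decision policy used throughout the analyses. Two
#' groups: unpaired t test or Mann-Whitney (paired t / Wilcoxon signed
#' rank when paired), chosen by [normality_gate()]. More than two
#' groups: one-way ANOVA with a Tukey or Dunnett post-hoc when
#' parametric, Kruskal-Wallis with Dunn's post-hoc otherwise; for
#' paired designs, repeated-measures one-way ANOVA with Tukey contrasts
#' or a Friedman test with Dunn's post-hoc.
#'
#' @param groups list of numeric groups (named if possible); paired
#'   designs require equal lengths, observations aligned by subject.
#' @param design `"unpaired"` or `"paired"`.
#' @param alpha significance level.
#' @param posthoc `"tukey"` (default) or `"dunnett"` for the parametric
#'   k-group branch; Dunnett compares every group with the first.
#' @param p_adjust adjustment for Dunn's pairwise p values.
#' @return object of class `stat_decision`: `test_name`, `p_value`
#'   (omnibus), `parametric`, `effect_direction` (`increase`,
#'   `decrease` or `none`, second group relative to first; only for 2
#'   groups), `n_per_group`, and a `posthoc` table for k > 2.
#' @export
compare_groups <- function(groups, design = c("unpaired", "paired"),
                           alpha = 0.05, posthoc = c("tukey", "dunnett"),
                           p_adjust = "bonferroni") {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  stopifnot(is.list(groups), length(groups) >= 2L)
  k <- length(groups)
  if (design == "paired" && length(unique(lengths(groups))) != 1L) {
    stop("paired groups must have equal lengths")
  }
  parametric <- normality_gate(groups, alpha = alpha)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  names(groups) <- nm
  post <- NULL
  if (k == 2L) {
    a <- groups[[1]]; b <- groups[[2]]
    if (parametric) {
      ht <- stats::t.test(b, a, paired = design == "paired")
      test_name <- if (design == "paired") "paired t test" else "unpaired t test"
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(b, a, paired = design == "paired", exact = FALSE))
      test_name <- if (design == "paired") "Wilcoxon signed-rank test"
                   else "Mann-Whitney test"
    }
    p <- ht$p.value
    loc <- if (parametric) mean(b) - mean(a)
           else stats::median(b) - stats::median(a)
    direction <- if (is.na(p) || p > alpha || loc == 0) "none"
                 else if (loc > 0) "increase" else "decrease"
  } else {
    direction <- NA_character_
    val <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(nm, lengths(groups)), levels = nm)
    if (design == "unpaired") {
      if (parametric) {
        fit <- stats::aov(val ~ fac)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        test_name <- "one-way ANOVA"
        if (posthoc == "tukey") {
          tk <- stats::TukeyHSD(fit)$fac
          post <- data.frame(comparison = rownames(tk),
                             estimate = tk[, "diff"], p = tk[, "p adj"],
                             row.names = NULL)
          test_name <- paste(test_name, "+ Tukey")
        } else {
          em <- emmeans::emmeans(fit, "fac")
          ct <- as.data.frame(emmeans::contrast(em, "trt.vs.ctrl", ref = 1))
          post <- data.frame(comparison = ct$contrast,
                             estimate = ct$estimate, p = ct$p.value)
          test_name <- paste(test_name, "+ Dunnett")
        }
      } else {
        p <- stats::kruskal.test(val, fac)$p.value
        post <- dunn_test(groups, p_adjust = p_adjust)
        test_name <- "Kruskal-Wallis + Dunn"
      }
    } else {
      mat <- do.call(cbind, groups)
      subj <- factor(rep(seq_len(nrow(mat)), k))
      if (parametric) {
        rm_dat <- data.frame(val = as.vector(mat),
                             fac = factor(rep(nm, each = nrow(mat)),
                                          levels = nm),
                             subj = subj)
        # do.call embeds the data in the stored call so emmeans can
        # re-fit the aovlist outside this frame
        fit <- do.call(stats::aov,
                       list(val ~ fac + Error(subj), data = rm_dat))
        p <- summary(fit)[["Error: Within"]][[1]][["Pr(>F)"]][1]
        em <- suppressMessages(emmeans::emmeans(fit, "fac", data = rm_dat))
        ct <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
        post <- data.frame(comparison = ct$contrast, estimate = ct$estimate,
                           p = ct$p.value)
        test_name <- "repeated-measures one-way ANOVA + Tukey"
      } else {
        p <- stats::friedman.test(mat)$p.value
        post <- friedman_dunn_test(mat, p_adjust = p_adjust)
        test_name <- "Friedman + Dunn"
      }
    }
  }
  structure(list(test_name = test_name, p_value = p,
                 parametric = parametric, effect_direction = direction,
                 n_per_group = lengths(groups), design = design,
                 alpha = alpha, posthoc = post),
            class = "stat_decision")
}

#' @export
print.stat_decision <- function(x, ...) {
  cat(sprintf("<stat_decision> %s: p = %.4g (%s)%s\n", x$test_name,
              x$p_value, if (x$parametric) "parametric" else "nonparametric",
              if (!is.na(x$effect_direction %||% NA))
                paste0(", direction: ", x$effect_direction) else ""))
  invisible(x)
}

#' Classify a per-subject change as improvement, deficit or no change
#'
#' Compares a metric before and after a manipulation with the gated
#' two-sample policy and maps the significant direction onto functional
#' semantics: a significant change in the gain direction is an
#' improvement (e.g. an increase in angular excursion, stride length or
#' step height; a *decrease* in burst duration or swing-phase CV), the
#' opposite a deficit; non-significant changes are no change.
#'
#' @param pre,post numeric samples of the metric before and after.
#' @param gain_direction `"increase_is_gain"` or `"decrease_is_gain"`.
#' @param design `"unpaired"` (default: per-mouse cycle samples) or
#'   `"paired"`.
#' @param alpha significance level.
#' @return object of class `change_class`: `category` in
#'   `c("improvement", "deficit", "no_change")`, the underlying
#'   `decision`, and the `basis` direction semantics.
#' @export
classify_change <- function(pre, post,
                            gain_direction = c("increase_is_gain",
                                               "decrease_is_gain"),
                            design = "unpaired", alpha = 0.05) {
  gain_direction <- match.arg(gain_direction)
  d <- compare_groups(list(pre = pre, post = post), design = design,
                      alpha = alpha)
  category <- if (d$effect_direction == "none") {
    "no_change"
  } else if ((d$effect_direction == "increase") ==
             (gain_direction == "increase_is_gain")) {
    "improvement"
  } else "deficit"
  structure(list(category = category, decision = d,
                 basis = gain_direction),
            class = "change_class")
}

#' @export
print.change_class <- function(x, ...) {
  cat(sprintf("<change_class> %s (%s, p = %.4g)\n", x$category,
              x$decision$test_name, x$decision$p_value))
  invisible(x)
}
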