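#' Normality-gated test selection
#'
#' Implements the study's decision rule: every group is screened with the
#' Shapiro-Wilk test at `alpha`; for two groups a (paired, when pairing ids
#' are present) two-tailed Student's t-test is chosen when all groups pass,
#' otherwise the two-tailed Mann-Whitney test; for more than two groups the
#' Kruskal-Wallis test followed by Dunn's multiple comparisons is used.
#'
#' @param values numeric measurements (one per animal).
#' @param groups condition label per value.
#' @param pairing optional pairing id per value (paired designs).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return A `test_plan`: list with `test` (one of `"t"`, `"paired_t"`,
#'   `"mann_whitney"`, `"kruskal_dunn"`), `shapiro_p` per group, `normal`.
#' @export
choose_test <- function(values, groups, pairing = NULL, alpha = 0.05) {
  groups <- factor(groups)
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 3L))
    stop("each group needs n >= 3 for the Shapiro-Wilk gate", call. = FALSE)
  shapiro_p <- vapply(split_vals, function(v) stats::shapiro.test(v)$p.value,
                      numeric(1))
  normal <- all(shapiro_p >= alpha)
  test <- if (nlevels(groups) > 2L) "kruskal_dunn"
          else if (!normal) "mann_whitney"
          else if (!is.null(pairing)) "paired_t" else "t"
  structure(list(test = test, shapiro_p = shapiro_p, normal = normal,
                 alpha = alpha),
            class = "test_plan")
}

#' Run the planned hypothesis test(s)
#'
#' Two-tailed throughout. For `"kruskal_dunn"` the omnibus Kruskal-Wallis
#' p-value is returned together with Dunn's pairwise comparisons
#' (Bonferroni-adjusted over the performed comparisons; all-vs-control when
#' `control` is given, otherwise all pairs).
#'
#' @param plan a `test_plan` from [choose_test()].
#' @param values,groups,pairing as in [choose_test()].
#' @param control optional reference level for Dunn comparisons.
#' @return list with `test`, `p` (omnibus or two-group p-value) and, for
#'   Dunn, a `comparisons` data.frame (`group1`, `group2`, `z`, `p`,
#'   `p_adjusted`).
#' @export
run_tests <- function(plan, values, groups, pairing = NULL, control = NULL) {
  stopifnot(inherits(plan, "test_plan"))
  groups <- factor(groups)
  switch(plan$test,
    t = list(test = "t",
             p = stats::t.test(values ~ groups, var.equal = TRUE)$p.value),
    paired_t = {
      sp <- split(values, groups)
      ord <- split(pairing, groups)
      stopifnot(identical(sort(ord[[1]]), sort(ord[[2]])))
      a <- sp[[1]][order(ord[[1]])]; b <- sp[[2]][order(ord[[2]])]
      list(test = "paired_t", p = stats::t.test(a, b, paired = TRUE)$p.value)
    },
    mann_whitney = {
      sp <- split(values, groups)
      ties <- anyDuplicated(values) > 0
      list(test = "mann_whitney",
           p = stats::wilcox.test(sp[[1]], sp[[2]], exact = !ties,
                                  correct = FALSE)$p.value)
    },
    kruskal_dunn = {
      kw <- stats::kruskal.test(values, groups)
      list(test = "kruskal_dunn", p = kw$p.value,
           comparisons = dunn_test(values, groups, control = control))
    },
    stop("unknown test in plan", call. = FALSE))
}

#' Dunn's multiple-comparison test
#'
#' Rank-based post-hoc comparisons after Kruskal-Wallis: standard tie-
#' corrected z statistics on mean ranks, two-sided normal p-values, and
#' Bonferroni adjustment over the performed comparisons (all pairs, or
#' all-vs-control when `control` is given).
#'
#' @param values,groups measurements and condition labels.
#' @param control optional reference level.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data.frame: `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, control = NULL,
                      p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- if (is.null(control)) utils::combn(lv, 2, simplify = FALSE)
           else lapply(setdiff(lv, control), function(g) c(control, g))
  rows <- lapply(pairs, function(pr) {
    g1 <- pr[1]; g2 <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Cohen's d with asymptotic uncertainty
#'
#' \eqn{d = (\bar{b} - \bar{a}) / s_p} with the pooled standard deviation
#' \eqn{s_p}, and standard error
#' \eqn{\sqrt{(n_a + n_b)/(n_a n_b) + d^2 / (2 (n_a + n_b))}}. The
#' classical (uncorrected) definition is the default; `hedges = TRUE`
#' applies the small-sample correction.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param hedges apply Hedges' small-sample correction?
#' @return list with `d`, `se`.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))$d  # 2
cohens_d <- function(a, b, hedges = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(b) - mean(a)) / sp
  if (hedges) d <- d * (1 - 3 / (4 * (na + nb) - 9))
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  list(d = d, se = se)
}

#' Common-language effect size with U-statistic uncertainty
#'
#' \eqn{\theta = P(a > b) + \frac{1}{2} P(a = b)}, estimated over all
#' \eqn{n_a n_b} pairs; the standard error comes from the two-sample
#' U-statistic asymptotics via per-observation placements (DeLong-style):
#' \eqn{\mathrm{SE}^2 = S_a^2/n_a + S_b^2/n_b} with the placement variances
#' \eqn{S^2}. Under no effect \eqn{\theta = 0.5}.
#'
#' @param a,b numeric samples.
#' @return list with `theta`, `se`.
#' @export
#' @examples
#' cles_theta(c(1, 3), c(2, 4))$theta  # 0.25
cles_theta <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both groups must be non-empty", call. = FALSE)
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  theta <- mean(cmp)
  p_a <- rowMeans(cmp)   # placement of each a among the b's
  p_b <- 1 - colMeans(cmp)
  va <- if (na > 1L) stats::var(p_a) else 0
  vb <- if (nb > 1L) stats::var(p_b) else 0
  list(theta = theta, se = sqrt(va / na + vb / nb))
}

#' Joint p-value / effect-size significance decision
#'
#' The study calls a difference significant only when the p-value is below
#' `alpha` AND the effect size clears its boundary (\eqn{d_c = 1} for
#' Cohen's d, \eqn{\theta_c = 0.5} for the common-language effect size).
#' Two readings of the boundary rule are provided: `"exclude"` (default)
#' requires the interval estimate +/- uncertainty to exclude the boundary;
#' `"beyond"` only requires the point estimate to lie beyond it.
#'
#' @param p p-value.
#' @param estimate effect-size point estimate.
#' @param uncertainty its standard uncertainty (>= 0).
#' @param boundary the boundary value (1 for d, 0.5 for theta).
#' @param alpha p-value cutoff (default 0.05).
#' @param rule `"exclude"` or `"beyond"`.
#' @param null_value the no-effect value of the scale (0 for d, 0.5 for
#'   theta; guessed from `boundary` by default).
#' @return list with `significant`, `p_ok`, `effect_ok`,
#'   `boundary_in_interval`.
#' @export
significance_decision <- function(p, estimate, uncertainty, boundary,
                                  alpha = 0.05,
                                  rule = c("exclude", "beyond"),
                                  null_value = if (boundary == 0.5) 0.5 else 0) {
  rule <- match.arg(rule)
  if (uncertainty < 0) stop("uncertainty must be >= 0", call. = FALSE)
  inside <- abs(estimate - boundary) <= uncertainty
  effect_ok <- if (rule == "exclude") !inside
               else abs(estimate - null_value) >= abs(boundary - null_value)
  p_ok <- p < alpha
  list(significant = p_ok && effect_ok, p_ok = p_ok, effect_ok = effect_ok,
       boundary_in_interval = inside)
}

#' Percent change of a group mean
#'
#' Reduction convention: `100 * (control - treated) / control`.
#'
#' @param control_mean,treated_mean group means; `control_mean` non-zero.
#' @return Percent change (positive for reductions).
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (any(control_mean == 0)) stop("zero control mean", call. = FALSE)
  100 * (control_mean - treated_mean) / control_mean
}

#' Delta-delta-Ct fold change
#'
#' \eqn{FC = 2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref})_{cond} -
#' (Ct_{target} - Ct_{ref})_{ctrl}}. Vector inputs (technical replicates)
#' are averaged per term first.
#'
#' @param ct_target_ctrl,ct_target_cond target-gene Ct values in control
#'   and condition.
#' @param ct_ref_ctrl,ct_ref_cond reference-gene Ct values.
#' @return list with `ddct`, `fold_change`.
#' @export
#' @examples
#' ddct_fold_change(22, 20, 15, 15)$fold_change  # 4
ddct_fold_change <- function(ct_target_ctrl, ct_target_cond,
                             ct_ref_ctrl, ct_ref_cond) {
  vals <- c(ct_target_ctrl, ct_target_cond, ct_ref_ctrl, ct_ref_cond)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_cond) - mean(ct_ref_cond)) -
          (mean(ct_target_ctrl) - mean(ct_ref_ctrl))
  list(ddct = ddct, fold_change = 2^(-ddct))
}
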