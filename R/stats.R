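#' Brown-Forsythe (median-centered) Levene test
#'
#' One-way ANOVA on the absolute deviations from the group medians; the
#' robust default for testing variance homogeneity before a one-way ANOVA.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  meds <- tapply(values, groups, stats::median)
  z <- abs(values - meds[groups])
  fit <- stats::anova(stats::lm(z ~ groups))
  list(statistic = fit$`F value`[1],
       df = c(fit$Df[1], fit$Df[2]),
       p_value = fit$`Pr(>F)`[1])
}

#' Games-Howell post-hoc test
#'
#' Pairwise comparisons that assume neither equal variances nor equal group
#' sizes: Welch-type standard errors and degrees of freedom with the
#' studentized-range distribution.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector.
#' @return data.frame with columns `pair`, `diff`, `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  stopifnot(k >= 2L)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    t_stat <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(t_stat * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(lev[i], lev[j], sep = "-"),
      diff = unname(m[i] - m[j]), p = unname(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

posthoc_table <- function(values, groups, method) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) return(NULL)
  if (method == "games_howell") return(games_howell(values, groups))
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    return(data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  # bonferroni
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pw$p.value
  rows <- list()
  for (r in rownames(pm)) for (cc in colnames(pm)) {
    if (!is.na(pm[r, cc])) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(cc, r, sep = "-"),
        diff = mean(values[groups == cc]) - mean(values[groups == r]),
        p = pm[r, cc], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Greenhouse-Geisser / Huynh-Feldt epsilons from the residual SSP of the
# within-subject contrasts (orthonormal basis orthogonal to the intercept);
# same quantities base R prints in the anova.mlm heading.
sphericity_epsilons <- function(fit, p) {
  ssd <- stats::SSD(fit)
  C <- qr.Q(qr(stats::contr.helmert(p)))  # p x (p-1), orthonormal
  S <- t(C) %*% (ssd$SSD / ssd$df) %*% C
  pp <- p - 1L
  lambda <- Re(eigen(S, only.values = TRUE)$values)
  gg <- sum(lambda)^2 / sum(lambda^2) / pp
  n <- ssd$df
  hf <- ((n + 1) * pp * gg - 2) / (pp * (n - pp * gg))
  list(gg = gg, hf = min(1, hf))
}

#' Two-way mixed ANOVA across the dark-adapted flash series
#'
#' Between-subject factor: genotype; within-subject repeated factor: flash
#' strength. Sphericity of the within-subject covariance is assessed with
#' Mauchly's test; on violation the Greenhouse-Geisser correction is applied
#' for severe departures (GG epsilon < 0.75) and Huynh-Feldt otherwise.
#' Post-hoc genotype comparisons (on subject means across strengths) use
#' Bonferroni after a sphericity correction and Tukey otherwise. Subjects
#' with incomplete flash series raise an error — no imputation.
#'
#' @param measures Measures data.frame (from [quantify_cohort()]), containing
#'   at least two genotypes.
#' @param parameter Parameter to analyse (`b_amp`, `a_amp`, `op_amp`, `a_it`,
#'   `b_it`).
#' @param unit Analysis unit, "eye" or "animal".
#' @param alpha Significance level of the sphericity test (default 0.05).
#' @param epsilon_severe GG-epsilon threshold below which a violation counts
#'   as severe (default 0.75).
#' @return Object of class `erg_comparison`: design `two_way_mixed`, the
#'   genotype / within / interaction p-values, the sphericity and correction
#'   trail, and the post-hoc table.
#' @export
compare_groups_da <- function(measures, parameter = "b_amp",
                              unit = c("eye", "animal"), alpha = 0.05,
                              epsilon_severe = 0.75) {
  unit <- match.arg(unit)
  df <- extract_parameter(measures, parameter, unit)
  df <- df[!is.na(df$value), , drop = FALSE]
  if (length(unique(df$genotype)) < 2L) {
    stop("need at least two genotypes", call. = FALSE)
  }
  df$subject <- paste(df$animal_id, df$eye_id, sep = "/")
  strengths <- sort(unique(df$flash_strength))
  wide <- stats::reshape(df[, c("subject", "genotype", "flash_strength",
                                "value")],
                         idvar = c("subject", "genotype"),
                         timevar = "flash_strength", direction = "wide")
  ycols <- paste0("value.", strengths)
  if (anyNA(wide[, ycols])) {
    stop("incomplete within-subject flash series; no imputation is performed",
         call. = FALSE)
  }
  Y <- as.matrix(wide[, ycols])
  genotype <- factor(wide$genotype)
  # between-subject effect on the subject means across strengths
  between <- stats::anova(stats::lm(rowMeans(Y) ~ genotype))
  p_genotype <- between$`Pr(>F)`[1]
  # within-subject effects from the multivariate fit
  fit <- stats::lm(Y ~ genotype)
  idata <- data.frame(strength = factor(strengths))
  av <- stats::anova(fit, X = ~1, idata = idata, test = "Spherical")
  tab <- av[, , drop = FALSE]
  mt <- stats::mauchly.test(fit, X = ~1, idata = idata)
  eps <- sphericity_epsilons(fit, length(strengths))
  eps_gg <- eps$gg
  eps_hf <- eps$hf
  violated <- is.finite(mt$p.value) && mt$p.value < alpha
  correction <- "none"
  p_col <- "Pr(>F)"
  if (violated) {
    if (eps_gg < epsilon_severe) {
      correction <- "greenhouse_geisser"; p_col <- "G-G Pr"
    } else {
      correction <- "huynh_feldt"; p_col <- "H-F Pr"
    }
  }
  p_within <- tab[[p_col]][rownames(tab) == "(Intercept)"]
  p_inter <- tab[[p_col]][rownames(tab) == "genotype"]
  posthoc_method <- if (correction == "none") "tukey" else "bonferroni"
  structure(
    list(design = "two_way_mixed", parameter = parameter, unit = unit,
         p_genotype = p_genotype, p_within = p_within,
         p_interaction = p_inter,
         sphericity_p = unname(mt$p.value),
         epsilon_gg = unname(eps_gg), epsilon_hf = unname(eps_hf),
         correction = correction, posthoc_method = posthoc_method,
         posthoc = posthoc_table(rowMeans(Y), genotype, posthoc_method),
         n_subjects = nrow(Y)),
    class = "erg_comparison"
  )
}

#' One-way group comparison for the single-flash light-adapted condition
#'
#' Levene's test (Brown-Forsythe) decides the path: with homogeneous
#' variances a classical one-way ANOVA with Tukey post-hoc; on heterogeneity
#' the Welch-corrected ANOVA with Games-Howell post-hoc.
#'
#' @param measures Measures data.frame containing LA rows for >= 2 genotypes.
#' @param parameter `la_b_amp` (default) or `la_b_it`.
#' @param unit Analysis unit.
#' @param alpha Significance level of the Levene test.
#' @return An `erg_comparison` with design `one_way`.
#' @export
compare_groups_la <- function(measures, parameter = "la_b_amp",
                              unit = c("eye", "animal"), alpha = 0.05) {
  unit <- match.arg(unit)
  df <- extract_parameter(measures, parameter, unit)
  df <- df[!is.na(df$value), , drop = FALSE]
  groups <- factor(df$genotype)
  if (nlevels(groups) < 2L) stop("need at least two genotypes", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least two analysis units", call. = FALSE)
  }
  lev <- levene_test(df$value, groups)
  heterogeneous <- lev$p_value < alpha
  if (heterogeneous) {
    w <- stats::oneway.test(value ~ genotype, data = df, var.equal = FALSE)
    p <- w$p.value
    correction <- "welch"
    posthoc_method <- "games_howell"
  } else {
    a <- stats::anova(stats::lm(value ~ genotype, data = df))
    p <- a$`Pr(>F)`[1]
    correction <- "none"
    posthoc_method <- "tukey"
  }
  structure(
    list(design = "one_way", parameter = parameter, unit = unit,
         p_genotype = p, levene_p = lev$p_value, correction = correction,
         posthoc_method = posthoc_method,
         posthoc = posthoc_table(df$value, groups, posthoc_method),
         n_subjects = nrow(df)),
    class = "erg_comparison"
  )
}

#' @export
print.erg_comparison <- function(x, ...) {
  cat(sprintf("<erg_comparison> %s on %s (unit = %s)\n", x$design,
              x$parameter, x$unit))
  cat(sprintf("  genotype p = %.4g  [correction: %s, post-hoc: %s]\n",
              x$p_genotype, x$correction, x$posthoc_method))
  if (!is.null(x$p_within)) {
    cat(sprintf("  flash-strength p = %.4g, interaction p = %.4g\n",
                x$p_within, x$p_interaction))
  }
  invisible(x)
}
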