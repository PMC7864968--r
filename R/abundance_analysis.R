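# The quantitative Abundance Analysis.
#
# Two dimensions per (variable, compartment):
#   margin change = mean(experimental) - mean(control), interpreted with a
#   two-sample Student's t-test against a dependence-corrected threshold;
#   error-normalised fold change (ENFC) =
#     log10(mean_E / mean_C) / sqrt((a^2 + b^2) / 2),
#   with a, b the sample standard deviations of the control and
#   experimental group values on their stored (per-mille) scale.

#' Margin change between phenotype groups with a t-test p-value
#'
#' @param values_E,values_C Numeric vectors of experimental and control
#'   group values.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   classical Student test?  Default \code{FALSE}.
#' @return List \code{margin} (mean difference, experimental minus
#'   control) and \code{p} (two-tailed p-value; \code{NA} with a warning
#'   when a group has fewer than two samples).  Degenerate zero-variance
#'   cases take the limit: p = 1 for a zero margin, p = 0 otherwise.
#' @export
margin_change <- function(values_E, values_C, welch = FALSE) {
  margin <- mean(values_E) - mean(values_C)
  if (length(values_E) < 2L || length(values_C) < 2L) {
    warning("a group has fewer than 2 samples: p-value undefined",
            call. = FALSE)
    return(list(margin = margin, p = NA_real_))
  }
  if (stats::sd(values_E) == 0 && stats::sd(values_C) == 0) {
    return(list(margin = margin, p = if (margin == 0) 1 else 0))
  }
  p <- stats::t.test(values_E, values_C, var.equal = !welch)$p.value
  list(margin = margin, p = p)
}

#' Error-normalised fold change (ENFC)
#'
#' \code{log10(mean_E / mean_C) / sqrt((a^2 + b^2) / 2)}, where \code{a}
#' and \code{b} are the sample (n-1) standard deviations of the control
#' and experimental values.  The numerator is a log fold change and the
#' denominator a raw-scale propagated error; the ratio is a
#' signal-to-noise-scaled effect size.
#'
#' @param values_E,values_C Numeric vectors.
#' @return The ENFC, or \code{NA} with a warning when either group mean is
#'   not positive or the pooled standard deviation is zero (undefined).
#' @examples
#' enfc(c(9, 10, 11), c(0, 1, 2))  # log10(10)/1 = 1
#' @export
enfc <- function(values_E, values_C) {
  m_e <- mean(values_E); m_c <- mean(values_C)
  if (!is.finite(m_e) || !is.finite(m_c) || m_e <= 0 || m_c <= 0) {
    warning("ENFC undefined: non-positive group mean", call. = FALSE)
    return(NA_real_)
  }
  a <- stats::sd(values_C); b <- stats::sd(values_E)
  denom <- sqrt((a^2 + b^2) / 2)
  if (!is.finite(denom) || denom == 0) {
    warning("ENFC undefined: zero pooled standard deviation", call. = FALSE)
    return(NA_real_)
  }
  log10(m_e / m_c) / denom
}

#' Dependence-corrected per-test significance threshold
#'
#' \code{alpha / sqrt(n_variables)}: a correction for families of mutually
#' dependent variables, intermediate between no correction and Bonferroni.
#' For 586 variables at alpha = 0.05 this gives 0.0021 (2 s.f.).
#'
#' @param n_variables Number of dependent variables tested (>= 1).
#' @param alpha Nominal significance level (default 0.05).
#' @param rule \code{"sqrt"} (default) or \code{"bonferroni"}
#'   (\code{alpha / n}).
#' @return The threshold at full precision (round with
#'   \code{signif(x, 2)} for display).
#' @examples
#' signif(corrected_threshold(586), 2)  # 0.0021
#' @export
corrected_threshold <- function(n_variables, alpha = 0.05,
                                rule = c("sqrt", "bonferroni")) {
  rule <- match.arg(rule)
  if (!is.numeric(n_variables) || n_variables < 1) {
    stop("n_variables must be >= 1")
  }
  switch(rule,
         sqrt = alpha / sqrt(n_variables),
         bonferroni = alpha / n_variables)
}

#' Per-variable, per-compartment abundance comparison of two phenotypes
#'
#' For every (variable, compartment) pair, computes group means and
#' standard deviations, the margin change with its Student's t-test
#' p-value, and the ENFC, and flags significance against the corrected
#' threshold for the number of variables tested.
#'
#' The t statistics are computed vectorised; zero-variance and
#' too-few-sample cases follow the [margin_change()] conventions, and
#' variables with a non-positive mean in either group get \code{NA} ENFC
#' with a reason rather than a number.
#'
#' @param table A signal-corrected \code{lta_table}.
#' @param network A \code{compartment_network}; comparisons run over its
#'   compartments.
#' @param control,experimental Phenotype labels.
#' @param alpha Nominal significance level.
#' @param correction Threshold rule passed to [corrected_threshold()].
#' @param welch Use Welch's t-test?  Default \code{FALSE} (Student).
#' @return An \code{abundance_report}: data.frame with one row per
#'   (variable, compartment): \code{variable}, \code{compartment},
#'   \code{n_control}, \code{n_experimental}, \code{mean_control},
#'   \code{mean_experimental}, \code{sd_control}, \code{sd_experimental},
#'   \code{margin_change}, \code{t_pvalue}, \code{enfc},
#'   \code{significant}, \code{reason} (non-\code{NA} where a quantity was
#'   not computable).  The threshold used is stored in the
#'   \code{"threshold"} attribute.
#' @export
abundance_report <- function(table, network, control, experimental,
                             alpha = 0.05,
                             correction = c("sqrt", "bonferroni"),
                             welch = FALSE) {
  stopifnot(inherits(table, "lta_table"),
            inherits(network, "compartment_network"))
  if (!table$corrected) {
    warning("table is not signal-corrected; comparing raw signals",
            call. = FALSE)
  }
  correction <- match.arg(correction)
  vars <- lta_variables(table)
  thr <- corrected_threshold(length(vars), alpha, correction)
  ph <- table$samples$phenotype
  comp <- table$samples$compartment

  out <- list()
  for (cc in network$nodes) {
    rows_c <- which(comp == cc & ph == control)
    rows_e <- which(comp == cc & ph == experimental)
    n_c <- length(rows_c); n_e <- length(rows_e)
    block <- data.frame(
      variable = vars, compartment = cc, n_control = n_c,
      n_experimental = n_e,
      mean_control = NA_real_, mean_experimental = NA_real_,
      sd_control = NA_real_, sd_experimental = NA_real_,
      margin_change = NA_real_, t_pvalue = NA_real_, enfc = NA_real_,
      significant = NA, reason = NA_character_,
      stringsAsFactors = FALSE)
    if (n_c == 0L || n_e == 0L) {
      block$reason <- "compartment absent for a phenotype"
      out[[cc]] <- block
      next
    }
    vc <- table$values[rows_c, vars, drop = FALSE]
    ve <- table$values[rows_e, vars, drop = FALSE]
    m_c <- colMeans(vc); m_e <- colMeans(ve)
    sd_c <- .col_sds(vc); sd_e <- .col_sds(ve)
    block$mean_control <- m_c; block$mean_experimental <- m_e
    block$sd_control <- sd_c; block$sd_experimental <- sd_e
    block$margin_change <- m_e - m_c
    block$t_pvalue <- .t_pvalues(m_e, m_c, sd_e, sd_c, n_e, n_c, welch)
    denom <- sqrt((sd_c^2 + sd_e^2) / 2)
    ok <- m_c > 0 & m_e > 0 & denom > 0
    block$enfc[ok] <- log10(m_e[ok] / m_c[ok]) / denom[ok]
    block$reason[!ok] <- ifelse(m_c[!ok] <= 0 | m_e[!ok] <= 0,
                                "non-positive group mean",
                                "zero pooled standard deviation")
    block$significant <- !is.na(block$t_pvalue) & block$t_pvalue < thr
    out[[cc]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  attr(res, "control") <- control
  attr(res, "experimental") <- experimental
  class(res) <- c("abundance_report", "data.frame")
  res
}

.col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
}

# Vectorised two-sample t-test p-values (Student or Welch), with
# zero-variance limits: p = 1 when the means agree, 0 otherwise.
.t_pvalues <- function(m_e, m_c, sd_e, sd_c, n_e, n_c, welch = FALSE) {
  k <- length(m_e)
  if (n_e < 2L || n_c < 2L) return(rep(NA_real_, k))
  diff <- m_e - m_c
  if (welch) {
    se2 <- sd_e^2 / n_e + sd_c^2 / n_c
    df <- se2^2 / (sd_e^4 / (n_e^2 * (n_e - 1)) +
                     sd_c^4 / (n_c^2 * (n_c - 1)))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n_e - 1) * sd_e^2 + (n_c - 1) * sd_c^2) / (n_e + n_c - 2)
    se <- sqrt(sp2 * (1 / n_e + 1 / n_c))
    df <- rep(n_e + n_c - 2, k)
  }
  p <- rep(NA_real_, k)
  zero <- !is.na(se) & se == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  ok <- !is.na(se) & se > 0
  p[ok] <- 2 * stats::pt(abs(diff[ok] / se[ok]), df[ok], lower.tail = FALSE)
  p
}

#' @export
`[.abundance_report` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.abundance_report <- function(x, ...) {
  if (is.null(attr(x, "threshold"))) return(NextMethod())
  cat("<abundance_report> ", attr(x, "control"), " vs ",
      attr(x, "experimental"), ", threshold ",
      signif(attr(x, "threshold"), 2), "\n", sep = "")
  nsig <- sum(x$significant, na.rm = TRUE)
  cat("  ", nrow(x), " (variable, compartment) comparisons, ",
      nsig, " significant\n", sep = "")
  invisible(x)
}

#' Wide ENFC matrix (variables x compartments)
#'
#' Rearranges an abundance report into the matrix used for radar-style
#' visualisation of effect sizes across the network.
#'
#' @param report An \code{abundance_report}.
#' @return Numeric matrix, rows = variables, columns = compartments.
#' @export
enfc_matrix <- function(report) {
  vars <- unique(report$variable)
  comps <- unique(report$compartment)
  m <- matrix(NA_real_, length(vars), length(comps),
              dimnames = list(vars, comps))
  m[cbind(match(report$variable, vars),
          match(report$compartment, comps))] <- report$enfc
  m
}
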