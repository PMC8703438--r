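# Gaussian fitting of interface H-bond count distributions and one-way
# ANOVA with Bonferroni post hoc comparisons for condition-level summaries.

#' Fit a Gaussian to the frequency distribution of an N_HB series
#'
#' Tabulates the integer series into unit bins and fits a scaled Gaussian
#' `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the frequencies by nonlinear
#' least squares (Levenberg-Marquardt), with initial guesses from the sample
#' moments.  The coefficient of determination is computed against the binned
#' frequencies.
#'
#' @param nhb_series integer vector of per-frame interface H-bond counts
#'   (length at least 100)
#' @return object of class `gaussian_fit`: list with `mu`, `sigma`,
#'   `amplitude`, `r_squared`, `bins` (data.frame of bin centre and
#'   frequency)
#' @export
fit_gaussian <- function(nhb_series) {
  x <- as.numeric(nhb_series)
  if (length(x) < 100L) stop("input error: need at least 100 frames")
  if (length(unique(x)) < 3L)
    stop("fit error: degenerate series (fewer than 3 distinct values); ",
         "report moment summary (mean, sd) instead")
  centre <- seq(floor(min(x)), ceiling(max(x)))
  freq <- vapply(centre, function(c0) sum(round(x) == c0), numeric(1))
  bins <- data.frame(centre = centre, freq = freq)
  start <- list(A = max(freq), mu = mean(x), sigma = max(sd(x), 0.1))
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ A * exp(-(centre - mu)^2 / (2 * sigma^2)),
                      data = bins, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: Gaussian fit failed (",
                             conditionMessage(e),
                             "); report moment summary instead"))
  cf <- coef(fit)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((freq - mean(freq))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  structure(list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
                 amplitude = unname(cf["A"]), r_squared = r2, bins = bins),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: mu = %.3f, sigma = %.3f, amplitude = %.1f, R^2 = %.4f\n",
              x$mu, x$sigma, x$amplitude, x$r_squared))
  invisible(x)
}

#' Compare conditions by one-way ANOVA with Bonferroni post hoc tests
#'
#' Classical one-way ANOVA over two or more groups of per-replicate scalars,
#' followed by pairwise t-tests (pooled SD) with Bonferroni adjustment.
#' Significance is called at p < 0.05.
#'
#' @param groups named list of two or more numeric vectors (each of length
#'   at least 2)
#' @param alpha significance level (default 0.05)
#' @return list with `f_statistic`, `p_value`, `df` (between, within),
#'   `pairwise` (data.frame: group1, group2, p_adjusted, significant),
#'   `alpha`
#' @export
compare_conditions <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  k <- length(groups); n <- length(values)
  combos <- utils::combn(names(groups), 2L)
  if (all(values == values[1])) {
    # all observations identical: no variance anywhere, nothing to test
    pairwise <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                           p_adjusted = 1, significant = FALSE,
                           stringsAsFactors = FALSE)
    return(list(f_statistic = 0, p_value = 1, df = c(k - 1L, n - k),
                pairwise = pairwise, alpha = alpha))
  }
  fit <- aov(values ~ labels)
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p_val <- tab[["Pr(>F)"]][1]
  if (is.na(f_stat)) { f_stat <- 0; p_val <- 1 }  # zero between-group SS path
  pt <- suppressWarnings(
    pairwise.t.test(values, labels, p.adjust.method = "bonferroni",
                    pool.sd = TRUE))
  p_adj <- apply(combos, 2L, function(pair) {
    p <- pt$p.value[pair[2], pair[1]]
    if (is.null(p) || is.na(p)) p <- pt$p.value[pair[1], pair[2]]
    p
  })
  p_adj[is.na(p_adj)] <- 1
  pairwise <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                         p_adjusted = as.numeric(p_adj),
                         significant = as.numeric(p_adj) < alpha,
                         stringsAsFactors = FALSE)
  list(f_statistic = f_stat, p_value = p_val, df = c(k - 1L, n - k),
       pairwise = pairwise, alpha = alpha)
}
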