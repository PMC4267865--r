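## Invasiveness models: nearest-native trait contrasts, all-subsets
## binomial GLMs with AICc model averaging, country-scale group linear
## models, nested random-intercept mixed models of plot relatedness, and
## the change-index rank-sum check.

#' Build the invasiveness design matrix with nearest-native contrasts
#'
#' One row per alien with a country-scale relatedness record.  Absolute
#' predictors: PNND, alien group, Ellenberg L/F/N/R/S, log height,
#' clonality, and primary life-form (categorical, most frequent class as
#' reference).  Difference predictors against the recorded nearest
#' native: continuous traits as native value minus alien value (height on
#' the log scale); categorical traits as a 0/1 mismatch indicator.
#' Response: invasive (0/1).  Rows with missing cells are removed
#' listwise and counted in attribute `n_excluded`.  The sign convention
#' of the continuous differences is stamped into attribute
#' `difference_convention`.
#'
#' @param species species table with trait columns (`L`, `F`, `N`, `R`,
#'   `S`, `height`, `life_form`, `clonal`).
#' @param relatedness country-scale records from [country_relatedness()].
#' @return data frame of class `phynat_design`; attribute `variables`
#'   maps model "variables" to design columns (the life-form factor
#'   counts as one variable).
#' @export
trait_contrasts <- function(species, relatedness) {
  stopifnot(all(c("species", "pnnd", "nearest_native", "invasive") %in%
                  names(relatedness)))
  al <- species[match(relatedness$species, species$species), ,
                drop = FALSE]
  nn <- species[match(relatedness$nearest_native, species$species), ,
                drop = FALSE]
  lf <- factor(al$life_form)
  if (nlevels(lf) > 1) {
    lf <- stats::relevel(lf, ref = names(which.max(table(lf))))
  }
  d <- data.frame(
    species = relatedness$species,
    invasive = as.integer(relatedness$invasive),
    pnnd = relatedness$pnnd,
    alien_group = factor(al$alien_group,
                         levels = c("archaeophyte", "neophyte")),
    L = as.numeric(al$L), F = as.numeric(al$F), N = as.numeric(al$N),
    R = as.numeric(al$R), S = as.numeric(al$S),
    log_height = log(al$height),
    clonal = as.numeric(al$clonal),
    life_form = lf,
    d_L = as.numeric(nn$L) - as.numeric(al$L),
    d_F = as.numeric(nn$F) - as.numeric(al$F),
    d_N = as.numeric(nn$N) - as.numeric(al$N),
    d_R = as.numeric(nn$R) - as.numeric(al$R),
    d_S = as.numeric(nn$S) - as.numeric(al$S),
    d_log_height = log(nn$height) - log(al$height),
    d_clonal = as.integer(nn$clonal != al$clonal),
    d_life_form = as.integer(as.character(nn$life_form) !=
                               as.character(al$life_form)),
    stringsAsFactors = FALSE)
  ok <- complete.cases(d)
  out <- d[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "difference_convention") <- "native minus alien"
  attr(out, "variables") <- setdiff(names(out), c("species", "invasive"))
  class(out) <- c("phynat_design", class(out))
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return the AICc value (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one candidate binomial GLM
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of
#' the invasive flag on a subset of design variables, returning the
#' pieces model averaging needs.  Fits showing signs of complete
#' separation (non-convergence, runaway coefficients or standard errors)
#' are flagged so the averaging stage can exclude them.
#'
#' @param design a [trait_contrasts()] design matrix (or any data frame
#'   with an `invasive` 0/1 column).
#' @param variables character vector of design column names (possibly
#'   empty: intercept-only model).
#' @param use_aicc if `FALSE`, plain AIC is stored in the `aicc` slot.
#' @return list with `variables`, `coef`, `vcov`, `loglik`, `k`, `n`,
#'   `aicc`, `separation`.
#' @export
fit_binomial_glm <- function(design, variables = character(),
                             use_aicc = TRUE) {
  stopifnot("invasive" %in% names(design))
  if (length(unique(design$invasive)) < 2) {
    stop("response has a single class")
  }
  fml <- if (length(variables)) {
    as.formula(paste("invasive ~", paste(variables, collapse = " + ")))
  } else invasive ~ 1
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = design),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  V <- vcov(fit)
  se <- sqrt(diag(V))
  sep <- !fit$converged || any(abs(cf) > 15) ||
    (warned && any(se > 50))
  k <- length(cf)
  n <- nrow(design)
  ll <- as.numeric(logLik(fit))
  list(variables = variables, coef = cf, vcov = V, loglik = ll, k = k,
       n = n,
       aicc = if (use_aicc) aicc(ll, k, n) else -2 * ll + 2 * k,
       separation = isTRUE(sep))
}

#' Enumerate candidate variable subsets
#'
#' All subsets of the candidate variables of size 0 to `max_size`
#' (the intercept-only model is always included), in deterministic order:
#' by subset size, then [utils::combn()] column order.  A categorical
#' variable is one name here and enters or leaves candidate models as a
#' unit.
#'
#' @param variables character vector of variable names.
#' @param max_size largest subset size.
#' @return list of character vectors.
#' @export
enumerate_candidates <- function(variables, max_size = 5) {
  stopifnot(max_size >= 1)
  out <- list(character())
  for (k in seq_len(min(max_size, length(variables)))) {
    cols <- combn(variables, k, simplify = FALSE)
    out <- c(out, cols)
  }
  out
}

#' AICc multimodel averaging of candidate GLMs
#'
#' Akaike weights from AICc differences over the candidate set; averaged
#' coefficients over the full set (a coefficient is treated as 0, with 0
#' variance, in models that exclude its variable — "full" averaging;
#' `conditional = TRUE` averages over containing models only).  The
#' adjusted (unconditional) standard error follows Burnham & Anderson:
#' \deqn{SE = \sqrt{\sum_i w_i (\mathrm{var}(\hat\beta_i) +
#'   (\hat\beta_i - \bar\beta)^2)}}
#' with 95% CI \eqn{\bar\beta \pm 1.96\,SE}.  Relative importance of a
#' variable is the sum of the weights of models containing it; a
#' coefficient is flagged significant when its CI excludes 0.  Fits
#' flagged for separation are excluded with a warning.
#'
#' @param fits list of [fit_binomial_glm()] results.
#' @param conditional average over containing models only.
#' @return object of class `phynat_modavg`: data frame `coefficients`
#'   (term, variable, estimate, adjusted_se, ci_lower, ci_upper,
#'   importance, significant), plus `weights`, `n_models`.
#' @export
model_average <- function(fits, conditional = FALSE) {
  ok <- !vapply(fits, function(f) isTRUE(f$separation), logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " fit(s) excluded from averaging (separation)")
    fits <- fits[ok]
  }
  if (!length(fits)) stop("no successful fits to average")
  ic <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  # map terms (coefficient names) to the variable they belong to
  terms <- unique(unlist(lapply(fits, function(f) names(f$coef))))
  all_vars <- unique(unlist(lapply(fits, `[[`, "variables")))
  term_var <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return("(Intercept)")
    hit <- all_vars[vapply(all_vars, function(v) startsWith(tm, v),
                           logical(1))]
    if (!length(hit)) return(tm)
    hit[which.max(nchar(hit))]
  }, character(1))
  rows <- lapply(terms, function(tm) {
    b <- vapply(fits, function(f) {
      if (tm %in% names(f$coef)) unname(f$coef[tm]) else 0
    }, numeric(1))
    v <- vapply(fits, function(f) {
      if (tm %in% names(f$coef)) f$vcov[tm, tm] else 0
    }, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(f$coef), logical(1))
    if (conditional) {
      wc <- w[has] / sum(w[has])
      est <- sum(wc * b[has])
      se <- sqrt(sum(wc * (v[has] + (b[has] - est)^2)))
    } else {
      est <- sum(w * b)
      se <- sqrt(sum(w * (v + (b - est)^2)))
    }
    imp <- sum(w[vapply(fits, function(f) {
      term_var[[tm]] %in% f$variables
    }, logical(1))])
    if (tm == "(Intercept)") imp <- 1
    data.frame(term = tm, variable = unname(term_var[[tm]]),
               estimate = est, adjusted_se = se,
               ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
               importance = imp, stringsAsFactors = FALSE)
  })
  coefs <- do.call(rbind, rows)
  coefs$significant <- coefs$ci_lower > 0 | coefs$ci_upper < 0
  out <- list(coefficients = coefs, weights = w, n_models = length(fits),
              conditional = conditional)
  class(out) <- "phynat_modavg"
  out
}

#' @export
print.phynat_modavg <- function(x, ...) {
  cat(sprintf("Model-averaged coefficients over %d candidate models (%s average)\n",
              x$n_models, if (x$conditional) "conditional" else "full"))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' All-subsets model-averaged invasiveness model
#'
#' Convenience wrapper: enumerate candidate subsets of up to `max_size`
#' variables, fit each binomial GLM, and average.
#'
#' @param design a [trait_contrasts()] design matrix.
#' @param variables candidate variable names (default: all design
#'   variables).
#' @param max_size cap on variables per candidate model.
#' @param use_aicc use AICc (default) or plain AIC.
#' @param conditional see [model_average()].
#' @return a `phynat_modavg` object.
#' @export
invasiveness_model <- function(design,
                               variables = attr(design, "variables"),
                               max_size = 5, use_aicc = TRUE,
                               conditional = FALSE) {
  cand <- enumerate_candidates(variables, max_size)
  fits <- lapply(cand, function(v) {
    fit_binomial_glm(design, v, use_aicc = use_aicc)
  })
  model_average(fits, conditional = conditional)
}

#' Country-scale group comparison of PNND and MPD
#'
#' Two-group linear model (pooled-variance t test) of each relatedness
#' metric on invasiveness.
#'
#' @param records country-scale records from [country_relatedness()].
#' @param responses metric columns to test.
#' @return data frame: `response`, `t`, `df1`, `df2`, `p`,
#'   `mean_invasive`, `mean_noninvasive`.
#' @export
country_group_lm <- function(records, responses = c("pnnd", "mpd")) {
  g <- records$invasive
  if (sum(g) < 2 || sum(!g) < 2) {
    stop("each invasiveness group needs at least 2 species")
  }
  rows <- lapply(responses, function(resp) {
    yv <- records[[resp]]
    fit <- lm(yv ~ g)
    sm <- summary(fit)$coefficients
    data.frame(response = resp, t = sm["gTRUE", "t value"],
               df1 = 1, df2 = length(yv) - 2,
               p = sm["gTRUE", "Pr(>|t|)"],
               mean_invasive = mean(yv[g]),
               mean_noninvasive = mean(yv[!g]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nested random-intercept model of plot-scale relatedness
#'
#' REML fit of `response ~ invasiveness + (1 | species/square)`: a fixed
#' invasiveness effect with random intercepts for species and for square
#' within species, accounting for repeated occurrences of the same alien
#' across plots and squares.  Group means are estimated directly by
#' fitting the cell-means parameterization (`~ 0 + group`) so each
#' invasiveness class gets an estimate and standard error.
#'
#' @param records plot-scale records from [plot_relatedness()].
#' @param response `"pnnd"` or `"mpd"`.
#' @return list of class `phynat_lmm`: `means` (group, estimate, se),
#'   `varcomp` (species, square-in-species, residual variances),
#'   `reml_loglik`, `converged`, `messages`, and the `lme4` `fit`.
#' @export
fit_nested_lmm <- function(records, response = c("pnnd", "mpd")) {
  response <- match.arg(response)
  d <- data.frame(y = records[[response]],
                  group = factor(ifelse(records$invasive, "invasive",
                                        "non-invasive"),
                                 levels = c("invasive", "non-invasive")),
                  species = records$species, square = records$square,
                  stringsAsFactors = FALSE)
  if (length(unique(d$species[d$group == "invasive"])) < 2 ||
      length(unique(d$species[d$group == "non-invasive"])) < 2) {
    stop("each group needs at least 2 species")
  }
  fit <- lme4::lmer(y ~ 0 + group + (1 | species / square), data = d,
                    REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(nm) {
    i <- which(vc$grp == nm)
    if (length(i)) vc$vcov[i[1]] else NA_real_
  }
  sm <- summary(fit)$coefficients
  out <- list(
    means = data.frame(group = sub("^group", "", rownames(sm)),
                       estimate = sm[, "Estimate"],
                       se = sm[, "Std. Error"], row.names = NULL,
                       stringsAsFactors = FALSE),
    varcomp = data.frame(component = c("species", "square_in_species",
                                       "residual"),
                         variance = c(var_of("species"),
                                      var_of("square:species"),
                                      vc$vcov[vc$grp == "Residual"]),
                         stringsAsFactors = FALSE),
    reml_loglik = as.numeric(logLik(fit)),
    converged = is.null(msgs),
    messages = msgs,
    fit = fit)
  class(out) <- "phynat_lmm"
  out
}

#' @export
print.phynat_lmm <- function(x, ...) {
  cat("Nested random-intercept model (REML)\n")
  print(x$means, digits = 4, row.names = FALSE)
  cat("variance components:\n")
  print(x$varcomp, digits = 4, row.names = FALSE)
  if (!x$converged) cat("convergence messages:",
                        paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of change indices
#'
#' Rank-sum test (mid-ranks for ties) that invasive aliens increased
#' more in range than non-invasive aliens.  Exact enumeration is used
#' for small untied samples (`min(n1, n2) <= 8`); otherwise the normal
#' approximation with tie correction.
#'
#' @param x change indices of the first group (e.g. invasive aliens).
#' @param y change indices of the second group.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list of class `phynat_wilcoxon`: `W`, `p`, `n1`, `n2`,
#'   `alternative`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- min(length(x), length(y)) <= 8 &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  out <- list(W = unname(ht$statistic), p = ht$p.value, n1 = length(x),
              n2 = length(y), alternative = alternative)
  class(out) <- "phynat_wilcoxon"
  out
}

#' @export
print.phynat_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %.1f, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$W, x$p, x$n1, x$n2, x$alternative))
  invisible(x)
}
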